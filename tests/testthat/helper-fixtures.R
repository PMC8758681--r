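# Shared test helpers: small builders and independent brute-force oracles.

make_bins <- function(values, chromosome = "chr1", width = 100) {
  n <- length(values)
  data.frame(chromosome = rep(chromosome, n),
             start = (seq_len(n) - 1L) * width,
             end = seq_len(n) * width,
             log2_ratio = values,
             stringsAsFactors = FALSE)
}

# Planted NMF factors with anchor features/regions so the factorization is
# identifiable (pure random dense factors are recoverable only up to rotation).
planted_nmf_factors <- function(n_features = 18, n_regions = 30, rank = 4) {
  W0 <- matrix(runif(n_features * rank, 0, 0.2), n_features, rank)
  anchors <- split(seq_len(n_features),
                   rep_len(seq_len(rank), n_features))
  for (j in seq_len(rank)) W0[anchors[[j]], j] <- runif(length(anchors[[j]]), 1, 2)
  H0 <- matrix(runif(rank * n_regions, 0, 0.2), rank, n_regions)
  anchor_cols <- split(seq_len(n_regions), rep_len(seq_len(rank), n_regions))
  for (j in seq_len(rank)) {
    H0[j, anchor_cols[[j]]] <- runif(length(anchor_cols[[j]]), 1, 2)
  }
  list(W = W0, H = H0)
}

toy_profile <- function(values, bins = c(10, 30, 60), id = "R") {
  stops <- cumsum(bins) * 100
  starts <- c(0, stops[-length(stops)])
  segment_profile("chr1", starts, stops, values, bins, region_id = id)
}

# Brute-force multi-region segmentation: enumerate every breakpoint subset on
# one chromosome and minimize SSE + gamma * breakpoints directly.
brute_segment <- function(values_by_region, gamma) {
  y <- do.call(rbind, values_by_region)
  n <- ncol(y)
  cuts <- n - 1L
  best <- Inf
  best_breaks <- NULL
  for (mask in 0:(2^cuts - 1L)) {
    breaks <- which(bitwAnd(mask, 2^(0:(cuts - 1L))) > 0)
    bounds <- c(0L, breaks, n)
    sse <- 0
    for (s in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      seg <- y[, idx, drop = FALSE]
      sse <- sse + sum(sweep(seg, 1L, rowMeans(seg))^2)
    }
    obj <- sse + gamma * length(breaks)
    if (obj < best - 1e-12) {
      best <- obj
      best_breaks <- breaks
    }
  }
  list(objective = best, breaks = best_breaks)
}

segmentation_objective <- function(seg, bins_by_region) {
  sse <- 0
  for (r in rownames(seg$means)) {
    b <- bins_by_region[[r]]
    for (s in seq_len(nrow(seg$segments))) {
      idx <- b$chromosome == seg$segments$chromosome[s] &
        b$start >= seg$segments$start[s] & b$end <= seg$segments$end[s]
      sse <- sse + sum((b$log2_ratio[idx] - seg$means[r, s])^2)
    }
  }
  n_chrom <- length(unique(seg$segments$chromosome))
  sse + seg$gamma * (nrow(seg$segments) - n_chrom)
}

# phangorn-based parsimony oracle: the diploid root constraint is modelled by
# an extra all-neutral taxon adjacent to the in-group root.
phangorn_score <- function(topology_newick, matrix) {
  chars <- matrix
  chars[is.na(chars)] <- "?"
  chars <- rbind(chars, diploid = rep("0", ncol(matrix)))
  dat <- phangorn::phyDat(chars, type = "USER", levels = c("-1", "0", "1"),
                          ambiguity = "?")
  tr <- ape::read.tree(text = topology_newick)
  phangorn::parsimony(tr, dat)
}

nested_to_newick <- function(topo) {
  fmt <- function(t) {
    if (!is.list(t)) return(t)
    paste0("(", fmt(t[[1]]), ",", fmt(t[[2]]), ")")
  }
  paste0("(", fmt(topo), ",diploid);")
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
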
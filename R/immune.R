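# Compartmentalized immune-cell densities, decile regularization, rank-4 NMF
# into meta-markers, and immune-state assignment.

.imm_cell_types <- c("BC", "TC", "TREG")
.imm_states_prolif <- c("p", "np", "t")
.imm_compartments <- c("Epi", "Str")

#' The 18 density feature names
#'
#' {B-cells, T-cells, T-regs} x {Ki67+ (p), Ki67- (np), total (t)} x
#' {epithelium (Epi), stroma (Str)}, e.g. `TC_p_Epi`.
#'
#' @return Character vector of 18 feature names.
#' @export
immune_feature_names <- function() {
  as.vector(outer(.imm_cell_types, outer(.imm_states_prolif, .imm_compartments,
                                         paste, sep = "_"),
                  paste, sep = "_"))
}

#' Compute the regions x 18 density matrix from cell tables
#'
#' For every region, counts phenotyped cells per compartment and divides by
#' the compartment area, yielding cells/mm2 for each of the 18 features.
#' Absent cell types yield density 0, never missing. By default T-regs
#' (CD3+/FOXP3+) are excluded from the T-cell feature so the features stay
#' non-redundant; set `tregs_in_tc = TRUE` to count them in both.
#'
#' @param cells Data frame with columns `region_id`, `phenotype` (one of
#'   `"T-cell"`, `"B-cell"`, `"T-reg"`, `"epithelial"`, `"other"`), `ki67`
#'   (`"positive"`/`"negative"`) and `compartment`
#'   (`"epithelium"`/`"stroma"`); `x`/`y` positions may be present but are not
#'   used for densities.
#' @param areas Data frame with columns `region_id`, `epithelium_mm2`,
#'   `stroma_mm2` (both > 0).
#' @param tregs_in_tc Count T-regs inside the T-cell features as well.
#' @return Numeric matrix, rows = regions (in `areas` order), columns =
#'   [immune_feature_names()].
#' @export
compute_density_matrix <- function(cells, areas, tregs_in_tc = FALSE) {
  stopifnot(is.data.frame(cells), is.data.frame(areas))
  if (!all(c("region_id", "epithelium_mm2", "stroma_mm2") %in% names(areas))) {
    stop("areas needs region_id, epithelium_mm2, stroma_mm2")
  }
  if (any(areas$epithelium_mm2 <= 0) || any(areas$stroma_mm2 <= 0)) {
    stop("compartment areas must be positive")
  }
  pheno_ok <- c("T-cell", "B-cell", "T-reg", "epithelial", "other")
  if (nrow(cells) > 0L) {
    if (!all(cells$phenotype %in% pheno_ok)) stop("unknown phenotype value")
    if (!all(cells$compartment %in% c("epithelium", "stroma"))) {
      stop("unknown compartment value")
    }
    if (!all(cells$ki67 %in% c("positive", "negative"))) stop("unknown ki67 value")
  }

  features <- immune_feature_names()
  out <- matrix(0, nrow = nrow(areas), ncol = length(features),
                dimnames = list(areas$region_id, features))
  pheno_of <- c(BC = "B-cell", TC = "T-cell", TREG = "T-reg")
  comp_of <- c(Epi = "epithelium", Str = "stroma")
  for (i in seq_len(nrow(areas))) {
    rc <- cells[cells$region_id == areas$region_id[i], , drop = FALSE]
    for (ct in .imm_cell_types) {
      is_type <- rc$phenotype == pheno_of[[ct]]
      if (ct == "TC" && tregs_in_tc) is_type <- is_type | rc$phenotype == "T-reg"
      for (cp in .imm_compartments) {
        area <- if (cp == "Epi") areas$epithelium_mm2[i] else areas$stroma_mm2[i]
        sel <- is_type & rc$compartment == comp_of[[cp]]
        n_p <- sum(sel & rc$ki67 == "positive")
        n_np <- sum(sel & rc$ki67 == "negative")
        out[i, paste(ct, "p", cp, sep = "_")] <- n_p / area
        out[i, paste(ct, "np", cp, sep = "_")] <- n_np / area
        out[i, paste(ct, "t", cp, sep = "_")] <- (n_p + n_np) / area
      }
    }
  }
  out
}

#' Regularize densities into distribution deciles
#'
#' Maps each feature column to integer decile scores 1..10 of its empirical
#' distribution across regions: `ceiling(10 * rank / n)` with average ranks
#' for ties, so a constant feature maps to a single shared decile and any
#' monotone transform of a feature leaves its scores unchanged. This is the
#' regularization applied before the NMF so features on very different
#' density scales contribute comparably.
#'
#' @param matrix Regions x features numeric matrix (>= 2 regions).
#' @return Integer matrix of the same shape with values in 1..10.
#' @export
decile_regularize <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L) stop("need at least 2 regions")
  n <- nrow(matrix)
  out <- apply(matrix, 2L, function(v) {
    as.integer(ceiling(10 * rank(v, ties.method = "average") / n))
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Factorize decile scores into meta-markers by NMF
#'
#' Non-negative matrix factorization of the features x regions score matrix
#' into `W` (features x rank, the meta-marker compositions) and `H`
#' (rank x regions, the per-region meta-marker values), minimizing the
#' Frobenius reconstruction error with Lee-Seung multiplicative updates. The
#' best of `n_restarts` seeded random initializations is kept; `W` columns are
#' normalized to unit maximum with compensating scaling of `H`, and columns
#' are ordered by decreasing total H weight so MM1..MM4 labels are
#' deterministic given the seed.
#'
#' @param scores Regions x features matrix (e.g. from [decile_regularize()]);
#'   transposed internally.
#' @param rank Factorization rank (default 4 meta-markers).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_restarts Number of random initializations (default 10).
#' @param max_iter Maximum multiplicative updates per restart.
#' @param tol Relative loss-change convergence tolerance.
#' @return A `metamarker_model`: list with `W` (features x rank, columns
#'   MM1..), `H` (rank x regions), `loss` (final squared Frobenius error),
#'   `loss_history` of the winning restart, `seed`, `iterations`.
#' @export
factorize_densities <- function(scores, rank = 4L, seed, n_restarts = 10L,
                                max_iter = 500L, tol = 1e-9) {
  V <- t(as.matrix(scores))  # features x regions
  if (any(V < 0)) stop("scores must be non-negative")
  if (missing(seed)) stop("seed is required")
  if (rank > min(dim(V))) stop("rank exceeds matrix dimensions")
  eps <- .Machine$double.eps

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(nrow(V) * rank, 0.1, 1), nrow(V), rank)
    H <- matrix(stats::runif(rank * ncol(V), 0.1, 1), rank, ncol(V))
    hist <- numeric(0)
    loss <- sum((V - W %*% H)^2)
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W) %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
      new_loss <- sum((V - W %*% H)^2)
      hist <- c(hist, new_loss)
      if (loss - new_loss < tol * max(loss, 1)) {
        loss <- new_loss
        break
      }
      loss <- new_loss
    }
    if (is.null(best) || loss < best$loss) {
      best <- list(W = W, H = H, loss = loss, loss_history = hist,
                   iterations = length(hist))
    }
  }

  W <- best$W; H <- best$H
  scale <- apply(W, 2L, max)
  scale[scale == 0] <- 1
  W <- sweep(W, 2L, scale, "/")
  H <- sweep(H, 1L, scale, "*")
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  colnames(W) <- rownames(H) <- paste0("MM", seq_len(rank))
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)

  structure(list(W = W, H = H, loss = best$loss,
                 loss_history = best$loss_history, seed = seed,
                 iterations = best$iterations, rank = rank),
            class = "metamarker_model")
}

#' @export
print.metamarker_model <- function(x, ...) {
  cat(sprintf("metamarker_model: %d features x %d regions, rank %d, loss %.4g (seed %d)\n",
              nrow(x$W), ncol(x$H), x$rank, x$loss, x$seed))
  invisible(x)
}

#' Assign immune states from the meta-marker H matrix
#'
#' Hierarchically clusters the regions (columns of H; Euclidean distance,
#' Ward linkage) and cuts at `k = 3`, then names the clusters from their mean
#' meta-marker profile: the cluster with maximal mean MM4 is `Excluded`
#' (stroma-restricted lymphocytes), of the remainder the cluster with maximal
#' mean MM2 is `Active` (ubiquitous high T-cells), and the last is
#' `Suppressed` (low T-cells, elevated B-cells/T-regs).
#'
#' @param model A `metamarker_model` (needs MM2 and MM4 rows, i.e. rank >= 4).
#' @param k Number of states (default and intended value 3).
#' @return Named character vector: region -> state label.
#' @export
assign_immune_states <- function(model, k = 3L) {
  stopifnot(inherits(model, "metamarker_model"))
  H <- model$H
  if (nrow(unique(t(H))) < k) stop("H has fewer than k distinct columns")
  hc <- stats::hclust(stats::dist(t(H)), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)

  mm_mean <- function(mm, cluster) mean(H[mm, cl == cluster])
  clusters <- sort(unique(cl))
  excluded <- clusters[which.max(vapply(clusters, function(c) mm_mean("MM4", c),
                                        numeric(1L)))]
  rest <- setdiff(clusters, excluded)
  active <- rest[which.max(vapply(rest, function(c) mm_mean("MM2", c),
                                  numeric(1L)))]
  suppressed <- setdiff(rest, active)

  labels <- character(length(clusters))
  labels[clusters == excluded] <- "Excluded"
  labels[clusters == active] <- "Active"
  labels[clusters %in% suppressed] <- "Suppressed"
  out <- labels[match(cl, clusters)]
  names(out) <- colnames(H)
  out
}

#' Stroma/epithelium density ratios per cell type
#'
#' For each region and cell type (total densities), the ratio of stromal to
#' epithelial density, a flag for unbounded ratios (stromal cells present,
#' epithelium empty), and a `high`/`low`/`none` category: `none` when both
#' compartments are empty, otherwise split at the per-cell-type median of the
#' nonzero epithelial densities (a reimplementation choice; the split rule is
#' configurable by recomputing from the returned densities).
#'
#' @param densities Regions x 18 density matrix (see
#'   [compute_density_matrix()]).
#' @return Data frame with columns `region_id`, `cell_type`, `epithelial`,
#'   `stromal`, `ratio` (NA when unbounded or undefined), `unbounded`,
#'   `category`.
#' @export
compartment_ratio <- function(densities) {
  densities <- as.matrix(densities)
  rows <- list()
  for (ct in .imm_cell_types) {
    epi <- densities[, paste0(ct, "_t_Epi")]
    str_ <- densities[, paste0(ct, "_t_Str")]
    nonzero <- epi[epi > 0]
    split <- if (length(nonzero) > 0L) stats::median(nonzero) else NA_real_
    category <- ifelse(epi == 0 & str_ == 0, "none",
                       ifelse(!is.na(split) & epi >= split, "high", "low"))
    ratio <- ifelse(epi > 0, str_ / epi, NA_real_)
    rows[[ct]] <- data.frame(
      region_id = rownames(densities),
      cell_type = ct,
      epithelial = unname(epi),
      stromal = unname(str_),
      ratio = unname(ratio),
      unbounded = unname(epi == 0 & str_ > 0),
      category = unname(category),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
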
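# Seeded generators that plant known truth with the statistical structure the
# analysis stages assume: multi-region copy-ratio bins from a clonal event
# tree, tumor-only variant tables with germline/somatic/artifact classes, and
# immune-cell density cohorts drawn from three state archetypes. All
# generators are pure functions of (spec, seed).

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Specification of a clonal copy-number simulation
#'
#' Defines a planted clonal history: a rooted binary tree over the regions
#' whose branches (including the trunk from the diploid ancestor) each carry
#' `events_per_branch` copy-number events — genome intervals shifted by
#' `magnitude` log2 units in every descendant region. Bin values are the sum
#' of ancestral event shifts plus Gaussian noise of sd `sigma`. Defaults: loss
#' events of -0.8 log2 units (clearing the -0.6 loss threshold under sigma =
#' 0.1 noise), 20-bin events on a 700-bin chromosome.
#'
#' @param n_regions Number of regions (tree leaves), 2..8.
#' @param n_bins Bins on the simulated chromosome.
#' @param bin_width Bin width in base pairs.
#' @param sigma Gaussian bin-noise standard deviation (>= 0).
#' @param magnitude Log2 shift of each event (negative = loss).
#' @param events_per_branch Events planted on every branch.
#' @param event_bins Width of each event in bins (>= the usual 12-probe
#'   character cutoff so planted events survive discretization).
#' @param topology Optional nested-list topology over `R1..Rn`; random when
#'   NULL.
#' @param seed Integer seed.
#' @return A `clonal_sim_spec` list.
#' @export
clonal_sim_spec <- function(n_regions = 4L, n_bins = 700L, bin_width = 1e5,
                            sigma = 0.1, magnitude = -0.8,
                            events_per_branch = 3L, event_bins = 20L,
                            topology = NULL, seed = 1L) {
  if (n_regions < 2L || n_regions > 8L) stop("n_regions must be in 2..8")
  if (sigma < 0) stop("sigma must be >= 0")
  n_branches <- 2L * n_regions - 1L
  need <- n_branches * events_per_branch * (event_bins + 10L)
  if (need > n_bins) {
    stop("n_bins too small for the requested events: need at least ", need)
  }
  structure(list(n_regions = as.integer(n_regions), n_bins = as.integer(n_bins),
                 bin_width = bin_width, sigma = sigma, magnitude = magnitude,
                 events_per_branch = as.integer(events_per_branch),
                 event_bins = as.integer(event_bins), topology = topology,
                 seed = as.integer(seed)),
            class = "clonal_sim_spec")
}

.random_topology <- function(leaves) {
  topo <- list(leaves[1L], leaves[2L])
  for (k in seq_along(leaves)[-(1:2)]) {
    n_edges <- 2L * (k - 1L) - 1L
    topo <- .insert_edge(topo, leaves[k], sample.int(n_edges, 1L))
  }
  topo
}

#' Simulate multi-region copy-ratio bins from a planted clonal tree
#'
#' Draws the planted tree and per-branch events of `spec`, then emits one bin
#' table per region whose log2 values are the summed ancestral event shifts
#' plus Gaussian noise. Events never overlap (each bin is affected by at most
#' one event), so with `sigma = 0` the pipeline
#' `discretize(joint_segment(bins))` reproduces the planted character matrix
#' exactly.
#'
#' @param spec A [clonal_sim_spec()].
#' @return List with `bins` (named list of per-region bin data frames) and
#'   `truth`: `topology`, `newick` (canonical, comparable to
#'   [build_mp_tree()]'s `$newick`), `events` (data frame: branch child label,
#'   bin interval, coordinates, log2 shift), `segments` (the induced noise-free
#'   segmentation), `means` (regions x segments noise-free values) and
#'   `character_matrix` (the planted characters under default discretization).
#' @export
simulate_clonal_cna <- function(spec) {
  stopifnot(inherits(spec, "clonal_sim_spec"))
  .with_seed(spec$seed, {
    leaves <- paste0("R", seq_len(spec$n_regions))
    topo <- if (is.null(spec$topology)) .random_topology(leaves) else
      .as_topology(spec$topology)
    nd <- .tree_nodes(topo)
    n_nodes <- length(nd$label)
    branch_ids <- 2:n_nodes  # child node of each branch; 2 = trunk

    # non-overlapping event placement: one event per equal-width block,
    # shuffled over branches
    n_events <- length(branch_ids) * spec$events_per_branch
    block <- spec$n_bins %/% n_events
    min_gap <- 10L  # keeps adjacent induced segments from merging at small gamma
    if (spec$event_bins + min_gap > block) stop("events do not fit their blocks")
    starts <- (seq_len(n_events) - 1L) * block + min_gap +
      sample.int(block - spec$event_bins - min_gap + 1L, n_events,
                 replace = TRUE) - 1L
    owner <- sample(rep(branch_ids, spec$events_per_branch))
    events <- data.frame(
      branch = ifelse(nd$label[owner] == "", paste0("node", owner),
                      nd$label[owner]),
      branch_id = owner,
      bin_start = starts + 1L,
      bin_end = starts + spec$event_bins,
      shift = spec$magnitude,
      stringsAsFactors = FALSE
    )
    events$start <- (events$bin_start - 1L) * spec$bin_width
    events$end <- events$bin_end * spec$bin_width

    # ancestral branch sets per leaf
    path_to_root <- function(id) {
      out <- integer(0)
      while (!is.na(nd$parent[id])) {
        out <- c(out, id)
        id <- nd$parent[id]
      }
      out
    }
    leaf_ids <- which(nd$label %in% leaves)
    signal <- matrix(0, nrow = length(leaves), ncol = spec$n_bins,
                     dimnames = list(leaves, NULL))
    for (li in leaf_ids) {
      anc <- path_to_root(li)
      for (e in which(events$branch_id %in% anc)) {
        idx <- events$bin_start[e]:events$bin_end[e]
        signal[nd$label[li], idx] <- signal[nd$label[li], idx] + events$shift[e]
      }
    }

    # induced noise-free segmentation: maximal runs of constant region vectors
    changes <- which(colSums(abs(signal[, -1L, drop = FALSE] -
                                   signal[, -spec$n_bins, drop = FALSE])) > 0)
    seg_start <- c(1L, changes + 1L)
    seg_end <- c(changes, spec$n_bins)
    segments <- data.frame(
      chromosome = "chr1",
      start = (seg_start - 1L) * spec$bin_width,
      end = seg_end * spec$bin_width,
      n_bins = seg_end - seg_start + 1L,
      stringsAsFactors = FALSE
    )
    means <- vapply(seq_along(seg_start), function(s) {
      signal[, seg_start[s], drop = TRUE]
    }, numeric(length(leaves)))
    if (is.null(dim(means))) means <- matrix(means, nrow = length(leaves))
    rownames(means) <- leaves
    colnames(means) <- sprintf("%s:%d-%d", segments$chromosome,
                               segments$start, segments$end)

    params <- discretization_params()
    keep <- segments$n_bins >= params$min_probes
    cmat <- matrix(NA_integer_, nrow = nrow(means), ncol = sum(keep),
                   dimnames = list(leaves, colnames(means)[keep]))
    mk <- means[, keep, drop = FALSE]
    cmat[mk < params$loss_below] <- -1L
    cmat[mk >= params$neutral_low & mk <= params$neutral_high] <- 0L
    class(cmat) <- c("character_matrix", class(cmat))

    bins <- lapply(leaves, function(r) {
      data.frame(
        chromosome = "chr1",
        start = (seq_len(spec$n_bins) - 1L) * spec$bin_width,
        end = seq_len(spec$n_bins) * spec$bin_width,
        log2_ratio = signal[r, ] + stats::rnorm(spec$n_bins, 0, spec$sigma),
        stringsAsFactors = FALSE
      )
    })
    names(bins) <- leaves

    list(bins = bins,
         truth = list(topology = topo,
                      newick = paste0("(", .canon(topo), ")diploid_ancestor;"),
                      events = events, segments = segments, means = means,
                      character_matrix = cmat))
  })
}

#' Specification of a synthetic tumor-only variant table
#'
#' @param n_germline Planted common germline records: good quality, VAF near
#'   0.5 or near 1, population allele frequency above 1e-3 and carrier counts
#'   above 9.
#' @param n_somatic Planted somatic records: good quality,
#'   VAF ~ Uniform(0.1, 0.4), no population annotation.
#' @param n_artifact Planted artifacts: each fails one random quality
#'   threshold, or is recurrent in the pool of normals.
#' @param seed Integer seed.
#' @return A `variant_sim_spec` list.
#' @export
variant_sim_spec <- function(n_germline = 40L, n_somatic = 30L,
                             n_artifact = 30L, seed = 1L) {
  structure(list(n_germline = as.integer(n_germline),
                 n_somatic = as.integer(n_somatic),
                 n_artifact = as.integer(n_artifact), seed = as.integer(seed)),
            class = "variant_sim_spec")
}

.sim_quality_ok <- function(n) {
  data.frame(
    depth = sample(30:400, n, replace = TRUE),
    mapping_quality = stats::runif(n, 50, 60),
    mean_read_position = stats::runif(n, 20, 40),
    mean_mismatches = stats::runif(n, 0, 2),
    microsatellite_length = sample(0:3, n, replace = TRUE),
    tlod = stats::runif(n, 15, 80),
    fs_phred = stats::runif(n, 0, 8)
  )
}

#' Simulate a variant table with planted truth labels
#'
#' Emits one record per planted variant with every field the filtering cascade
#' consumes and a `truth` column in {`"germline"`, `"somatic"`,
#' `"artifact"`}. Germline records carry population annotations that trip the
#' common-germline rule (and high-VAF homozygous-like records additionally
#' trip the VAF rule); somatic records pass every filter; artifacts fail a
#' randomly chosen quality threshold or the pool-of-normals rule.
#'
#' @param spec A [variant_sim_spec()].
#' @return Data frame of variant records with truth labels.
#' @export
simulate_variant_table <- function(spec) {
  stopifnot(inherits(spec, "variant_sim_spec"))
  .with_seed(spec$seed, {
    make <- function(n, truth) {
      if (n == 0L) return(NULL)
      base <- data.frame(
        chromosome = paste0("chr", sample(1:22, n, replace = TRUE)),
        position = sample.int(5e7, n),
        ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
        alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
        gene = paste0("GENE", sample.int(500, n, replace = TRUE)),
        cgc_tier1 = FALSE, in_cosmic = FALSE, in_clinvar = FALSE,
        cosmic_patient_count = 0L,
        population_af = NA_real_, population_count = NA_integer_,
        pon_patients = sample(0:2, n, replace = TRUE),
        truth = truth,
        stringsAsFactors = FALSE
      )
      cbind(base, .sim_quality_ok(n))
    }

    germ <- make(spec$n_germline, "germline")
    if (!is.null(germ)) {
      hom <- stats::runif(spec$n_germline) < 0.5
      germ$vaf <- ifelse(hom, pmin(1, stats::rnorm(spec$n_germline, 0.97, 0.02)),
                         pmin(0.85, pmax(0.3, stats::rnorm(spec$n_germline, 0.5, 0.05))))
      germ$population_af <- 10^stats::runif(spec$n_germline, -2.9, -0.5)
      germ$population_count <- sample(10:5000, spec$n_germline, replace = TRUE)
    }

    som <- make(spec$n_somatic, "somatic")
    if (!is.null(som)) som$vaf <- stats::runif(spec$n_somatic, 0.1, 0.4)

    art <- make(spec$n_artifact, "artifact")
    if (!is.null(art)) {
      art$vaf <- stats::runif(spec$n_artifact, 0.12, 0.35)
      mode <- sample(c("depth", "mq", "readpos", "mismatch", "ms", "tlod",
                       "fs", "vaf", "pon"), spec$n_artifact, replace = TRUE)
      art$depth[mode == "depth"] <- sample(0:4, sum(mode == "depth"), replace = TRUE)
      art$mapping_quality[mode == "mq"] <- stats::runif(sum(mode == "mq"), 10, 45)
      art$mean_read_position[mode == "readpos"] <-
        stats::runif(sum(mode == "readpos"), 1, 15)
      art$mean_mismatches[mode == "mismatch"] <-
        stats::runif(sum(mode == "mismatch"), 2.5, 6)
      art$microsatellite_length[mode == "ms"] <-
        sample(5:12, sum(mode == "ms"), replace = TRUE)
      art$tlod[mode == "tlod"] <- stats::runif(sum(mode == "tlod"), 0, 10)
      art$fs_phred[mode == "fs"] <- stats::runif(sum(mode == "fs"), 10, 60)
      art$vaf[mode == "vaf"] <- stats::runif(sum(mode == "vaf"), 0.01, 0.1)
      art$pon_patients[mode == "pon"] <- sample(3:10, sum(mode == "pon"),
                                                replace = TRUE)
    }

    out <- rbind(germ, som, art)
    rownames(out) <- NULL
    out
  })
}

#' Specification of a synthetic immune-density cohort
#'
#' Three planted archetypes follow the immune-state definitions: `Active` has
#' ubiquitous high T-cells (epithelial T-cell density around 120 cells/mm2);
#' `Suppressed` has low T-cells with elevated epithelial B-cells and T-regs
#' (around 8 and 10 cells/mm2); `Excluded` has high stromal but near-empty
#' epithelial lymphocyte densities. Per-region densities are archetype values
#' with multiplicative lognormal dispersion, hence non-negative, and the
#' Ki67+/Ki67- components are drawn so that totals remain their sum.
#'
#' @param regions_per_state Regions simulated per planted state (>= 2).
#' @param dispersion Lognormal sd of the multiplicative noise (0 = exact
#'   archetypes).
#' @param seed Integer seed.
#' @return An `immune_sim_spec` list.
#' @export
immune_sim_spec <- function(regions_per_state = 10L, dispersion = 0.25,
                            seed = 1L) {
  if (regions_per_state < 2L) stop("need at least 2 regions per state")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(regions_per_state = as.integer(regions_per_state),
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "immune_sim_spec")
}

# archetype mean densities (cells/mm2) for the p and np components
.immune_archetypes <- function() {
  a <- function(...) c(...)
  list(
    Active = a(TC_p_Epi = 20, TC_np_Epi = 100, TC_p_Str = 50, TC_np_Str = 400,
               BC_p_Epi = 1, BC_np_Epi = 4, BC_p_Str = 5, BC_np_Str = 40,
               TREG_p_Epi = 1, TREG_np_Epi = 4, TREG_p_Str = 5, TREG_np_Str = 30),
    Suppressed = a(TC_p_Epi = 2, TC_np_Epi = 18, TC_p_Str = 10, TC_np_Str = 90,
                   BC_p_Epi = 1.1, BC_np_Epi = 7, BC_p_Str = 8, BC_np_Str = 60,
                   TREG_p_Epi = 1.4, TREG_np_Epi = 9, TREG_p_Str = 8,
                   TREG_np_Str = 50),
    Excluded = a(TC_p_Epi = 0.5, TC_np_Epi = 4.5, TC_p_Str = 50, TC_np_Str = 450,
                 BC_p_Epi = 0.1, BC_np_Epi = 0.9, BC_p_Str = 10, BC_np_Str = 70,
                 TREG_p_Epi = 0.1, TREG_np_Epi = 0.9, TREG_p_Str = 8,
                 TREG_np_Str = 55)
  )
}

#' Simulate an immune-density cohort with planted states
#'
#' @param spec An [immune_sim_spec()].
#' @return List with `densities` (regions x 18 matrix, feature names as in
#'   [immune_feature_names()]) and `truth` (named character vector of planted
#'   states).
#' @export
simulate_immune_cohort <- function(spec) {
  stopifnot(inherits(spec, "immune_sim_spec"))
  .with_seed(spec$seed, {
    arch <- .immune_archetypes()
    features <- immune_feature_names()
    n <- spec$regions_per_state * 3L
    out <- matrix(0, nrow = n, ncol = length(features),
                  dimnames = list(character(n), features))
    truth <- character(n)
    i <- 0L
    for (state in names(arch)) {
      for (r in seq_len(spec$regions_per_state)) {
        i <- i + 1L
        rid <- sprintf("%s_%02d", state, r)
        rownames(out)[i] <- rid
        truth[i] <- state
        comp <- arch[[state]] * exp(stats::rnorm(length(arch[[state]]), 0,
                                                 spec$dispersion))
        for (ct in c("BC", "TC", "TREG")) {
          for (cp in c("Epi", "Str")) {
            p <- comp[[paste(ct, "p", cp, sep = "_")]]
            np <- comp[[paste(ct, "np", cp, sep = "_")]]
            out[i, paste(ct, "p", cp, sep = "_")] <- p
            out[i, paste(ct, "np", cp, sep = "_")] <- np
            out[i, paste(ct, "t", cp, sep = "_")] <- p + np
          }
        }
      }
    }
    names(truth) <- rownames(out)
    list(densities = out, truth = truth)
  })
}
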
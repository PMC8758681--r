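# Copy-number burden, bin-weighted divergence between regions, and ternary
# discretization of a shared segmentation into parsimony characters.

#' Discretization thresholds for segment copy-ratio calls
#'
#' Defaults follow the ternary coding used for parsimony characters: a segment
#' is a loss when its log2 copy ratio falls below -0.6, neutral inside
#' [-0.4, 0.3], and undetermined (missing) anywhere else. Segments supported
#' by fewer than `min_probes` bins are dropped. Gains (+1 above `gain_above`)
#' are an off-by-default option: the character coding is loss/neutral, but
#' branch annotation of gains can be useful descriptively.
#'
#' @param loss_below Log2 ratio below which a segment is a loss (-1).
#' @param neutral_low,neutral_high Closed interval coded neutral (0).
#' @param min_probes Minimum bins per segment for the segment to become a
#'   character.
#' @param include_gains Code +1 above `gain_above` instead of missing.
#' @param gain_above Log2 ratio above which a segment is a gain when
#'   `include_gains` is on.
#' @return A `discretization_params` list.
#' @export
discretization_params <- function(loss_below = -0.6, neutral_low = -0.4,
                                  neutral_high = 0.3, min_probes = 12L,
                                  include_gains = FALSE, gain_above = 0.6) {
  if (!(loss_below <= neutral_low && neutral_low < neutral_high)) {
    stop("need loss_below <= neutral_low < neutral_high")
  }
  structure(list(loss_below = loss_below, neutral_low = neutral_low,
                 neutral_high = neutral_high, min_probes = as.integer(min_probes),
                 include_gains = isTRUE(include_gains), gain_above = gain_above),
            class = "discretization_params")
}

#' Copy-number burden of a segment profile
#'
#' Fraction of the base pairs covered by the profile's segments that fall in
#' segments called gain or loss. The denominator is the covered span (targeted
#' bins only), not a nominal genome length. Cutoff defaults are the complement
#' of the neutral band used for discretization: gain above 0.3, loss below
#' -0.4.
#'
#' @param profile A `segment_profile`.
#' @param gain_above Log2 ratio above which a segment counts as gained.
#' @param loss_below Log2 ratio below which a segment counts as lost.
#' @return Burden in [0, 1].
#' @examples
#' p <- segment_profile("chr1", c(0, 100), c(100, 200), c(0.8, 0.0), c(20, 20))
#' cna_burden(p) # 0.5
#' @export
cna_burden <- function(profile, gain_above = 0.3, loss_below = -0.4) {
  stopifnot(inherits(profile, "segment_profile"))
  span <- profile$end - profile$start
  total <- sum(span)
  if (total <= 0) stop("profile covers zero base pairs")
  altered <- profile$log2_ratio > gain_above | profile$log2_ratio < loss_below
  sum(span[altered]) / total
}

.check_shared_segmentation <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$chromosome == b$chromosome) ||
      !all(a$start == b$start) || !all(a$end == b$end) ||
      !all(a$n_bins == b$n_bins)) {
    stop("profiles do not share a segmentation (coordinates or bin counts differ)")
  }
}

#' Bin-weighted copy-number divergence between two regions
#'
#' The genetic distance between two regions of a sample on their shared
#' segmentation:
#' \deqn{D_{a,b} = \sum_k |a_k - b_k| \cdot bins_k / \sum_k bins_k}
#' where \eqn{a_k, b_k} are the regions' segment mean log2 copy ratios and
#' \eqn{bins_k} the number of bins supporting segment k — a weighted L1
#' distance in which each segment contributes in proportion to its bin
#' support.
#'
#' @param a,b Two `segment_profile`s from the same shared segmentation.
#' @return Non-negative divergence.
#' @examples
#' s <- function(v, id) segment_profile("chr1", c(0, 10, 40), c(10, 40, 100),
#'                                      v, c(10, 30, 60), id)
#' pairwise_divergence(s(c(1, 0, -0.5), "a"), s(c(0, 0, -0.5), "b")) # 0.1
#' @export
pairwise_divergence <- function(a, b) {
  stopifnot(inherits(a, "segment_profile"), inherits(b, "segment_profile"))
  .check_shared_segmentation(a, b)
  w <- a$n_bins / sum(a$n_bins)
  sum(abs(a$log2_ratio - b$log2_ratio) * w)
}

#' Maximum pairwise divergence of a sample
#'
#' For samples with more than two regions the maximum divergence between any
#' two regions represents the sample.
#'
#' @param profiles A `multiregion_segmentation`, or a list of >= 2
#'   `segment_profile`s sharing one segmentation.
#' @return The largest pairwise divergence.
#' @export
sample_divergence <- function(profiles) {
  if (inherits(profiles, "multiregion_segmentation")) {
    profiles <- lapply(rownames(profiles$means),
                       function(r) region_profile(profiles, r))
  }
  if (length(profiles) < 2L) stop("need at least 2 regions")
  best <- 0
  for (i in seq_len(length(profiles) - 1L)) {
    for (j in seq(i + 1L, length(profiles))) {
      best <- max(best, pairwise_divergence(profiles[[i]], profiles[[j]]))
    }
  }
  best
}

#' Discretize a shared segmentation into parsimony characters
#'
#' Maps each region x segment mean to a ternary character: -1 (loss) below
#' `loss_below`, 0 (neutral) inside [`neutral_low`, `neutral_high`], and NA
#' (undetermined) otherwise — or +1 above `gain_above` when `include_gains`
#' is set. Segments with fewer than `min_probes` bins are dropped entirely,
#' so weakly supported segments never become characters.
#'
#' The mapping is monotone: for fixed thresholds a lower log2 value never maps
#' to a higher character.
#'
#' @param seg A `multiregion_segmentation`.
#' @param params A [discretization_params()] list.
#' @return A `character_matrix`: integer matrix, rows = regions, columns =
#'   retained segments (named `chr:start-end`), values in {-1, 0, NA} (plus
#'   +1 with gains).
#' @export
discretize <- function(seg, params = discretization_params()) {
  stopifnot(inherits(seg, "multiregion_segmentation"),
            inherits(params, "discretization_params"))
  keep <- seg$segments$n_bins >= params$min_probes
  m <- seg$means[, keep, drop = FALSE]
  out <- matrix(NA_integer_, nrow = nrow(m), ncol = ncol(m),
                dimnames = dimnames(m))
  out[m < params$loss_below] <- -1L
  out[m >= params$neutral_low & m <= params$neutral_high] <- 0L
  if (params$include_gains) out[m > params$gain_above] <- 1L
  class(out) <- c("character_matrix", class(out))
  out
}
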
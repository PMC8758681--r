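# Tumor-only somatic-variant filtering.
#
# Records are labeled, never dropped: each filter adds a predicate-based label
# so the cascade is auditable and the final label set does not depend on the
# order the filters ran in. `somatic_pass` is the closing conjunction.

#' Filtering thresholds for the tumor-only cascade
#'
#' Defaults follow the published cascade: a call needs coverage of at least 5
#' reads, mapping quality > 45, mean position in read > 15, mean read
#' mismatches < 2.5, microsatellite length < 5, tumor log-odds > 10, Fisher
#' strand-bias Phred score < 10 and VAF > 0.1. Common germline variants are
#' those with population allele frequency > 1e-3 or seen in > 9 individuals;
#' VAF >= 0.9 outside LOH flags likely germline; presence in > 2
#' pool-of-normal patients flags germline/artifact; COSMIC hotspots seen in
#' >= 15 patients inside the breast-cancer driver gene list are rescued.
#' Threshold senses are applied literally (e.g. mapping quality exactly 45
#' fails the strict `> 45`).
#'
#' @param min_depth,min_mq,min_read_pos,max_mismatches,max_ms_length,min_tlod,max_fs,min_vaf
#'   Quality thresholds (see above for their senses).
#' @param max_pop_af,max_pop_count Common-germline population cutoffs.
#' @param germline_vaf VAF at or above which a non-LOH variant is likely
#'   germline.
#' @param max_pon_patients Pool-of-normal patient count above which a variant
#'   is flagged.
#' @param hotspot_min_patients COSMIC patient count from which a driver-gene
#'   variant is rescued.
#' @param strict When TRUE, records missing a quality field fail that filter;
#'   by default missing fields are not held against the record (the upstream
#'   caller may not emit them).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_depth = 5, min_mq = 45, min_read_pos = 15,
                          max_mismatches = 2.5, max_ms_length = 5,
                          min_tlod = 10, max_fs = 10, min_vaf = 0.1,
                          max_pop_af = 1e-3, max_pop_count = 9,
                          germline_vaf = 0.9, max_pon_patients = 2,
                          hotspot_min_patients = 15, strict = FALSE) {
  p <- list(min_depth = min_depth, min_mq = min_mq, min_read_pos = min_read_pos,
            max_mismatches = max_mismatches, max_ms_length = max_ms_length,
            min_tlod = min_tlod, max_fs = max_fs, min_vaf = min_vaf,
            max_pop_af = max_pop_af, max_pop_count = max_pop_count,
            germline_vaf = germline_vaf, max_pon_patients = max_pon_patients,
            hotspot_min_patients = hotspot_min_patients, strict = isTRUE(strict))
  if (!all(is.finite(unlist(p[1:13])))) stop("all thresholds must be finite")
  if (p$min_vaf >= p$germline_vaf) stop("min_vaf must be below germline_vaf")
  structure(p, class = "filter_params")
}

.check_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  if (!all(c("chromosome", "position", "vaf") %in% names(records))) {
    stop("records need at least chromosome, position, vaf columns")
  }
  if (any(records$vaf < 0 | records$vaf > 1, na.rm = TRUE)) {
    stop("vaf must lie in [0, 1]")
  }
  invisible(records)
}

# comparison helper honoring the strict/lenient treatment of missing fields
.fails <- function(records, field, test, strict) {
  if (!field %in% names(records)) {
    return(rep(strict, nrow(records)))
  }
  v <- records[[field]]
  out <- !test(v)
  out[is.na(v)] <- strict
  out
}

#' Apply the per-record quality filters
#'
#' Labels (never drops) records failing any of the depth, mapping-quality,
#' read-position, mismatch, microsatellite, tumor log-odds, strand-bias or VAF
#' thresholds with `quality_fail`.
#'
#' @param records Variant data frame; quality fields used when present:
#'   `depth`, `mapping_quality`, `mean_read_position`, `mean_mismatches`,
#'   `microsatellite_length`, `tlod`, `fs_phred`, `vaf`.
#' @param params A [filter_params()] list.
#' @return `records` with a logical `quality_fail` column.
#' @export
apply_quality_filters <- function(records, params = filter_params()) {
  .check_records(records)
  s <- params$strict
  fail <-
    .fails(records, "depth", function(v) v >= params$min_depth, s) |
    .fails(records, "mapping_quality", function(v) v > params$min_mq, s) |
    .fails(records, "mean_read_position", function(v) v > params$min_read_pos, s) |
    .fails(records, "mean_mismatches", function(v) v < params$max_mismatches, s) |
    .fails(records, "microsatellite_length", function(v) v < params$max_ms_length, s) |
    .fails(records, "tlod", function(v) v > params$min_tlod, s) |
    .fails(records, "fs_phred", function(v) v < params$max_fs, s) |
    .fails(records, "vaf", function(v) v > params$min_vaf, s)
  records$quality_fail <- fail
  records
}

#' Flag likely germline variants
#'
#' Two labels: `common_germline` when the variant is common in population
#' databases (allele frequency above `max_pop_af` or carrier count above
#' `max_pop_count`) — unless it sits in a tier-1 cancer gene census gene and
#' is known in COSMIC or ClinVar, in which case it is retained; and
#' `vaf_germline` when the allele fraction is at or above `germline_vaf` and
#' the position lies outside every supplied LOH interval (inside LOH a
#' germline allele can legitimately reach high VAF, so such records are
#' exempt).
#'
#' Where several population sources disagree, callers should supply the
#' maximum count across sources.
#'
#' @param records Variant data frame; uses `population_af`,
#'   `population_count`, `cgc_tier1`, `in_cosmic`, `in_clinvar`, `vaf`,
#'   `chromosome`, `position`.
#' @param loh_segments Data frame of LOH intervals (`chromosome`, `start`,
#'   `end`, 0-based half-open), possibly empty or NULL.
#' @param params A [filter_params()] list.
#' @return `records` with logical `common_germline` and `vaf_germline`
#'   columns.
#' @export
flag_germline <- function(records, loh_segments = NULL, params = filter_params()) {
  .check_records(records)
  n <- nrow(records)
  get <- function(field, default) {
    if (field %in% names(records)) records[[field]] else rep(default, n)
  }
  pop_af <- get("population_af", NA_real_)
  pop_n <- get("population_count", NA_integer_)
  common <- (!is.na(pop_af) & pop_af > params$max_pop_af) |
    (!is.na(pop_n) & pop_n > params$max_pop_count)
  tier1_known <- get("cgc_tier1", FALSE) &
    (get("in_cosmic", FALSE) | get("in_clinvar", FALSE))
  records$common_germline <- common & !tier1_known

  in_loh <- rep(FALSE, n)
  if (!is.null(loh_segments) && nrow(loh_segments) > 0L) {
    if (!all(c("chromosome", "start", "end") %in% names(loh_segments)) ||
        any(loh_segments$end <= loh_segments$start)) {
      stop("loh_segments must have chromosome/start/end with end > start")
    }
    for (i in seq_len(nrow(loh_segments))) {
      in_loh <- in_loh |
        (records$chromosome == loh_segments$chromosome[i] &
           records$position > loh_segments$start[i] &
           records$position <= loh_segments$end[i])
    }
  }
  records$vaf_germline <- !is.na(records$vaf) &
    records$vaf >= params$germline_vaf & !in_loh
  records
}

#' Flag variants recurrent in the pool of normals
#'
#' @param records Variant data frame.
#' @param pon_patient_counts Either a numeric column name in `records`
#'   (default `"pon_patients"`), or a named vector keyed by
#'   `chromosome:position:ref>alt`.
#' @param params A [filter_params()] list.
#' @return `records` with a logical `pon` column: TRUE when seen in more than
#'   `max_pon_patients` pool-of-normal patients.
#' @export
apply_pon_filter <- function(records, pon_patient_counts = "pon_patients",
                             params = filter_params()) {
  .check_records(records)
  if (is.character(pon_patient_counts) && length(pon_patient_counts) == 1L) {
    counts <- if (pon_patient_counts %in% names(records)) {
      records[[pon_patient_counts]]
    } else {
      rep(0L, nrow(records))
    }
  } else {
    key <- sprintf("%s:%d:%s>%s", records$chromosome, records$position,
                   records$ref, records$alt)
    counts <- unname(pon_patient_counts[key])
  }
  counts[is.na(counts)] <- 0L
  records$pon <- counts > params$max_pon_patients
  records
}

#' Rescue known hotspot mutations in driver genes
#'
#' Variants previously observed in at least `hotspot_min_patients` COSMIC
#' patients and falling inside the supplied breast-cancer driver gene list are
#' labeled `rescued_hotspot`; rescued records survive the cascade regardless
#' of the common-germline label.
#'
#' @param records Variant data frame; uses `cosmic_patient_count` and `gene`.
#' @param driver_genes Character vector of driver gene symbols.
#' @param params A [filter_params()] list.
#' @return `records` with a logical `rescued_hotspot` column.
#' @export
rescue_hotspots <- function(records, driver_genes, params = filter_params()) {
  .check_records(records)
  n <- nrow(records)
  count <- if ("cosmic_patient_count" %in% names(records)) {
    records$cosmic_patient_count
  } else {
    rep(0L, n)
  }
  count[is.na(count)] <- 0L
  gene <- if ("gene" %in% names(records)) records$gene else rep(NA_character_, n)
  records$rescued_hotspot <- count >= params$hotspot_min_patients &
    !is.na(gene) & gene %in% driver_genes
  records
}

#' Run the full cascade and close with the somatic_pass predicate
#'
#' Applies [apply_quality_filters()], [flag_germline()], [apply_pon_filter()]
#' and [rescue_hotspots()] and defines
#' `somatic_pass = rescued_hotspot | !(quality_fail | common_germline |
#' vaf_germline | pon)`. Because every label is a pure predicate of the
#' record, the outcome is invariant to the order of application.
#'
#' @param records Variant data frame.
#' @param loh_segments Optional LOH intervals (see [flag_germline()]).
#' @param driver_genes Driver gene list for hotspot rescue (default none).
#' @param pon_patient_counts See [apply_pon_filter()].
#' @param params A [filter_params()] list.
#' @return Labeled records with the final logical `somatic_pass` column.
#' @export
filter_variants <- function(records, loh_segments = NULL,
                            driver_genes = character(0),
                            pon_patient_counts = "pon_patients",
                            params = filter_params()) {
  records <- apply_quality_filters(records, params)
  records <- flag_germline(records, loh_segments, params)
  records <- apply_pon_filter(records, pon_patient_counts, params)
  records <- rescue_hotspots(records, driver_genes, params)
  records$somatic_pass <- records$rescued_hotspot |
    !(records$quality_fail | records$common_germline |
        records$vaf_germline | records$pon)
  records
}

#' Parameters of the multi-region presence caller
#'
#' @param error_rate Sequencing error rate e used by the absence model
#'   (default 0.02).
#' @param f_min Minimum allele fraction of the presence alternative
#'   (default 0.05).
#' @param bf_present Bayes factor above which a variant is called present
#'   (default 10).
#' @param bf_absent Bayes factor below which a variant is called absent
#'   (default 0.1).
#' @return A `presence_params` list.
#' @export
presence_params <- function(error_rate = 0.02, f_min = 0.05,
                            bf_present = 10, bf_absent = 0.1) {
  if (!(error_rate > 0 && error_rate < 0.5)) stop("error_rate must be in (0, 0.5)")
  if (!(f_min > 0 && f_min < 1)) stop("f_min must be in (0, 1)")
  if (bf_absent >= bf_present) stop("bf_absent must be below bf_present")
  structure(list(error_rate = error_rate, f_min = f_min,
                 bf_present = bf_present, bf_absent = bf_absent),
            class = "presence_params")
}

#' Call variant presence per region by Bayes factor
#'
#' For each region x variant cell with alt count k out of depth n, computes
#' \deqn{BF = \frac{\int_{f_{min}}^{1} Binom(k; n, f)\,df}{Binom(k; n, e)}}
#' — the marginal likelihood of a real variant at unknown allele fraction
#' above `f_min` against sequencing error at rate e. Cells with BF above
#' `bf_present` are `present`, below `bf_absent` are `absent`, otherwise (or
#' at zero depth) `unknown`. The numerator integral has the closed form
#' `(1 - pbeta(f_min, k+1, n-k+1)) / (n+1)`.
#'
#' For fixed depth the call is monotone in k: more alt reads never turn a
#' present call absent.
#'
#' @param alt_counts,depths Integer matrices (regions x variants) of alt-read
#'   counts and total depths.
#' @param params A [presence_params()] list.
#' @return Character matrix (regions x variants) in
#'   {`"present"`, `"absent"`, `"unknown"`}.
#' @export
call_presence <- function(alt_counts, depths, params = presence_params()) {
  alt_counts <- as.matrix(alt_counts)
  depths <- as.matrix(depths)
  if (!all(dim(alt_counts) == dim(depths))) {
    stop("alt_counts and depths must have matching dimensions")
  }
  if (any(depths < 0)) stop("depths must be >= 0")
  if (any(alt_counts > depths)) stop("alt count exceeds depth")
  bf <- presence_bayes_factor(alt_counts, depths, params)
  out <- matrix("unknown", nrow = nrow(bf), ncol = ncol(bf),
                dimnames = dimnames(alt_counts))
  out[!is.na(bf) & bf > params$bf_present] <- "present"
  out[!is.na(bf) & bf < params$bf_absent] <- "absent"
  out
}

#' Bayes factor of the presence caller
#'
#' @inheritParams call_presence
#' @return Numeric matrix of Bayes factors (NA at zero depth).
#' @export
presence_bayes_factor <- function(alt_counts, depths, params = presence_params()) {
  k <- as.matrix(alt_counts)
  n <- as.matrix(depths)
  # log numerator: choose(n,k) * Beta(k+1, n-k+1) * P(Beta > f_min)
  log_num <- lchoose(n, k) + lbeta(k + 1, n - k + 1) +
    stats::pbeta(params$f_min, k + 1, n - k + 1, lower.tail = FALSE, log.p = TRUE)
  log_den <- stats::dbinom(k, n, params$error_rate, log = TRUE)
  bf <- exp(log_num - log_den)
  bf[n == 0] <- NA_real_
  bf
}
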
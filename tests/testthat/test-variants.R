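base_record <- function(...) {
  rec <- data.frame(chromosome = "chr1", position = 1000L, ref = "A", alt = "T",
                    vaf = 0.25, depth = 100L, mapping_quality = 60,
                    mean_read_position = 30, mean_mismatches = 1,
                    microsatellite_length = 1L, tlod = 50, fs_phred = 2,
                    population_af = NA_real_, population_count = NA_integer_,
                    gene = "GENEX", cgc_tier1 = FALSE, in_cosmic = FALSE,
                    in_clinvar = FALSE, cosmic_patient_count = 0L,
                    pon_patients = 0L, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

test_that("quality thresholds follow the printed senses exactly", {
  recs <- rbind(
    base_record(),                       # clean
    base_record(depth = 4L),             # below 'at least five reads'
    base_record(depth = 5L),             # exactly five passes
    base_record(mapping_quality = 45),   # strict > 45 fails the boundary
    base_record(mean_read_position = 15),
    base_record(mean_mismatches = 2.5),
    base_record(microsatellite_length = 5L),
    base_record(tlod = 10),
    base_record(fs_phred = 10),
    base_record(vaf = 0.1)
  )
  out <- apply_quality_filters(recs)
  expect_equal(out$quality_fail,
               c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
})

test_that("missing quality fields fail only in strict mode", {
  rec <- base_record(tlod = NA_real_)
  expect_false(apply_quality_filters(rec)$quality_fail)
  expect_true(apply_quality_filters(rec, filter_params(strict = TRUE))$quality_fail)
})

test_that("germline flags honour population, VAF and LOH rules", {
  loh <- data.frame(chromosome = "chr1", start = 500L, end = 2000L)

  high_vaf <- base_record(vaf = 0.95, position = 5000L)
  out <- flag_germline(high_vaf)
  expect_true(out$vaf_germline)

  inside_loh <- base_record(vaf = 0.95, position = 1500L)
  out <- flag_germline(inside_loh, loh)
  expect_false(out$vaf_germline)

  common <- base_record(population_af = 0.01)
  expect_true(flag_germline(common)$common_germline)
  by_count <- base_record(population_count = 10L)
  expect_true(flag_germline(by_count)$common_germline)
  at_count <- base_record(population_count = 9L)
  expect_false(flag_germline(at_count)$common_germline)

  rescued <- base_record(population_af = 0.01, cgc_tier1 = TRUE, in_cosmic = TRUE)
  expect_false(flag_germline(rescued)$common_germline)
  tier1_unknown <- base_record(population_af = 0.01, cgc_tier1 = TRUE)
  expect_true(flag_germline(tier1_unknown)$common_germline)

  bad_loh <- data.frame(chromosome = "chr1", start = 10L, end = 5L)
  expect_error(flag_germline(high_vaf, bad_loh), "end > start")
})

test_that("pool-of-normal and hotspot rules use the printed cutoffs", {
  recs <- rbind(base_record(pon_patients = 3L), base_record(pon_patients = 2L),
                base_record(pon_patients = 0L))
  out <- apply_pon_filter(recs)
  expect_equal(out$pon, c(TRUE, FALSE, FALSE))

  drivers <- c("PIK3CA", "TP53", "GATA3")
  recs <- rbind(
    base_record(cosmic_patient_count = 15L, gene = "PIK3CA"),
    base_record(cosmic_patient_count = 14L, gene = "PIK3CA"),
    base_record(cosmic_patient_count = 20L, gene = "GENEX")
  )
  out <- rescue_hotspots(recs, drivers)
  expect_equal(out$rescued_hotspot, c(TRUE, FALSE, FALSE))

  # a rescued hotspot survives a common-germline label
  hot <- base_record(population_af = 0.01, cosmic_patient_count = 30L,
                     gene = "TP53")
  lab <- filter_variants(hot, driver_genes = drivers)
  expect_true(lab$common_germline)
  expect_true(lab$somatic_pass)
})

test_that("labels are order-invariant across all filter orderings", {
  set.seed(17)
  recs <- simulate_variant_table(variant_sim_spec(10, 10, 10, seed = 40))
  drivers <- c("GENE1", "GENE2")
  params <- filter_params()
  steps <- list(
    q = function(r) apply_quality_filters(r, params),
    g = function(r) flag_germline(r, NULL, params),
    p = function(r) apply_pon_filter(r, "pon_patients", params),
    h = function(r) rescue_hotspots(r, drivers, params)
  )
  perms <- list(c("q","g","p","h"), c("h","p","g","q"), c("g","h","q","p"),
                c("p","q","h","g"))
  results <- lapply(perms, function(ord) {
    out <- recs
    for (s in ord) out <- steps[[s]](out)
    out[, c("quality_fail", "common_germline", "vaf_germline", "pon",
            "rescued_hotspot")]
  })
  for (i in 2:length(results)) expect_equal(results[[i]], results[[1]])
})

test_that("the cascade recovers planted somatic and removes planted germline", {
  somatic_rate <- numeric(20)
  germline_removed <- numeric(20)
  for (s in 1:20) {
    tab <- simulate_variant_table(variant_sim_spec(seed = s))
    lab <- filter_variants(tab)
    som <- lab$truth == "somatic"
    germ <- lab$truth == "germline"
    somatic_rate[s] <- mean(lab$somatic_pass[som])
    germline_removed[s] <- mean(!lab$somatic_pass[germ])
  }
  expect_gte(min(somatic_rate), 0.95)
  expect_gte(min(germline_removed), 0.95)
})

test_that("presence Bayes factors match a numeric-integration oracle", {
  pp <- presence_params()
  oracle <- function(k, n) {
    num <- integrate(function(f) dbinom(k, n, f), pp$f_min, 1,
                     rel.tol = 1e-10)$value
    num / dbinom(k, n, pp$error_rate)
  }
  for (k in c(0L, 1L, 3L, 10L, 30L, 80L)) {
    expect_equal(presence_bayes_factor(matrix(k), matrix(100L))[1, 1],
                 oracle(k, 100L), tolerance = 1e-8)
  }

  calls <- call_presence(matrix(c(0L, 30L, 0L), 1), matrix(c(100L, 100L, 0L), 1))
  expect_equal(unname(calls[1, ]), c("absent", "present", "unknown"))

  expect_error(call_presence(matrix(5L), matrix(4L)), "exceeds depth")
  expect_error(call_presence(matrix(0L), matrix(-1L)), ">= 0")
})

test_that("presence calls are monotone in the alt count", {
  for (n in c(20L, 60L, 200L)) {
    bf <- presence_bayes_factor(matrix(0:n, 1), matrix(rep(n, n + 1L), 1))
    expect_false(is.unsorted(bf[1, ]))
    calls <- call_presence(matrix(0:n, 1), matrix(rep(n, n + 1L), 1))
    rank <- c(absent = 1L, unknown = 2L, present = 3L)
    expect_false(is.unsorted(rank[calls[1, ]]))
  }
})

test_that("labeled records round-trip through VCF", {
  skip_if_not_installed("vcfR")
  tab <- simulate_variant_table(variant_sim_spec(5, 5, 5, seed = 9))
  lab <- filter_variants(tab)
  tmp <- tempfile(fileext = ".vcf")
  on.exit(unlink(tmp))
  write_variant_vcf(lab, tmp)
  back <- read_variant_vcf(tmp)

  expect_equal(back$chromosome, lab$chromosome)
  expect_equal(back$position, lab$position)
  expect_equal(back$vaf, lab$vaf, tolerance = 1e-6)
  expect_equal(back$depth, lab$depth)
  expect_equal(back$gene, lab$gene)
  expect_equal(back$population_count, lab$population_count)
  expect_equal(back$cgc_tier1, lab$cgc_tier1)
  expect_equal(back$filter_labels == "PASS", lab$somatic_pass)

  # relabeling the parsed records reproduces the original labels
  relab <- filter_variants(back)
  expect_equal(relab$somatic_pass, lab$somatic_pass)
  expect_equal(relab$quality_fail, lab$quality_fail)
  expect_equal(relab$common_germline, lab$common_germline)
})
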
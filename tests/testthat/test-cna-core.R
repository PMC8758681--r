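test_that("winsorization clips per-chromosome outliers and is idempotent", {
  flat <- make_bins(rep(0.5, 10))
  expect_equal(winsorize_bins(flat), flat)

  # flat 0 over 10 bins plus one at 5: the 11-value MAD is 0, so the spike
  # clips to the median
  spike <- make_bins(c(rep(0, 10), 5))
  w <- winsorize_bins(spike, k_mad = 2.5)
  med <- median(spike$log2_ratio)
  bound <- med + 2.5 * mad(spike$log2_ratio)
  expect_equal(w$log2_ratio[11], bound)
  expect_equal(w$log2_ratio[1:10], rep(0, 10))
  expect_equal(winsorize_bins(w, 2.5), w)

  set.seed(2)
  noisy <- make_bins(rnorm(50, 0, 0.2))
  expect_equal(winsorize_bins(winsorize_bins(noisy)), winsorize_bins(noisy))
  expect_error(winsorize_bins(make_bins(numeric(0))), "empty")
})

test_that("joint segmentation finds a clean shared step and its means", {
  step <- c(rep(0, 10), rep(0.9, 10))
  bins <- list(A = make_bins(step), B = make_bins(step - 0.9))
  seg <- joint_segment(bins, gamma = 0.5)
  expect_equal(nrow(seg$segments), 2L)
  expect_equal(seg$segments$start, c(0, 1000))
  expect_equal(unname(seg$means["A", ]), c(0, 0.9))
  expect_equal(unname(seg$means["B", ]), c(-0.9, 0))

  # gamma above the total variance collapses to one segment per chromosome
  seg1 <- joint_segment(bins, gamma = 100)
  expect_equal(nrow(seg1$segments), 1L)
  expect_equal(unname(seg1$means["A", 1]), mean(step))

  # mismatched grids are rejected with the offending bin named
  bad <- bins
  bad$B$start[3] <- bad$B$start[3] + 1
  bad$B$end[2] <- bad$B$start[3]
  expect_error(joint_segment(bad, gamma = 1), "bin 2")
})

test_that("the DP equals brute-force breakpoint enumeration on small instances", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(8:12, 1)
    vals <- list(A = cumsum(rnorm(n, 0, 0.4)), B = cumsum(rnorm(n, 0, 0.4)))
    gamma <- runif(1, 0.1, 2)
    bins <- lapply(vals, make_bins)
    seg <- joint_segment(bins, gamma = gamma)
    oracle <- brute_segment(vals, gamma)
    expect_equal(segmentation_objective(seg, bins), oracle$objective,
                 tolerance = 1e-9)
    expect_equal(seg$segments$end[-nrow(seg$segments)] / 100, oracle$breaks)
  }
})

test_that("a single region degenerates to ordinary penalized PCF", {
  set.seed(12)
  v <- cumsum(rnorm(11, 0, 0.5))
  seg <- joint_segment(list(R = make_bins(v)), gamma = 0.8)
  oracle <- brute_segment(list(R = v), 0.8)
  expect_equal(segmentation_objective(seg, list(R = make_bins(v))),
               oracle$objective, tolerance = 1e-9)
})

test_that("burden is the altered fraction of covered base pairs", {
  allneutral <- toy_profile(c(0, 0.1, -0.1))
  expect_equal(cna_burden(allneutral), 0)

  # one gained segment covering 14% of the covered bases
  p <- segment_profile("chr1", c(0, 1400), c(1400, 10000), c(0.8, 0),
                       c(14, 86))
  expect_equal(cna_burden(p), 0.14)

  lost <- toy_profile(c(-1, -1, -1))
  expect_equal(cna_burden(lost), 1)

  # tightening cutoffs toward zero never decreases burden
  set.seed(4)
  prof <- toy_profile(runif(3, -1, 1))
  cuts <- seq(0.5, 0.05, by = -0.05)
  burdens <- vapply(cuts, function(c) cna_burden(prof, c, -c), numeric(1))
  expect_false(is.unsorted(burdens))
  expect_true(all(burdens >= 0 & burdens <= 1))
})

test_that("divergence matches the hand-computed toy and the max rule", {
  a <- toy_profile(c(1, 0, -0.5), id = "a")
  b <- toy_profile(c(0, 0, -0.5), id = "b")
  expect_equal(pairwise_divergence(a, a), 0)
  expect_equal(pairwise_divergence(a, b), 0.1)
  expect_equal(pairwise_divergence(a, b), pairwise_divergence(b, a))

  # three regions realizing pairwise divergences 0.1, 0.3, 0.2
  r1 <- toy_profile(c(0.0, 0, 0), bins = c(10, 45, 45), id = "r1")
  r2 <- toy_profile(c(1.0, 0, 0), bins = c(10, 45, 45), id = "r2")
  r3 <- toy_profile(c(3.0, 0, 0), bins = c(10, 45, 45), id = "r3")
  expect_equal(pairwise_divergence(r1, r2), 0.1)
  expect_equal(pairwise_divergence(r1, r3), 0.3)
  expect_equal(pairwise_divergence(r2, r3), 0.2)
  expect_equal(sample_divergence(list(r1, r2, r3)), 0.3)
  expect_equal(sample_divergence(list(r1, r2, r3, r3)), 0.3)
  expect_error(sample_divergence(list(r1)), "2 regions")

  mismatch <- toy_profile(c(0, 0, 0), bins = c(20, 35, 45), id = "x")
  expect_error(pairwise_divergence(r1, mismatch), "segmentation")
})

test_that("divergence satisfies the weighted-L1 metric axioms on random triples", {
  set.seed(99)
  for (rep in 1:100) {
    bins <- sample(5:50, 4, replace = TRUE)
    mk <- function(id) toy_profile(runif(4, -1.5, 1.5),
                                   bins = bins, id = id)
    x <- mk("x"); y <- mk("y"); z <- mk("z")
    dxy <- pairwise_divergence(x, y)
    dyz <- pairwise_divergence(y, z)
    dxz <- pairwise_divergence(x, z)
    expect_gte(dxy, 0)
    expect_equal(dxy, pairwise_divergence(y, x))
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
  # zero iff equal means
  p <- toy_profile(c(0.2, -0.3, 0.4))
  q <- toy_profile(c(0.2, -0.3, 0.4 + 1e-6))
  expect_gt(pairwise_divergence(p, q), 0)
})

test_that("discretization applies the published thresholds and probe cutoff", {
  bins <- list(A = make_bins(rep(c(-0.7, 0.0, 0.45), each = 20)),
               B = make_bins(rep(c(-0.7, 0.0, 0.45), each = 20)))
  seg <- joint_segment(bins, gamma = 0.5)
  cm <- discretize(seg)
  expect_equal(unname(unclass(cm)["A", ]), c(-1L, 0L, NA))

  # exact boundary senses: -0.6 and 0.3 are not losses; -0.4 is neutral
  seg$means[] <- rep(c(-0.6, -0.4, 0.3), length.out = length(seg$means))
  cm2 <- discretize(seg)
  expect_true(all(unclass(cm2) == 0L, na.rm = TRUE))
  expect_equal(sum(is.na(cm2)), sum(seg$means == -0.6))

  # segments under the probe minimum vanish
  seg$segments$n_bins <- c(11L, 20L, 20L)
  expect_equal(ncol(discretize(seg)), 2L)

  # monotone: lower log2 never maps to a higher character
  grid <- seq(-1.2, 1.2, by = 0.01)
  seg3 <- joint_segment(list(A = make_bins(rep(0, 20)),
                             B = make_bins(rep(0, 20))), gamma = 100)
  chars <- vapply(grid, function(v) {
    seg3$means[] <- v
    val <- unclass(discretize(seg3))[1, 1]
    if (is.na(val)) NA_integer_ else val
  }, integer(1))
  observed <- chars[!is.na(chars)]
  expect_false(is.unsorted(observed))

  # gains become +1 only when enabled
  seg3$means[] <- 0.8
  expect_true(is.na(unclass(discretize(seg3))[1, 1]))
  withg <- discretize(seg3, discretization_params(include_gains = TRUE))
  expect_equal(unclass(withg)[1, 1], 1L)
})

test_that("SEG files round-trip the shared segmentation", {
  step <- c(rep(0, 10), rep(-0.9, 10))
  seg <- joint_segment(list(A = make_bins(step), B = make_bins(rev(step))),
                       gamma = 0.5)
  tmp <- tempfile(fileext = ".seg")
  on.exit(unlink(tmp))
  write_seg(seg, tmp)
  profiles <- read_seg(tmp)
  expect_named(profiles, c("A", "B"))
  pa <- region_profile(seg, "A")
  expect_equal(profiles$A$log2_ratio, pa$log2_ratio)
  expect_equal(profiles$A$start, pa$start)
  expect_equal(profiles$A$n_bins, pa$n_bins)
})
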
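make_cells <- function(region, n, phenotype, compartment, ki67 = "negative") {
  if (n == 0) return(NULL)
  data.frame(region_id = region, x = runif(n, 0, 1000), y = runif(n, 0, 1000),
             phenotype = phenotype, ki67 = ki67, compartment = compartment,
             stringsAsFactors = FALSE)
}

test_that("densities are counts over compartment areas, zeros included", {
  cells <- rbind(
    make_cells("r1", 10, "T-cell", "epithelium"),
    make_cells("r1", 3, "T-cell", "epithelium", ki67 = "positive"),
    make_cells("r1", 6, "T-reg", "stroma"),
    make_cells("r1", 40, "epithelial", "epithelium")
  )
  areas <- data.frame(region_id = c("r1", "r2"),
                      epithelium_mm2 = c(0.5, 1), stroma_mm2 = c(2, 1))
  d <- compute_density_matrix(cells, areas)
  expect_equal(dim(d), c(2L, 18L))
  expect_equal(d["r1", "TC_np_Epi"], 20)
  expect_equal(d["r1", "TC_p_Epi"], 6)
  expect_equal(d["r1", "TC_t_Epi"], 26)
  expect_equal(d["r1", "TREG_t_Str"], 3)
  # no B-cells anywhere: all six BC features are zero, not missing
  expect_equal(unname(d[, grepl("^BC", colnames(d))]), matrix(0, 2, 6))
  # r2 has no cells at all
  expect_equal(unname(d["r2", ]), rep(0, 18))

  # T-regs count in TC features only when configured
  d2 <- compute_density_matrix(cells, areas, tregs_in_tc = TRUE)
  expect_equal(d2["r1", "TC_t_Str"], 3)
  expect_equal(d["r1", "TC_t_Str"], 0)

  # additivity holds feature-wise
  for (ct in c("BC", "TC", "TREG")) for (cp in c("Epi", "Str")) {
    expect_equal(d[, paste(ct, "t", cp, sep = "_")],
                 d[, paste(ct, "p", cp, sep = "_")] +
                   d[, paste(ct, "np", cp, sep = "_")])
  }

  expect_error(compute_density_matrix(cells, transform(areas, stroma_mm2 = 0)),
               "positive")
})

test_that("decile scores follow rank arithmetic with average ties", {
  m <- cbind(distinct = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
             constant = rep(7, 10))
  sc <- decile_regularize(m)
  expect_equal(unname(sc[, "distinct"]), 1:10)
  expect_equal(unname(sc[, "constant"]), rep(6L, 10))  # ceiling(10 * 5.5 / 10)
  expect_true(all(sc >= 1 & sc <= 10))

  # rank invariance under monotone transforms
  sc2 <- decile_regularize(cbind(exp(m[, "distinct", drop = FALSE])))
  expect_equal(unname(sc2[, 1]), unname(sc[, "distinct"]))

  expect_error(decile_regularize(m[1, , drop = FALSE]), "2 regions")

  # near-uniform coverage when values are distinct
  set.seed(3)
  sc3 <- decile_regularize(matrix(rnorm(40), ncol = 2))
  tabs <- apply(sc3, 2, tabulate, nbins = 10)
  expect_true(all(tabs >= 1 & tabs <= 3))
})

test_that("NMF recovers planted rank-4 factors and decreases its loss", {
  set.seed(42)
  planted <- planted_nmf_factors()
  W0 <- planted$W
  H0 <- planted$H
  V <- W0 %*% H0
  mod <- factorize_densities(t(V), rank = 4, seed = 3, n_restarts = 10,
                             max_iter = 5000, tol = 1e-13)
  expect_lt(mod$loss, 1e-6)
  # each planted column matched by some recovered column up to scale
  sim <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
    cosine_sim(mod$W[, i], W0[, j])
  }))
  expect_true(all(apply(sim, 2, max) > 0.99))

  expect_false(is.unsorted(rev(mod$loss_history)))  # loss non-increasing
  expect_true(all(mod$W >= 0) && all(mod$H >= 0))

  # determinism given the seed
  sc <- decile_regularize(simulate_immune_cohort(immune_sim_spec(seed = 5))$densities)
  m1 <- factorize_densities(sc, rank = 4, seed = 9)
  m2 <- factorize_densities(sc, rank = 4, seed = 9)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$H, m2$H)

  expect_error(factorize_densities(sc, rank = 40, seed = 1), "rank")
  expect_error(factorize_densities(sc, rank = 4), "seed")
})

test_that("state naming follows the dominant meta-marker rule", {
  # synthetic H with three well-separated archetypes
  H <- cbind(
    matrix(rep(c(1, 8, 1, 1), 4), 4) + 0.05 * matrix(seq_len(16), 4),   # MM2 high
    matrix(rep(c(1, 1, 8, 1), 4), 4) + 0.05 * matrix(seq_len(16), 4),   # MM3 high
    matrix(rep(c(1, 1, 1, 8), 4), 4) + 0.05 * matrix(seq_len(16), 4)    # MM4 high
  )
  rownames(H) <- paste0("MM", 1:4)
  colnames(H) <- paste0("r", seq_len(ncol(H)))
  model <- structure(list(W = diag(4), H = H, rank = 4), class = "metamarker_model")
  states <- assign_immune_states(model)
  expect_equal(unname(states[1:4]), rep("Active", 4))
  expect_equal(unname(states[5:8]), rep("Suppressed", 4))
  expect_equal(unname(states[9:12]), rep("Excluded", 4))

  # permutation of regions permutes labels identically
  perm <- sample(ncol(H))
  model2 <- structure(list(W = diag(4), H = H[, perm], rank = 4),
                      class = "metamarker_model")
  expect_equal(assign_immune_states(model2), states[perm])

  # duplicating every region leaves per-region assignments unchanged
  model3 <- structure(list(W = diag(4), H = cbind(H, H), rank = 4),
                      class = "metamarker_model")
  dup <- assign_immune_states(model3)
  expect_equal(dup[colnames(H)], states)

  flat <- structure(list(W = diag(4), H = H[, c(1, 1, 1)], rank = 4),
                    class = "metamarker_model")
  expect_error(assign_immune_states(flat), "distinct")
})

test_that("compartment ratios reproduce the stroma/epithelium skew", {
  d <- matrix(0, nrow = 3, ncol = 18,
              dimnames = list(c("r1", "r2", "r3"), immune_feature_names()))
  d["r1", "TC_t_Epi"] <- 10; d["r1", "TC_t_Str"] <- 98
  d["r2", "TC_t_Epi"] <- 0;  d["r2", "TC_t_Str"] <- 50
  cr <- compartment_ratio(d)
  tc <- cr[cr$cell_type == "TC", ]
  expect_equal(tc$ratio[tc$region_id == "r1"], 9.8)
  expect_true(tc$unbounded[tc$region_id == "r2"])
  expect_equal(tc$category[tc$region_id == "r3"], "none")
  # scale invariance
  cr2 <- compartment_ratio(d * 2)
  expect_equal(cr2$ratio, cr$ratio)
  # both-zero cell types are 'none' everywhere
  expect_true(all(cr$category[cr$cell_type == "BC"] == "none"))
})

test_that("the immune pipeline recovers planted states (ARI >= 0.8, 20 seeds)", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:20, function(s) {
    sim <- simulate_immune_cohort(immune_sim_spec(seed = s))
    scores <- decile_regularize(sim$densities)
    model <- factorize_densities(scores, rank = 4, seed = s)
    states <- assign_immune_states(model)
    mclust::adjustedRandIndex(states[names(sim$truth)], sim$truth)
  }, numeric(1))
  expect_gte(min(aris), 0.8)

  # zero dispersion recovers the partition exactly
  sim0 <- simulate_immune_cohort(immune_sim_spec(dispersion = 0, seed = 1))
  model0 <- factorize_densities(decile_regularize(sim0$densities),
                                rank = 4, seed = 1)
  states0 <- assign_immune_states(model0)
  expect_equal(mclust::adjustedRandIndex(states0[names(sim0$truth)], sim0$truth), 1)
})
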
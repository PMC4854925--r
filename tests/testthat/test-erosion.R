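m_matrix_from <- function(values, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(sprintf("p%03d", seq_len(nrow(values))), sample_ids)
  beta_to_m(methyl_matrix(1 / (1 + 2^(-values)), "beta"), epsilon = 1e-8)
}

test_that("intra/inter variances match the naive two-pass oracle", {
  set.seed(40)
  vals <- matrix(rnorm(30 * 8), 30, 8)
  m <- m_matrix_from(vals)
  grp <- factor(rep(c("young", "old"), each = 4), levels = c("young", "old"))
  ev <- methylome_variances(m, grp, top_n = 5)
  naive_intra <- apply(unclass(m), 2, var)
  expect_equal(ev$intra$intra_variance, unname(naive_intra), tolerance = 1e-10)
  naive_inter_y <- apply(unclass(m)[, 1:4], 1, var)
  expect_equal(ev$inter$inter_variance_young, unname(naive_inter_y),
               tolerance = 1e-10)
  expect_length(ev$top_probes, 5)

  # documented (n-1) convention: [-2,0,2] and [-1,0,1] give 4 and 1
  m2 <- m_matrix_from(cbind(c(-2, 0, 2), c(-1, 0, 1), c(0, 0, 0), c(1, 1, 1)))
  ev2 <- methylome_variances(m2, factor(c("young", "young", "old", "old"),
                                        levels = c("young", "old")))
  expect_equal(ev2$intra$intra_variance, c(4, 1, 0, 0))
  expect_error(methylome_variances(m2[1, , drop = FALSE], grp[1:4]), "two probes")
})

test_that("planted erosion reduces old intra-variance and correlation", {
  cf <- synth_config(n_probes = 2000, age_design = "two_group", seed = 41,
                     effect_fractions = c(null = 1, linear_drift = 0,
                                          changepoint = 0,
                                          age_independent_variable = 0),
                     erosion = list(s = 0.8, h = 2))
  coh <- generate_methylome_cohort(cf)
  grp <- factor(coh$samples$group, levels = c("young", "old"))
  ev <- methylome_variances(beta_to_m(coh$beta), grp)
  expect_lt(ev$intra_test$median_2, ev$intra_test$median_1)
  expect_lt(ev$intra_test$p_value, 0.01)
  sc <- sample_correlation_summary(coh$beta, grp)
  expect_lt(sc$block_means[["within_old"]], sc$block_means[["within_young"]])
})

test_that("spatial pairs, medians, and decay behave as constructed", {
  beta <- tiny_beta(matrix(c(0.30, 0.30, 0.40, 0.40, 0.20, 0.20), 3, 2,
                           byrow = TRUE),
                    probe_ids = c("cgA", "cgB", "cgC"))
  ann <- tiny_annotation(c("cgA", "cgB", "cgC"), pos = c(100, 200, 1500))
  grp <- factor(c("young", "old"), levels = c("young", "old"))
  # need >= 2 per group: duplicate columns
  beta4 <- tiny_beta(unclass(beta)[, c(1, 1, 2, 2)],
                     probe_ids = rownames(beta))
  grp4 <- factor(rep(c("young", "old"), each = 2), levels = c("young", "old"))
  sp <- spatial_decay_curve(beta4, ann, grp4, max_dist = 1000)
  expect_equal(sp$n_pairs, 1)  # only cgA-cgB within 1000 bases
  young_curve <- sp$curves[sp$curves$group == "young", ]
  expect_equal(young_curve$distance, 100)
  expect_equal(young_curve$median_dbeta, 0.10)  # |0.30 - 0.40|
  expect_error(spatial_decay_curve(beta4, ann, grp4, max_dist = 50), "no probe pairs")

  # generator: monotone decay with distance, old curve above young
  cf <- synth_config(n_probes = 4000, age_design = "two_group", seed = 42,
                     effect_fractions = c(null = 1, linear_drift = 0,
                                          changepoint = 0,
                                          age_independent_variable = 0),
                     erosion = list(s = 0.8, h = 2))
  coh <- generate_methylome_cohort(cf)
  grpc <- factor(coh$samples$group, levels = c("young", "old"))
  spc <- spatial_decay_curve(coh$beta, coh$annotation, grpc)
  yy <- spc$curves[spc$curves$group == "young", ]
  expect_gt(cor(yy$distance, yy$median_dbeta, method = "spearman"), 0)
  oo <- spc$curves[spc$curves$group == "old", ]
  common <- intersect(yy$distance, oo$distance)
  expect_true(all(oo$smoothed[match(common, oo$distance)] >
                  yy$smoothed[match(common, yy$distance)]))
  expect_lt(spc$p_value, 0.01)
})

test_that("sample correlations handle duplicates, inversions and degeneracy", {
  set.seed(43)
  x <- runif(50, 0.1, 0.9)
  vals <- cbind(x, x, 1 - x, runif(50, 0.1, 0.9))
  beta <- tiny_beta(vals, sample_ids = sprintf("S%02d", 1:4))
  grp <- factor(rep(c("young", "old"), each = 2), levels = c("young", "old"))
  sc <- sample_correlation_summary(beta, grp)
  expect_equal(sc$correlation["S01", "S02"], 1)
  expect_equal(sc$correlation["S01", "S03"], -1)
  expect_true(isSymmetric(sc$correlation))
  # affine transform of every sample with positive scale leaves r unchanged
  beta_t <- tiny_beta(vals * 0.5 + 0.2, sample_ids = sprintf("S%02d", 1:4))
  sc_t <- sample_correlation_summary(beta_t, grp)
  expect_equal(sc_t$correlation, sc$correlation, tolerance = 1e-12)

  vals2 <- cbind(vals[, 1:3], rep(0.4, 50))
  beta2 <- tiny_beta(vals2, sample_ids = sprintf("S%02d", 1:4))
  expect_warning(sc2 <- sample_correlation_summary(beta2, grp), "zero-variance")
  expect_true(is.na(sc2$correlation["S04", "S01"]))
  expect_false(is.na(sc2$block_means[["within_young"]]))
})

test_that("with erosion disabled the intra-variance test is null-calibrated", {
  pvals <- vapply(1:40, function(seed) {
    cf <- synth_config(n_probes = 400, age_design = "two_group", seed = seed,
                       n_young = 12, n_old = 12,
                       effect_fractions = c(null = 1, linear_drift = 0,
                                            changepoint = 0,
                                            age_independent_variable = 0),
                       erosion = list(s = 1, h = 1))
    coh <- generate_methylome_cohort(cf)
    grp <- factor(coh$samples$group, levels = c("young", "old"))
    methylome_variances(beta_to_m(coh$beta), grp)$intra_test$p_value
  }, numeric(1))
  # rejection rate at 5% within binomial tolerance for 40 seeds
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
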
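make_m_matrix <- function(values) {
  dimnames(values) <- list(sprintf("p%04d", seq_len(nrow(values))),
                           sprintf("S%03d", seq_len(ncol(values))))
  beta_to_m(methyl_matrix(1 / (1 + 2^(-values)), "beta"), epsilon = 1e-8)
}

test_that("moderated t matches the from-the-formulas oracle", {
  set.seed(10)
  m <- make_m_matrix(matrix(rnorm(200 * 12, sd = 0.8), 200, 12))
  grp <- factor(rep(c("young", "old"), each = 6), levels = c("young", "old"))
  fit <- moderated_t_test(m, grp)
  orc <- oracle_moderated_t(unclass(m), 1:6, 7:12)
  expect_equal(fit$ebayes$df_prior, orc$d0, tolerance = 1e-8)
  expect_equal(fit$ebayes$s2_prior, orc$s02, tolerance = 1e-8)
  expect_equal(fit$table$t, orc$t, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$table$p_value, orc$p, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate probes and limiting priors behave as documented", {
  set.seed(11)
  vals <- matrix(rnorm(50 * 10, sd = 0.5), 50, 10)
  vals[1, ] <- 0.3  # constant probe in both groups
  m <- make_m_matrix(vals)
  grp <- factor(rep(c("young", "old"), each = 5), levels = c("young", "old"))
  fit <- moderated_t_test(m, grp)
  expect_equal(fit$table$t[1], 0)
  expect_equal(fit$table$p_value[1], 1)
  expect_equal(fit$table$delta_beta[1], 0)
  expect_true(is.na(fit$table$direction[1]))
  # adjusted p never below raw p; |delta beta| bounded; direction = sign
  expect_true(all(fit$table$adj_p_value >= fit$table$p_value))
  expect_true(all(abs(fit$table$delta_beta) <= 1))
  expect_identical(fit$table$direction[fit$table$delta_beta > 0][1], "hyper")
  # sign(delta beta) tracks sign(delta m) except for negligible effects
  # (group means of the nonlinear inverse-logit can flip sign near zero)
  big <- abs(fit$table$delta_beta) > 1e-3
  expect_true(all(sign(fit$table$delta_beta[big]) == sign(fit$table$delta_m[big])))

  # d0 -> 0 forces the ordinary equal-variance t-test
  fit0 <- moderated_t_test(m[-1, ], grp, df_prior = 0, s2_prior = 1)
  plain <- apply(unclass(m)[-1, ], 1, function(v) {
    ht <- t.test(v[6:10], v[1:5], var.equal = TRUE)
    c(ht$statistic, ht$p.value)
  })
  expect_equal(fit0$table$t, unname(plain[1, ]), tolerance = 1e-10)
  expect_equal(fit0$table$p_value, unname(plain[2, ]), tolerance = 1e-10)

  # d0 -> Inf gives the normal-theory statistic with pooled prior variance
  fitInf <- moderated_t_test(m[-1, ], grp, df_prior = Inf, s2_prior = 0.25)
  dm <- rowMeans(unclass(m)[-1, 6:10]) - rowMeans(unclass(m)[-1, 1:5])
  z <- dm / sqrt(0.25 * (1 / 5 + 1 / 5))
  expect_equal(fitInf$table$t, unname(z), tolerance = 1e-10)
  expect_equal(fitInf$table$p_value, unname(2 * pnorm(-abs(z))), tolerance = 1e-10)
})

test_that("moderated t agrees with limma to high precision", {
  set.seed(12)
  m <- make_m_matrix(matrix(rnorm(300 * 14, sd = 0.6), 300, 14))
  grp <- factor(rep(c("young", "old"), each = 7), levels = c("young", "old"))
  fit <- moderated_t_test(m, grp)
  design <- cbind(1, as.integer(grp) - 1)
  lf <- limma::eBayes(limma::lmFit(unclass(m), design))
  expect_equal(fit$ebayes$df_prior, lf$df.prior, tolerance = 1e-10)
  expect_equal(fit$ebayes$s2_prior, lf$s2.prior, tolerance = 1e-10)
  expect_equal(fit$table$t, unname(lf$t[, 2]), tolerance = 1e-10)
  expect_equal(fit$table$p_value, unname(lf$p.value[, 2]), tolerance = 1e-10)
})

test_that("BH adjustment matches hand-computed and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.001, 0.5, 0.9)), c(0.003, 0.75, 0.9))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-15)
  }
})

test_that("substructure analysis flags the planted island hypermethylation", {
  set.seed(14)
  base <- matrix(runif(8 * 8, 0.3, 0.5), 8, 8)
  base[1:4, 5:8] <- base[1:4, 5:8] + 0.2  # island probes up in old
  beta <- tiny_beta(base)
  ann <- tiny_annotation(rownames(beta),
                         island = c(rep("island", 4), rep("open_sea", 4)))
  grp <- factor(rep(c("young", "old"), each = 4), levels = c("young", "old"))
  m <- beta_to_m(beta)
  fit <- moderated_t_test(m, grp)
  sub <- suppressWarnings(substructure_analysis(beta, ann, grp, fit, alpha = 0.05))
  ct <- sub$class_test
  expect_gt(ct$difference[ct$class == "island"], 0.15)
  expect_lt(ct$p_value[ct$class == "island"], 0.05)
  expect_gt(ct$p_value[ct$class == "open_sea"], 0.05)

  # enrichment arithmetic on constructed counts: 40 of 50 hyper DMPs island
  # against an array-wide island fraction of 20% gives fraction 0.8, ratio 4
  ids <- sprintf("x%03d", 1:250)
  ann2 <- tiny_annotation(ids, island = c(rep("island", 50), rep("open_sea", 200)))
  dmp_tab <- data.frame(
    probe_id = ids,
    adj_p_value = c(rep(0, 50), rep(1, 200)),
    direction = "hyper", stringsAsFactors = FALSE)
  dmp_tab$adj_p_value[c(1:40, 51:60)] <- 0    # 40 island + 10 open sea hyper
  dmp_tab$adj_p_value[setdiff(1:250, c(1:40, 51:60))] <- 1
  fake_fit <- list(table = dmp_tab)
  beta2 <- tiny_beta(matrix(0.5, 250, 4), probe_ids = ids)
  grp2 <- factor(rep(c("young", "old"), each = 2), levels = c("young", "old"))
  sub2 <- suppressWarnings(substructure_analysis(beta2, ann2, grp2, fake_fit, alpha = 0.5))
  hyper <- sub2$enrichment$hyper
  expect_equal(hyper$fraction[hyper$class == "island"], 0.8)
  expect_equal(hyper$enrichment_ratio[hyper$class == "island"], 4)

  # single represented class is not testable
  ann3 <- tiny_annotation(rownames(beta), island = "island")
  sub3 <- suppressWarnings(substructure_analysis(beta, ann3, grp, fit, alpha = 0.05))
  expect_identical(unique(sub3$enrichment$hyper$note), "not testable")
})

test_that("LAD mean beta reports group means and differences correctly", {
  beta <- tiny_beta(matrix(0.6, 10, 8))
  ann <- tiny_annotation(rownames(beta), lad = c(rep(TRUE, 6), rep(FALSE, 4)))
  grp <- factor(rep(c("young", "old"), each = 4), levels = c("young", "old"))
  res <- lad_mean_beta(beta, ann, grp)
  expect_equal(unname(res$group_mean), c(0.6, 0.6))
  expect_equal(res$difference, 0)
  expect_equal(res$n_lad_probes, 6)

  b2 <- unclass(beta)
  b2[1:6, 5:8] <- 0.5  # LAD probes drop by 0.1 in old
  res2 <- lad_mean_beta(tiny_beta(b2), ann, grp)
  expect_equal(res2$difference, -0.1)

  ann$lad <- FALSE
  expect_error(lad_mean_beta(beta, ann, grp), "no LAD probes")
})

test_that("no LAD difference arises without a planted LAD effect", {
  cf <- synth_config(n_probes = 2000, age_design = "two_group", seed = 31,
                     effect_fractions = c(null = 1, linear_drift = 0,
                                          changepoint = 0,
                                          age_independent_variable = 0),
                     erosion = list(s = 1, h = 1))
  coh <- generate_methylome_cohort(cf)
  grp <- factor(coh$samples$group, levels = c("young", "old"))
  res <- lad_mean_beta(coh$beta, coh$annotation, grp)
  # group means are over hundreds of LAD probes: SE is tiny; allow 3 SEs of
  # the per-sample mean variability
  se <- sd(res$sample_means) * sqrt(1 / 24 + 1 / 24)
  expect_lt(abs(res$difference), 3 * se)
  expect_gt(res$p_value, 0.01)
})
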
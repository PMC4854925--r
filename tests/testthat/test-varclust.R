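test_that("top variable probes are ranked by SD with lexicographic ties", {
  sds <- c(0.30, 0.20, 0.10, 0.05, 0.01)
  vals <- t(vapply(sds, function(s) s * c(-1, 1, -1, 1) * sqrt(3) / 2 + 0.5,
                   numeric(4)))
  beta <- tiny_beta(vals, probe_ids = c("cgE", "cgD", "cgC", "cgB", "cgA"))
  expect_identical(top_variable_probes(beta, 2), c("cgE", "cgD"))
  expect_identical(top_variable_probes(beta, 5),
                   c("cgE", "cgD", "cgC", "cgB", "cgA"))
  expect_error(top_variable_probes(beta, 0), "positive")

  # exact SD tie at the boundary: lexicographically smaller id wins
  vals2 <- rbind(A = c(0.2, 0.4), B = c(0.4, 0.2), C = c(0.5, 0.5))
  beta2 <- tiny_beta(vals2, probe_ids = c("cgB", "cgA", "cgC"))
  expect_identical(top_variable_probes(beta2, 1), "cgA")
})

test_that("duplicated samples always co-cluster; seeded reruns are identical", {
  set.seed(30)
  vals <- matrix(runif(40 * 10), 40, 10)
  vals[, 2] <- vals[, 1]  # exact duplicate pair
  beta <- tiny_beta(vals)
  res <- consensus_cluster(beta, k = 2, B = 50, p_item = 0.8, seed = 3)
  expect_equal(res$consensus["S01", "S02"], 1)
  expect_true(all(res$consensus >= 0 & res$consensus <= 1))
  expect_true(isSymmetric(res$consensus))
  expect_equal(unname(diag(res$consensus)), rep(1, 10))
  res2 <- consensus_cluster(beta, k = 2, B = 50, p_item = 0.8, seed = 3)
  expect_identical(res$consensus, res2$consensus)
  expect_error(consensus_cluster(beta, k = 9, B = 5, p_item = 0.8), "smaller than k")
})

test_that("pure-noise consensus is diffuse, separated groups are crisp", {
  set.seed(31)
  noise <- tiny_beta(matrix(runif(60 * 16), 60, 16))
  res <- consensus_cluster(noise, k = 2, B = 200, seed = 4)
  off <- res$consensus[upper.tri(res$consensus)]
  expect_gt(max(off) - min(off), 0.3)

  sep <- matrix(0.3, 60, 16)
  sep[, 9:16] <- 0.7
  sep <- tiny_beta(sep + matrix(rnorm(60 * 16, sd = 0.03), 60, 16))
  res2 <- consensus_cluster(sep, k = 2, B = 200, seed = 4)
  off2 <- res2$consensus[upper.tri(res2$consensus)]
  expect_true(all(off2 %in% c(0, 1)))
  expect_equal(length(unique(res2$assignment[1:8])), 1)
  expect_equal(length(unique(res2$assignment[9:16])), 1)
})

test_that("age dependence uses closed mean+/-SD interval separation", {
  # three dyadic values m-a, m, m+a have mean m and SD a exactly in floating
  # point, so interval endpoints (including the exact-touch case) are exact
  mk <- function(y_mean, y_sd, o_mean, o_sd) {
    c(y_mean + y_sd * c(-1, 0, 1), o_mean + o_sd * c(-1, 0, 1))
  }
  vals <- rbind(mk(0.2500, 0.0625, 0.5000, 0.0625),  # disjoint -> dependent
                mk(0.3125, 0.1250, 0.4375, 0.1250),  # overlap -> not
                mk(0.3125, 0.0625, 0.4375, 0.0625),  # touching -> not (closed)
                mk(0.4000, 0.0000, 0.4000, 0.0000))  # degenerate equal -> not
  beta <- tiny_beta(vals)
  grp <- factor(rep(c("young", "old"), each = 3), levels = c("young", "old"))
  dep <- classify_age_dependence(beta, grp)
  expect_identical(unname(dep), c(TRUE, FALSE, FALSE, FALSE))
  # symmetric in group labels
  dep_sw <- classify_age_dependence(beta, factor(grp, levels = c("old", "young")))
  expect_identical(unname(dep), unname(dep_sw))
})

test_that("single-split fit handles perfect steps, constants and ties", {
  perfect <- fit_single_split(c(20, 25, 30, 60, 65, 70),
                              c(0.2, 0.2, 0.2, 0.6, 0.6, 0.6), min_branch = 3)
  expect_equal(perfect$tau, 45)
  expect_equal(perfect$rel_err, 0)
  expect_identical(perfect$direction, "hyper")
  expect_true(perfect$retained)

  const <- fit_single_split(c(20, 25, 30, 60, 65, 70), rep(0.4, 6), min_branch = 3)
  expect_equal(const$rel_err, 1)
  expect_false(const$retained)

  # two equally good splits: youngest tau wins
  tie <- fit_single_split(c(20, 30, 40, 50), c(0.2, 0.4, 0.2, 0.4), min_branch = 1)
  expect_equal(tie$tau, 25)

  expect_error(fit_single_split(c(20, 30), c(0.1, 0.2), min_branch = 3), "min_branch")
  expect_error(fit_single_split(rep(50, 10), runif(10), min_branch = 5), "distinct")
})

test_that("single-split fit agrees exactly with the brute-force oracle", {
  set.seed(32)
  for (i in 1:100) {
    n <- sample(10:30, 1)
    ages <- sample(18:79, n, replace = TRUE)
    if (length(unique(ages)) < 2) next
    betas <- runif(n)
    mine <- fit_single_split(ages, betas, min_branch = 3)
    orc <- oracle_single_split(ages, betas, min_branch = 3)
    expect_equal(mine$tau, orc$tau)
    expect_equal(mine$rel_err, orc$rel_err, tolerance = 1e-10)
  }
})

test_that("relative error falls as the planted step grows", {
  set.seed(33)
  ages <- sample(20:79, 60, replace = TRUE)
  mean_rel_err <- vapply(c(0.05, 0.15, 0.3), function(step) {
    mean(vapply(1:50, function(r) {
      y <- 0.3 + step * (ages >= 50) + rnorm(60, sd = 0.05)
      fit_single_split(ages, y)$rel_err
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rel_err) < 0))
})

test_that("discontinuity detection recovers noiseless planted steps", {
  set.seed(34)
  ages <- c(seq(20, 78, length.out = 40))
  n <- length(ages)
  mk_step <- function(tau, step) 0.3 + step * (ages >= tau)
  vals <- rbind(
    t(replicate(10, mk_step(40, 0.3))),   # hyper at 40
    t(replicate(5, mk_step(55, -0.25))),  # hypo at 55
    matrix(0.5, 5, n))                    # constants, never retained
  beta <- tiny_beta(vals, sample_ids = sprintf("S%02d", 1:n))
  ann <- tiny_annotation(rownames(beta),
                         island = c(rep("island", 10), rep("open_sea", 10)))
  sheet <- sample_sheet(data.frame(sample_id = colnames(beta), age = ages,
                                   group = "other", stringsAsFactors = FALSE))
  disc <- detect_discontinuous_changes(beta, sheet, rownames(beta),
                                       annotation = ann, bin_width = 5)
  expect_equal(nrow(disc$retained), 15)
  expect_equal(sum(disc$retained$direction == "hyper"), 10)
  expect_equal(sum(disc$retained$direction == "hypo"), 5)
  expect_equal(disc$counts["hyper", "[40,45)"], 10)
  # tau_hat is the midpoint between the flanking grid ages (54.2 and 55.7)
  expect_equal(disc$counts["hypo", "[50,55)"], 5)
  expect_equal(unname(disc$island_fraction["hyper"]), 1)
  expect_equal(unname(disc$island_fraction["hypo"]), 0)
  expect_error(detect_discontinuous_changes(beta, sheet, character(0)), "empty")
})
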
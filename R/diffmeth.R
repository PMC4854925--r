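#' Empirical-Bayes moderated t-test between two age groups
#'
#' Fits a per-probe two-group linear model on M values and shrinks the
#' residual variances toward a pooled prior using the standard
#' scaled-inverse-chi-square empirical-Bayes model: the prior degrees of
#' freedom `d0` and prior variance `s0^2` are estimated by matching the first
#' two moments of `log(s_g^2)` (digamma/trigamma inversion), the posterior
#' variance is `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and the
#' moderated t is `delta_m / (s~_g sqrt(1/n1 + 1/n2))` on `d0 + d_g` degrees
#' of freedom. Effect sizes (`delta_beta`) are reported on the beta scale
#' (difference of group mean betas, second level minus first).
#'
#' @param m_matrix [methyl_matrix] on the M scale.
#' @param groups two-level factor (or sample sheet with a `group` column)
#'   aligned with the matrix columns; the contrast is level 2 minus level 1
#'   (young/old labels are ordered young first).
#' @param df_prior,s2_prior optional overrides of the estimated prior; use
#'   `df_prior = 0` to force the ordinary equal-variance t-test and
#'   `df_prior = Inf` for complete shrinkage to `s2_prior`.
#' @param var_floor residual variances below this are floored before the
#'   log-moment estimation (digamma inversion needs positive variances).
#' @return object of class `dmp_fit`: list with `table` (per-probe results:
#'   group mean betas, `delta_beta`, moderated `t`, `p_value`, `adj_p_value`,
#'   `direction`) and `ebayes` (`df_prior`, `s2_prior`, `s2_post`,
#'   `df_residual`, `df_total`).
#' @export
moderated_t_test <- function(m_matrix, groups, df_prior = NULL,
                             s2_prior = NULL, var_floor = 1e-12) {
  if (meth_scale(m_matrix) != "m") {
    stop("moderated_t_test expects M values; run beta_to_m() first")
  }
  groups <- as_two_groups(groups, colnames(m_matrix))
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  n1 <- length(g1); n2 <- length(g2)
  d_g <- n1 + n2 - 2
  if (d_g < 1) stop("zero residual degrees of freedom")

  m <- unclass(m_matrix)
  mean1 <- rowMeans(m[, g1, drop = FALSE])
  mean2 <- rowMeans(m[, g2, drop = FALSE])
  ss1 <- rowSums((m[, g1, drop = FALSE] - mean1)^2)
  ss2 <- rowSums((m[, g2, drop = FALSE] - mean2)^2)
  s2_g <- (ss1 + ss2) / d_g

  if (is.null(df_prior) || is.null(s2_prior)) {
    fit <- fit_scaled_invchisq(pmax(s2_g, var_floor), d_g)
    if (is.null(df_prior)) df_prior <- fit$df_prior
    if (is.null(s2_prior)) s2_prior <- fit$s2_prior
  }
  if (df_prior < 0) stop("df_prior must be >= 0")

  s2_post <- if (is.infinite(df_prior)) rep(s2_prior, length(s2_g)) else {
    (df_prior * s2_prior + d_g * s2_g) / (df_prior + d_g)
  }
  df_total <- df_prior + d_g
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  delta_m <- mean2 - mean1
  tstat <- ifelse(se > 0, delta_m / se, 0)
  # constant probe in both groups: no evidence, t = 0, p = 1
  tstat[s2_g == 0 & delta_m == 0] <- 0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat)) else {
    2 * stats::pt(-abs(tstat), df = df_total)
  }

  beta <- ilogit2(m)
  bmean1 <- rowMeans(beta[, g1, drop = FALSE])
  bmean2 <- rowMeans(beta[, g2, drop = FALSE])
  dbeta <- bmean2 - bmean1

  tab <- data.frame(
    probe_id = rownames(m),
    mean_beta_1 = bmean1, mean_beta_2 = bmean2,
    delta_beta = dbeta, delta_m = delta_m,
    t = tstat, p_value = p, adj_p_value = bh_adjust(p),
    direction = ifelse(dbeta > 0, "hyper", ifelse(dbeta < 0, "hypo", NA)),
    stringsAsFactors = FALSE, row.names = NULL)
  names(tab)[2:3] <- paste0("mean_beta_", levels(groups))

  structure(list(
    table = tab,
    ebayes = list(df_prior = df_prior, s2_prior = s2_prior,
                  s2_g = s2_g, s2_post = s2_post,
                  df_residual = d_g, df_total = df_total),
    groups = levels(groups), n = c(n1, n2)),
    class = "dmp_fit")
}

#' @export
print.dmp_fit <- function(x, alpha = 0.01, ...) {
  n_sig <- sum(x$table$adj_p_value < alpha)
  cat("<dmp_fit> ", nrow(x$table), " probes, groups ", x$groups[1], " (n=",
      x$n[1], ") vs ", x$groups[2], " (n=", x$n[2], ")\n", sep = "")
  cat("  prior df: ", format(x$ebayes$df_prior, digits = 4),
      ", prior variance: ", format(x$ebayes$s2_prior, digits = 4), "\n", sep = "")
  cat("  ", n_sig, " probes with adjusted p < ", alpha, "\n", sep = "")
  invisible(x)
}

#' @export
summary.dmp_fit <- function(object, alpha = 0.01, ...) {
  sig <- object$table[object$table$adj_p_value < alpha, ]
  out <- list(
    n_probes = nrow(object$table), alpha = alpha, n_significant = nrow(sig),
    n_hyper = sum(sig$direction == "hyper", na.rm = TRUE),
    n_hypo = sum(sig$direction == "hypo", na.rm = TRUE),
    median_abs_delta_beta = stats::median(abs(sig$delta_beta)),
    df_prior = object$ebayes$df_prior, s2_prior = object$ebayes$s2_prior)
  class(out) <- "summary.dmp_fit"
  out
}

#' @export
print.summary.dmp_fit <- function(x, ...) {
  cat(x$n_significant, " of ", x$n_probes, " probes at adjusted p < ",
      x$alpha, " (", x$n_hyper, " hyper / ", x$n_hypo, " hypo)\n", sep = "")
  cat("median |delta beta| among significant:",
      format(x$median_abs_delta_beta, digits = 3), "\n")
  invisible(x)
}

# Closed-form moment estimation of the scaled inverse-chi-square prior for
# residual variances: match mean and variance of log(s2_g), with the known
# sampling contributions digamma(d/2), trigamma(d/2) removed.
fit_scaled_invchisq <- function(s2_g, d_g) {
  z <- log(s2_g)
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  ebar <- mean(e)
  n <- length(e)
  if (n < 2) return(list(df_prior = Inf, s2_prior = exp(ebar)))
  evar <- stats::var(e) - trigamma(d_g / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(ebar + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(ebar)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# Newton iteration for trigamma^{-1}(x) on the log scale is unnecessary:
# the update y <- y + tri*(1-tri/x)/psigamma(y,2) is monotone and quadratic.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1, input
#' order preserved.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Methylation summaries per epigenomic substructure
#'
#' (i) Per sample and island-relation class, the mean beta; young vs old
#' compared per class with a two-sided Wilcoxon rank-sum test on the
#' per-sample means. (ii) Among DMPs at `adj_p < alpha`, split by direction,
#' the per-class fractions compared with the array-wide class fractions via a
#' chi-square goodness-of-fit test; enrichment ratio = class fraction among
#' DMPs / array-wide class fraction.
#'
#' @param beta [methyl_matrix] on the beta scale.
#' @param annotation probe annotation covering all probes.
#' @param groups two-level factor or sample sheet.
#' @param dmp a `dmp_fit`.
#' @param alpha adjusted-p threshold for calling DMPs (default 0.01).
#' @return object of class `substructure_summary`.
#' @export
substructure_analysis <- function(beta, annotation, groups, dmp, alpha = 0.01) {
  stopifnot(meth_scale(beta) == "beta")
  groups <- as_two_groups(groups, colnames(beta))
  idx <- match(rownames(beta), annotation$probe_id)
  if (anyNA(idx)) stop("annotation does not cover all probes")
  ann <- annotation[idx, , drop = FALSE]

  present <- table(ann$island_relation)
  empty <- names(present)[present == 0]
  if (length(empty)) {
    warning("classes with zero probes excluded: ", paste(empty, collapse = ", "))
  }
  classes <- names(present)[present > 0]

  sample_means <- t(vapply(classes, function(cl) {
    colMeans(unclass(beta)[ann$island_relation == cl, , drop = FALSE])
  }, numeric(ncol(beta))))

  class_test <- do.call(rbind, lapply(classes, function(cl) {
    v <- sample_means[cl, ]
    y <- v[groups == levels(groups)[1]]
    o <- v[groups == levels(groups)[2]]
    wt <- stats::wilcox.test(o, y, exact = FALSE)
    data.frame(class = cl, mean_1 = mean(y), mean_2 = mean(o),
               difference = mean(o) - mean(y), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  names(class_test)[2:3] <- paste0("mean_", levels(groups))

  array_counts <- as.numeric(present[classes])
  array_frac <- array_counts / sum(array_counts)
  tab <- dmp$table
  sig <- tab[tab$adj_p_value < alpha & !is.na(tab$direction), ]
  enrichment <- lapply(c(hyper = "hyper", hypo = "hypo"), function(dir) {
    ids <- sig$probe_id[sig$direction == dir]
    cls <- ann$island_relation[match(ids, ann$probe_id)]
    counts <- as.numeric(table(factor(cls, levels = classes)))
    frac <- if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, length(classes))
    testable <- length(classes) > 1 && sum(counts) > 0
    chisq <- if (testable) {
      suppressWarnings(stats::chisq.test(counts, p = array_frac))
    } else NULL
    data.frame(class = classes, n_dmp = counts, fraction = frac,
               array_fraction = array_frac,
               enrichment_ratio = frac / array_frac,
               chisq_stat = if (testable) chisq$statistic else NA_real_,
               chisq_p = if (testable) chisq$p.value else NA_real_,
               note = if (testable) "" else "not testable",
               stringsAsFactors = FALSE, row.names = NULL)
  })

  structure(list(sample_means = sample_means, class_test = class_test,
                 enrichment = enrichment, alpha = alpha,
                 groups = levels(groups)),
            class = "substructure_summary")
}

#' @export
print.substructure_summary <- function(x, ...) {
  cat("<substructure_summary> group comparison (", x$groups[2], " - ",
      x$groups[1], "):\n", sep = "")
  print(x$class_test, row.names = FALSE, digits = 3)
  cat("DMP enrichment at adjusted p <", x$alpha, "(hyper):\n")
  print(x$enrichment$hyper[, c("class", "n_dmp", "fraction", "array_fraction",
                               "enrichment_ratio")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Mean beta of lamina-associated-domain probes per group
#'
#' For each group: the mean over LAD probes of the per-probe group-mean beta,
#' its dispersion (SD over LAD probes), per-sample LAD means for plotting,
#' and the old-minus-young difference with a rank-sum p-value on per-sample
#' means.
#'
#' @param beta [methyl_matrix] on the beta scale.
#' @param annotation probe annotation with the `lad` flag.
#' @param groups two-level factor or sample sheet.
#' @return list with `group_mean`, `group_sd`, `difference`, `sample_means`,
#'   `p_value`, `n_lad_probes`.
#' @export
lad_mean_beta <- function(beta, annotation, groups) {
  stopifnot(meth_scale(beta) == "beta")
  groups <- as_two_groups(groups, colnames(beta))
  idx <- match(rownames(beta), annotation$probe_id)
  if (anyNA(idx)) stop("annotation does not cover all probes")
  lad <- annotation$lad[idx]
  if (!any(lad)) stop("no LAD probes in the matrix")
  b <- unclass(beta)[lad, , drop = FALSE]
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  pm1 <- rowMeans(b[, g1, drop = FALSE])
  pm2 <- rowMeans(b[, g2, drop = FALSE])
  sample_means <- colMeans(b)
  wt <- stats::wilcox.test(sample_means[g2], sample_means[g1], exact = FALSE)
  gm <- c(mean(pm1), mean(pm2))
  names(gm) <- levels(groups)
  gs <- c(stats::sd(pm1), stats::sd(pm2))
  names(gs) <- levels(groups)
  list(group_mean = gm, group_sd = gs,
       difference = gm[[2]] - gm[[1]],
       sample_means = sample_means, p_value = wt$p.value,
       n_lad_probes = sum(lad))
}

#' Write a DMP table to TSV
#' @param dmp a `dmp_fit`.
#' @param path output path.
#' @export
write_dmp_table <- function(dmp, path) {
  utils::write.table(dmp$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
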
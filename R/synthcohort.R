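#' Configuration for a synthetic methylation cohort
#'
#' The defaults emulate the study design the package targets: 108 female
#' donors (24 young aged 18-27, 24 old aged 61-78, 60 spanning 20-79),
#' bimodally methylated probes (low ~0.12 / high ~0.85, island probes
#' preferentially low), per-probe age effects (linear drift, step changes, or
#' age-independent inter-individual variability), an age-dependent erosion of
#' patterning (dynamic-range compression `s` and inter-individual noise
#' multiplier `h`, each interpolating linearly from 1 at the youngest age to
#' the configured value at the oldest), and short-range spatial structure:
#' a shared methylation landscape plus per-sample random fields smoothed over
#' an autocorrelation length along the chromosome.
#'
#' @param n_probes,n_samples cohort dimensions. `n_samples` is used for the
#'   `uniform` design; the `two_group` design has `n_young + n_old` samples
#'   and `mixed` adds `n_uniform` more.
#' @param age_design `"two_group"`, `"uniform"` or `"mixed"`.
#' @param n_young,n_old,n_uniform group sizes (defaults 24/24/60).
#' @param young_range,old_range,uniform_range age ranges in years.
#' @param effect_fractions named numeric summing to 1 over classes
#'   `null`, `linear_drift`, `changepoint`, `age_independent_variable`.
#' @param drift_slope_range absolute drift slope range, beta/year.
#' @param changepoint list with `step` (delta-beta), `tau_range` (years) and
#'   `p_hyper` (fraction of steps that are hypermethylating).
#' @param noise_sd_beta inter-individual noise SD on the beta scale.
#' @param erosion list with `s` (old-age dynamic-range compression in (0,1])
#'   and `h` (old-age noise multiplier >= 1).
#' @param spatial list with `mean_spacing` (bases between probes),
#'   `autocorr_length` (bases), `field_sd_beta` (per-sample field SD),
#'   `landscape_sd_beta` (shared landscape SD) and `domain_length`
#'   (persistence of low/high methylation domains, bases).
#' @param island_fraction per-class probability that a probe of that class is
#'   island-annotated.
#' @param aiv_sd_beta extra inter-individual SD for the
#'   age-independent-variable class.
#' @param lad_fraction fraction of open-sea probes flagged as LAD.
#' @param epsilon clipping bound for the noise-free profile.
#' @param n_chrom number of chromosomes the probes are spread over.
#' @param seed integer RNG seed; identical configs and seeds reproduce
#'   bit-identical cohorts.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_probes = 20000,
                         n_samples = 108,
                         age_design = c("mixed", "two_group", "uniform"),
                         n_young = 24, n_old = 24, n_uniform = 60,
                         young_range = c(18, 27),
                         old_range = c(61, 78),
                         uniform_range = c(20, 79),
                         effect_fractions = c(null = 0.90, linear_drift = 0.05,
                                              changepoint = 0.03,
                                              age_independent_variable = 0.02),
                         drift_slope_range = c(0.002, 0.005),
                         changepoint = list(step = 0.3, tau_range = c(30, 60),
                                            p_hyper = 0.75),
                         noise_sd_beta = 0.05,
                         erosion = list(s = 0.8, h = 2),
                         spatial = list(mean_spacing = 300,
                                        autocorr_length = 500,
                                        field_sd_beta = 0.015,
                                        landscape_sd_beta = 0.015,
                                        domain_length = 5000),
                         island_fraction = c(null = 0.31, linear_drift = 0.31,
                                             changepoint = 0.42,
                                             age_independent_variable = 0.31),
                         aiv_sd_beta = 0.15,
                         lad_fraction = 0.25,
                         epsilon = 1e-3,
                         n_chrom = 4,
                         seed = 1) {
  age_design <- match.arg(age_design)
  classes <- c("null", "linear_drift", "changepoint", "age_independent_variable")
  if (!setequal(names(effect_fractions), classes)) {
    stop("effect_fractions must be named: ", paste(classes, collapse = ", "))
  }
  effect_fractions <- effect_fractions[classes]
  if (any(effect_fractions < 0) || abs(sum(effect_fractions) - 1) > 1e-8) {
    stop("effect_fractions must be non-negative and sum to 1")
  }
  for (rng in list(young_range, old_range, uniform_range, drift_slope_range,
                   changepoint$tau_range)) {
    if (length(rng) != 2 || rng[1] > rng[2]) stop("ranges must be well-ordered pairs")
  }
  if (!(erosion$s > 0 && erosion$s <= 1)) stop("erosion$s must be in (0, 1]")
  if (erosion$h < 1) stop("erosion$h must be >= 1")
  if (noise_sd_beta < 0) stop("noise_sd_beta must be >= 0")
  if (changepoint$step < 0 || changepoint$step > 1) stop("changepoint step must be in [0,1]")
  if (n_probes < 1) stop("n_probes must be positive")
  structure(list(
    n_probes = as.integer(n_probes), n_samples = as.integer(n_samples),
    age_design = age_design, n_young = n_young, n_old = n_old,
    n_uniform = n_uniform, young_range = young_range, old_range = old_range,
    uniform_range = uniform_range, effect_fractions = effect_fractions,
    drift_slope_range = drift_slope_range, changepoint = changepoint,
    noise_sd_beta = noise_sd_beta, erosion = erosion, spatial = spatial,
    island_fraction = island_fraction, aiv_sd_beta = aiv_sd_beta,
    lad_fraction = lad_fraction, epsilon = epsilon,
    n_chrom = as.integer(n_chrom), seed = as.integer(seed)),
    class = "synth_config")
}

#' Generate a synthetic methylation cohort with planted age effects
#'
#' Per probe `i` and sample `j` the noise-free beta-scale profile is
#' `c_ij = mu_i + effect_i(age_j) + L(pos_i) + F_j(pos_i)`, where `mu_i` is a
#' bimodal baseline organized into low/high methylation domains along the
#' chromosome, `L` is a shared smooth landscape and `F_j` a per-sample smooth
#' random field (both with the configured autocorrelation length, so
#' short-range beta similarity decays with distance). Effects are `0` (null),
#' `slope * (age - 40)` (drift), or `step * 1[age >= tau]` (changepoint).
#' Erosion then compresses the profile toward the cohort grand mean,
#' `c <- mbar + s(age) * (c - mbar)` with `s(age)` interpolating 1 -> `s`
#' across the observed age range, and the profile is clipped to
#' `[eps, 1-eps]`. Finally inter-individual noise with beta-scale SD
#' `noise_sd_beta * h(age)` (delta-method scaled on the M scale, so M values
#' are Gaussian per probe) is added and values are mapped back to beta.
#'
#' @param config a [synth_config()].
#' @return list with `beta` ([methyl_matrix]), `annotation`, `samples`,
#'   `mask` (all-`FALSE`), and `truth` (list: `probes` data frame of planted
#'   parameters, `samples` with per-sample `s_age`/`h_age`, `erosion`,
#'   `grand_mean`).
#' @export
generate_methylome_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cf <- config

  samples <- synth_ages(cf)
  n <- nrow(samples)
  m <- cf$n_probes

  # --- genomic layout: positions, domains, annotation ----------------------
  per_chrom <- diff(floor(seq(0, m, length.out = cf$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(cf$n_chrom)), times = per_chrom)
  gaps <- pmax(10, round(stats::rexp(m, rate = 1 / cf$spatial$mean_spacing)))
  pos <- stats::ave(gaps, chrom, FUN = cumsum) + 1000
  probe_id <- sprintf("cg%06d", seq_len(m))

  # low/high methylation domains: state persists along the chromosome and is
  # redrawn with probability 1 - exp(-gap / domain_length)
  p_low <- 0.35
  redraw <- stats::runif(m) < (1 - exp(-gaps / cf$spatial$domain_length))
  draw <- stats::runif(m) < p_low
  low <- logical(m)
  new_chrom <- c(TRUE, chrom[-1] != chrom[-m])
  state <- FALSE
  for (i in seq_len(m)) {
    if (new_chrom[i] || redraw[i]) state <- draw[i]
    low[i] <- state
  }

  island_relation <- ifelse(low,
    ifelse(stats::runif(m) < 0.7, "island", "shore"),
    c("open_sea", "shelf", "shore")[1 + findInterval(stats::runif(m), c(0.75, 0.90))])

  # --- effect classes, island enrichment via stratified assignment ---------
  n_class <- round(cf$effect_fractions * m)
  n_class["null"] <- m - sum(n_class[-1])
  class <- rep("null", m)
  is_island <- island_relation == "island"
  avail_isl <- which(is_island)
  avail_sea <- which(!is_island)
  for (cl in c("linear_drift", "changepoint", "age_independent_variable")) {
    k <- n_class[[cl]]
    if (k == 0) next
    k_isl <- min(round(k * cf$island_fraction[[cl]]), length(avail_isl))
    pick_isl <- if (k_isl > 0) sample(avail_isl, k_isl) else integer(0)
    pick_sea <- if (k - k_isl > 0) sample(avail_sea, k - k_isl) else integer(0)
    picked <- c(pick_isl, pick_sea)
    class[picked] <- cl
    avail_isl <- setdiff(avail_isl, picked)
    avail_sea <- setdiff(avail_sea, picked)
  }

  # --- planted parameters ---------------------------------------------------
  slope <- rep(0, m)
  tau <- rep(NA_real_, m)
  step <- rep(0, m)
  direction <- rep(NA_character_, m)
  i_dr <- class == "linear_drift"
  if (any(i_dr)) {
    sgn <- ifelse(stats::runif(sum(i_dr)) < 0.5, 1, -1)
    slope[i_dr] <- sgn * stats::runif(sum(i_dr), cf$drift_slope_range[1],
                                      cf$drift_slope_range[2])
    direction[i_dr] <- ifelse(sgn > 0, "hyper", "hypo")
  }
  i_cp <- class == "changepoint"
  if (any(i_cp)) {
    hyper <- stats::runif(sum(i_cp)) < cf$changepoint$p_hyper
    step[i_cp] <- ifelse(hyper, 1, -1) * cf$changepoint$step
    tau[i_cp] <- stats::runif(sum(i_cp), cf$changepoint$tau_range[1],
                              cf$changepoint$tau_range[2])
    direction[i_cp] <- ifelse(hyper, "hyper", "hypo")
  }

  # --- baselines: bimodal, spatially organized; effect probes start at
  # intermediate methylation so planted steps are not distorted by clipping
  mu <- ifelse(low, stats::rnorm(m, 0.12, 0.01), stats::rnorm(m, 0.85, 0.015))
  mu <- clip01(mu, 0.03)
  mu[i_dr & slope > 0] <- stats::rnorm(sum(i_dr & slope > 0), 0.30, 0.05)
  mu[i_dr & slope < 0] <- stats::rnorm(sum(i_dr & slope < 0), 0.70, 0.05)
  mu[i_cp & step > 0] <- stats::rnorm(sum(i_cp & step > 0), 0.20, 0.03)
  mu[i_cp & step < 0] <- stats::rnorm(sum(i_cp & step < 0), 0.70, 0.03)
  mu <- clip01(mu, 0.03)

  lad <- !low & island_relation == "open_sea" &
    stats::runif(m) < cf$lad_fraction / 0.75

  annotation <- probe_annotation(data.frame(
    probe_id = probe_id, chrom = chrom, pos = as.integer(pos),
    island_relation = island_relation, lad = lad,
    on_sex_chromosome = FALSE, cross_reactive = FALSE, snp_near_sbe = FALSE,
    context = "CpG", stringsAsFactors = FALSE))

  # --- spatial smoothing operator (banded Gaussian kernel, unit-variance) --
  W <- spatial_smoother(chrom, pos, cf$spatial$autocorr_length)

  landscape <- if (cf$spatial$landscape_sd_beta > 0) {
    cf$spatial$landscape_sd_beta * as.numeric(W %*% stats::rnorm(m))
  } else rep(0, m)

  ages <- samples$age
  eff <- matrix(0, m, n)
  if (any(i_dr)) eff[i_dr, ] <- outer(slope[i_dr], ages - 40)
  if (any(i_cp)) {
    eff[i_cp, ] <- step[i_cp] *
      outer(tau[i_cp], ages, function(tt, aa) as.numeric(aa >= tt))
  }

  centers <- mu + landscape + eff
  if (cf$spatial$field_sd_beta > 0) {
    Z <- matrix(stats::rnorm(m * n), m, n)
    centers <- centers + cf$spatial$field_sd_beta * as.matrix(W %*% Z)
  }

  # --- erosion of the noise-free profile -----------------------------------
  age_span <- range(ages)
  frac <- if (diff(age_span) > 0) (ages - age_span[1]) / diff(age_span) else rep(0, n)
  s_age <- 1 + frac * (cf$erosion$s - 1)
  h_age <- 1 + frac * (cf$erosion$h - 1)
  mbar <- mean(mu)
  centers <- mbar + sweep(centers - mbar, 2, s_age, `*`)
  centers <- clip01(centers, cf$epsilon)

  # --- inter-individual noise on the M scale, beta-scale SD as configured --
  sd_beta <- matrix(rep(cf$noise_sd_beta * h_age, each = m), m, n)
  i_aiv <- class == "age_independent_variable"
  if (any(i_aiv)) sd_beta[i_aiv, ] <- sqrt(sd_beta[i_aiv, ]^2 + cf$aiv_sd_beta^2)
  deriv <- log(2) * pmax(centers * (1 - centers), 0.03 * 0.97)
  mvals <- logit2(centers)
  if (any(sd_beta > 0)) {
    mvals <- mvals + matrix(stats::rnorm(m * n), m, n) * (sd_beta / deriv)
  }
  beta <- ilogit2(mvals)
  dimnames(beta) <- list(probe_id, samples$sample_id)

  truth <- list(
    probes = data.frame(probe_id = probe_id, class = class, slope = slope,
                        tau = tau, step = step, direction = direction,
                        baseline = mu, island = is_island,
                        stringsAsFactors = FALSE),
    samples = data.frame(sample_id = samples$sample_id, age = ages,
                         group = samples$group, s_age = s_age, h_age = h_age,
                         stringsAsFactors = FALSE),
    erosion = cf$erosion, grand_mean = mbar)

  list(beta = methyl_matrix(beta, "beta"), annotation = annotation,
       samples = samples,
       mask = matrix(FALSE, m, n, dimnames = list(probe_id, samples$sample_id)),
       truth = truth)
}

synth_ages <- function(cf) {
  age_int <- function(k, rng) sample(seq(rng[1], rng[2]), k, replace = TRUE)
  if (cf$age_design == "two_group") {
    ages <- c(age_int(cf$n_young, cf$young_range), age_int(cf$n_old, cf$old_range))
    group <- rep(c("young", "old"), c(cf$n_young, cf$n_old))
  } else if (cf$age_design == "uniform") {
    ages <- age_int(cf$n_samples, cf$uniform_range)
    group <- rep("other", cf$n_samples)
  } else {
    ages <- c(age_int(cf$n_young, cf$young_range),
              age_int(cf$n_old, cf$old_range),
              age_int(cf$n_uniform, cf$uniform_range))
    group <- c(rep("young", cf$n_young), rep("old", cf$n_old),
               rep("other", cf$n_uniform))
  }
  sample_sheet(data.frame(
    sample_id = sprintf("S%03d", seq_along(ages)), age = ages, group = group,
    stringsAsFactors = FALSE))
}

# Banded row-stochastic-in-L2 Gaussian smoother along genomic position:
# row i holds kernel weights over probes within 3*length on the same
# chromosome, normalized so the smoothed field has unit variance.
spatial_smoother <- function(chrom, pos, length_bp) {
  m <- length(pos)
  cutoff <- 3 * length_bp
  idx_i <- integer(0); idx_j <- integer(0); val <- numeric(0)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    p <- pos[sel]
    o <- order(p)
    sel <- sel[o]; p <- p[o]
    k <- length(sel)
    lo <- 1L
    out_i <- vector("list", k)
    for (a in seq_len(k)) {
      while (p[a] - p[lo] > cutoff) lo <- lo + 1L
      hi <- a
      while (hi < k && p[hi + 1] - p[a] <= cutoff) hi <- hi + 1L
      nb <- lo:hi
      w <- exp(-((p[nb] - p[a])^2) / (2 * length_bp^2))
      w <- w / sqrt(sum(w^2))
      out_i[[a]] <- cbind(rep(sel[a], length(nb)), sel[nb], w)
    }
    block <- do.call(rbind, out_i)
    idx_i <- c(idx_i, block[, 1]); idx_j <- c(idx_j, block[, 2])
    val <- c(val, block[, 3])
  }
  Matrix::sparseMatrix(i = idx_i, j = idx_j, x = val, dims = c(m, m))
}

#' Generate a synthetic expression cohort with age-dependent co-expression
#'
#' Module genes follow a single-factor model per group: standardized
#' expression `= sqrt(r) * factor + sqrt(1-r) * noise`, giving population
#' pairwise correlation `r_young` among young and `r_old` among old samples.
#' Non-module genes are independent noise. Values are on a log2-like
#' intensity scale (gene-specific mean and spread); module genes get larger
#' spreads so that variance-based gene selection retains them.
#'
#' @param n_genes total genes.
#' @param modules list of lists/vectors with elements `size`, `r_young`,
#'   `r_old` (each `r` in `[0, 1)`).
#' @param n_young,n_old group sizes (defaults 12 and 19).
#' @param seed RNG seed.
#' @return list with `expr` (genes x samples matrix), `samples` (sample
#'   sheet), `gene_sets` (named list of module memberships) and `truth`.
#' @export
generate_expression_cohort <- function(n_genes = 2000,
                                       modules = list(
                                         list(size = 40, r_young = 0.7, r_old = 0.2),
                                         list(size = 40, r_young = 0.7, r_old = 0.2)),
                                       n_young = 12, n_old = 19, seed = 1) {
  set.seed(seed)
  sizes <- vapply(modules, function(mo) as.integer(mo[["size"]]), 1L)
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")
  for (mo in modules) {
    for (r in c(mo[["r_young"]], mo[["r_old"]])) {
      if (r < 0 || r >= 1) {
        stop("module correlations must lie in [0, 1); got ", r,
             " (use 0.999 for the degenerate r = 1 boundary)")
      }
    }
  }
  n <- n_young + n_old
  group <- rep(c("young", "old"), c(n_young, n_old))
  ages <- c(sample(20:30, n_young, replace = TRUE),
            sample(61:79, n_old, replace = TRUE))
  samples <- sample_sheet(data.frame(
    sample_id = sprintf("E%03d", seq_len(n)), age = ages, group = group,
    stringsAsFactors = FALSE))

  gene_id <- sprintf("G%05d", seq_len(n_genes))
  membership <- rep(0L, n_genes)
  pool <- sample(n_genes)
  at <- 1L
  gene_sets <- list()
  for (k in seq_along(sizes)) {
    idx <- pool[at:(at + sizes[k] - 1)]
    membership[idx] <- k
    gene_sets[[sprintf("MODULE_%02d", k)]] <- gene_id[idx]
    at <- at + sizes[k]
  }

  z <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  for (k in seq_along(sizes)) {
    idx <- which(membership == k)
    for (grp in c("young", "old")) {
      cols <- which(group == grp)
      r <- if (grp == "young") modules[[k]][["r_young"]] else modules[[k]][["r_old"]]
      f <- stats::rnorm(length(cols))
      z[idx, cols] <- sqrt(r) * matrix(f, length(idx), length(cols), byrow = TRUE) +
        sqrt(1 - r) * z[idx, cols]
    }
  }
  gene_mean <- stats::rnorm(n_genes, 8, 1.5)
  gene_sd <- ifelse(membership > 0, stats::runif(n_genes, 1.5, 2.5),
                    stats::runif(n_genes, 0.5, 1.5))
  expr <- gene_mean + gene_sd * z
  dimnames(expr) <- list(gene_id, samples$sample_id)

  truth <- list(
    genes = data.frame(gene_id = gene_id, module = membership,
                       stringsAsFactors = FALSE),
    modules = data.frame(
      module = seq_along(sizes), size = sizes,
      r_young = vapply(modules, function(mo) mo[["r_young"]], 1),
      r_old = vapply(modules, function(mo) mo[["r_old"]], 1)))

  list(expr = expr, samples = samples, gene_sets = gene_sets, truth = truth)
}

#' Write a synthetic truth table
#' @param truth truth component of [generate_methylome_cohort()].
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
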
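# Independent naive oracles, written directly from the defining formulas and
# kept deliberately different from the package's implementation (loops instead
# of vectorized cumulants, uniroot instead of Newton iteration).

# Moderated two-group t-test, straight from the hierarchical-model formulas.
oracle_moderated_t <- function(m, g1_idx, g2_idx) {
  n1 <- length(g1_idx); n2 <- length(g2_idx)
  dg <- n1 + n2 - 2
  nprobe <- nrow(m)
  s2 <- numeric(nprobe); dm <- numeric(nprobe)
  for (i in seq_len(nprobe)) {
    y1 <- m[i, g1_idx]; y2 <- m[i, g2_idx]
    s2[i] <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / dg
    dm[i] <- mean(y2) - mean(y1)
  }
  s2f <- pmax(s2, 1e-12)
  e <- log(s2f) - digamma(dg / 2) + log(dg / 2)
  evar <- sum((e - mean(e))^2) / (length(e) - 1) - trigamma(dg / 2)
  if (evar > 0) {
    half_d0 <- stats::uniroot(function(y) trigamma(y) - evar,
                              interval = c(1e-8, 1e8), tol = 1e-14)$root
    d0 <- 2 * half_d0
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  s2post <- if (is.infinite(d0)) rep(s02, nprobe) else {
    (d0 * s02 + dg * s2f) / (d0 + dg)
  }
  tt <- dm / sqrt(s2post * (1 / n1 + 1 / n2))
  tt[s2 == 0 & dm == 0] <- 0
  df_tot <- d0 + dg
  pp <- if (is.infinite(df_tot)) 2 * pnorm(-abs(tt)) else 2 * pt(-abs(tt), df_tot)
  list(t = tt, p = pp, d0 = d0, s02 = s02)
}

# O(m^2) brute-force BH: for each p, the minimum over all q >= p of q * m / rank(q).
oracle_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- p >= p[i]
    min(1, min(p[cand] * m / rk[cand]))
  }, numeric(1))
}

# Brute-force depth-one split: every midpoint threshold, direct SSE sums.
oracle_single_split <- function(ages, betas, min_branch = 5) {
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  root <- sse(betas)
  ua <- sort(unique(ages))
  best <- NULL
  for (i in seq_len(length(ua) - 1)) {
    thr <- (ua[i] + ua[i + 1]) / 2
    left <- ages < thr
    if (sum(left) < min_branch || sum(!left) < min_branch) next
    s <- sse(betas[left]) + sse(betas[!left])
    if (is.null(best) || s < best$sse - 1e-12) {
      best <- list(tau = thr, sse = s,
                   left_mean = mean(betas[left]), right_mean = mean(betas[!left]))
    }
  }
  if (is.null(best)) return(list(tau = NA_real_, rel_err = 1))
  best$rel_err <- if (root > 0) best$sse / root else 1
  best
}
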
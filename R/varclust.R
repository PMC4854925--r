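#' Most variable probes by beta-value standard deviation
#'
#' @param beta [methyl_matrix] on the beta scale.
#' @param k number of probes to return (largest SDs across all samples
#'   supplied); ties broken by lexicographic probe id for determinism.
#' @return character vector of probe ids, in decreasing-SD order.
#' @export
top_variable_probes <- function(beta, k) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(beta)) stop("k exceeds the number of probes")
  sds <- row_sds(unclass(beta))
  ord <- order(-sds, rownames(beta))
  rownames(beta)[ord[seq_len(k)]]
}

#' Consensus clustering by subsampled k-means
#'
#' Runs `B` iterations; each draws `ceiling(p_item * n)` samples (and
#' `ceiling(p_feature * m)` probes) without replacement, clusters the
#' subsample with k-means, and tallies co-clustering over co-sampling counts.
#' The consensus entry (i, j) is the fraction of co-sampled iterations in
#' which samples i and j landed in the same cluster; the final assignment
#' cuts an average-linkage hierarchical clustering of `1 - consensus` into
#' `k` groups.
#'
#' @param beta_subset [methyl_matrix] (typically the most variable probes).
#' @param k number of clusters (>= 2).
#' @param B number of subsampled clustering iterations (default 1000).
#' @param p_item item (sample) subsampling proportion in (0, 1].
#' @param p_feature feature (probe) subsampling proportion in (0, 1].
#' @param seed RNG seed.
#' @param nstart k-means restarts per iteration.
#' @return object of class `consensus_result`: `consensus` (samples x samples
#'   matrix in `[0,1]`, diagonal 1), `assignment` (named integer vector),
#'   `params`.
#' @export
consensus_cluster <- function(beta_subset, k = 2, B = 1000, p_item = 0.8,
                              p_feature = 1, seed = 1, nstart = 5) {
  if (k < 2) stop("k must be >= 2")
  if (!(p_item > 0 && p_item <= 1)) stop("p_item must be in (0, 1]")
  if (!(p_feature > 0 && p_feature <= 1)) stop("p_feature must be in (0, 1]")
  x <- t(unclass(beta_subset))  # samples x probes
  n <- nrow(x); m <- ncol(x)
  n_item <- ceiling(p_item * n)
  n_feat <- ceiling(p_feature * m)
  if (n_item < k) stop("subsample size (", n_item, ") smaller than k (", k, ")")

  set.seed(seed)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (b in seq_len(B)) {
    items <- sample(n, n_item)
    feats <- if (n_feat < m) sample(m, n_feat) else seq_len(m)
    km <- stats::kmeans(x[items, feats, drop = FALSE], centers = k,
                        nstart = nstart)
    ind <- matrix(0, n, k)
    ind[cbind(items, km$cluster)] <- 1
    co_cluster <- co_cluster + tcrossprod(ind)
    samp <- numeric(n); samp[items] <- 1
    co_sample <- co_sample + tcrossprod(samp)
  }
  if (any(co_sample == 0 & upper.tri(co_sample))) {
    warning("some sample pairs were never co-sampled; consensus set to 0 there")
  }
  consensus <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(rownames(x), rownames(x))

  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  assignment <- stats::cutree(hc, k = k)

  structure(list(consensus = consensus, assignment = assignment,
                 params = list(k = k, B = B, p_item = p_item,
                               p_feature = p_feature, seed = seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  off <- x$consensus[upper.tri(x$consensus)]
  cat("<consensus_result> ", ncol(x$consensus), " samples, k=", x$params$k,
      ", B=", x$params$B, "\n", sep = "")
  cat("  cluster sizes:", paste(table(x$assignment), collapse = "/"), "\n")
  cat(sprintf("  off-diagonal consensus: min %.3f / median %.3f / max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Classify probes as age-dependent by interval separation
#'
#' A probe is age-dependent iff the closed intervals mean +/- SD of its beta
#' values in the two groups do not overlap (a shared endpoint counts as
#' overlap).
#'
#' @param beta [methyl_matrix] on the beta scale.
#' @param groups two-level factor or sample sheet.
#' @return named logical vector per probe.
#' @export
classify_age_dependence <- function(beta, groups) {
  groups <- as_two_groups(groups, colnames(beta))
  b <- unclass(beta)
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  m1 <- rowMeans(b[, g1, drop = FALSE]); s1 <- row_sds(b[, g1, drop = FALSE])
  m2 <- rowMeans(b[, g2, drop = FALSE]); s2 <- row_sds(b[, g2, drop = FALSE])
  disjoint <- (m1 + s1 < m2 - s2) | (m2 + s2 < m1 - s1)
  stats::setNames(disjoint, rownames(b))
}

#' Fit the best single split of beta values over age
#'
#' Depth-one regression tree by exhaustive search: candidate thresholds are
#' the midpoints between consecutive distinct sorted ages; the split
#' minimizing `SSE_left + SSE_right` subject to both branches holding at
#' least `min_branch` samples is chosen, ties broken toward the youngest
#' threshold. The relative error is the post-split SSE divided by the
#' unsplit SSE (defined as 1 for constant input or when no feasible split
#' exists).
#'
#' @param ages numeric vector of ages in years.
#' @param betas numeric vector of beta values, same length.
#' @param min_branch minimum samples per branch (default 5).
#' @param rel_err_max retention threshold on the relative error (default 0.75).
#' @return one-row data frame: `tau` (split age, midpoint), `left_mean`,
#'   `right_mean`, `n_left`, `n_right`, `rel_err`, `direction`
#'   (sign of right minus left mean), `retained`.
#' @export
fit_single_split <- function(ages, betas, min_branch = 5, rel_err_max = 0.75) {
  stopifnot(length(ages) == length(betas))
  n <- length(ages)
  if (n < 2 * min_branch) stop("need at least 2 * min_branch samples")
  if (length(unique(ages)) < 2) stop("need at least two distinct ages")

  o <- order(ages)
  a <- ages[o]; x <- betas[o]
  sse_root <- sum((x - mean(x))^2)

  # candidate split points: after each run of equal ages
  last_of_age <- which(diff(a) > 0)
  csum <- cumsum(x); csq <- cumsum(x^2)
  total <- csum[n]; total_sq <- csq[n]
  nl <- last_of_age
  feasible <- nl >= min_branch & (n - nl) >= min_branch
  no_split <- function() data.frame(
    tau = NA_real_, left_mean = NA_real_, right_mean = NA_real_,
    n_left = NA_integer_, n_right = NA_integer_, rel_err = 1,
    direction = NA_character_, retained = FALSE, stringsAsFactors = FALSE)
  if (!any(feasible)) return(no_split())
  nl <- nl[feasible]
  cut_idx <- last_of_age[feasible]

  sse_left <- csq[cut_idx] - csum[cut_idx]^2 / nl
  sse_right <- (total_sq - csq[cut_idx]) - (total - csum[cut_idx])^2 / (n - nl)
  sse <- sse_left + sse_right
  best <- which(sse <= min(sse) + 1e-12)[1]  # tie -> youngest threshold
  i <- cut_idx[best]
  tau <- (a[i] + a[i + 1]) / 2
  lmean <- csum[i] / i
  rmean <- (total - csum[i]) / (n - i)
  rel_err <- if (sse_root > 0) sse[best] / sse_root else 1
  data.frame(
    tau = tau, left_mean = lmean, right_mean = rmean,
    n_left = i, n_right = n - i, rel_err = rel_err,
    direction = if (rmean > lmean) "hyper" else if (rmean < lmean) "hypo" else NA_character_,
    retained = sse_root > 0 && rel_err <= rel_err_max,
    stringsAsFactors = FALSE)
}

#' Detect discontinuous (step-like) age-related methylation changes
#'
#' Applies [fit_single_split()] to every probe in `probe_list`, retains
#' probes with relative error at most `rel_err_max`, and stratifies retained
#' records by direction and by split age binned in `bin_width`-year bins,
#' with CpG-island fractions per direction and a cumulative count-by-age
#' table.
#'
#' @param beta [methyl_matrix] on the beta scale.
#' @param ages sample sheet or numeric age vector.
#' @param probe_list probe ids to analyze (subset of the matrix probes).
#' @param rel_err_max relative-error retention threshold (default 0.75).
#' @param annotation probe annotation (for island fractions); optional.
#' @param bin_width age bin width in years (default 5).
#' @param min_branch minimum samples per branch.
#' @return object of class `discontinuity_table`: `records` (all
#'   changepoint fits), `retained`, `counts` (direction x age-bin), and
#'   `island_fraction` per direction.
#' @export
detect_discontinuous_changes <- function(beta, ages, probe_list,
                                         rel_err_max = 0.75,
                                         annotation = NULL, bin_width = 5,
                                         min_branch = 5) {
  if (!length(probe_list)) stop("probe_list is empty")
  miss <- setdiff(probe_list, rownames(beta))
  if (length(miss)) stop("probes not in matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  age <- ages_from(ages, colnames(beta))
  b <- unclass(beta)

  records <- do.call(rbind, lapply(probe_list, function(pid) {
    rec <- fit_single_split(age, b[pid, ], min_branch = min_branch,
                            rel_err_max = rel_err_max)
    cbind(probe_id = pid, rec, stringsAsFactors = FALSE)
  }))

  retained <- records[records$retained & !is.na(records$direction), ]

  breaks <- seq(bin_width * floor(min(age) / bin_width),
                bin_width * ceiling(max(age) / bin_width), by = bin_width)
  bin <- cut(retained$tau, breaks = breaks, right = FALSE)
  counts <- table(direction = factor(retained$direction,
                                     levels = c("hyper", "hypo")), bin)
  cumulative <- t(apply(counts, 1, cumsum))

  island_fraction <- c(hyper = NA_real_, hypo = NA_real_)
  if (!is.null(annotation)) {
    isl <- annotation$island_relation[match(retained$probe_id,
                                            annotation$probe_id)] == "island"
    for (dir in c("hyper", "hypo")) {
      sel <- retained$direction == dir
      if (any(sel)) island_fraction[dir] <- mean(isl[sel])
    }
  }

  structure(list(records = records, retained = retained, counts = counts,
                 cumulative = cumulative, island_fraction = island_fraction,
                 rel_err_max = rel_err_max, bin_width = bin_width),
            class = "discontinuity_table")
}

#' @export
print.discontinuity_table <- function(x, ...) {
  cat("<discontinuity_table> ", nrow(x$records), " probes scanned, ",
      nrow(x$retained), " retained at relative error <= ", x$rel_err_max,
      "\n", sep = "")
  dirs <- table(factor(x$retained$direction, levels = c("hyper", "hypo")))
  cat("  ", dirs[["hyper"]], " hyper / ", dirs[["hypo"]], " hypo\n", sep = "")
  if (!all(is.na(x$island_fraction))) {
    cat(sprintf("  island fraction: hyper %.2f, hypo %.2f\n",
                x$island_fraction[["hyper"]], x$island_fraction[["hypo"]]))
  }
  invisible(x)
}

#' Write changepoint records to TSV
#' @param disc a `discontinuity_table`.
#' @param path output path.
#' @export
write_changepoints <- function(disc, path) {
  utils::write.table(disc$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
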
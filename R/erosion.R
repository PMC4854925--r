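#' Intra- and inter-methylome variance
#'
#' Intra-methylome variance: per sample, the variance of M values across all
#' probes (the dynamic range of that methylome); compared young vs old with a
#' two-sided Wilcoxon rank-sum test. Inter-methylome variance: per probe and
#' group, the variance of M values across that group's samples. Variances use
#' the unbiased (n-1) convention.
#'
#' @param m_matrix [methyl_matrix] on the M scale.
#' @param groups two-level factor or sample sheet.
#' @param top_n number of most inter-variable probes to report (default 30,
#'   ranked by variance across all samples).
#' @return object of class `erosion_variances`: `intra` (data frame per
#'   sample), `intra_test` (rank-sum p-value and group medians), `inter`
#'   (per-probe per-group variances), `top_probes`.
#' @export
methylome_variances <- function(m_matrix, groups, top_n = 30) {
  if (meth_scale(m_matrix) != "m") stop("methylome_variances expects M values")
  if (nrow(m_matrix) < 2) stop("need at least two probes")
  groups <- as_two_groups(groups, colnames(m_matrix))
  m <- unclass(m_matrix)
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]

  intra <- col_vars(m)
  wt <- stats::wilcox.test(intra[g2], intra[g1], exact = FALSE)
  intra_df <- data.frame(sample_id = colnames(m), group = as.character(groups),
                         intra_variance = intra, stringsAsFactors = FALSE,
                         row.names = NULL)

  inter <- data.frame(probe_id = rownames(m),
                      v1 = row_vars(m[, g1, drop = FALSE]),
                      v2 = row_vars(m[, g2, drop = FALSE]),
                      stringsAsFactors = FALSE, row.names = NULL)
  names(inter)[2:3] <- paste0("inter_variance_", levels(groups))

  overall <- row_vars(m)
  top_probes <- rownames(m)[order(-overall)][seq_len(min(top_n, nrow(m)))]

  structure(list(
    intra = intra_df,
    intra_test = list(
      p_value = wt$p.value,
      median_1 = stats::median(intra[g1]), median_2 = stats::median(intra[g2]),
      groups = levels(groups)),
    inter = inter, top_probes = top_probes),
    class = "erosion_variances")
}

#' @export
print.erosion_variances <- function(x, ...) {
  it <- x$intra_test
  cat("<erosion_variances> intra-methylome variance by group:\n")
  cat(sprintf("  median %s: %.3f   median %s: %.3f   rank-sum p = %.3g\n",
              it$groups[1], it$median_1, it$groups[2], it$median_2, it$p_value))
  invisible(x)
}

#' Spatial decay of methylation similarity with probe distance
#'
#' Enumerates unordered same-chromosome probe pairs within `max_dist` bases,
#' computes per group the absolute difference of the two probes' group-mean
#' beta values, takes the median per distinct distance, and smooths the
#' median curve by locally weighted regression over distance. The group
#' difference is tested with a two-sided paired Wilcoxon signed-rank test
#' over distances present in both groups.
#'
#' @param beta [methyl_matrix] on the beta scale.
#' @param annotation probe annotation with coordinates.
#' @param groups two-level factor or sample sheet.
#' @param max_dist maximum pair distance in bases (default 1000).
#' @param smooth_frac lowess span over distance (default 0.3).
#' @return object of class `spatial_decay`: `curves` (data frame: group,
#'   distance, median_dbeta, smoothed), `p_value`, `n_pairs`.
#' @export
spatial_decay_curve <- function(beta, annotation, groups, max_dist = 1000,
                                smooth_frac = 0.3) {
  stopifnot(meth_scale(beta) == "beta")
  if (max_dist < 1) stop("max_dist must be >= 1")
  groups <- as_two_groups(groups, colnames(beta))
  idx <- match(rownames(beta), annotation$probe_id)
  if (anyNA(idx)) stop("annotation does not cover all probes")
  ann <- annotation[idx, , drop = FALSE]

  pairs <- enumerate_pairs(ann$chrom, ann$pos, max_dist)
  if (!nrow(pairs)) stop("no probe pairs within ", max_dist, " bases")

  b <- unclass(beta)
  curves <- list()
  medians <- list()
  for (lev in levels(groups)) {
    gm <- rowMeans(b[, groups == lev, drop = FALSE])
    dbeta <- abs(gm[pairs[, 1]] - gm[pairs[, 2]])
    med <- tapply(dbeta, pairs[, 3], stats::median)
    d <- as.numeric(names(med))
    o <- order(d)
    d <- d[o]; med <- as.numeric(med)[o]
    smoothed <- if (length(d) >= 2) {
      sm <- stats::lowess(d, med, f = smooth_frac)
      stats::approx(sm$x, sm$y, xout = d, rule = 2)$y
    } else med
    curves[[lev]] <- data.frame(group = lev, distance = d, median_dbeta = med,
                                smoothed = smoothed, stringsAsFactors = FALSE)
    medians[[lev]] <- stats::setNames(med, d)
  }
  common <- intersect(names(medians[[1]]), names(medians[[2]]))
  wt <- stats::wilcox.test(medians[[2]][common], medians[[1]][common],
                           paired = TRUE, exact = FALSE)

  structure(list(curves = do.call(rbind, curves), p_value = wt$p.value,
                 n_pairs = nrow(pairs), max_dist = max_dist,
                 groups = levels(groups)),
            class = "spatial_decay")
}

#' @export
print.spatial_decay <- function(x, ...) {
  cat("<spatial_decay> ", x$n_pairs, " probe pairs within ", x$max_dist,
      " bases\n", sep = "")
  for (lev in x$groups) {
    cv <- x$curves[x$curves$group == lev, ]
    cat(sprintf("  %s: smoothed median |dbeta| %.4f at %d b -> %.4f at %d b\n",
                lev, cv$smoothed[1], as.integer(cv$distance[1]),
                cv$smoothed[nrow(cv)], as.integer(cv$distance[nrow(cv)])))
  }
  cat(sprintf("  paired signed-rank p = %.3g\n", x$p_value))
  invisible(x)
}

# unordered same-chromosome pairs with 0 < distance <= max_dist;
# returns a matrix with columns i, j, distance
enumerate_pairs <- function(chrom, pos, max_dist) {
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    o <- order(pos[sel])
    sel <- sel[o]
    p <- pos[sel]
    k <- length(sel)
    if (k < 2) next
    blocks <- list()
    for (a in seq_len(k - 1)) {
      hi <- a
      while (hi < k && p[hi + 1] - p[a] <= max_dist) hi <- hi + 1L
      if (hi > a) {
        nb <- (a + 1):hi
        d <- p[nb] - p[a]
        keep <- d > 0
        if (any(keep)) {
          blocks[[length(blocks) + 1]] <-
            cbind(sel[a], sel[nb[keep]], d[keep])
        }
      }
    }
    if (length(blocks)) out[[ch]] <- do.call(rbind, blocks)
  }
  if (!length(out)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, out)
}

#' Pairwise sample correlation of beta profiles
#'
#' Full Pearson correlation matrix of the samples' beta vectors plus the mean
#' correlation within the young-young, old-old and young-old off-diagonal
#' blocks. Zero-variance samples have undefined correlations; they are
#' reported as `NA` and excluded from the block means with a warning.
#'
#' @param beta [methyl_matrix] on the beta scale (>= 2 probes).
#' @param groups two-level factor or sample sheet.
#' @return object of class `sample_correlation`: `correlation` (matrix),
#'   `block_means` (named: within group 1, within group 2, between).
#' @export
sample_correlation_summary <- function(beta, groups) {
  if (nrow(beta) < 2) stop("need at least two probes")
  groups <- as_two_groups(groups, colnames(beta))
  b <- unclass(beta)
  sds <- apply(b, 2, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate)) {
    warning("zero-variance samples excluded from block means: ",
            paste(colnames(b)[degenerate], collapse = ", "))
  }
  cc <- suppressWarnings(stats::cor(b))
  cc[degenerate, ] <- NA
  cc[, degenerate] <- NA
  diag(cc)[!degenerate] <- 1

  g1 <- which(groups == levels(groups)[1] & !degenerate)
  g2 <- which(groups == levels(groups)[2] & !degenerate)
  block_mean <- function(rows, cols, within) {
    blk <- cc[rows, cols, drop = FALSE]
    if (within) blk <- blk[upper.tri(blk)]
    mean(blk, na.rm = TRUE)
  }
  bm <- c(block_mean(g1, g1, TRUE), block_mean(g2, g2, TRUE),
          block_mean(g1, g2, FALSE))
  names(bm) <- c(paste0("within_", levels(groups)[1]),
                 paste0("within_", levels(groups)[2]), "between")

  structure(list(correlation = cc, block_means = bm, groups = levels(groups)),
            class = "sample_correlation")
}

#' @export
print.sample_correlation <- function(x, ...) {
  cat("<sample_correlation> ", ncol(x$correlation), " samples\n", sep = "")
  print(round(x$block_means, 4))
  invisible(x)
}

#' Write an erosion report to TSV
#' @param ev an `erosion_variances` object.
#' @param path output path.
#' @export
write_erosion_report <- function(ev, path) {
  utils::write.table(ev$intra, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write spatial decay curves to TSV
#' @param sd_obj a `spatial_decay` object.
#' @param path output path.
#' @export
write_spatial_decay <- function(sd_obj, path) {
  utils::write.table(sd_obj$curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
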
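#' Pairwise co-expression correlation density per age group
#'
#' Selects the `top_frac` most variable genes (variance computed once across
#' all samples jointly, to avoid selection-induced group artifacts),
#' optionally intersects with a gene set, and computes all pairwise Pearson
#' correlations separately within each group. Summaries per group: mean |r|
#' and the fraction of pairs with |r| below `null_threshold` ("no expression
#' correlation").
#'
#' @param expr genes x samples numeric matrix.
#' @param groups two-level factor or sample sheet aligned with the columns.
#' @param top_frac fraction of genes retained by variance, in (0, 1].
#' @param gene_set optional character vector of gene ids to restrict to
#'   (intersected after variance selection; at least 2 must survive).
#' @param null_threshold |r| below this counts as uncorrelated (default 0.1).
#' @param n_bins number of density bins over [-1, 1] (default 50).
#' @return object of class `correlation_density`: `r_values` (list per
#'   group), `density` (data frame: group, bin_center, density), `summary`
#'   (per group: n_genes, n_pairs, mean_abs_r, frac_null) and `contrast`
#'   (group 2 minus group 1 differences).
#' @export
correlation_density <- function(expr, groups, top_frac = 0.3, gene_set = NULL,
                                null_threshold = 0.1, n_bins = 50) {
  if (!(top_frac > 0 && top_frac <= 1)) stop("top_frac must be in (0, 1]")
  if (anyNA(expr)) stop("missing values in expression matrix")
  groups <- as_two_groups(groups, colnames(expr))
  if (any(table(groups) < 3)) stop("need at least 3 samples per group")

  v <- row_vars(expr)
  n_keep <- max(2, ceiling(top_frac * nrow(expr)))
  keep <- rownames(expr)[order(-v, rownames(expr))][seq_len(n_keep)]
  if (!is.null(gene_set)) {
    keep <- intersect(keep, gene_set)
  }
  if (length(keep) < 2) stop("fewer than 2 genes after selection")
  x <- expr[keep, , drop = FALSE]

  breaks <- seq(-1, 1, length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2

  r_values <- list()
  density <- list()
  summ <- list()
  for (lev in levels(groups)) {
    cc <- stats::cor(t(x[, groups == lev, drop = FALSE]))
    r <- cc[upper.tri(cc)]
    r_values[[lev]] <- r
    counts <- tabulate(findInterval(r, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = n_bins)
    dens <- counts / (length(r) * diff(breaks))
    density[[lev]] <- data.frame(group = lev, bin_center = centers,
                                 density = dens, stringsAsFactors = FALSE)
    summ[[lev]] <- data.frame(group = lev, n_genes = length(keep),
                              n_pairs = length(r),
                              mean_abs_r = mean(abs(r)),
                              frac_null = mean(abs(r) < null_threshold),
                              stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, summ)

  structure(list(
    r_values = r_values,
    density = do.call(rbind, density),
    summary = summ,
    contrast = list(
      mean_abs_r_diff = summ$mean_abs_r[2] - summ$mean_abs_r[1],
      frac_null_diff = summ$frac_null[2] - summ$frac_null[1]),
    genes = keep, null_threshold = null_threshold,
    groups = levels(groups)),
    class = "correlation_density")
}

#' @export
print.correlation_density <- function(x, ...) {
  cat("<correlation_density> ", length(x$genes), " genes, groups: ",
      paste(x$groups, collapse = " vs "), "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  cat(sprintf("  mean |r| difference (%s - %s): %.3f; frac(|r| < %.2g) difference: %.3f\n",
              x$groups[2], x$groups[1], x$contrast$mean_abs_r_diff,
              x$null_threshold, x$contrast$frac_null_diff))
  invisible(x)
}

#' Write co-expression density and summary tables
#' @param cd a `correlation_density`.
#' @param density_path,summary_path output TSV paths.
#' @export
write_coexpr_tables <- function(cd, density_path, summary_path) {
  utils::write.table(cd$density, density_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cd$summary, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(density_path, summary_path))
}
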
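#' Construct a methylation matrix
#'
#' A methylation matrix is a probes x samples numeric matrix carrying a scale
#' flag: `"beta"` for proportion-scale values in `[0, 1]` or `"m"` for
#' log2-odds (M) values. Probe and sample identifiers live in the dimnames and
#' must be unique; missing values are rejected because every downstream
#' statistic assumes complete matrices.
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   complete unique dimnames.
#' @param scale `"beta"` or `"m"`.
#' @param logit_eps clipping bound used when the matrix was produced by
#'   [beta_to_m()]; `NA` for matrices read from disk.
#' @return a `methyl_matrix` (a numeric matrix with a `meth_scale` attribute).
#' @export
methyl_matrix <- function(values, scale = c("beta", "m"), logit_eps = NA_real_) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("probe ids (rownames) and sample ids (colnames) are required")
  }
  if (anyDuplicated(rownames(values))) stop("probe ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at probe ", rownames(values)[bad[1]],
         ", sample ", colnames(values)[bad[2]],
         "; missing values are rejected, not imputed")
  }
  if (scale == "beta" && (min(values) < 0 || max(values) > 1)) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop("beta value outside [0,1] at probe ", rownames(values)[bad[1]],
         ", sample ", colnames(values)[bad[2]],
         " (value ", values[bad[1], bad[2]], ")")
  }
  structure(values, class = c("methyl_matrix", class(values)),
            meth_scale = scale, logit_eps = logit_eps)
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat("<methyl_matrix> ", nrow(x), " probes x ", ncol(x), " samples, scale=",
      attr(x, "meth_scale"), "\n", sep = "")
  cat("  value range: [", format(min(x), digits = 4), ", ",
      format(max(x), digits = 4), "]\n", sep = "")
  invisible(x)
}

meth_scale <- function(x) attr(x, "meth_scale")

#' @export
`[.methyl_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, class = class(x), meth_scale = meth_scale(x),
                     logit_eps = attr(x, "logit_eps"))
  }
  out
}

# keep class/attributes when subsetting through the constructor
subset_meth <- function(x, i = NULL, j = NULL) {
  v <- unclass(x)
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  methyl_matrix(v, scale = meth_scale(x), logit_eps = attr(x, "logit_eps"))
}

ISLAND_LEVELS <- c("island", "shore", "shelf", "open_sea")

#' Validate a probe annotation table
#'
#' Required columns: `probe_id`, `chrom`, `pos` (1-based), `island_relation`
#' (one of island/shore/shelf/open_sea), `lad`, `on_sex_chromosome`,
#' `cross_reactive`, `snp_near_sbe` (logicals) and `context` (CpG/CH).
#'
#' @param df data frame of per-probe annotation.
#' @return the validated data frame (invisibly classed).
#' @export
probe_annotation <- function(df) {
  req <- c("probe_id", "chrom", "pos", "island_relation", "lad",
           "on_sex_chromosome", "cross_reactive", "snp_near_sbe", "context")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) {
    stop("duplicated probe ids in annotation: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  if (any(df$pos < 1)) stop("probe positions must be >= 1 (1-based)")
  if (!all(df$island_relation %in% ISLAND_LEVELS)) {
    stop("island_relation must be one of: ", paste(ISLAND_LEVELS, collapse = ", "))
  }
  for (col in c("lad", "on_sex_chromosome", "cross_reactive", "snp_near_sbe")) {
    df[[col]] <- as.logical(df[[col]])
    if (anyNA(df[[col]])) stop("annotation column ", col, " must be logical (no NA)")
  }
  if (!all(df$context %in% c("CpG", "CH"))) stop("context must be CpG or CH")
  df$island_relation <- factor(df$island_relation, levels = ISLAND_LEVELS)
  df
}

#' Validate a sample sheet
#'
#' @param df data frame with columns `sample_id`, `age` (years, > 0) and an
#'   optional `group` column with levels young/old/other.
#' @return validated data frame.
#' @export
sample_sheet <- function(df) {
  if (!all(c("sample_id", "age") %in% names(df))) {
    stop("sample sheet needs columns sample_id and age")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in sample sheet")
  df$age <- as.numeric(df$age)
  if (anyNA(df$age) || any(df$age <= 0)) stop("ages must be positive numbers")
  if (!"group" %in% names(df)) df$group <- "other"
  df$group[is.na(df$group) | df$group == ""] <- "other"
  if (!all(df$group %in% c("young", "old", "other"))) {
    stop("group labels must be young, old or other")
  }
  df
}

#' Load a methylation cohort from disk
#'
#' Reads the TSV/CSV dialects written by [write_cohort()]: a beta matrix (TSV,
#' first column `probe_id`, header = sample ids), a probe annotation TSV (or
#' BED3+name for coordinates only), a sample sheet CSV and an optional
#' detection-failure mask TSV (0/1, same layout as the beta matrix). All
#' objects are validated and aligned; the sample order of the matrix is
#' preserved.
#'
#' @param beta_path,annotation_path,samplesheet_path,mask_path file paths;
#'   `mask_path` may be `NULL` (no detection failures).
#' @return list with elements `beta` ([methyl_matrix]), `annotation`,
#'   `samples`, `mask` (logical matrix, `TRUE` = detection failure).
#' @export
load_cohort <- function(beta_path, annotation_path, samplesheet_path,
                        mask_path = NULL) {
  for (p in c(beta_path, annotation_path, samplesheet_path, mask_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  beta <- read_beta_matrix(beta_path)
  ann <- read_annotation(annotation_path)
  sheet <- sample_sheet(utils::read.csv(samplesheet_path, stringsAsFactors = FALSE))

  missing_samples <- setdiff(colnames(beta), sheet$sample_id)
  if (length(missing_samples)) {
    stop("samples present in matrix but missing from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  }
  missing_probes <- setdiff(rownames(beta), ann$probe_id)
  if (length(missing_probes)) {
    stop("probes present in matrix but missing from annotation: ",
         paste(utils::head(missing_probes, 5), collapse = ", "),
         if (length(missing_probes) > 5) " ..." else "")
  }
  ann <- ann[match(rownames(beta), ann$probe_id), , drop = FALSE]
  rownames(ann) <- NULL

  if (is.null(mask_path)) {
    mask <- matrix(FALSE, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  } else {
    mask <- read_mask(mask_path)
    if (!identical(dim(mask), dim(beta)) ||
        !identical(rownames(mask), rownames(beta)) ||
        !identical(colnames(mask), colnames(beta))) {
      stop("detection mask dimensions/ids do not match the beta matrix")
    }
  }
  list(beta = beta, annotation = ann, samples = sheet, mask = mask)
}

read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("beta matrix ", path, " needs probe_id plus sample columns")
  probe_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_col <- colnames(m)[!vapply(seq_len(ncol(m)), function(j) is.numeric(df[[j + 1]]), TRUE)][1]
    stop("non-numeric beta values in column ", bad_col, " of ", path)
  }
  rownames(m) <- probe_ids
  methyl_matrix(m, scale = "beta")
}

read_mask <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!all(m %in% c(0, 1))) stop("detection mask must contain only 0/1: ", path)
  mode(m) <- "logical"
  m
}

read_annotation <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("probe_id", header, fixed = TRUE)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(probe_annotation(df))
  }
  # BED3+name: chrom, start (0-based), end, name -- coordinates only
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED annotation needs at least chrom/start/end/name: ", path)
  probe_annotation(data.frame(
    probe_id = as.character(df[[4]]), chrom = as.character(df[[1]]),
    pos = as.integer(df[[2]]) + 1L, island_relation = "open_sea",
    lad = FALSE, on_sex_chromosome = FALSE, cross_reactive = FALSE,
    snp_near_sbe = FALSE, context = "CpG", stringsAsFactors = FALSE))
}

#' Write a cohort to disk in the package's TSV/CSV dialect
#'
#' Numeric values are written with 17 significant digits so that a
#' load/write/load cycle round-trips bit-identically.
#'
#' @param cohort list as returned by [load_cohort()] or
#'   [generate_methylome_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             samples = file.path(dir, "samples.csv"),
             mask = file.path(dir, "mask.tsv"))
  write_numeric_tsv(cohort$beta, paths["beta"])
  ann <- cohort$annotation
  ann$island_relation <- as.character(ann$island_relation)
  utils::write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cohort$samples, paths["samples"], row.names = FALSE, quote = FALSE)
  mask <- cohort$mask
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(cohort$beta), ncol(cohort$beta),
                   dimnames = dimnames(cohort$beta))
  }
  storage <- mask * 1L
  write_numeric_tsv(storage, paths["mask"], digits = FALSE)
  invisible(paths)
}

write_numeric_tsv <- function(m, path, digits = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  fmt <- if (digits) function(v) sprintf("%.17g", v) else function(v) format(v)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
}

#' Filter probes by exclusion flags and detection failures
#'
#' Removes probes on sex chromosomes, cross-reactive probes, probes with a SNP
#' within five bases of the single-base extension site, and probes that failed
#' detection in at least one sample. Probe order is preserved and removal
#' counts per criterion are attached (a probe failing several criteria is
#' counted under each but removed once).
#'
#' @param matrix a [methyl_matrix].
#' @param annotation probe annotation covering all matrix probes.
#' @param mask logical probes x samples matrix, `TRUE` = detection failure;
#'   `NULL` means no failures.
#' @return filtered `methyl_matrix` with attribute `removal_counts`.
#' @export
filter_probes <- function(matrix, annotation, mask = NULL) {
  ids <- rownames(matrix)
  idx <- match(ids, annotation$probe_id)
  if (anyNA(idx)) {
    stop("annotation does not cover probes: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  }
  ann <- annotation[idx, , drop = FALSE]
  fail_sex <- ann$on_sex_chromosome
  fail_xr <- ann$cross_reactive
  fail_snp <- ann$snp_near_sbe
  fail_det <- if (is.null(mask)) rep(FALSE, length(ids)) else {
    rowSums(mask[ids, , drop = FALSE]) > 0
  }
  drop <- fail_sex | fail_xr | fail_snp | fail_det
  if (all(drop)) stop("no probes left after filtering")
  out <- subset_meth(matrix, i = !drop)
  attr(out, "removal_counts") <- c(
    sex_chromosome = sum(fail_sex), cross_reactive = sum(fail_xr),
    snp_near_sbe = sum(fail_snp), detection_failure = sum(fail_det),
    removed_total = sum(drop), retained = sum(!drop))
  out
}

#' Convert beta values to M values (log2-odds)
#'
#' Applies `M = log2(beta'/(1 - beta'))` with `beta' = min(max(beta, eps),
#' 1 - eps)`. The pure-logit convention (no offset) is used; the clipping
#' bound is recorded in the result's `logit_eps` attribute so that
#' [m_to_beta()] recovers the clipped values exactly.
#'
#' @param matrix a `methyl_matrix` on the beta scale.
#' @param epsilon clipping bound, `0 < epsilon < 0.5`; default `1e-3`.
#' @return `methyl_matrix` on the M scale.
#' @export
beta_to_m <- function(matrix, epsilon = 1e-3) {
  if (meth_scale(matrix) != "beta") stop("input is already on the M scale")
  if (!(epsilon > 0 && epsilon < 0.5)) stop("epsilon must be in (0, 0.5)")
  v <- clip01(unclass(matrix), epsilon)
  methyl_matrix(logit2(v), scale = "m", logit_eps = epsilon)
}

#' Convert M values back to the beta scale
#'
#' Exact inverse of [beta_to_m()] on clipped values.
#'
#' @param matrix a `methyl_matrix` on the M scale.
#' @return `methyl_matrix` on the beta scale.
#' @export
m_to_beta <- function(matrix) {
  if (meth_scale(matrix) != "m") stop("input is not on the M scale")
  methyl_matrix(ilogit2(unclass(matrix)), scale = "beta",
                logit_eps = attr(matrix, "logit_eps"))
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene identifiers.
#' Duplicate genes within a set are removed.
#'
#' @param gmt_path path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(gmt_path) {
  if (!file.exists(gmt_path)) stop("file not found: ", gmt_path)
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", gmt_path)
    return(structure(list(), names = character(0)))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields in ", gmt_path)
    }
    name <- fields[1]
    if (name %in% names(sets)) stop("duplicated set name at GMT line ", i, ": ", name)
    sets[[name]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
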
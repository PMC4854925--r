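# Internal helpers shared across modules.

# log2-odds transform; inputs must already be clipped away from 0/1
logit2 <- function(p) log2(p / (1 - p))

# inverse of logit2, numerically safe for large |m|
ilogit2 <- function(m) 1 / (1 + 2^(-m))

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("need at least two columns to compute row variances")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) stop("need at least two rows to compute column variances")
  mu <- colMeans(x)
  colSums((t(t(x) - mu))^2) / (n - 1)
}

row_sds <- function(x) sqrt(row_vars(x))

# Validate and normalise a two-level grouping factor aligned with matrix columns.
# Returns a factor whose first level is the reference (young) group.
as_two_groups <- function(groups, sample_ids) {
  if (inherits(groups, "data.frame")) {
    groups <- group_factor_from_sheet(groups, sample_ids)
  }
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != length(sample_ids)) {
    stop("grouping factor length (", length(groups),
         ") does not match number of samples (", length(sample_ids), ")")
  }
  if (nlevels(groups) != 2) {
    stop("exactly two groups are required, got levels: ",
         paste(levels(groups), collapse = ", "))
  }
  if (any(table(groups) < 2)) stop("each group needs at least two samples")
  # conventional ordering: young before old when those labels are used
  if (all(c("young", "old") %in% levels(groups))) {
    groups <- factor(groups, levels = c("young", "old"))
  }
  groups
}

group_factor_from_sheet <- function(sheet, sample_ids) {
  stopifnot(all(c("sample_id", "group") %in% names(sheet)))
  idx <- match(sample_ids, sheet$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from sample sheet: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  sheet$group[idx]
}

ages_from <- function(ages, sample_ids) {
  if (inherits(ages, "data.frame")) {
    idx <- match(sample_ids, ages$sample_id)
    if (anyNA(idx)) {
      stop("samples missing from sample sheet: ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    }
    return(ages$age[idx])
  }
  if (!is.null(names(ages))) {
    idx <- match(sample_ids, names(ages))
    if (anyNA(idx)) stop("ages missing for samples: ",
                         paste(sample_ids[is.na(idx)], collapse = ", "))
    return(unname(ages[idx]))
  }
  if (length(ages) != length(sample_ids)) {
    stop("age vector length does not match number of samples")
  }
  as.numeric(ages)
}

# derive a bounded child seed from a master seed (kept below 2^31)
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483561L + 1)
}
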
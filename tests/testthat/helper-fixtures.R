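# Small in-code fixtures shared across tests.

tiny_annotation <- function(probe_ids, chrom = "chr1",
                            pos = seq(100, by = 200, length.out = length(probe_ids)),
                            island = "open_sea", lad = FALSE,
                            sex = FALSE, xr = FALSE, snp = FALSE) {
  probe_annotation(data.frame(
    probe_id = probe_ids, chrom = chrom, pos = pos,
    island_relation = rep_len(island, length(probe_ids)),
    lad = rep_len(lad, length(probe_ids)),
    on_sex_chromosome = rep_len(sex, length(probe_ids)),
    cross_reactive = rep_len(xr, length(probe_ids)),
    snp_near_sbe = rep_len(snp, length(probe_ids)),
    context = "CpG", stringsAsFactors = FALSE))
}

tiny_beta <- function(values, probe_ids = NULL, sample_ids = NULL) {
  if (is.null(probe_ids)) probe_ids <- sprintf("cg%03d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(probe_ids, sample_ids)
  methyl_matrix(values, "beta")
}

tiny_sheet <- function(n_young = 2, n_old = 2, sample_ids = NULL) {
  n <- n_young + n_old
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n))
  sample_sheet(data.frame(
    sample_id = sample_ids,
    age = c(rep(25, n_young), rep(70, n_old)),
    group = rep(c("young", "old"), c(n_young, n_old)),
    stringsAsFactors = FALSE))
}

# writes a 6-probe x 4-sample cohort to disk; returns the paths
write_tiny_cohort_files <- function(dir, beta_values = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(beta_values)) {
    set.seed(99)
    beta_values <- matrix(round(runif(24), 6), 6, 4)
  }
  beta <- tiny_beta(beta_values)
  ann <- tiny_annotation(rownames(beta))
  sheet <- tiny_sheet(2, 2)
  mask <- matrix(FALSE, 6, 4, dimnames = dimnames(beta))
  write_cohort(list(beta = beta, annotation = ann, samples = sheet,
                    mask = mask), dir)
}
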
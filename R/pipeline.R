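#' Default pipeline parameters
#'
#' Central record of the analysis defaults: DMP threshold `alpha = 0.01`,
#' `top_k = 2000` most variable probes, changepoint relative-error threshold
#' `0.75`, spatial pair distance `max_dist = 1000` bases, consensus
#' clustering `k = 2`, `B = 1000`, `p_item = 0.8`, `p_feature = 1`, gene
#' selection `top_frac = 0.3`, cross-validation scheme `"loo"`.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(alpha = 0.01, top_k = 2000, rel_err_max = 0.75, bin_width = 5,
       max_dist = 1000, smooth_frac = 0.3, consensus_k = 2, consensus_B = 1000,
       p_item = 0.8, p_feature = 1, top_frac = 0.3, cv_scheme = "loo",
       svr_cost = 1, svr_epsilon = 0.1, epsilon = 1e-3, min_branch = 5)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate/load -> filter
#' -> convert -> dmp -> predict -> varclust -> erosion -> coexpr), writes
#' each stage's tables under `out_dir`, and finishes with `manifest.json`
#' recording package and R versions, the master seed, a parameter echo and
#' MD5 hashes of every output, so identical configs and seeds rerun to
#' identical files.
#'
#' @param config nested list (or path handled by
#'   [read_pipeline_config()]): either `simulate` (arguments to
#'   [synth_config()]) or `inputs` (paths for [load_cohort()]); optional
#'   `expression` block (arguments to [generate_expression_cohort()]);
#'   `stages` (character vector among filter, dmp, predict, varclust,
#'   erosion, coexpr); `params` overriding [pipeline_defaults()]; `seed`.
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  stages <- config$stages %||% c("filter", "dmp", "predict", "varclust",
                                 "erosion", "coexpr")
  seed <- as.integer(config$seed %||% 1L)

  known <- c("filter", "dmp", "predict", "varclust", "erosion", "coexpr")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if ("coexpr" %in% stages && is.null(config$expression) &&
      is.null(config$inputs$expr)) {
    stop("stage coexpr is enabled but no expression input or simulation ",
         "block is configured")
  }

  outputs <- character(0)
  note <- function(path) outputs <<- c(outputs, path)

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% child_seed(seed, 1)
    cohort <- generate_methylome_cohort(do.call(synth_config, sim_args))
    for (p in write_cohort(cohort, out_dir)) note(p)
    note(write_truth(cohort$truth, file.path(out_dir, "truth.tsv")))
  } else if (!is.null(config$inputs)) {
    ins <- config$inputs
    cohort <- load_cohort(ins$beta, ins$annotation, ins$samplesheet,
                          ins$mask %||% NULL)
  } else {
    stop("config needs either a `simulate` block or an `inputs` block")
  }

  expr_data <- NULL
  if (!is.null(config$expression)) {
    ex_args <- config$expression
    ex_args$seed <- ex_args$seed %||% child_seed(seed, 2)
    expr_data <- do.call(generate_expression_cohort, ex_args)
  }

  beta <- cohort$beta
  if ("filter" %in% stages) {
    beta <- filter_probes(beta, cohort$annotation, cohort$mask)
    counts <- attr(beta, "removal_counts")
    utils::write.table(
      data.frame(criterion = names(counts), count = as.integer(counts)),
      fp <- file.path(out_dir, "filter_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    note(fp)
  }
  mmat <- beta_to_m(beta, epsilon = params$epsilon)
  two_group <- sum(cohort$samples$group %in% c("young", "old")) >= 4 &&
    length(unique(cohort$samples$group[cohort$samples$group != "other"])) == 2
  grp_cols <- colnames(beta)[group_of(cohort$samples, colnames(beta)) != "other"]
  grp <- NULL
  if (two_group) {
    grp <- factor(group_of(cohort$samples, grp_cols), levels = c("young", "old"))
  }

  results <- list()

  if ("dmp" %in% stages) {
    if (is.null(grp)) stop("stage dmp needs young/old groups in the sample sheet")
    fit <- moderated_t_test(subset_meth(mmat, j = grp_cols), grp)
    note(write_dmp_table(fit, file.path(out_dir, "dmp.tsv")))
    sub <- substructure_analysis(subset_meth(beta, j = grp_cols),
                                 cohort$annotation, grp, fit,
                                 alpha = params$alpha)
    utils::write.table(sub$class_test,
                       fp <- file.path(out_dir, "substructure.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(fp)
    results$dmp <- summary(fit, alpha = params$alpha)
  }

  if ("predict" %in% stages) {
    fit <- cv_age_prediction(beta, cohort$samples, scheme = params$cv_scheme,
                             cost = params$svr_cost,
                             epsilon = params$svr_epsilon,
                             seed = child_seed(seed, 3))
    utils::write.table(fit$predictions,
                       fp <- file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(fp)
    results$predict <- fit$metrics
  }

  if ("varclust" %in% stages) {
    top <- top_variable_probes(beta, min(params$top_k, nrow(beta)))
    disc <- detect_discontinuous_changes(
      beta, cohort$samples, top, rel_err_max = params$rel_err_max,
      annotation = cohort$annotation, bin_width = params$bin_width,
      min_branch = params$min_branch)
    note(write_changepoints(disc, file.path(out_dir, "changepoints.tsv")))
    utils::write.table(as.data.frame.matrix(disc$cumulative),
                       fp <- file.path(out_dir, "discontinuity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    note(fp)
    if (!is.null(grp)) {
      cons <- consensus_cluster(
        subset_meth(beta, i = top, j = grp_cols), k = params$consensus_k,
        B = params$consensus_B, p_item = params$p_item,
        p_feature = params$p_feature, seed = child_seed(seed, 4))
      utils::write.table(cons$consensus, fp <- file.path(out_dir, "consensus.tsv"),
                         sep = "\t", quote = FALSE)
      note(fp)
      results$consensus_sizes <- unname(table(cons$assignment))
    }
    results$discontinuity <- list(
      retained = nrow(disc$retained),
      island_fraction = disc$island_fraction)
  }

  if ("erosion" %in% stages) {
    if (is.null(grp)) stop("stage erosion needs young/old groups")
    ev <- methylome_variances(subset_meth(mmat, j = grp_cols), grp)
    note(write_erosion_report(ev, file.path(out_dir, "erosion_report.tsv")))
    sp <- spatial_decay_curve(subset_meth(beta, j = grp_cols),
                              cohort$annotation, grp,
                              max_dist = params$max_dist,
                              smooth_frac = params$smooth_frac)
    note(write_spatial_decay(sp, file.path(out_dir, "spatial_decay.tsv")))
    sc <- sample_correlation_summary(subset_meth(beta, j = grp_cols), grp)
    results$erosion <- list(intra_p = ev$intra_test$p_value,
                            spatial_p = sp$p_value,
                            block_means = sc$block_means)
  }

  if ("coexpr" %in% stages) {
    grp_e <- factor(group_of(expr_data$samples, colnames(expr_data$expr)),
                    levels = c("young", "old"))
    cd <- correlation_density(expr_data$expr, grp_e,
                              top_frac = params$top_frac)
    write_coexpr_tables(cd, d1 <- file.path(out_dir, "coexpr_density.tsv"),
                        d2 <- file.path(out_dir, "coexpr_summary.tsv"))
    note(d1); note(d2)
    results$coexpr <- cd$contrast
  }

  manifest <- list(
    package = "epidrift",
    version = as.character(utils::packageVersion("epidrift")),
    r_version = R.version.string,
    seed = seed, stages = stages, params = params,
    config = config,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

group_of <- function(sheet, sample_ids) {
  sheet$group[match(sample_ids, sheet$sample_id)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
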
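#' Pipeline configuration
#'
#' Collects paths, the temperature grid, clustering thresholds, NPARC
#' scopes and significance levels with the standard defaults. Either
#' `input` points at a peptide table on disk, or `simulate` holds arguments
#' for [simulate_tpp_experiment()] / [simulate_cohort()].
#'
#' @param input Optional path to a peptide/PSM TSV (see
#'   [read_peptide_table()]).
#' @param simulate Optional list of arguments for the synthetic generator.
#' @param grid A [temperature_grid()].
#' @param thresholds See [proteoform_thresholds()].
#' @param alpha Significance level for every screen.
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param vsn_trim Trim fraction for the normalization fits.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, simulate = list(),
                            grid = temperature_grid(),
                            thresholds = proteoform_thresholds(),
                            alpha = 0.05, seed = 1, vsn_trim = 0.1) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(input = input, simulate = simulate, grid = grid,
                 thresholds = thresholds, alpha = alpha,
                 seed = as.integer(seed), vsn_trim = vsn_trim),
            class = "pipeline_config")
}

write_manifest <- function(out_dir, config, tables, extra = list()) {
  manifest <- c(list(
    package = "tppforms",
    version = as.character(utils::packageVersion("tppforms")),
    seed = config$seed, alpha = config$alpha,
    thresholds = config$thresholds,
    tables = tables), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the TPP proteoform pipeline end to end
#'
#' Stages: read (or simulate) the peptide table, preprocess to relative
#' melt profiles, cluster peptides into proteoform groups, summarize to
#' group melt curves, and run the NPARC screen across the whole dataset and
#' within each cell line. Result tables and a manifest recording the
#' configuration, seeds and gate decisions are written to `out_dir`;
#' re-running with an identical configuration reproduces identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage objects and result paths.
#' @export
run_tpp_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  quant <- step("read", {
    if (!is.null(config$input)) {
      read_peptide_table(config$input, config$grid)
    } else {
      args <- config$simulate
      args$grid <- config$grid
      args$seed <- args$seed %||% stage_seed(config$seed, "simulate")
      do.call(simulate_tpp_experiment, args)$quant
    }
  })
  profiles <- step("preprocess", melt_profiles(quant, config$vsn_trim))
  assignments <- step("cluster",
                      assign_proteoform_groups(profiles, config$thresholds,
                                               seed = config$seed))
  gc <- step("summarize",
             suppressWarnings(summarize_groups(quant, assignments,
                                               config$vsn_trim)))
  scopes <- c(list(all = gc$samples),
              split(gc$sample_meta$sample_id, gc$sample_meta$cell_line))
  nparc_res <- step("nparc", {
    lapply(names(scopes), function(sc) {
      nparc(gc, scope = sc, samples = scopes[[sc]], alpha = config$alpha)
    })
  })
  names(nparc_res) <- names(scopes)

  tables <- character()
  p <- file.path(out_dir, "proteoform_assignments.tsv")
  write_results_table(as.data.frame(assignments), p)
  tables <- c(tables, basename(p))
  curves_df <- data.frame(group = rep(rownames(gc$curves),
                                      each = ncol(gc$curves)),
                          sample_id = rep(gc$layout$sample_id,
                                          nrow(gc$curves)),
                          channel = rep(gc$layout$channel, nrow(gc$curves)),
                          fold_change = as.vector(t(gc$curves)))
  p <- file.path(out_dir, "group_melt_curves.tsv")
  write_results_table(curves_df, p)
  tables <- c(tables, basename(p))
  for (sc in names(nparc_res)) {
    p <- file.path(out_dir, sprintf("nparc_%s.tsv", sc))
    write_results_table(as.data.frame(nparc_res[[sc]]), p)
    tables <- c(tables, basename(p))
  }
  gate_counts <- attr(assignments, "gate_counts")
  message("gate decisions: ",
          paste(sprintf("%s=%d", names(gate_counts), gate_counts),
                collapse = ", "))
  write_manifest(out_dir, config, tables,
                 list(gate_counts = as.list(gate_counts),
                      n_peptides = nrow(profiles$fold),
                      n_groups = nrow(gc$curves)))
  invisible(list(quant = quant, profiles = profiles,
                 assignments = assignments, group_curves = gc,
                 nparc = nparc_res, out_dir = out_dir, tables = tables))
}

#' Run the cohort abundance pipeline end to end
#'
#' Stages: simulate (or accept) a PSM-level cohort, calibrate per set, sum
#' to gene / proteoform-group / randomized groupings, log-transform and
#' median-center, run the randomized-membership variance F-screen, the
#' treated-versus-untreated Wilcoxon screen, and response correlations per
#' stratum. Three result tables plus a manifest are written to `out_dir`.
#'
#' @param config A [pipeline_config()]; `config$simulate` holds
#'   [simulate_cohort()] arguments, or `config$input` is a list with
#'   elements `psm`, `annotations`, `grouping` already in memory.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the stage objects and result paths.
#' @export
run_cohort_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$input)) {
    cohort <- config$input
  } else {
    args <- config$simulate
    args$seed <- args$seed %||% stage_seed(config$seed, "cohort")
    cohort <- do.call(simulate_cohort, args)
  }
  values <- normalize_cohort_psms(cohort$psm, cohort$annotations,
                                  config$vsn_trim)
  meta <- cohort$psm[, c("psm_id", "peptide_id", "gene")]
  null_grouping <- randomize_membership(cohort$grouping,
                                        seed = stage_seed(config$seed, "null"))
  mats <- list(
    gene = sum_to_grouping(values, meta, "gene"),
    proteoform = sum_to_grouping(values, meta, cohort$grouping),
    randomized = sum_to_grouping(values, meta, null_grouping))
  logmats <- lapply(mats, log_median_center)

  ftest <- variance_f_test(logmats$proteoform, logmats$randomized,
                           alpha = config$alpha)
  ann <- cohort$annotations
  wilcox <- wilcoxon_treatment_test(
    logmats$proteoform,
    treated = ann$patient_id[ann$treated],
    untreated = ann$patient_id[!ann$treated],
    alpha = config$alpha)
  correlations <- subgroup_analysis(
    logmats$proteoform, ann,
    significant_groups = ftest$group[ftest$significant])

  tables <- c("variance_ftest.tsv", "wilcoxon_treatment.tsv",
              "response_correlations.tsv")
  write_results_table(ftest, file.path(out_dir, tables[1]))
  write_results_table(wilcox, file.path(out_dir, tables[2]))
  write_results_table(correlations, file.path(out_dir, tables[3]))
  write_manifest(out_dir, config, tables,
                 list(n_patients = ncol(logmats$proteoform),
                      n_groups = nrow(logmats$proteoform),
                      n_significant_variance = sum(ftest$significant)))
  invisible(list(matrices = logmats, ftest = ftest, wilcox = wilcox,
                 correlations = correlations, annotations = ann,
                 grouping = cohort$grouping, null_grouping = null_grouping,
                 out_dir = out_dir, tables = tables))
}
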
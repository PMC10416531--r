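#' Simulation presets mirroring the study designs
#'
#' * `standards7x2` — seven methylation standards (0, 0.10, 0.25, 0.50,
#'   0.75, 0.90, 1) in duplicate: 14 libraries (repeatability design).
#' * `sensitivity16` — two levels (0.25, 0.75) across four DNA inputs in
#'   duplicate: 16 libraries (sensitivity design).
#' * `blood5x2` — five blood donors aged 7, 28, 46, 61, 78 in duplicate:
#'   10 libraries (clock-performance design).
#'
#' @param preset Preset name.
#' @param panel Panel tibble; default [example_panel()].
#' @param config A [sim_config()].
#' @param clock Generating clock for `blood5x2`; default the fixture HANNUM
#'   model.
#' @param noise_sd Beta-scale noise for `blood5x2` (default 0).
#' @return List with `counts`, `truth`, `samples` (see the simulate_*
#'   functions).
#' @export
simulate_preset <- function(preset = c("standards7x2", "sensitivity16", "blood5x2"),
                            panel = example_panel(), config = sim_config(),
                            clock = NULL, noise_sd = 0) {
  preset <- match.arg(preset)
  switch(preset,
    standards7x2 = simulate_standard_series(panel, config = config),
    sensitivity16 = simulate_sensitivity_series(panel, config = config),
    blood5x2 = simulate_blood_cohort(
      panel, clock = clock %||% example_clocks(panel)$HANNUM,
      noise_sd = noise_sd, config = config)
  )
}

#' Run the full quantification-to-evaluation pipeline
#'
#' Quantifies betas with strand merging and read-depth thresholding,
#' produces the per-sample QC report, applies all clocks with imputation,
#' calibrates clock outputs through a transform registry, and computes the
#' evaluation statistics applicable to the supplied metadata (replicate
#' concordance where replicate pairs exist, accuracy where expected betas
#' exist, age MAE where ages exist). Deterministic on fixed inputs: no
#' randomness outside the generator.
#'
#' @param counts Count tibble.
#' @param panel Panel tibble.
#' @param models List of [clock_model()] objects.
#' @param samples Optional sample metadata (`sample_id`, `source_id`,
#'   `replicate`, `sample_type`, `expected_beta`, `input_ng`, `age`, ...).
#' @param rule Optional [mrs_rule()].
#' @param transforms Optional named list of [meth_transform()] keyed by
#'   clock name.
#' @param min_reads Read-depth threshold (default 50).
#' @return List of class `methclocks_run`: `betas`, `qc`, `clocks`,
#'   `metrics` (named list of evaluation tibbles).
#' @export
run_pipeline <- function(counts, panel, models, samples = NULL, rule = NULL,
                         transforms = NULL, min_reads = 50) {
  betas <- call_betas(counts, panel, min_reads)
  if (all(is.na(betas$beta))) {
    warn("all beta calls are missing at this read-depth threshold; clock outputs are fully imputed")
  }
  qc <- qc_report(counts, panel, min_reads)
  clocks <- run_all_clocks(betas, models, rule)
  if (!is.null(transforms)) clocks <- calibrate_outputs(clocks, transforms)

  metrics <- list()
  if (!is.null(samples)) {
    if (all(c("source_id", "replicate") %in% names(samples))) {
      pairing <- replicate_pairs(samples)
      if (nrow(pairing) > 0) metrics$replicate_mad <- replicate_mad(betas, pairing)
    }
    if ("expected_beta" %in% names(samples) &&
        any(!is.na(samples$expected_beta))) {
      std <- filter(samples, !is.na(.data$expected_beta))
      metrics$accuracy <- accuracy_vs_expected(
        filter(betas, .data$sample_id %in% std$sample_id),
        select(std, "sample_id", "expected_beta"))
      if ("input_ng" %in% names(samples)) {
        metrics$sensitivity <- sensitivity_summary(
          filter(betas, .data$sample_id %in% std$sample_id), std)
      }
      metrics$level_variability <- level_variability(
        filter(betas, .data$sample_id %in% std$sample_id), std)
    }
    if ("age" %in% names(samples) && any(!is.na(samples$age))) {
      ages <- filter(samples, !is.na(.data$age))
      value_col <- if ("value_calibrated" %in% names(clocks))
        "value_calibrated" else "value"
      for (m in models) {
        if (m$units == "years") {
          pred <- clocks |>
            filter(.data$clock == m$name,
                   .data$sample_id %in% ages$sample_id) |>
            left_join(select(ages, "sample_id", "age"), by = "sample_id")
          metrics[[paste0("mae_", tolower(m$name))]] <-
            mae_age(pred[[value_col]], pred$age)
        }
      }
      metrics$clock_correlation <- clock_cross_correlation(
        clocks, select(ages, "sample_id", "age"))
    }
  }
  structure(list(betas = betas, qc = qc, clocks = clocks, metrics = metrics),
            class = "methclocks_run")
}

#' @export
print.methclocks_run <- function(x, ...) {
  cat(sprintf("<methclocks_run> %d samples, %d markers, %d clock outputs\n",
              dplyr::n_distinct(x$betas$sample_id),
              dplyr::n_distinct(x$betas$marker_id),
              nrow(x$clocks)))
  cat("metrics:", paste(names(x$metrics), collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes the beta matrix TSV, QC JSON, clock-output TSV and metrics JSON,
#' plus a manifest naming the seed and configuration hash that produced the
#' run.
#'
#' @param run A `methclocks_run` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used (for the manifest), or `NULL`.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(run, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_beta_matrix(run$betas, file.path(dir, "beta_matrix.tsv"))
  write_qc_json(run$qc, file.path(dir, "qc_report.json"))
  readr::write_tsv(run$clocks, file.path(dir, "clock_outputs.tsv"),
                   progress = FALSE)
  metrics <- map(run$metrics, function(m) {
    if (is.matrix(m)) as.data.frame(m) else m
  })
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(config)) {
    write_manifest(config, file.path(dir, "manifest.json"),
                   extra = list(outputs = c("beta_matrix.tsv", "qc_report.json",
                                            "clock_outputs.tsv", "metrics.json")))
  }
  invisible(dir)
}
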
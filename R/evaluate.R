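#' Assay-performance statistics
#'
#' Summary statistics describing assay sensitivity, repeatability, accuracy
#' against methylation standards, cross-method agreement, and age-prediction
#' error. All statistics use pairwise-complete handling of missing beta
#' calls (a cell is dropped when either side is missing, never imputed),
#' report the number of cells retained, and use the n-1 denominator for
#' standard deviations throughout.
#'
#' @name evaluation
NULL

#' Build a replicate pairing from sample metadata
#'
#' @param samples Metadata tibble with `sample_id`, `source_id`,
#'   `replicate`; each source contributes its first two replicates.
#' @return Tibble `source_id`, `rep1`, `rep2`.
#' @export
replicate_pairs <- function(samples) {
  samples |>
    arrange(.data$source_id, .data$replicate) |>
    summarise(rep1 = .data$sample_id[1], rep2 = .data$sample_id[2],
              .by = "source_id") |>
    filter(!is.na(.data$rep2))
}

validate_pairing <- function(pairing) {
  stopifnot(all(c("rep1", "rep2") %in% names(pairing)))
  all_ids <- c(pairing$rep1, pairing$rep2)
  if (anyDuplicated(all_ids)) {
    stop_data("a sample appears in more than one replicate pair: %s",
              all_ids[duplicated(all_ids)][1])
  }
  invisible(pairing)
}

#' Mean absolute difference between technical replicates
#'
#' Pools `|beta_rep1 - beta_rep2|` over all (pair, marker) cells where both
#' replicates have a beta call.
#'
#' @param betas Long beta tibble (`sample_id`, `marker_id`, `beta`).
#' @param pairing Tibble with `rep1`, `rep2` sample-id columns (see
#'   [replicate_pairs()]); each sample in at most one pair.
#' @return One-row tibble `mean_abs_diff`, `sd_abs_diff`, `n_cells`.
#' @export
replicate_mad <- function(betas, pairing) {
  validate_pairing(pairing)
  b <- select(betas, "sample_id", "marker_id", "beta")
  cells <- pairing |>
    inner_join(b, by = c(rep1 = "sample_id"), relationship = "many-to-many") |>
    rename(beta1 = "beta") |>
    inner_join(b, by = c(rep2 = "sample_id", "marker_id")) |>
    rename(beta2 = "beta") |>
    filter(!is.na(.data$beta1), !is.na(.data$beta2))
  if (nrow(cells) == 0) {
    stop_data("no overlapping non-missing markers between replicates")
  }
  d <- abs(cells$beta1 - cells$beta2)
  tibble(mean_abs_diff = mean(d), sd_abs_diff = sd(d), n_cells = length(d))
}

#' Accuracy of methylation quantification against expected standards
#'
#' Pooled mean (+/- SD) of `|observed - expected|` over every non-missing
#' (sample, marker) cell of a standard series.
#'
#' @param betas Long beta tibble for standard samples.
#' @param truth Tibble `sample_id`, `expected_beta` covering every sample.
#' @return One-row tibble `mean_abs_diff`, `sd_abs_diff`, `n_cells`.
#' @export
accuracy_vs_expected <- function(betas, truth) {
  stopifnot(all(c("sample_id", "expected_beta") %in% names(truth)))
  missing <- setdiff(unique(betas$sample_id), truth$sample_id)
  if (length(missing) > 0 ||
      anyNA(truth$expected_beta[truth$sample_id %in% betas$sample_id])) {
    stop_data("missing expected_beta for sample(s): %s",
              paste(head(c(missing,
                           truth$sample_id[is.na(truth$expected_beta)]), 3),
                    collapse = ", "))
  }
  cells <- betas |>
    inner_join(distinct(truth, .data$sample_id, .data$expected_beta),
               by = "sample_id") |>
    filter(!is.na(.data$beta))
  d <- abs(cells$beta - cells$expected_beta)
  tibble(mean_abs_diff = mean(d), sd_abs_diff = sd(d), n_cells = length(d))
}

#' Sensitivity summary by DNA input and methylation level
#'
#' Grouped mean and SD of observed betas per (input mass, expected level),
#' the summary used to locate the input below which measurement variability
#' inflates.
#'
#' @param betas Long beta tibble.
#' @param samples Metadata tibble with `sample_id`, `input_ng`,
#'   `expected_beta` covering all samples.
#' @return Tibble `input_ng`, `expected_beta`, `mean_beta`, `sd_beta`,
#'   `n_cells`, sorted by decreasing input.
#' @export
sensitivity_summary <- function(betas, samples) {
  stopifnot(all(c("sample_id", "input_ng", "expected_beta") %in% names(samples)))
  uncovered <- setdiff(unique(betas$sample_id), samples$sample_id)
  if (length(uncovered) > 0) {
    stop_data("metadata does not cover sample(s): %s",
              paste(head(uncovered, 3), collapse = ", "))
  }
  cells <- betas |>
    inner_join(select(samples, "sample_id", "input_ng", "expected_beta"),
               by = "sample_id") |>
    filter(!is.na(.data$beta))
  empty <- anti_join(distinct(samples, .data$input_ng, .data$expected_beta),
                     distinct(cells, .data$input_ng, .data$expected_beta),
                     by = c("input_ng", "expected_beta"))
  if (nrow(empty) > 0) {
    warn(sprintf("skipping %d group(s) with no non-missing cells", nrow(empty)))
  }
  cells |>
    summarise(mean_beta = mean(.data$beta), sd_beta = sd(.data$beta),
              n_cells = dplyr::n(), .by = c("input_ng", "expected_beta")) |>
    arrange(desc(.data$input_ng), .data$expected_beta)
}

#' Per-level replicate variability of observed betas
#'
#' SD of observed betas per standard level, either per-marker-then-averaged
#' (default: the SD across replicates is computed within each marker and
#' averaged over markers) or pooled across all cells.
#'
#' @param betas Long beta tibble.
#' @param samples Metadata with `sample_id`, `expected_beta`.
#' @param pooled Pool all cells per level instead of averaging per-marker
#'   SDs (default `FALSE`).
#' @return Tibble `expected_beta`, `sd_beta`, `n_cells`.
#' @export
level_variability <- function(betas, samples, pooled = FALSE) {
  cells <- betas |>
    inner_join(select(samples, "sample_id", "expected_beta"), by = "sample_id") |>
    filter(!is.na(.data$beta))
  if (pooled) {
    cells |>
      summarise(sd_beta = sd(.data$beta), n_cells = dplyr::n(),
                .by = "expected_beta")
  } else {
    cells |>
      summarise(sd_beta = sd(.data$beta), n_cells = dplyr::n(),
                .by = c("expected_beta", "marker_id")) |>
      summarise(sd_beta = mean(.data$sd_beta, na.rm = TRUE),
                n_cells = sum(.data$n_cells), .by = "expected_beta")
  }
}

#' Cross-technology agreement of beta values
#'
#' For every pair of technologies, the Spearman rank correlation (computed
#' as the product-moment correlation of mid-ranks, so ties get averaged
#' ranks) and the mean absolute beta difference, over the (sample, marker)
#' cells shared and non-missing in both.
#'
#' @param beta_list Named list (>= 2 entries) of long beta tibbles, one per
#'   technology; cells are matched by (sample or source id, marker id). If
#'   a `source_id` column is present it is used for matching so replicates
#'   measured on different platforms align.
#' @param min_cells Minimum shared non-missing cells per pair (default 3).
#' @return List of symmetric matrices: `spearman` (unit diagonal),
#'   `mean_abs_diff` (zero diagonal), `n_cells`.
#' @export
method_correlation <- function(beta_list, min_cells = 3) {
  if (!is.list(beta_list) || length(beta_list) < 2 || is.null(names(beta_list))) {
    stop_data("beta_list must be a named list of >= 2 beta tables")
  }
  key_cols <- function(b) if ("source_id" %in% names(b)) "source_id" else "sample_id"
  techs <- names(beta_list)
  k <- length(techs)
  sp <- matrix(1, k, k, dimnames = list(techs, techs))
  mad <- matrix(0, k, k, dimnames = list(techs, techs))
  nc <- matrix(NA_real_, k, k, dimnames = list(techs, techs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      bi <- beta_list[[i]]; bj <- beta_list[[j]]
      ki <- key_cols(bi); kj <- key_cols(bj)
      cells <- inner_join(
        select(bi, id = all_of(ki), "marker_id", beta_i = "beta"),
        select(bj, id = all_of(kj), "marker_id", beta_j = "beta"),
        by = c("id", "marker_id")) |>
        filter(!is.na(.data$beta_i), !is.na(.data$beta_j))
      if (nrow(cells) < min_cells) {
        stop_data("fewer than %d shared non-missing cells between %s and %s",
                  min_cells, techs[i], techs[j])
      }
      r <- cor(cells$beta_i, cells$beta_j, method = "spearman")
      sp[i, j] <- sp[j, i] <- r
      mad[i, j] <- mad[j, i] <- mean(abs(cells$beta_i - cells$beta_j))
      nc[i, j] <- nc[j, i] <- nrow(cells)
    }
  }
  list(spearman = sp, mean_abs_diff = mad, n_cells = nc)
}

#' Mean absolute error of age prediction
#'
#' @param predicted Predicted ages (finite numeric).
#' @param chronological Chronological ages (same length).
#' @return One-row tibble `mae`, `sd_abs_error`, `n`.
#' @export
mae_age <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop_data("predicted and chronological ages have different lengths")
  }
  if (!all(is.finite(predicted)) || !all(is.finite(chronological))) {
    stop_data("non-finite values in age vectors")
  }
  d <- abs(predicted - chronological)
  tibble(mae = mean(d), sd_abs_error = sd(d), n = length(d))
}

#' Correlation matrix between clocks (and chronological age)
#'
#' Product-moment correlations between clock outputs across samples, with
#' chronological age as an extra column when supplied. Constant columns
#' yield `NA` entries (reported, not an error); a caveat is emitted when
#' fewer than 10 samples are available.
#'
#' @param outputs Clock-output tibble (`sample_id`, `clock`, `value`) with
#'   >= 3 samples having all clocks.
#' @param ages Optional tibble `sample_id`, `age`.
#' @return Correlation matrix (clocks x clocks, plus `age` if given).
#' @export
clock_cross_correlation <- function(outputs, ages = NULL) {
  wide <- outputs |>
    select("sample_id", "clock", "value") |>
    pivot_wider(names_from = "clock", values_from = "value")
  if (!is.null(ages)) {
    wide <- left_join(wide, select(ages, "sample_id", "age"), by = "sample_id")
  }
  m <- as.matrix(select(wide, -"sample_id"))
  if (sum(stats::complete.cases(m)) < 3) {
    stop_data("need >= 3 samples with all clocks computed")
  }
  if (nrow(m) < 10) {
    inform(sprintf("small sample size (N = %d): correlations are unstable",
                   nrow(m)))
  }
  suppressWarnings(cor(m, use = "pairwise.complete.obs"))
}
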
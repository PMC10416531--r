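#' Linear epigenetic estimators
#'
#' A `clock_model` holds the intercept, per-marker weights, imputation means
#' and output units of one linear methylation-based estimator:
#' `value = intercept + sum_i weight_i * beta_i`. The same engine serves
#' chronological-age clocks (years), pace-of-aging scores (z-score-like
#' units, ~1 physiological year per calendar year) and the continuous
#' mortality risk score, which differ only in coefficients and units.
#'
#' @param name Clock identifier.
#' @param intercept Output-scale constant.
#' @param weights Named numeric vector, marker_id -> coefficient (non-empty).
#' @param imputation_means Named numeric vector of mean betas in `[0, 1]`;
#'   must cover every weighted marker (used to fill missing values).
#' @param units One of `"years"`, `"poam"`, `"mrs"`.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, weights, imputation_means,
                        units = c("years", "poam", "mrs")) {
  units <- match.arg(units)
  if (length(weights) == 0 || is.null(names(weights))) {
    stop_data("weights must be a non-empty named numeric vector")
  }
  missing_means <- setdiff(names(weights), names(imputation_means))
  if (length(missing_means) > 0) {
    stop_data("weighted marker lacking an imputation mean: %s",
              paste(missing_means, collapse = ", "))
  }
  means <- imputation_means[names(weights)]
  if (any(means < 0 | means > 1)) stop_data("imputation means must lie in [0, 1]")
  structure(
    list(name = name, intercept = as.numeric(intercept),
         weights = weights, imputation_means = means, units = units),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model '%s'> %d markers, intercept %.4g, units %s\n",
              x$name, length(x$weights), x$intercept, x$units))
  invisible(x)
}

#' Tidy a clock model into a coefficient table
#' @param x A [clock_model()].
#' @param ... Unused.
#' @return Tibble `marker_id`, `weight`, `imputation_mean` (intercept via
#'   [glance()]).
#' @export
tidy.clock_model <- function(x, ...) {
  tibble(marker_id = names(x$weights), weight = unname(x$weights),
         imputation_mean = unname(x$imputation_means))
}

#' One-row clock model summary
#' @param x A [clock_model()].
#' @param ... Unused.
#' @export
glance.clock_model <- function(x, ...) {
  tibble(name = x$name, n_markers = length(x$weights),
         intercept = x$intercept, units = x$units)
}

#' Load a clock model from coefficient and imputation-mean TSVs
#'
#' Coefficient TSV: columns `marker_id`, `weight`, intercept on a reserved
#' `(Intercept)` row. Means TSV: `marker_id`, `mean_beta`.
#'
#' @param coef_path,means_path File paths.
#' @param name Clock name (default the coefficient file stem).
#' @param units Output units.
#' @return A validated [clock_model()].
#' @export
load_clock_model <- function(coef_path, means_path, name = NULL,
                             units = "years") {
  name <- name %||% sub("\\.[^.]*$", "", basename(coef_path))
  co <- readr::read_tsv(coef_path, col_types = "cd", progress = FALSE)
  me <- readr::read_tsv(means_path, col_types = "cd", progress = FALSE)
  int_row <- co$marker_id == "(Intercept)"
  if (!any(int_row)) stop_data("coefficient file lacks an (Intercept) row")
  clock_model(
    name = name,
    intercept = co$weight[int_row][1],
    weights = setNames(co$weight[!int_row], co$marker_id[!int_row]),
    imputation_means = setNames(me$mean_beta, me$marker_id),
    units = units
  )
}

#' Write a clock model to coefficient and imputation-mean TSVs
#' @param model A [clock_model()].
#' @param coef_path,means_path Output paths.
#' @export
write_clock_model <- function(model, coef_path, means_path) {
  readr::write_tsv(
    tibble(marker_id = c("(Intercept)", names(model$weights)),
           weight = c(model$intercept, unname(model$weights))),
    coef_path, progress = FALSE)
  readr::write_tsv(
    tibble(marker_id = names(model$imputation_means),
           mean_beta = unname(model$imputation_means)),
    means_path, progress = FALSE)
  invisible(coef_path)
}

#' Mean-impute missing betas over a model's markers
#'
#' Returns a complete beta table over exactly the model's markers: observed
#' values are never altered; missing or absent values are replaced by the
#' model's imputation means (the mean-imputation convention of online clock
#' calculators).
#'
#' @param betas Long beta tibble (`sample_id`, `marker_id`, `beta`).
#' @param model A [clock_model()].
#' @return Tibble `sample_id`, `marker_id`, `beta`, `imputed` covering every
#'   (sample, model marker) cell.
#' @export
impute_missing <- function(betas, model) {
  stopifnot(inherits(model, "clock_model"))
  grid <- tidyr::expand_grid(sample_id = unique(betas$sample_id),
                             marker_id = names(model$weights))
  grid |>
    left_join(select(betas, "sample_id", "marker_id", "beta"),
              by = c("sample_id", "marker_id")) |>
    mutate(imputed = is.na(.data$beta),
           beta = ifelse(.data$imputed,
                         model$imputation_means[.data$marker_id],
                         .data$beta))
}

#' Evaluate a linear clock on complete beta rows
#'
#' `value = intercept + sum_i weight_i * beta_i` per sample. The input must
#' be complete over the model's markers: impute first with
#' [impute_missing()].
#'
#' @param betas Long beta tibble covering all model markers with no missing
#'   values (an `imputed` column, if present, is used to count imputations).
#' @param model A [clock_model()].
#' @return Tibble `sample_id`, `clock`, `value`, `n_imputed`.
#' @export
predict_linear_clock <- function(betas, model) {
  stopifnot(inherits(model, "clock_model"))
  sub <- filter(betas, .data$marker_id %in% names(model$weights))
  per_sample <- sub |>
    summarise(n = dplyr::n(), n_na = sum(is.na(.data$beta)),
              n_imputed = if ("imputed" %in% names(sub))
                sum(.data$imputed) else 0L,
              value = model$intercept +
                sum(model$weights[.data$marker_id] * .data$beta),
              .by = "sample_id")
  bad <- per_sample$n < length(model$weights) | per_sample$n_na > 0
  if (any(bad)) {
    stop_data(paste0("incomplete beta row for sample %s over clock '%s' ",
                     "markers; run impute_missing() first"),
              per_sample$sample_id[bad][1], model$name)
  }
  per_sample |>
    transmute(.data$sample_id, clock = model$name, .data$value,
              n_imputed = as.integer(.data$n_imputed))
}

#' Mortality-risk rule set
#'
#' Per-marker risk directions and beta thresholds for the categorical
#' mortality risk score: a marker contributes one risk point when its beta
#' lies strictly on the risk side of its threshold.
#'
#' @param marker_id Marker ids (exactly the MRS clock markers).
#' @param threshold Beta thresholds in `[0, 1]`.
#' @param direction `"above"` (risk if beta > threshold) or `"below"`.
#' @return Tibble of class `mrs_rule`.
#' @export
mrs_rule <- function(marker_id, threshold, direction) {
  stopifnot(length(marker_id) == length(threshold),
            length(marker_id) == length(direction),
            all(threshold >= 0 & threshold <= 1),
            all(direction %in% c("above", "below")))
  if (anyDuplicated(marker_id)) stop_data("duplicated marker in MRS rule")
  structure(tibble(marker_id = marker_id, threshold = threshold,
                   direction = direction),
            class = c("mrs_rule", "tbl_df", "tbl", "data.frame"))
}

#' Categorical mortality risk score by per-marker thresholding
#'
#' Counts, per sample, the markers whose beta lies on the risk side of its
#' threshold, yielding an integer score from 0 to the number of rule markers
#' (10 in the published configuration). The row must be complete over the
#' rule's markers.
#'
#' @param betas Long beta tibble complete over the rule markers.
#' @param rule An [mrs_rule()].
#' @return Tibble `sample_id`, `score`.
#' @export
mrs_categorical <- function(betas, rule) {
  stopifnot(inherits(rule, "mrs_rule"))
  sub <- betas |>
    filter(.data$marker_id %in% rule$marker_id) |>
    left_join(as_tibble(rule), by = "marker_id")
  per_sample <- sub |>
    summarise(n = dplyr::n(), n_na = sum(is.na(.data$beta)),
              score = sum(ifelse(.data$direction == "above",
                                 .data$beta > .data$threshold,
                                 .data$beta < .data$threshold)),
              .by = "sample_id")
  bad <- per_sample$n < nrow(rule) | per_sample$n_na > 0
  if (any(bad)) {
    stop_data("incomplete beta row for sample %s over MRS rule markers",
              per_sample$sample_id[bad][1])
  }
  transmute(per_sample, .data$sample_id, score = as.integer(.data$score))
}

#' Map a continuous mortality risk score to the categorical scale
#'
#' Alternative to per-marker thresholding: applies the published quadratic
#' continuous-to-categorical mapping (by default the built-in
#' `mrs_cat_hts` transform) and rounds into `[0, 10]`.
#'
#' @param value Continuous (calibrated) MRS values.
#' @param transform Quadratic [meth_transform()]; default
#'   `builtin_transforms()$mrs_cat_hts`.
#' @return Integer scores clamped to 0..10.
#' @export
mrs_categorical_from_continuous <- function(value,
                                            transform = builtin_transforms()$mrs_cat_hts) {
  as.integer(clamp(round(apply_transform(value, transform)), 0, 10))
}

#' Interpret a categorical mortality risk score
#'
#' Relative all-cause mortality risk versus a score of 0: a score of 1 means
#' a two-fold, 2-5 a three-fold, and above 5 a seven-fold increased risk.
#'
#' @param score Non-negative integer score(s).
#' @return Character vector of risk labels.
#' @export
interpret_mrs <- function(score) {
  if (any(score < 0) || any(score != floor(score))) {
    stop_data("MRS score must be a non-negative integer")
  }
  dplyr::case_when(
    score == 0 ~ "reference (1x)",
    score == 1 ~ "2-fold increased risk",
    score <= 5 ~ "3-fold increased risk",
    TRUE ~ "7-fold increased risk"
  )
}

#' Run all clocks on a beta table
#'
#' For each model: impute missing markers, evaluate the linear predictor,
#' and record per-sample imputation counts. If an MRS rule is supplied, a
#' `MRS_categorical` row per sample is appended (computed on the imputed
#' betas of the `MRS` model when present, else on the raw betas).
#'
#' @param betas Long beta-call tibble (e.g. from [call_betas()]).
#' @param models List of [clock_model()] objects.
#' @param rule Optional [mrs_rule()].
#' @return Tibble `sample_id`, `clock`, `value`, `n_imputed` (one row per
#'   sample per clock).
#' @export
run_all_clocks <- function(betas, models, rule = NULL) {
  out <- map(models, function(m) {
    predict_linear_clock(impute_missing(betas, m), m)
  }) |> list_rbind()
  if (!is.null(rule)) {
    mrs_model <- purrr::detect(models, function(m) m$name == "MRS")
    base <- if (!is.null(mrs_model)) impute_missing(betas, mrs_model) else betas
    cat_scores <- mrs_categorical(base, rule) |>
      transmute(.data$sample_id, clock = "MRS_categorical",
                value = as.numeric(.data$score),
                n_imputed = NA_integer_)
    out <- bind_rows(out, cat_scores)
  }
  out
}

# ---- fixture clocks ---------------------------------------------------------

#' Synthetic example clock models matching the example panel
#'
#' Builds four clearly synthetic fixture estimators over [example_panel()]
#' membership lists, with the published marker counts (71 HANNUM, 6 VISAGE
#' blood-age markers, 46 POAM, 10 MRS) but invented weights, intercepts and
#' imputation means: the real published coefficients are external plug-ins
#' loaded with [load_clock_model()]. Weight scales are chosen so that
#' inverting either age clock over ages 7-78 keeps all betas inside
#' `[0.01, 0.99]` (see [simulate_blood_cohort()]). Deterministic (internal
#' fixed seed).
#'
#' @param panel Panel tibble; default [example_panel()].
#' @return Named list of four [clock_model()] objects
#'   (`HANNUM`, `VISAGE`, `POAM`, `MRS`).
#' @export
example_clocks <- function(panel = example_panel()) {
  members <- clock_panels(panel)
  withr::with_seed(20230810L, {
    # deterministic magnitude ladders with randomised signs keep the
    # inversion in simulate_blood_cohort() inside [0.01, 0.99] for ages 7-78
    make <- function(name, markers, w_lo, w_hi, target, units) {
      mag <- seq(w_lo, w_hi, length.out = length(markers))
      w <- setNames(mag * sample(c(-1, 1), length(markers), replace = TRUE),
                    markers)
      mu <- setNames(runif(length(markers), 0.35, 0.65), markers)
      clock_model(name, intercept = target - sum(w * mu), weights = w,
                  imputation_means = mu, units = units)
    }
    list(
      HANNUM = make("HANNUM", members$HANNUM, 1.5, 3, 44, "years"),
      VISAGE = make("VISAGE", members$VISAGE[1:6], 28, 38, 44, "years"),
      POAM = make("POAM", members$POAM, 0.05, 0.15, 1.0, "poam"),
      MRS = make("MRS", members$MRS, 0.5, 1.5, -2.5, "mrs")
    )
  })
}

#' Default synthetic MRS categorical rule
#'
#' Threshold equal to each marker's imputation mean, direction given by the
#' sign of its continuous weight (risk above the mean for positive weights).
#' A documented fixture default: the published rule set is not distributed.
#'
#' @param model The continuous MRS [clock_model()].
#' @return An [mrs_rule()].
#' @export
example_mrs_rule <- function(model = example_clocks()$MRS) {
  mrs_rule(names(model$weights),
           threshold = unname(model$imputation_means),
           direction = ifelse(model$weights > 0, "above", "below"))
}
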
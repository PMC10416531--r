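#' Polynomial calibration transforms
#'
#' A `meth_transform` is a degree-1 or degree-2 polynomial mapping a raw
#' predictor output (or a beta value, when used as a simulated platform
#' bias) to a calibrated output: `a + b*x` or `a + b*x + c*x^2`. Transforms
#' always act on clock outputs in the calibration layer; the printed
#' cross-technology equations shipped with the package all have this form.
#'
#' @param coefficients Numeric vector `c(a, b)` (degree 1) or `c(a, b, c)`
#'   (degree 2).
#' @param name Transform label.
#' @param source_label,target_label Free-text provenance, e.g. `"HTS"` and
#'   `"chronological age"`.
#' @return An object of class `meth_transform`.
#' @export
meth_transform <- function(coefficients, name = "transform",
                           source_label = NA_character_,
                           target_label = NA_character_) {
  coefficients <- as.numeric(coefficients)
  if (!length(coefficients) %in% c(2L, 3L)) {
    stop_data("coefficients must have length 2 (linear) or 3 (quadratic)")
  }
  if (!all(is.finite(coefficients))) stop_data("non-finite transform coefficient")
  structure(
    list(name = name, degree = length(coefficients) - 1L,
         coefficients = coefficients, source_label = source_label,
         target_label = target_label, fit = NULL),
    class = "meth_transform"
  )
}

#' Identity transform
#' @export
identity_transform <- function() meth_transform(c(0, 1), name = "identity")

#' @export
print.meth_transform <- function(x, ...) {
  co <- x$coefficients
  eq <- if (x$degree == 1L) sprintf("%.4g + %.4g*x", co[1], co[2])
        else sprintf("%.4g + %.4g*x + %.4g*x^2", co[1], co[2], co[3])
  cat(sprintf("<meth_transform '%s'> degree %d: y = %s\n", x$name, x$degree, eq))
  invisible(x)
}

#' Apply a calibration transform
#'
#' @param value Numeric vector of raw predictor outputs.
#' @param transform A [meth_transform()].
#' @return Transformed values (same length as `value`).
#' @export
apply_transform <- function(value, transform) {
  stopifnot(inherits(transform, "meth_transform"))
  co <- transform$coefficients
  out <- co[1] + co[2] * value
  if (transform$degree == 2L) out <- out + co[3] * value^2
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration transform
#'
#' @param x A [meth_transform()].
#' @param ... Unused.
#' @return Tibble with columns `term` (`intercept`, `slope`, `quadratic`)
#'   and `estimate`.
#' @export
tidy.meth_transform <- function(x, ...) {
  tibble(term = c("intercept", "slope", "quadratic")[seq_along(x$coefficients)],
         estimate = x$coefficients)
}

#' One-row summary of a calibration transform
#'
#' For fitted transforms, includes the training fit statistics.
#'
#' @param x A [meth_transform()].
#' @param ... Unused.
#' @export
glance.meth_transform <- function(x, ...) {
  tibble(name = x$name, degree = x$degree,
         n = x$fit$n %||% NA_integer_,
         r.squared = x$fit$r.squared %||% NA_real_,
         sigma = x$fit$sigma %||% NA_real_)
}

fit_stats <- function(model) {
  # suppress the "essentially perfect fit" note: exact fits are expected here
  s <- suppressWarnings(summary(model))
  list(n = length(model$residuals), r.squared = s$r.squared, sigma = s$sigma)
}

#' Fit a linear (degree-1) calibration transform by OLS
#'
#' Ordinary least squares of `y` on `x` — the regression-based derivation of
#' cross-technology correction equations (predictor outputs on one platform
#' regressed on outputs from a reference platform, or on chronological age).
#' Plain OLS is used even though both axes carry error; this matches how the
#' shipped default equations were derived and is documented as a
#' simplification.
#'
#' @param x Raw predictor outputs (>= 3 finite values, non-constant).
#' @param y Reference values (same length).
#' @param name Transform label.
#' @return A fitted [meth_transform()] of degree 1 (fit statistics
#'   available via [glance()]).
#' @export
fit_linear_transform <- function(x, y, name = "fitted_linear") {
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_data("need at least 3 paired finite observations")
  if (sd(x) == 0) stop_data("x is constant; slope is unidentifiable")
  fit <- lm(y ~ x)
  out <- meth_transform(unname(coef(fit)), name = name)
  out$fit <- fit_stats(fit)
  out
}

#' Fit a quadratic (degree-2) calibration transform by OLS
#'
#' @param x Raw predictor outputs (>= 4 finite values, at least 3 distinct).
#' @param y Reference values.
#' @param name Transform label.
#' @return A fitted [meth_transform()] of degree 2.
#' @export
fit_quadratic_transform <- function(x, y, name = "fitted_quadratic") {
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop_data("need at least 4 paired finite observations")
  if (length(unique(x)) < 3) {
    stop_data("design matrix rank-deficient: need at least 3 distinct x values")
  }
  fit <- lm(y ~ x + I(x^2))
  out <- meth_transform(unname(coef(fit)), name = name)
  out$fit <- fit_stats(fit)
  out
}

#' Built-in cross-technology calibration transforms
#'
#' The six published default correction equations mapping raw clock outputs
#' between technologies (HTS sequencing vs. EPIC-style microarray) or onto
#' chronological age:
#' \itemize{
#'   \item `hannum_hts`: 0.64 + 0.89 x
#'   \item `hannum_epic`: -5.16 + 1.10 x
#'   \item `visage_ampliseq`: -1.61 + 0.93 x
#'   \item `poam_hts`: 0.23 + 0.72 x
#'   \item `mrs_cont_hts`: -1.72 + 0.61 x
#'   \item `mrs_cat_hts`: 25.76 + 13.29 x + 1.81 x^2 (maps the transformed
#'     continuous mortality risk score to the categorical 0-10 scale)
#' }
#'
#' These are shipped as constants: the extended donor set they were derived
#' from is not distributed, so they are not re-derived here.
#'
#' @return Named list of six [meth_transform()] objects.
#' @export
builtin_transforms <- function() {
  list(
    hannum_hts = meth_transform(c(0.64, 0.89), "hannum_hts",
                                "HannumAge HTS", "HannumAge calibrated"),
    hannum_epic = meth_transform(c(-5.16, 1.10), "hannum_epic",
                                 "HannumAge EPIC", "HannumAge calibrated"),
    visage_ampliseq = meth_transform(c(-1.61, 0.93), "visage_ampliseq",
                                     "VISAGE blood age AmpliSeq",
                                     "VISAGE blood age calibrated"),
    poam_hts = meth_transform(c(0.23, 0.72), "poam_hts",
                              "PoAm HTS", "PoAm calibrated"),
    mrs_cont_hts = meth_transform(c(-1.72, 0.61), "mrs_cont_hts",
                                  "MRS continuous HTS", "MRS continuous calibrated"),
    mrs_cat_hts = meth_transform(c(25.76, 13.29, 1.81), "mrs_cat_hts",
                                 "MRS continuous calibrated", "MRS categorical")
  )
}

#' Write a transform registry to TSV
#'
#' Columns: name, degree, a, b, c (c empty for degree-1 transforms).
#'
#' @param transforms Named list of [meth_transform()] objects.
#' @param path Output path.
#' @export
write_transform_registry <- function(transforms, path) {
  rows <- imap(transforms, function(t, nm) {
    co <- t$coefficients
    tibble(name = nm, degree = t$degree, a = co[1], b = co[2],
           c = if (t$degree == 2L) co[3] else NA_real_)
  }) |> list_rbind()
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read a transform registry from TSV
#'
#' @param path Registry TSV written by [write_transform_registry()].
#' @return Named list of [meth_transform()] objects.
#' @export
read_transform_registry <- function(path) {
  rows <- readr::read_tsv(path, col_types = "cinnn", progress = FALSE)
  out <- pmap(rows, function(name, degree, a, b, c) {
    meth_transform(if (degree == 2) c(a, b, c) else c(a, b), name = name)
  })
  setNames(out, rows$name)
}

#' Calibrate clock outputs with a registry of transforms
#'
#' Joins a clock-output table with a clock-to-transform mapping and adds a
#' calibrated value column; clocks without a transform pass through
#' unchanged.
#'
#' @param outputs Clock-output tibble with columns `clock` and `value` (see
#'   [run_all_clocks()]).
#' @param transforms Named list of [meth_transform()]; names are clock names.
#' @return `outputs` with an added `value_calibrated` column.
#' @export
calibrate_outputs <- function(outputs, transforms) {
  stopifnot(all(c("clock", "value") %in% names(outputs)))
  outputs |>
    mutate(value_calibrated = map2_dbl(.data$clock, .data$value, function(cl, v) {
      t <- transforms[[cl]]
      if (is.null(t)) v else apply_transform(v, t)
    }))
}
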
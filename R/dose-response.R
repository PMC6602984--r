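# Tabulated non-linear dose-response relative-risk curves, as produced by
# non-linear dose-response meta-analysis. Curves enter the pipeline as
# dose grids with point RR and a 95% CI band; evaluation anywhere on
# [0, Inf) is by linear interpolation with constant extrapolation beyond
# the maximum observed dose.

#' Construct a dose-response curve
#'
#' @param food,disease labels for the association the curve describes.
#' @param doses strictly increasing dose grid in g/day; the first entry is
#'   the reference dose, where RR must equal 1.
#' @param rr relative risks at `doses`; strictly positive.
#' @param rr_lo,rr_hi optional 95% CI bounds, enclosing `rr` pointwise.
#' @param max_observed_dose largest dose supported by the underlying
#'   meta-analysis; RR is clamped (held constant) beyond it. Defaults to
#'   the last grid dose.
#' @return an object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(food, disease, doses, rr,
                                rr_lo = NULL, rr_hi = NULL,
                                max_observed_dose = max(doses)) {
  doses <- as.numeric(doses)
  rr <- as.numeric(rr)
  if (length(doses) < 2L || length(rr) != length(doses)) {
    stop("need a dose grid of >= 2 points with matching rr values", call. = FALSE)
  }
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing", call. = FALSE)
  if (doses[1] < 0) stop("reference dose must be non-negative", call. = FALSE)
  if (abs(rr[1] - 1) > 1e-9) {
    stop("rr at the reference dose must equal 1", call. = FALSE)
  }
  if (any(rr <= 0)) stop("relative risks must be strictly positive", call. = FALSE)
  if (xor(is.null(rr_lo), is.null(rr_hi))) {
    stop("supply both CI bounds or neither", call. = FALSE)
  }
  if (!is.null(rr_lo)) {
    rr_lo <- as.numeric(rr_lo)
    rr_hi <- as.numeric(rr_hi)
    if (length(rr_lo) != length(rr) || length(rr_hi) != length(rr)) {
      stop("CI bounds must match the dose grid", call. = FALSE)
    }
    if (any(rr_lo > rr + 1e-12) || any(rr_hi < rr - 1e-12)) {
      stop("CI band must contain the point curve (rr_lo <= rr <= rr_hi)", call. = FALSE)
    }
  }
  stop_if_not_scalar_number(max_observed_dose, "max_observed_dose")

  x <- structure(list(food = food, disease = disease,
                      doses = doses, rr = rr, rr_lo = rr_lo, rr_hi = rr_hi,
                      max_observed_dose = max_observed_dose,
                      direction = NA_character_),
                 class = "dose_response_curve")
  x$direction <- classify_direction(x)
  x
}

#' Evaluate a dose-response curve
#'
#' Linear interpolation on the tabulated grid; doses above the maximum
#' observed dose return the RR at that maximum (constant extrapolation —
#' the conservative convention in comparative risk assessment, where
#' extending a meta-analytic curve beyond its evidence base is avoided).
#'
#' @param curve a `dose_response_curve`.
#' @param dose non-negative doses in g/day (vectorised).
#' @return relative risks at `dose`.
#' @examples
#' cv <- dose_response_curve("fish", "CHD", c(0, 100), c(1, 1.2))
#' eval_rr(cv, 50)   # 1.1 by linear interpolation
#' eval_rr(cv, 500)  # clamped to RR at 100 g/day
#' @export
eval_rr <- function(curve, dose) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("dose must be finite and non-negative", call. = FALSE)
  }
  x <- pmin(dose, curve$max_observed_dose)
  stats::approx(curve$doses, curve$rr, xout = x, rule = 2)$y
}

#' Classify the statistical significance of an association
#'
#' An association is significant when its 95% CI band excludes 1 at some
#' non-reference grid dose, under strict inequalities: a CI that exactly
#' touches 1 (e.g. RR 1.06, 95% CI 1.00-1.13) counts as non-significant.
#'
#' @param curve a `dose_response_curve` with CI bounds.
#' @return logical flag.
#' @export
classify_significance <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (is.null(curve$rr_lo) || is.null(curve$rr_hi)) {
    stop("cannot classify: curve has no CI band", call. = FALSE)
  }
  any(curve$rr_lo[-1] > 1 | curve$rr_hi[-1] < 1)
}

#' Classify the direction of an association
#'
#' `inverse` for a non-increasing RR over the grid, `positive` for
#' non-decreasing, `mixed` otherwise (e.g. J- or U-shaped). A flat curve
#' satisfies both monotonicity checks and ties to `inverse`; the label is
#' cosmetic there since a flat curve carries zero attributable fraction.
#'
#' @param curve a `dose_response_curve`.
#' @param tol tolerance on grid differences for monotonicity.
#' @return one of `"inverse"`, `"positive"`, `"mixed"`.
#' @export
classify_direction <- function(curve, tol = 1e-6) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (length(curve$doses) < 3L) {
    stop("direction classification needs a grid of >= 3 points", call. = FALSE)
  }
  d <- diff(curve$rr)
  if (all(d <= tol)) return("inverse")
  if (all(d >= -tol)) return("positive")
  "mixed"
}

#' @export
print.dose_response_curve <- function(x, ...) {
  sig <- if (is.null(x$rr_lo)) "no CI band" else {
    if (classify_significance(x)) "significant" else "non-significant"
  }
  cat(sprintf("Dose-response curve %s -> %s (%s, %s)\n",
              x$food, x$disease, x$direction, sig))
  cat(sprintf("  %d grid doses on [%g, %g] g/day, RR range [%.3f, %.3f]\n",
              length(x$doses), x$doses[1], max(x$doses), min(x$rr), max(x$rr)))
  invisible(x)
}

# Lookup helper over a list of curves.
find_curve <- function(curves, food, disease) {
  k <- pair_key(food, disease)
  if (!is.null(names(curves)) && k %in% names(curves)) return(curves[[k]])
  for (cv in curves) {
    if (identical(cv$food, food) && identical(cv$disease, disease)) return(cv)
  }
  NULL
}
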
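# Theoretical minimum risk exposure levels (TMRELs).
#
# Disease-specific rule: for a monotonically decreasing risk association
# the TMREL is the cross-country mean of the P97.5 intake (observed
# maximum consumption); for all other dose-response shapes it is the
# minimum-risk dose found by one-dimensional optimization; for a
# monotone-increasing curve that minimum sits at zero intake.
#
# Single (cross-disease) rule: one TMREL per food group, chosen to
# maximize the total attributable DALYs summed over diseases and
# countries — the maximum possible health gain from a single recommended
# intake level.

#' Disease-specific TMREL for one dose-response curve
#'
#' @param curve a `dose_response_curve`, or `NULL` when no curve exists
#'   for the pair (TMREL is then not applicable).
#' @param p975_mean cross-country mean of the P97.5 intake, g/day.
#' @return list with `value` (g/day, `NA` if not applicable) and
#'   `provenance`, one of `"p975_mean"`, `"curve_optimum"`,
#'   `"fixed_zero"`, `"not_applicable"`.
#' @examples
#' cv <- dose_response_curve("fish", "CHD", c(0, 50, 150), c(1, 0.9, 0.85))
#' disease_tmrel(cv, p975_mean = 131)  # monotone decreasing -> 131
#' @export
disease_tmrel <- function(curve, p975_mean) {
  if (is.null(curve)) {
    return(list(value = NA_real_, provenance = "not_applicable"))
  }
  stopifnot(inherits(curve, "dose_response_curve"))
  stop_if_not_scalar_number(p975_mean, "p975_mean")
  if (p975_mean <= 0) stop("p975_mean must be positive", call. = FALSE)
  dir <- classify_direction(curve)
  if (dir == "inverse") {
    return(list(value = p975_mean, provenance = "p975_mean"))
  }
  if (dir == "positive") {
    return(list(value = 0, provenance = "fixed_zero"))
  }
  value <- minimize_1d(function(t) eval_rr(curve, t),
                       lower = 0, upper = curve$max_observed_dose)
  list(value = value, provenance = "curve_optimum")
}

# Bounded 1-D minimization: Brent plus a 0.5 g/day grid scan to guard
# against local optima, then a local Brent polish around the best point.
minimize_1d <- function(f, lower, upper, grid_step = 0.5) {
  if (upper <= lower) return(lower)
  opt <- stats::optimize(f, interval = c(lower, upper), tol = 1e-4)
  grid <- seq(lower, upper, by = grid_step)
  if (grid[length(grid)] < upper) grid <- c(grid, upper)
  gv <- vapply(grid, f, numeric(1))
  gi <- which.min(gv)
  best <- if (gv[gi] < opt$objective) grid[gi] else opt$minimum
  lo <- max(lower, best - grid_step)
  hi <- min(upper, best + grid_step)
  pol <- stats::optimize(f, interval = c(lo, hi), tol = 1e-6)
  cand_x <- c(opt$minimum, grid[gi], pol$minimum, lower, upper)
  cand_v <- c(opt$objective, gv[gi], pol$objective, f(lower), f(upper))
  cand_x[which.min(cand_v)]
}

#' Single cross-disease TMREL for one food group
#'
#' Finds the intake level t* maximising the total attributable DALYs
#' summed over diseases and countries,
#' `sum_d sum_c PAF(c, d, t) * DALY(c, d)`, with PAFs computed exactly as
#' in [compute_paf()]. Because the expected relative risk E[RR(X)] does
#' not depend on t, the objective reduces to minimising
#' `sum_d RR_d(t) * w_d` with fixed weights
#' `w_d = sum_c DALY(c, d) / E[RR_d(X_c)]`; the search is still the
#' one-dimensional bounded optimization the method prescribes, made cheap.
#'
#' The search interval is `[0, min(D_max, p975_mean)]`, where `D_max` is
#' the largest maximum observed dose among eligible curves and
#' `p975_mean` the cross-country mean P97.5 intake: like the
#' disease-specific rule, the single counterfactual never exceeds the
#' observed maximum consumption, so a food whose eligible curves are all
#' monotone-protective gets the same TMREL in both modes.
#'
#' @param food food-group label (used in error messages).
#' @param curves named list of `dose_response_curve` objects for this
#'   food, one per disease (missing/`NULL` entries allowed).
#' @param exposures data frame of fitted gamma parameters for this food:
#'   columns `country`, `shape`, `scale`.
#' @param dalys data frame of DALY point means: columns `country`,
#'   `disease`, `mean`.
#' @param include_nonsignificant if `FALSE`, curves whose CI band never
#'   excludes 1 are dropped from the objective before optimising.
#' @param grid_step step of the guarding grid scan, g/day.
#' @return list with `value` (g/day) and `provenance`.
#' @export
single_tmrel <- function(food, curves, exposures, dalys,
                         include_nonsignificant = TRUE, grid_step = 0.5) {
  curves <- Filter(Negate(is.null), curves)
  if (!include_nonsignificant) {
    curves <- Filter(classify_significance, curves)
  }
  if (length(curves) == 0L) {
    stop("no associations for food '", food, "'", call. = FALSE)
  }
  stopifnot(all(c("country", "shape", "scale") %in% names(exposures)),
            all(c("country", "disease", "mean") %in% names(dalys)))

  p975_mean <- mean(stats::qgamma(0.975, shape = exposures$shape,
                                  scale = exposures$scale))
  d_max <- max(vapply(curves, function(cv) cv$max_observed_dose, numeric(1)))
  upper <- min(d_max, p975_mean)

  # fixed per-disease weights: sum_c DALY(c,d) / E[RR_d(X_c)]
  weights <- vapply(curves, function(cv) {
    w <- 0
    for (i in seq_len(nrow(exposures))) {
      ctry <- exposures$country[i]
      daly <- dalys$mean[dalys$country == ctry & dalys$disease == cv$disease]
      if (length(daly) != 1L) {
        stop("DALY mean missing for country '", ctry, "', disease '",
             cv$disease, "'", call. = FALSE)
      }
      ex <- as_gamma_exposure(exposures$shape[i], exposures$scale[i])
      w <- w + daly / expected_rr(ex, cv)
    }
    w
  }, numeric(1))

  objective <- function(t) {
    sum(weights * vapply(curves, function(cv) eval_rr(cv, t), numeric(1)))
  }
  value <- minimize_1d(objective, lower = 0, upper = upper, grid_step = grid_step)

  provenance <- if (abs(value - p975_mean) < 1e-6) {
    "p975_mean"
  } else if (value < 1e-9) {
    "fixed_zero"
  } else {
    "curve_optimum"
  }
  list(value = value, provenance = provenance)
}

#' TMREL table for all food groups
#'
#' Derives TMRELs for every food group, either per disease
#' (`mode = "disease_specific"`) or one value per food across diseases
#' (`mode = "single"`).
#'
#' @param curves named list of `dose_response_curve` objects, keyed
#'   `"food|disease"` (as built by [build_curves()] or [read_rr_csv()]).
#' @param exposures data frame of fitted gamma parameters: columns
#'   `country`, `food`, `shape`, `scale`.
#' @param dalys data frame: `country`, `disease`, `mean`. Only needed for
#'   `mode = "single"`.
#' @param mode `"disease_specific"` or `"single"`.
#' @param diseases disease labels to cover; defaults to those present in
#'   `curves`.
#' @param include_nonsignificant passed to [single_tmrel()] (the
#'   disease-specific rule does not depend on the significance filter,
#'   since a filtered-out pair simply contributes no attributable burden).
#' @return data frame with columns `food`, `disease` (`NA` for single
#'   mode), `tmrel` (g/day), `provenance`.
#' @export
tmrel_table <- function(curves, exposures, dalys = NULL,
                        mode = c("disease_specific", "single"),
                        diseases = NULL, include_nonsignificant = TRUE) {
  mode <- match.arg(mode)
  foods <- unique(exposures$food)
  if (is.null(diseases)) {
    diseases <- unique(vapply(curves, function(cv) cv$disease, character(1)))
  }
  rows <- list()
  for (fd in foods) {
    exf <- exposures[exposures$food == fd, , drop = FALSE]
    p975_mean <- mean(stats::qgamma(0.975, shape = exf$shape, scale = exf$scale))
    if (mode == "disease_specific") {
      for (ds in diseases) {
        cv <- find_curve(curves, fd, ds)
        tm <- disease_tmrel(cv, p975_mean)
        rows[[length(rows) + 1L]] <- data.frame(
          food = fd, disease = ds, tmrel = tm$value, provenance = tm$provenance,
          stringsAsFactors = FALSE)
      }
    } else {
      food_curves <- list()
      for (ds in diseases) {
        cv <- find_curve(curves, fd, ds)
        if (!is.null(cv)) food_curves[[ds]] <- cv
      }
      eligible <- food_curves
      if (!include_nonsignificant) eligible <- Filter(classify_significance, eligible)
      if (length(eligible) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          food = fd, disease = NA_character_, tmrel = NA_real_,
          provenance = "not_applicable", stringsAsFactors = FALSE)
      } else {
        tm <- single_tmrel(fd, food_curves, exf, dalys,
                           include_nonsignificant = include_nonsignificant)
        rows[[length(rows) + 1L]] <- data.frame(
          food = fd, disease = NA_character_, tmrel = tm$value,
          provenance = tm$provenance, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
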
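# Synthetic study world: intake surveys, dose-response curves and DALY
# envelopes with the statistical structure the analysis assumes, so every
# pipeline stage can be tested against known ground truth without any
# external database.
#
# Ground-truth exposure model: the world's (shape, scale) parameters
# define the gamma distribution of an individual's intake averaged over
# the survey days. Per-day intakes are drawn iid gamma(shape/d, scale*d),
# so the d-day mean is *exactly* gamma(shape, scale) — every downstream
# quantity (percentiles, densities, expected relative risks) then has a
# closed form against which the pipeline can be checked. The per-day
# distribution is sqrt(d) times wider in CV than the d-day mean,
# reproducing the widening that few-day food records impose on empirical
# intake distributions relative to usual intake.

#' The twelve default food groups
#' @return character vector of food-group labels.
#' @export
default_food_groups <- function() {
  c("whole_grain", "refined_grain", "vegetables", "fruit", "nuts", "legumes",
    "eggs", "dairy", "fish", "red_meat", "processed_meat", "SSB")
}

#' The four default disease outcomes
#' @return character vector: coronary heart disease, stroke, type 2
#'   diabetes, colorectal cancer.
#' @export
default_diseases <- function() c("CHD", "stroke", "T2D", "CRC")

#' The sixteen default countries
#' @return character vector of country labels.
#' @export
default_countries <- function() {
  c("Austria", "Belgium", "Czech Republic", "Denmark", "Finland", "France",
    "Germany", "Hungary", "Ireland", "Italy", "Latvia", "Netherlands",
    "Romania", "Spain", "Sweden", "United Kingdom")
}

# Cross-country anchor intakes (g/day): mean and P97.5 per food group.
food_anchors <- function() {
  data.frame(
    food  = c("refined_grain", "whole_grain", "vegetables", "fruit", "eggs",
              "SSB", "nuts", "legumes", "processed_meat", "red_meat",
              "dairy", "fish"),
    mean  = c(145, 38, 152, 142, 15, 120, 2, 17, 44, 53, 251, 26),
    p975  = c(403, 224, 412, 488, 68, 713, 20, 122, 226, 195, 718, 131),
    stringsAsFactors = FALSE)
}

# Default food-disease association map: curve family, effect size and
# significance flag per pair. Protective foods are monotone-decreasing or
# J/U-shaped (interior minimum d_star); harmful foods monotone-increasing;
# absent pairs carry family "none". max_dose is the curve's maximum
# observed dose (g/day).
default_associations <- function() {
  a <- function(food, disease, family, significant, effect, d_star = NA, max_dose) {
    data.frame(food = food, disease = disease, family = family,
               significant = significant, effect = effect, d_star = d_star,
               max_dose = max_dose, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    a("whole_grain", "CHD", "u_shaped", TRUE,  0.20, 114, 280),
    a("whole_grain", "T2D", "u_shaped", TRUE,  0.25,  56, 280),
    a("whole_grain", "CRC", "monotone_dec", TRUE, 0.20, NA, 280),
    a("whole_grain", "stroke", "u_shaped", FALSE, 0.10, 124, 280),
    a("vegetables", "CHD", "monotone_dec", TRUE, 0.15, NA, 520),
    a("vegetables", "CRC", "monotone_dec", TRUE, 0.12, NA, 520),
    a("vegetables", "T2D", "u_shaped", TRUE, 0.12, 282, 520),
    a("vegetables", "stroke", "u_shaped", TRUE, 0.15, 194, 520),
    a("fruit", "CHD", "u_shaped", TRUE, 0.15, 173, 610),
    a("fruit", "CRC", "monotone_dec", TRUE, 0.10, NA, 610),
    a("fruit", "T2D", "u_shaped", TRUE, 0.12, 260, 610),
    a("fruit", "stroke", "monotone_dec", TRUE, 0.18, NA, 610),
    a("nuts", "CHD", "u_shaped", TRUE, 0.25, 12, 25),
    a("nuts", "CRC", "monotone_dec", FALSE, 0.08, NA, 25),
    a("nuts", "T2D", "u_shaped", FALSE, 0.08, 9, 25),
    a("nuts", "stroke", "u_shaped", FALSE, 0.08, 11, 25),
    a("legumes", "CHD", "monotone_dec", TRUE, 0.20, NA, 150),
    a("legumes", "CRC", "monotone_dec", FALSE, 0.06, NA, 150),
    a("legumes", "T2D", "monotone_dec", FALSE, 0.05, NA, 150),
    a("legumes", "stroke", "monotone_dec", FALSE, 0.06, NA, 150),
    a("fish", "CHD", "monotone_dec", TRUE, 0.15, NA, 165),
    a("fish", "stroke", "monotone_dec", TRUE, 0.18, NA, 165),
    a("fish", "T2D", "monotone_dec", FALSE, 0.05, NA, 165),
    a("dairy", "CHD", "u_shaped", TRUE, 0.10, 283, 900),
    a("dairy", "CRC", "monotone_dec", TRUE, 0.12, NA, 900),
    a("dairy", "T2D", "monotone_dec", TRUE, 0.08, NA, 900),
    a("dairy", "stroke", "u_shaped", TRUE, 0.08, 622, 900),
    a("eggs", "T2D", "monotone_inc", TRUE, 0.25, NA, 85),
    a("eggs", "CRC", "monotone_inc", FALSE, 0.08, NA, 85),
    a("red_meat", "stroke", "monotone_inc", TRUE, 0.15, NA, 245),
    a("red_meat", "T2D", "monotone_inc", TRUE, 0.25, NA, 245),
    a("red_meat", "CRC", "monotone_inc", TRUE, 0.20, NA, 245),
    a("processed_meat", "stroke", "monotone_inc", TRUE, 0.25, NA, 280),
    a("processed_meat", "T2D", "monotone_inc", TRUE, 0.35, NA, 280),
    a("processed_meat", "CRC", "monotone_inc", TRUE, 0.30, NA, 280),
    a("SSB", "CHD", "monotone_inc", TRUE, 0.25, NA, 900),
    a("SSB", "stroke", "monotone_inc", TRUE, 0.15, NA, 900),
    a("SSB", "T2D", "monotone_inc", TRUE, 0.30, NA, 900),
    a("refined_grain", "CHD", "monotone_inc", FALSE, 0.19, NA, 500),
    a("refined_grain", "T2D", "monotone_inc", FALSE, 0.06, NA, 500)
  )
  rows
}

# Per-country, per-disease baseline DALY scale (DALYs/year, order of
# magnitude of national burdens for a mid-size European country).
disease_daly_base <- function() {
  c(CHD = 620000, stroke = 310000, T2D = 170000, CRC = 140000)
}

# Solve the gamma shape whose P97.5/mean ratio equals `ratio` (> 1).
# qgamma(0.975, k, scale = m/k) / m = qgamma(0.975, k) / k. The ratio
# peaks at ~11.45 near shape 0.041 and decreases towards 1 as the shape
# grows; the root-find works on that decreasing branch, capping requested
# ratios just below the peak (a heavier right tail than a gamma can carry
# would need a zero-inflated or different family).
solve_shape_from_ratio <- function(ratio) {
  ratio <- min(max(ratio, 1.001), 11.4)
  f <- function(lk) stats::qgamma(0.975, exp(lk)) / exp(lk) - ratio
  exp(stats::uniroot(f, interval = c(log(0.042), log(2e4)), tol = 1e-10)$root)
}

#' Build a synthetic study world
#'
#' Creates the ground truth for a full synthetic comparative risk
#' assessment: per country x food gamma intake parameters (anchored to
#' cross-country mean and P97.5 intake levels typical of European food
#' consumption surveys), a food x disease association map with curve
#' families and significance flags, and per country x disease DALY means.
#' Everything downstream is a deterministic function of this object, and
#' regenerating with the same seed is byte-identical.
#'
#' @param countries,food_groups,diseases label sets. Default: 16 European
#'   countries, 12 food groups, 4 diseases.
#' @param seed integer seed for the world's own randomness (country-level
#'   variation); all generators derive substreams from it.
#' @param survey_days number of simulated survey days per participant
#'   whose intakes are averaged (food records span a few days).
#' @param zero_inflation share of never-consumers per food (0 disables;
#'   the gamma exposure model itself carries no point mass at zero).
#' @param country_cv between-country coefficient of variation of mean
#'   intake around the food anchors.
#' @param ratio_cv between-country jitter of the P97.5/mean ratio.
#' @param associations optional custom association map (data frame with
#'   columns food, disease, family, significant, effect, d_star,
#'   max_dose); defaults to [default_associations()] restricted to the
#'   requested labels. Pairs absent from the map get family `"none"`.
#' @return object of class `synthetic_world`.
#' @export
synthetic_world <- function(countries = default_countries(),
                            food_groups = default_food_groups(),
                            diseases = default_diseases(),
                            seed = 1L, survey_days = 3L, zero_inflation = 0,
                            country_cv = 0.15, ratio_cv = 0.05,
                            associations = NULL) {
  stopifnot(length(countries) >= 1, length(food_groups) >= 1,
            length(diseases) >= 1)
  if (zero_inflation < 0 || zero_inflation >= 1) {
    stop("zero_inflation must lie in [0, 1)", call. = FALSE)
  }
  anchors <- food_anchors()

  exposure_params <- with_seed(substream_seed(seed, 1L), {
    rows <- list()
    for (fi in seq_along(food_groups)) {
      fd <- food_groups[fi]
      i <- match(fd, anchors$food)
      m0 <- if (is.na(i)) 100 else anchors$mean[i]
      r0 <- if (is.na(i)) 3 else anchors$p975[i] / anchors$mean[i]
      for (ci in seq_along(countries)) {
        m <- m0 * exp(stats::rnorm(1, 0, country_cv))
        r <- max(1.05, r0 * exp(stats::rnorm(1, 0, ratio_cv)))
        k <- solve_shape_from_ratio(r)
        rows[[length(rows) + 1L]] <- data.frame(
          country = countries[ci], food = fd, shape = k, scale = m / k,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  if (is.null(associations)) {
    associations <- default_associations()
  }
  associations <- associations[associations$food %in% food_groups &
                                 associations$disease %in% diseases, , drop = FALSE]
  # explicit "no association" marker for every remaining pair
  all_pairs <- expand.grid(food = food_groups, disease = diseases,
                           stringsAsFactors = FALSE)
  have <- paste(associations$food, associations$disease)
  missing <- all_pairs[!paste(all_pairs$food, all_pairs$disease) %in% have, , drop = FALSE]
  if (nrow(missing)) {
    missing$family <- "none"
    missing$significant <- FALSE
    missing$effect <- NA_real_
    missing$d_star <- NA_real_
    missing$max_dose <- NA_real_
    associations <- rbind(associations, missing)
  }
  associations <- associations[order(associations$food, associations$disease), ]
  rownames(associations) <- NULL

  daly_means <- with_seed(substream_seed(seed, 2L), {
    base <- disease_daly_base()
    size <- exp(stats::rnorm(length(countries), 0, 0.8))
    rows <- list()
    for (ci in seq_along(countries)) {
      for (ds in diseases) {
        b <- if (ds %in% names(base)) base[[ds]] else 200000
        rows[[length(rows) + 1L]] <- data.frame(
          country = countries[ci], disease = ds,
          mean = round(b * size[ci] * exp(stats::rnorm(1, 0, 0.15))),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  structure(list(countries = countries, food_groups = food_groups,
                 diseases = diseases, exposure_params = exposure_params,
                 associations = associations, daly_means = daly_means,
                 seed = as.integer(seed), survey_days = as.integer(survey_days),
                 zero_inflation = zero_inflation),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic CRA world: %d countries x %d food groups x %d diseases (seed %d)\n",
              length(x$countries), length(x$food_groups), length(x$diseases), x$seed))
  n_assoc <- sum(x$associations$family != "none")
  cat(sprintf("  %d food-disease associations (%d significant), %d survey days\n",
              n_assoc, sum(x$associations$significant), x$survey_days))
  invisible(x)
}

#' Simulate an intake survey and summarise it
#'
#' Draws `n_participants` individual intakes per country for every food
#' group (each the mean of the world's `survey_days` per-day gamma draws)
#' and summarises them as mean, percentiles and sample size — the form in
#' which national food-consumption data reach the pipeline.
#'
#' @param world a `synthetic_world`.
#' @param n_participants participants per country: a single number or a
#'   named vector over countries. Must be at least 50.
#' @param probs percentile probabilities to report.
#' @return list with `summary` (data frame: country, food, n, mean, and
#'   one `p<q>` column per percentile) and `draws` (named list of the raw
#'   individual-level values, keyed `"country|food"`, for oracle checks).
#' @export
gen_intake_survey <- function(world, n_participants,
                              probs = default_percentile_probs()) {
  stopifnot(inherits(world, "synthetic_world"))
  n_by_country <- if (length(n_participants) == 1L) {
    stats::setNames(rep(n_participants, length(world$countries)), world$countries)
  } else n_participants
  for (ctry in world$countries) {
    n <- n_by_country[[ctry]]
    if (is.null(n) || is.na(n) || n <= 0) {
      stop("non-positive n_participants for country '", ctry, "'", call. = FALSE)
    }
    if (n < 50) {
      stop("n_participants must be at least 50 (country '", ctry, "')", call. = FALSE)
    }
  }

  d <- world$survey_days
  rows <- list()
  draws <- list()
  for (ci in seq_along(world$countries)) {
    ctry <- world$countries[ci]
    n <- as.integer(n_by_country[[ctry]])
    for (fi in seq_along(world$food_groups)) {
      fd <- world$food_groups[fi]
      p <- world$exposure_params[world$exposure_params$country == ctry &
                                   world$exposure_params$food == fd, ]
      x <- with_seed(substream_seed(world$seed, label_hash(ctry), label_hash(fd)), {
        per_day <- matrix(stats::rgamma(n * d, shape = p$shape / d,
                                        scale = p$scale * d), nrow = n)
        v <- rowMeans(per_day)
        if (world$zero_inflation > 0) {
          v[stats::runif(n) < world$zero_inflation] <- 0
        }
        v
      })
      q <- stats::quantile(x, probs, names = FALSE, type = 7)
      row <- data.frame(country = ctry, food = fd, n = n, mean = mean(x),
                        stringsAsFactors = FALSE)
      row[paste0("p", probs * 100)] <- as.list(q)
      rows[[length(rows) + 1L]] <- row
      draws[[pair_key(ctry, fd)]] <- x
    }
  }
  list(summary = do.call(rbind, rows), draws = draws)
}

#' Generate a parametric dose-response curve
#'
#' Builds a tabulated relative-risk curve of a given family with a 95% CI
#' band consistent with the requested significance: a significant band
#' hugs the point curve and excludes 1 wherever the effect is non-null; a
#' non-significant band is wide enough to cross 1 at every non-reference
#' dose. RR at the reference dose (0 g/day) is exactly 1.
#'
#' Families: `"monotone_dec"` `RR = 1 - a(1 - exp(-x/tau))`,
#' `"monotone_inc"` `RR = 1 + a(1 - exp(-x/tau))`,
#' `"u_shaped"` `RR = 1 + c((x - d_star)^2 - d_star^2)` with
#' `c = depth/d_star^2` (minimum `1 - depth` at `d_star`; the grid is
#' augmented with `d_star` so the tabulated curve attains its minimum
#' exactly), and `"flat"` `RR = 1` (always non-significant).
#'
#' @param family curve family, one of the four above.
#' @param params list of family parameters: `effect` (risk reduction /
#'   increase `a`, or U-curve depth), `tau` (saturation dose, default a
#'   third of the grid maximum), `d_star` (U-curve minimum).
#' @param dose_grid strictly increasing dose grid starting at 0.
#' @param significant should the CI band exclude 1 over the effect range?
#' @param food,disease labels attached to the curve.
#' @return a `dose_response_curve`.
#' @export
gen_dose_response <- function(family, params = list(), dose_grid,
                              significant = TRUE,
                              food = "food", disease = "disease") {
  if (length(dose_grid) < 3L || any(diff(dose_grid) <= 0) || dose_grid[1] != 0) {
    stop("dose_grid must be strictly increasing and start at 0", call. = FALSE)
  }
  dmax <- max(dose_grid)
  effect <- params$effect %||% 0.2
  tau <- params$tau %||% (dmax / 3)
  rr <- switch(family,
    flat = rep(1, length(dose_grid)),
    monotone_dec = 1 - effect * (1 - exp(-dose_grid / tau)),
    monotone_inc = 1 + effect * (1 - exp(-dose_grid / tau)),
    u_shaped = {
      d_star <- params$d_star %||% (dmax / 3)
      if (d_star <= 0 || d_star >= dmax) {
        stop("u_shaped requires 0 < d_star < max(dose_grid)", call. = FALSE)
      }
      if (effect >= 1) stop("u_shaped depth must be < 1", call. = FALSE)
      dose_grid <- sort(unique(c(dose_grid, d_star)))
      curv <- effect / d_star^2
      1 + curv * ((dose_grid - d_star)^2 - d_star^2)
    },
    stop("unknown dose-response family '", family, "'", call. = FALSE)
  )
  if (family == "flat") significant <- FALSE

  lrr <- log(rr)
  if (significant) {
    lo <- pmin(exp(0.75 * lrr), exp(1.25 * lrr))
    hi <- pmax(exp(0.75 * lrr), exp(1.25 * lrr))
  } else {
    w <- abs(lrr) + 0.1
    lo <- exp(lrr - w)
    hi <- exp(lrr + w)
    lo[1] <- 1
    hi[1] <- 1
  }
  dose_response_curve(food, disease, dose_grid, rr, rr_lo = lo, rr_hi = hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialise all dose-response curves of a world
#'
#' @param world a `synthetic_world`.
#' @param n_grid number of equispaced grid doses per curve.
#' @return named list of `dose_response_curve` objects keyed
#'   `"food|disease"`; pairs with no association are absent.
#' @export
build_curves <- function(world, n_grid = 41) {
  stopifnot(inherits(world, "synthetic_world"))
  curves <- list()
  assoc <- world$associations
  for (i in seq_len(nrow(assoc))) {
    if (assoc$family[i] == "none") next
    grid <- seq(0, assoc$max_dose[i], length.out = n_grid)
    cv <- gen_dose_response(assoc$family[i],
                            params = list(effect = assoc$effect[i],
                                          d_star = assoc$d_star[i]),
                            dose_grid = grid,
                            significant = assoc$significant[i],
                            food = assoc$food[i], disease = assoc$disease[i])
    curves[[pair_key(assoc$food[i], assoc$disease[i])]] <- cv
  }
  curves
}

#' Generate the DALY envelope table of a world
#'
#' Attaches a symmetric 95% uncertainty interval of relative half-width
#' `rel_ui_width` to every true DALY mean; the gamma uncertainty
#' distribution is fitted to these bounds downstream by
#' [fit_daly_gamma()].
#'
#' @param world a `synthetic_world`.
#' @param rel_ui_width relative half-width of the interval, in (0, 1).
#' @return data frame: `country`, `disease`, `mean`, `ui_lo`, `ui_hi`.
#' @export
gen_daly_envelope <- function(world, rel_ui_width = 0.1) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!is.numeric(rel_ui_width) || rel_ui_width <= 0 || rel_ui_width >= 1) {
    stop("rel_ui_width must lie in (0, 1)", call. = FALSE)
  }
  out <- world$daly_means
  out$ui_lo <- out$mean * (1 - rel_ui_width)
  out$ui_hi <- out$mean * (1 + rel_ui_width)
  out
}

# Analytic cross-country P97.5 mean per food (ground truth).
world_p975_means <- function(world) {
  ep <- world$exposure_params
  vapply(split(ep, ep$food), function(g) {
    mean(stats::qgamma(0.975, shape = g$shape, scale = g$scale))
  }, numeric(1))
}

#' Write a world's pipeline inputs to CSV
#'
#' Simulates the intake survey and writes the three input tables the
#' pipeline consumes (intake summaries, dose-response curves, DALY
#' envelopes), plus a ground-truth JSON sidecar with the world's true
#' parameters and a ready-to-run YAML config.
#'
#' @param world a `synthetic_world`.
#' @param n_participants survey size per country (see
#'   [gen_intake_survey()]).
#' @param dir output directory (created if needed).
#' @param rel_ui_width DALY interval half-width.
#' @param n_sim,seed entries written into the config.
#' @return named list of file paths, invisibly.
#' @export
simulate_inputs <- function(world, n_participants, dir,
                            rel_ui_width = 0.1, n_sim = 1e5, seed = world$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  survey <- gen_intake_survey(world, n_participants)
  curves <- build_curves(world)
  dalys <- gen_daly_envelope(world, rel_ui_width)

  paths <- list(
    intake_table = file.path(dir, "intake.csv"),
    rr_table = file.path(dir, "rr_curves.csv"),
    daly_table = file.path(dir, "dalys.csv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "config.yaml"))

  utils::write.csv(survey$summary, paths$intake_table, row.names = FALSE)
  write_rr_csv(curves, paths$rr_table)
  utils::write.csv(dalys, paths$daly_table, row.names = FALSE)
  jsonlite::write_json(
    list(seed = world$seed, survey_days = world$survey_days,
         zero_inflation = world$zero_inflation,
         exposure_params = world$exposure_params,
         associations = world$associations,
         daly_means = world$daly_means),
    paths$ground_truth, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(
    list(intake_table = paths$intake_table, rr_table = paths$rr_table,
         daly_table = paths$daly_table, out_dir = file.path(dir, "results"),
         n_sim = n_sim, seed = as.integer(seed)),
    paths$config)
  invisible(paths)
}
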
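# Optimal intake levels: disease-specific and single cross-disease TMRELs.

test_that("disease-specific TMREL follows the three provenance rules", {
  # monotone protective: the cross-country P97.5 mean, exactly as supplied
  fish <- gen_dose_response("monotone_dec", list(effect = 0.15), seq(0, 165, by = 5))
  tm <- disease_tmrel(fish, p975_mean = 131)
  expect_identical(tm$value, 131)
  expect_identical(tm$provenance, "p975_mean")

  veg <- gen_dose_response("monotone_dec", list(effect = 0.15), seq(0, 520, by = 10))
  expect_identical(disease_tmrel(veg, 412)$value, 412)

  # monotone harmful: zero intake
  ssb <- gen_dose_response("monotone_inc", list(effect = 0.3), seq(0, 900, by = 20))
  tm0 <- disease_tmrel(ssb, 713)
  expect_identical(tm0$value, 0)
  expect_identical(tm0$provenance, "fixed_zero")

  # interior minimum: one-dimensional optimization on the curve
  grid <- seq(0, 300, by = 1)
  u <- dose_response_curve("wg", "T2D", grid, 1 + 1e-5 * ((grid - 80)^2 - 80^2))
  tmu <- disease_tmrel(u, 224)
  expect_equal(tmu$value, 80, tolerance = 1e-3)
  expect_identical(tmu$provenance, "curve_optimum")

  # no curve available
  expect_identical(disease_tmrel(NULL, 100)$provenance, "not_applicable")
})

test_that("single TMREL reduces to the disease optimum for one or shared curves", {
  w <- small_world(seed = 3, n_countries = 3, foods = "whole_grain")
  sv <- gen_intake_survey(w, 400)
  ex <- fit_exposures(sv$summary)
  dalys <- w$daly_means
  grid <- seq(0, 280, by = 5)

  u <- gen_dose_response("u_shaped", list(effect = 0.2, d_star = 114), grid,
                         food = "whole_grain", disease = "CHD")
  one <- single_tmrel("whole_grain", list(CHD = u), ex, dalys)
  expect_equal(one$value, 114, tolerance = 0.01)

  # identical U-curves for every disease: the shared arg-min, whatever the weights
  curves <- lapply(c("CHD", "stroke", "T2D", "CRC"), function(ds) {
    gen_dose_response("u_shaped", list(effect = 0.2, d_star = 114), grid,
                      food = "whole_grain", disease = ds)
  })
  names(curves) <- c("CHD", "stroke", "T2D", "CRC")
  shared <- single_tmrel("whole_grain", curves, ex, dalys)
  expect_equal(shared$value, 114, tolerance = 0.01)

  expect_error(single_tmrel("eggs", list(), ex, dalys), "no associations for food")
})

test_that("single TMREL matches an exhaustive 1 g/day grid search of its objective", {
  for (seed in 1:4) {
    w <- small_world(seed = seed, n_countries = 3, foods = "dairy")
    sv <- gen_intake_survey(w, 400)
    ex <- fit_exposures(sv$summary)
    dalys <- w$daly_means
    set.seed(seed)
    grid <- seq(0, 700, by = 10)
    curves <- list(
      CHD = gen_dose_response("monotone_dec", list(effect = runif(1, 0.1, 0.3)),
                              grid, food = "dairy", disease = "CHD"),
      stroke = gen_dose_response("u_shaped",
                                 list(effect = runif(1, 0.1, 0.3),
                                      d_star = runif(1, 100, 500)),
                                 grid, food = "dairy", disease = "stroke"))
    t_star <- single_tmrel("dairy", curves, ex, dalys)$value

    # oracle: same objective (PAF x DALY summed over diseases and
    # countries), exhaustive scan at 1 g/day resolution
    p975_mean <- mean(qgamma(0.975, ex$shape, scale = ex$scale))
    upper <- min(max(sapply(curves, function(cv) cv$max_observed_dose)), p975_mean)
    exos <- lapply(seq_len(nrow(ex)), function(i) {
      foodcra:::as_gamma_exposure(ex$shape[i], ex$scale[i])
    })
    objective <- function(t) {
      tot <- 0
      for (cv in curves) for (i in seq_len(nrow(ex))) {
        daly <- dalys$mean[dalys$country == ex$country[i] & dalys$disease == cv$disease]
        tot <- tot + compute_paf(exos[[i]], cv, t) * daly
      }
      tot
    }
    ts <- seq(0, upper, by = 1)
    vals <- vapply(ts, objective, numeric(1))
    expect_lte(abs(t_star - ts[which.max(vals)]), 1)
  }
})

test_that("single TMREL is invariant to rescaling DALYs and reacts to the significance filter", {
  w <- small_world(seed = 9, n_countries = 3, foods = "whole_grain")
  sv <- gen_intake_survey(w, 400)
  ex <- fit_exposures(sv$summary)
  dalys <- w$daly_means
  grid <- seq(0, 280, by = 5)
  # the heavily-weighted CHD curve is non-significant: dropping it under the
  # filter moves the joint optimum to the significant CRC curve's minimum
  curves <- list(
    CHD = gen_dose_response("u_shaped", list(effect = 0.25, d_star = 60), grid,
                            significant = FALSE, food = "whole_grain", disease = "CHD"),
    CRC = gen_dose_response("u_shaped", list(effect = 0.2, d_star = 200), grid,
                            significant = TRUE, food = "whole_grain", disease = "CRC"))

  t_all <- single_tmrel("whole_grain", curves, ex, dalys,
                        include_nonsignificant = TRUE)$value
  t_sig <- single_tmrel("whole_grain", curves, ex, dalys,
                        include_nonsignificant = FALSE)$value
  expect_gt(abs(t_all - t_sig), 5)  # the filter genuinely moves the optimum
  expect_equal(t_sig, 200, tolerance = 0.1)

  dalys10 <- dalys
  dalys10$mean <- dalys10$mean * 10
  expect_equal(single_tmrel("whole_grain", curves, ex, dalys10)$value, t_all,
               tolerance = 1e-6)
})

test_that("tmrel_table covers both modes with provenance for every value", {
  w <- small_world(seed = 13)
  sv <- gen_intake_survey(w, 400)
  ex <- fit_exposures(sv$summary)
  curves <- build_curves(w)
  tt <- tmrel_table(curves, ex, dalys = w$daly_means, mode = "disease_specific",
                    diseases = w$diseases)
  expect_equal(nrow(tt), length(w$food_groups) * length(w$diseases))
  expect_true(all(tt$provenance %in%
                    c("p975_mean", "curve_optimum", "fixed_zero", "not_applicable")))
  expect_true(all(is.na(tt$tmrel) | tt$tmrel >= 0))

  ts <- tmrel_table(curves, ex, dalys = w$daly_means, mode = "single",
                    diseases = w$diseases)
  expect_equal(nrow(ts), length(w$food_groups))
  ok <- !is.na(ts$tmrel)
  p975 <- sapply(split(ex, ex$food), function(g) {
    mean(qgamma(0.975, g$shape, scale = g$scale))
  })
  dmax <- sapply(ts$food[ok], function(fd) {
    max(sapply(Filter(function(cv) cv$food == fd, curves),
               function(cv) cv$max_observed_dose))
  })
  expect_true(all(ts$tmrel[ok] <= pmax(p975[ts$food[ok]], dmax) + 1e-6))
})
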
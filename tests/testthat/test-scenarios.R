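# Scenario orchestration, aggregation, ranking and the config entry point.

test_that("the four canonical labels map to their TMREL mode and filter", {
  expect_equal(scenario_spec("A")$tmrel_mode, "disease_specific")
  expect_equal(scenario_spec("A")$association_filter, "all")
  expect_equal(scenario_spec("B")$association_filter, "significant_only")
  expect_equal(scenario_spec("C")$tmrel_mode, "single")
  expect_equal(scenario_spec("D")$tmrel_mode, "single")
  expect_equal(scenario_spec("D")$association_filter, "significant_only")
  expect_error(scenario_spec("E"), "A, B, C, D")
})

test_that("a world of flat curves attributes nothing", {
  w <- small_world(seed = 17, n_countries = 2, foods = c("fish", "SSB"))
  assoc <- expand.grid(food = w$food_groups, disease = w$diseases,
                       stringsAsFactors = FALSE)
  assoc$family <- "flat"
  assoc$significant <- FALSE
  assoc$effect <- 0
  assoc$d_star <- NA_real_
  assoc$max_dose <- 400
  wf <- synthetic_world(countries = w$countries, food_groups = w$food_groups,
                        diseases = w$diseases, seed = 17, associations = assoc)
  run <- run_all_scenarios(wf, n_participants = 200, n_sim = 1000, seed = 2)
  for (lb in c("A", "C")) {
    r <- run$results[[lb]]
    expect_equal(r$total$daly_mean, 0)
    expect_equal(r$total$proportion, 0)
    expect_true(all(r$results$paf == 0))
  }
})

test_that("the significance filter equals restricting the input to significant pairs", {
  grid <- seq(0, 300, by = 10)
  assoc <- rbind(
    data.frame(food = "fish", disease = "CHD", family = "monotone_dec",
               significant = TRUE, effect = 0.2, d_star = NA, max_dose = 300),
    data.frame(food = "SSB", disease = "CHD", family = "monotone_inc",
               significant = FALSE, effect = 0.3, d_star = NA, max_dose = 300),
    data.frame(food = "SSB", disease = "stroke", family = "monotone_inc",
               significant = FALSE, effect = 0.2, d_star = NA, max_dose = 300))
  w <- synthetic_world(countries = default_countries()[1:3],
                       food_groups = c("fish", "SSB"),
                       diseases = c("CHD", "stroke"), seed = 23,
                       associations = assoc)
  sv <- gen_intake_survey(w, 300)
  ex <- fit_exposures(sv$summary)
  curves <- build_curves(w)
  dalys <- gen_daly_envelope(w, 0.1)
  curves_sig <- Filter(classify_significance, curves)

  rB <- run_scenario("B", ex, curves, dalys, n_sim = 1000, seed = 5)
  rA_restricted <- run_scenario("A", ex, curves_sig, dalys, n_sim = 1000, seed = 5)
  expect_equal(rB$total$daly_mean, rA_restricted$total$daly_mean)

  rD <- run_scenario("D", ex, curves, dalys, n_sim = 1000, seed = 5)
  rC_restricted <- run_scenario("C", ex, curves_sig, dalys, n_sim = 1000, seed = 5)
  expect_equal(rD$total$daly_mean, rC_restricted$total$daly_mean)
})

test_that("label mismatches across inputs are reported with the offending labels", {
  w <- small_world(seed = 19, n_countries = 3, foods = c("fish", "SSB"))
  sv <- gen_intake_survey(w, 200)
  ex <- fit_exposures(sv$summary)
  curves <- build_curves(w)
  dalys <- gen_daly_envelope(w, 0.1)
  dalys_bad <- dalys[dalys$country != "Belgium", ]
  expect_error(run_scenario("A", ex, curves, dalys_bad, n_sim = 1000), "Belgium")
  ex_bad <- ex[ex$food != "fish", ]
  expect_error(run_scenario("A", ex_bad, curves, dalys, n_sim = 1000), "fish")
})

test_that("dropping a country removes exactly its contribution", {
  w <- small_world(seed = 29, n_countries = 3, foods = c("fish", "SSB"))
  sv <- gen_intake_survey(w, 200)
  ex <- fit_exposures(sv$summary)
  curves <- build_curves(w)
  dalys <- gen_daly_envelope(w, 0.1)
  # TMRELs held fixed: the P97.5-mean rule couples countries, so the
  # counterfactual is pinned before the country subset varies
  tms <- tmrel_table(curves, ex, dalys = w$daly_means, mode = "disease_specific",
                     diseases = w$diseases)
  r_all <- run_scenario("A", ex, curves, dalys, n_sim = 1000, seed = 7, tmrels = tms)

  drop <- "Czech Republic"
  ex2 <- ex[ex$country != drop, ]
  dalys2 <- dalys[dalys$country != drop, ]
  r_sub <- run_scenario("A", ex2, curves, dalys2, n_sim = 1000, seed = 7, tmrels = tms)

  expect_setequal(unique(r_sub$results$country), setdiff(w$countries, drop))
  kept <- r_all$country_totals$country != drop
  expect_equal(r_sub$country_totals$daly_mean,
               r_all$country_totals$daly_mean[kept], tolerance = 1e-12)
  dropped <- r_all$country_totals$daly_mean[!kept]
  expect_equal(r_sub$total$daly_mean, r_all$total$daly_mean - dropped,
               tolerance = 1e-9)
})

test_that("totals decompose into country sums and proportions stay in [0, 1]", {
  run <- run_all_scenarios(small_world(seed = 31), n_participants = 300,
                           n_sim = 1000, seed = 3)
  for (r in run$results) {
    expect_equal(sum(r$country_totals$daly_mean), r$total$daly_mean,
                 tolerance = 1e-9)
    expect_true(all(r$country_totals$proportion >= 0 &
                      r$country_totals$proportion <= 1))
    expect_gte(min(r$results$paf), 0)
  }
})

test_that("ranking averages the four scenarios and breaks ties alphabetically", {
  run <- run_all_scenarios(small_world(seed = 37), n_participants = 300,
                           n_sim = 1000, seed = 11)
  rk <- rank_food_groups(run$results)
  expect_setequal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$mean_dalys) <= 1e-9))  # sorted descending
  manual <- rowMeans(as.matrix(rk[, c("A", "B", "C", "D")]))
  expect_equal(rk$mean_dalys, manual)
  expect_error(rank_food_groups(run$results[c("A", "B", "C")]), "missing scenario")

  # a food with no associations at all ranks last with zero burden
  w0 <- small_world(seed = 41, foods = c("fish", "eggs"),
                    diseases = c("CHD", "stroke"))
  run0 <- run_all_scenarios(w0, n_participants = 200, n_sim = 1000, seed = 1)
  rk0 <- rank_food_groups(run0$results)
  expect_equal(rk0$food[nrow(rk0)], "eggs")
  expect_equal(rk0$mean_dalys[nrow(rk0)], 0)
})

test_that("identical scenario results rank like a single scenario", {
  run <- run_all_scenarios(small_world(seed = 43, foods = c("fish", "SSB")),
                           n_participants = 200, n_sim = 1000, seed = 2)
  rA <- run$results$A
  clones <- lapply(c("A", "B", "C", "D"), function(lb) {
    r <- rA
    r$scenario <- lb
    r
  })
  rk <- rank_food_groups(clones)
  single_order <- rA$food_totals$food[order(-rA$food_totals$daly_mean,
                                            rA$food_totals$food)]
  expect_equal(rk$food, single_order)
})

test_that("config-driven runs validate their schema and reproduce byte-identically", {
  td <- withr::local_tempdir()
  w <- small_world(seed = 47, n_countries = 2, foods = c("fish", "SSB"))
  paths <- simulate_inputs(w, n_participants = 200, dir = td, n_sim = 1000)

  cfg <- yaml::read_yaml(paths$config)
  cfg$daly_table <- NULL
  expect_error(cra_run_config(cfg), "daly_table")
  cfg2 <- yaml::read_yaml(paths$config)
  cfg2$scenarios <- c("A", "Z")
  expect_error(cra_run_config(cfg2), "scenarios")

  out1 <- cra_run_config(paths$config)
  csv1 <- lapply(out1$paths[grep("scenario|ranking|exposures", names(out1$paths))],
                 readLines)
  out_dir2 <- file.path(td, "rerun")
  cfg3 <- yaml::read_yaml(paths$config)
  cfg3$out_dir <- out_dir2
  out2 <- cra_run_config(cfg3)
  csv2 <- lapply(out2$paths[grep("scenario|ranking|exposures", names(out2$paths))],
                 readLines)
  expect_identical(unname(csv1), unname(csv2))
  expect_true(file.exists(out1$paths[["log"]]))
})
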
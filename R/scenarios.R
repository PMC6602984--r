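# Scenario orchestration: the 2x2 design crossing TMREL mode
# (disease-specific vs single) with the association filter (all vs
# significant-only), country/food aggregation, and the cross-scenario
# health-impact ranking.

#' Scenario specification
#'
#' The four canonical scenarios:
#' A = disease-specific TMREL / all associations,
#' B = disease-specific TMREL / significant associations only,
#' C = single TMREL / all associations,
#' D = single TMREL / significant associations only.
#'
#' @param label one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return object of class `scenario_spec` with fields `label`,
#'   `tmrel_mode`, `association_filter`.
#' @export
scenario_spec <- function(label) {
  map <- list(
    A = c(tmrel_mode = "disease_specific", association_filter = "all"),
    B = c(tmrel_mode = "disease_specific", association_filter = "significant_only"),
    C = c(tmrel_mode = "single", association_filter = "all"),
    D = c(tmrel_mode = "single", association_filter = "significant_only"))
  if (!label %in% names(map)) {
    stop("scenario label must be one of A, B, C, D", call. = FALSE)
  }
  structure(list(label = label,
                 tmrel_mode = unname(map[[label]]["tmrel_mode"]),
                 association_filter = unname(map[[label]]["association_filter"])),
            class = "scenario_spec")
}

# Check that the input groups cover consistent label sets.
check_labels <- function(exposures, curves, envelopes) {
  ec <- sort(unique(exposures$country))
  vc <- sort(unique(envelopes$country))
  if (!setequal(ec, vc)) {
    bad <- union(setdiff(ec, vc), setdiff(vc, ec))
    stop("country labels differ between exposures and DALY table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- unique(vapply(curves, function(x) x$food, character(1)))
  ef <- unique(exposures$food)
  if (length(setdiff(cf, ef))) {
    stop("curve food labels missing from exposures: ",
         paste(setdiff(cf, ef), collapse = ", "), call. = FALSE)
  }
  cd <- unique(vapply(curves, function(x) x$disease, character(1)))
  vd <- unique(envelopes$disease)
  if (length(setdiff(cd, vd))) {
    stop("curve disease labels missing from DALY table: ",
         paste(setdiff(cd, vd), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

summarise_draws <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  c(mean = mean(x), lo = min(q), hi = max(q))
}

#' Run one analysis scenario
#'
#' Computes, for every country x disease cell, the per-food PAFs under
#' the scenario's TMREL mode and association filter, combines them
#' multiplicatively, attributes national DALYs by Monte Carlo simulation,
#' and aggregates to per-food, per-country and grand totals. Under the
#' `significant_only` filter, pairs whose CI band never excludes 1
#' contribute a PAF of 0. All randomness is confined to per-cell
#' substreams derived deterministically from `seed`.
#'
#' @param spec a `scenario_spec` (or a label passed to [scenario_spec()]).
#' @param exposures fitted gamma parameters: data frame `country`, `food`,
#'   `shape`, `scale` (from [fit_exposures()]).
#' @param curves named list of `dose_response_curve` objects.
#' @param envelopes DALY table: data frame `country`, `disease`, `mean`,
#'   `ui_lo`, `ui_hi`.
#' @param n_sim Monte Carlo simulations per cell.
#' @param seed integer seed.
#' @param tmrels optional precomputed TMREL table (as from
#'   [tmrel_table()]); computed from the inputs when `NULL`.
#' @return object of class `attribution_result`: `results` (long data
#'   frame per country x disease x food, plus `"combined"` rows),
#'   `country_totals`, `food_totals`, `total` (grand total with
#'   uncertainty interval and proportion of total DALYs), and `tmrels`.
#' @export
run_scenario <- function(spec, exposures, curves, envelopes,
                         n_sim = 1e5, seed = 1L, tmrels = NULL) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  check_labels(exposures, curves, envelopes)

  countries <- unique(exposures$country)
  foods <- unique(exposures$food)
  diseases <- unique(envelopes$disease)
  daly_means <- envelopes[, c("country", "disease", "mean")]
  include_ns <- spec$association_filter == "all"

  if (is.null(tmrels)) {
    tmrels <- tmrel_table(curves, exposures, dalys = daly_means,
                          mode = spec$tmrel_mode, diseases = diseases,
                          include_nonsignificant = include_ns)
  }
  sig <- vapply(curves, classify_significance, logical(1))

  tmrel_for <- function(food, disease) {
    if (spec$tmrel_mode == "disease_specific") {
      tmrels$tmrel[tmrels$food == food & tmrels$disease == disease]
    } else {
      tmrels$tmrel[tmrels$food == food]
    }
  }

  res_rows <- list()
  country_draws <- stats::setNames(vector("list", length(countries)), countries)
  food_draws <- stats::setNames(
    lapply(foods, function(f) numeric(n_sim)), foods)
  total_draws <- numeric(n_sim)

  for (ci in seq_along(countries)) {
    ctry <- countries[ci]
    cdraws <- numeric(n_sim)
    for (di in seq_along(diseases)) {
      ds <- diseases[di]
      env_row <- envelopes[envelopes$country == ctry & envelopes$disease == ds, ]
      if (nrow(env_row) != 1L) {
        stop("DALY table must have exactly one row per country x disease (",
             ctry, ", ", ds, ")", call. = FALSE)
      }
      envelope <- fit_daly_gamma(env_row$mean, env_row$ui_lo, env_row$ui_hi,
                                 country = ctry, disease = ds)
      pafs <- numeric(length(foods))
      tm_used <- rep(NA_real_, length(foods))
      for (fi in seq_along(foods)) {
        fd <- foods[fi]
        cv <- find_curve(curves, fd, ds)
        if (is.null(cv)) next
        if (!include_ns && !sig[[pair_key(fd, ds)]]) next
        tm <- tmrel_for(fd, ds)
        if (length(tm) != 1L || is.na(tm)) next
        ep <- exposures[exposures$country == ctry & exposures$food == fd, ]
        ex <- as_gamma_exposure(ep$shape, ep$scale, ctry, fd)
        pafs[fi] <- compute_paf(ex, cv, tm)
        tm_used[fi] <- tm
      }
      paf_comb <- combine_pafs(pafs[!is.na(tm_used)])
      draws <- daly_draws(envelope, n_sim,
                          seed = substream_seed(seed, label_hash(ctry), label_hash(ds)))

      for (fi in seq_along(foods)) {
        s <- summarise_draws(pafs[fi] * draws)
        res_rows[[length(res_rows) + 1L]] <- data.frame(
          scenario = spec$label, country = ctry, disease = ds,
          food = foods[fi], paf = pafs[fi], tmrel_used = tm_used[fi],
          daly_mean = s["mean"], daly_lo = s["lo"], daly_hi = s["hi"],
          stringsAsFactors = FALSE, row.names = NULL)
        food_draws[[foods[fi]]] <- food_draws[[foods[fi]]] + pafs[fi] * draws
      }
      s <- summarise_draws(paf_comb * draws)
      res_rows[[length(res_rows) + 1L]] <- data.frame(
        scenario = spec$label, country = ctry, disease = ds,
        food = "combined", paf = paf_comb, tmrel_used = NA_real_,
        daly_mean = s["mean"], daly_lo = s["lo"], daly_hi = s["hi"],
        stringsAsFactors = FALSE, row.names = NULL)
      cdraws <- cdraws + paf_comb * draws
    }
    country_draws[[ctry]] <- cdraws
    total_draws <- total_draws + cdraws
  }

  daly_total_by_country <- vapply(countries, function(ctry) {
    sum(envelopes$mean[envelopes$country == ctry])
  }, numeric(1))
  country_totals <- do.call(rbind, lapply(seq_along(countries), function(ci) {
    s <- summarise_draws(country_draws[[countries[ci]]])
    data.frame(scenario = spec$label, country = countries[ci],
               daly_mean = s["mean"], daly_lo = s["lo"], daly_hi = s["hi"],
               daly_total = daly_total_by_country[ci],
               proportion = s["mean"] / daly_total_by_country[ci],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  food_totals <- do.call(rbind, lapply(foods, function(fd) {
    s <- summarise_draws(food_draws[[fd]])
    data.frame(scenario = spec$label, food = fd,
               daly_mean = s["mean"], daly_lo = s["lo"], daly_hi = s["hi"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  st <- summarise_draws(total_draws)
  total <- list(daly_mean = unname(st["mean"]), daly_lo = unname(st["lo"]),
                daly_hi = unname(st["hi"]),
                daly_total = sum(envelopes$mean),
                proportion = unname(st["mean"]) / sum(envelopes$mean))

  structure(list(scenario = spec$label, spec = spec,
                 results = do.call(rbind, res_rows),
                 country_totals = country_totals, food_totals = food_totals,
                 total = total, tmrels = tmrels,
                 n_sim = n_sim, seed = as.integer(seed)),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("Scenario %s: attributable DALYs %s (95%% UI %s-%s), %.0f%% of total\n",
              x$scenario, format(round(x$total$daly_mean), big.mark = ","),
              format(round(x$total$daly_lo), big.mark = ","),
              format(round(x$total$daly_hi), big.mark = ","),
              100 * x$total$proportion))
  invisible(x)
}

#' Rank food groups by health impact across the four scenarios
#'
#' Averages each food group's attributable DALYs (absolute and as a
#' proportion of total DALYs) over the four canonical scenarios and ranks
#' the groups by the mean absolute burden, descending; ties break
#' alphabetically.
#'
#' @param results list of the four `attribution_result` objects (any
#'   order; labels A, B, C, D must each occur exactly once).
#' @return data frame with one row per food: per-scenario attributable
#'   means, `mean_dalys`, `mean_proportion`, `rank`.
#' @export
rank_food_groups <- function(results) {
  labels <- vapply(results, function(r) r$scenario, character(1))
  need <- c("A", "B", "C", "D")
  if (!setequal(labels, need) || length(labels) != 4L) {
    stop("missing scenario: need exactly the four scenarios A, B, C, D; got ",
         paste(sort(labels), collapse = ", "), call. = FALSE)
  }
  results <- results[match(need, labels)]
  foods <- results[[1]]$food_totals$food
  per_scenario <- sapply(results, function(r) {
    r$food_totals$daly_mean[match(foods, r$food_totals$food)]
  })
  colnames(per_scenario) <- need
  proportions <- sapply(results, function(r) {
    r$food_totals$daly_mean[match(foods, r$food_totals$food)] / r$total$daly_total
  })
  out <- data.frame(food = foods, per_scenario,
                    mean_dalys = rowMeans(per_scenario),
                    mean_proportion = rowMeans(proportions),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$mean_dalys, out$food), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full comparative risk assessment
#'
#' Fits gamma exposures to the intake table, then runs the requested
#' scenarios and (when all four are present) the cross-scenario food
#' ranking.
#'
#' @param intake intake summary table (see [read_intake_csv()]).
#' @param curves named list of `dose_response_curve` objects.
#' @param dalys DALY table (see [read_daly_csv()]).
#' @param n_sim Monte Carlo simulations per country-disease cell.
#' @param seed integer seed.
#' @param scenarios subset of `c("A", "B", "C", "D")`.
#' @return object of class `cra_result`: `exposures`, `scenarios` (named
#'   list of `attribution_result`), `ranking` (or `NULL`).
#' @export
run_cra <- function(intake, curves, dalys, n_sim = 1e5, seed = 1L,
                    scenarios = c("A", "B", "C", "D")) {
  exposures <- fit_exposures(intake)
  res <- lapply(scenarios, function(lb) {
    run_scenario(scenario_spec(lb), exposures, curves, dalys,
                 n_sim = n_sim, seed = seed)
  })
  names(res) <- scenarios
  ranking <- if (setequal(scenarios, c("A", "B", "C", "D"))) {
    rank_food_groups(res)
  } else NULL
  structure(list(exposures = exposures, scenarios = res, ranking = ranking,
                 n_sim = n_sim, seed = as.integer(seed)),
            class = "cra_result")
}

#' @export
print.cra_result <- function(x, ...) {
  cat("Comparative risk assessment result\n")
  for (r in x$scenarios) print(r)
  if (!is.null(x$ranking)) {
    cat("Top-ranked food group:", x$ranking$food[1],
        sprintf("(%.1f%% of total DALYs)\n", 100 * x$ranking$mean_proportion[1]))
  }
  invisible(x)
}
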
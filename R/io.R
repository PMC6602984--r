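# CSV dialects for the three pipeline inputs and the results.

#' Read an intake summary table
#'
#' Expects columns `country`, `food`, `n`, `mean`, and percentile columns
#' named `p<q>` (e.g. `p2.5`, `p50`, `p97.5`), one row per country x food.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_intake_csv <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("country", "food")
  if (!all(need %in% names(x))) {
    stop("intake table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  intake_percentile_cols(x)  # validates presence of percentile columns
  x
}

#' Read dose-response curves from CSV
#'
#' Expects long format with columns `food`, `disease`, `dose`, `rr`,
#' `rr_lo`, `rr_hi`, one block of rows per food-disease pair, doses
#' increasing within each block. The maximum observed dose of each curve
#' is the last grid dose.
#'
#' @param path CSV file path.
#' @return named list of `dose_response_curve` objects keyed
#'   `"food|disease"`.
#' @export
read_rr_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("food", "disease", "dose", "rr", "rr_lo", "rr_hi")
  if (!all(need %in% names(x))) {
    stop("RR table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  curves <- list()
  for (g in split(x, paste(x$food, x$disease, sep = "|"))) {
    g <- g[order(g$dose), ]
    curves[[pair_key(g$food[1], g$disease[1])]] <-
      dose_response_curve(g$food[1], g$disease[1], g$dose, g$rr,
                          rr_lo = g$rr_lo, rr_hi = g$rr_hi)
  }
  curves
}

#' Write dose-response curves to CSV
#'
#' @param curves list of `dose_response_curve` objects.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(food = cv$food, disease = cv$disease, dose = cv$doses,
               rr = cv$rr,
               rr_lo = if (is.null(cv$rr_lo)) NA_real_ else cv$rr_lo,
               rr_hi = if (is.null(cv$rr_hi)) NA_real_ else cv$rr_hi,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a DALY envelope table
#'
#' Expects columns `country`, `disease`, `mean`, `ui_lo`, `ui_hi`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_daly_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "disease", "mean", "ui_lo", "ui_hi")
  if (!all(need %in% names(x))) {
    stop("DALY table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x
}
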
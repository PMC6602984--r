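# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded draws inside the
#' package never perturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic substream seed for a (i, j) cell, kept inside 32-bit range.
substream_seed <- function(seed, i, j = 0L) {
  s <- (as.double(seed) * 48271 + as.double(i) * 100003 + as.double(j) * 7919) %% 2147483629
  as.integer(s) + 1L
}

# Stable small-integer hash of a label, so per-cell RNG substreams are keyed
# by (country, disease/food) *names*: dropping a label from the input leaves
# every other cell's draws unchanged.
label_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 1000003
  as.integer(h)
}

# Key used for list lookups over (food, disease) pairs.
pair_key <- function(food, disease) paste(food, disease, sep = "|")

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
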
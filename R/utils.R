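#' Trial timepoint vocabulary
#'
#' The closed set of visit labels used throughout the package: `"W-2"` and
#' `"D0"` before the intervention, `"W2"` through `"W24"` after it, and the
#' pseudo-timepoint `"donor"` for donor samples. Unknown labels are rejected
#' at load time rather than passed through.
#'
#' @return Character vector of valid timepoint labels.
#' @export
trial_timepoints <- function() TIMEPOINTS

# Convert a timepoint label to its week number (D0 -> 0, W-2 -> -2, donor -> NA)
timepoint_week <- function(tp) {
  dplyr::case_match(
    tp,
    "W-2" ~ -2, "D0" ~ 0, "W2" ~ 2, "W6" ~ 6, "W10" ~ 10,
    "W14" ~ 14, "W18" ~ 18, "W24" ~ 24,
    .default = NA_real_
  )
}

assert_count_vector <- function(x, arg = "sample_counts") {
  if (!is.numeric(x) || length(x) == 0) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", arg))
  }
  if (anyNA(x) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative and free of NA.", arg))
  }
  if (sum(x) <= 0) {
    abort(sprintf("`%s` is all zero: diversity is undefined for an empty sample.", arg))
  }
  invisible(x)
}

# seeded evaluation that does not disturb the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
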
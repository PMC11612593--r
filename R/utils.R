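# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state so
#' that library internals never perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a participant sub-seed from a cohort seed
#'
#' Stable integer mixing so that participant `i` of a cohort always receives
#' the same stream, and adding participants never re-randomizes earlier ones.
#' The result is kept strictly below 2^31.
#'
#' @param seed cohort-level integer seed.
#' @param i participant index (0-based offsets allowed).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
mix_seed <- function(seed, i) {
  # multiplicative-congruential mixing; constants are odd primes
  as.integer((as.double(seed %% 1000003L) * 48271 + as.double(i) * 16807 + 11) %%
    2147483647)
}

# Stop with a message naming the offending field; used by config validators.
fail_field <- function(field, why) {
  stop(sprintf("invalid configuration field '%s': %s", field, why), call. = FALSE)
}

# Canonical group orders per granularity; later groups come later in these
# vectors, which fixes the sign convention of pairwise differences.
canonical_groups <- function(granularity, k = NULL) {
  switch(granularity,
    hour_of_day = 0:23,
    day_of_week = 0:6,
    month_of_year = 1:12,
    cluster = {
      if (is.null(k)) stop("cluster granularity needs k", call. = FALSE)
      seq_len(k)
    },
    weekday_weekend = c("weekday", "weekend"),
    winter_summer = c("winter", "summer"),
    year1_year2 = c("year1", "year2"),
    stop(sprintf("unknown granularity '%s'", granularity), call. = FALSE)
  )
}

aid_variables <- function() c("iob", "cob", "ig")

# mg/dL per mmol/L for glucose
MGDL_PER_MMOL <- 18.016
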
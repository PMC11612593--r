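# Shared fixtures: all synthetic, built in code at test time.

# Small, fast configuration for structural tests.
tiny_config <- function(...) {
  args <- list(...)
  base <- list(n_participants = 1, days = 35, readings_per_hour = 6,
    missing_hour_prob = 0, seed = 42)
  base[names(args)] <- args
  do.call(sim_config, base)
}

# A pure-noise configuration under which hour-of-day groups are exchangeable:
# no meals, no basal, no circadian component — only IG sensor noise. Used for
# null-calibration experiments where any detected hourly pattern is a type-1
# error.
null_config <- function(days = 60, seed = 1, ...) {
  sim_config(n_participants = 1, days = days, readings_per_hour = 6,
    meal_rate = 0, basal_rate = 0, circadian_amplitude = 0,
    missing_hour_prob = 0, noise_sd = c(iob = 0, cob = 0, ig = 0.6),
    seed = seed, ...)
}

# Build an hourly_grid directly from per-hour values (one reading per hour),
# bypassing the simulator; `days` full days starting at a Monday.
grid_from_values <- function(iob, cob, ig, start = "2021-01-04",
                             pid = "TEST") {
  n <- length(ig)
  ts <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 3600 + 1800
  s <- data.frame(participant_id = pid, timestamp = ts,
    iob = iob, cob = cob, ig = ig, stringsAsFactors = FALSE)
  class(s) <- c("participant_series", "data.frame")
  resample_hourly(s)
}

# O(n^2) pair-counting oracle for Kendall tau-b with tie correction.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- (x[i] - x[j]) * (y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tiex <- sum(sapply(split(seq_along(x), x), function(ii) {
    length(ii) * (length(ii) - 1) / 2
  }))
  tiey <- sum(sapply(split(seq_along(y), y), function(ii) {
    length(ii) * (length(ii) - 1) / 2
  }))
  (conc - disc) / sqrt((n0 - tiex) * (n0 - tiey))
}

# Brute-force matrix profile oracle: explicit per-pair z-normalization and
# Euclidean distance, population-sd scaling, double loop.
matrix_profile_oracle <- function(x, m, exclusion = ceiling(m / 2),
                                  eps = 1e-8) {
  nw <- length(x) - m + 1
  znorm <- function(w) {
    s <- sqrt(mean((w - mean(w))^2))
    (w - mean(w)) / max(s, eps)
  }
  Z <- t(vapply(seq_len(nw), function(i) znorm(x[i:(i + m - 1)]),
    numeric(m)))
  profile <- numeric(nw); index <- integer(nw)
  for (i in seq_len(nw)) {
    best <- Inf; bi <- NA_integer_
    for (j in seq_len(nw)) {
      if (abs(i - j) <= exclusion) next
      d <- sqrt(sum((Z[i, ] - Z[j, ])^2))
      if (d < best) { best <- d; bi <- j }
    }
    profile[i] <- best; index[i] <- bi
  }
  list(profile = profile, profile_index = index)
}

# One synthetic participant with planted effects at standardized size d:
# IOB+COB shifts at hours 14-16 (truth E1) and an IG shift at hours 3-5
# (truth U2). Meals are allowed at all hours so that, absent plants, the
# hour-of-day groups of every variable are exchangeable.
recovery_config <- function(days = 90, d = 2, seed = 1) {
  base <- sim_config(n_participants = 1, days = days, readings_per_hour = 6,
    meal_rate = 3, meal_hours = 0:23, circadian_amplitude = 0,
    missing_hour_prob = 0, seed = seed)
  shifts <- c(iob = shift_for_effect_size(base, "iob", d),
              cob = shift_for_effect_size(base, "cob", d),
              ig = shift_for_effect_size(base, "ig", d))
  base$planted_effects <- list(
    planted_effect("iob", "hour_of_day", 14:16, shifts[["iob"]], "E1"),
    planted_effect("cob", "hour_of_day", 14:16, shifts[["cob"]], NA),
    planted_effect("ig", "hour_of_day", 3:5, shifts[["ig"]], "U2"))
  base
}

# Grid whose days alternate among `k` planted diurnal archetypes. Archetype
# separation is `sep` IG units against within-archetype noise sd 1 (on the
# hourly scale), so sep = 4 means 4x the noise sd.
archetype_grid <- function(n_days, k, sep = 4, seed = 1) {
  set.seed(seed)
  arch <- lapply(seq_len(k), function(j) {
    list(ig = 6 + sep * sin(2 * pi * (0:23) / 24 + j),
         iob = 1 + 0.5 * j + sep * 0.2 * cos(2 * pi * (0:23) / 24 + j),
         cob = 10 + 2 * j)
  })
  lab <- rep_len(seq_len(k), n_days)
  mk <- function(v, noise) {
    unlist(lapply(lab, function(j) arch[[j]][[v]] + rnorm(24, 0, noise)))
  }
  g <- grid_from_values(iob = mk("iob", 0.2), cob = mk("cob", 0.5),
    ig = mk("ig", 1))
  list(grid = g, truth = lab)
}

# Did the pattern instances recover a planted truth code at its slots?
recovered_code <- function(instances, code, slots) {
  hit <- instances$code == code &
    (instances$group_a %in% as.character(slots) |
     instances$group_b %in% as.character(slots))
  any(hit)
}
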
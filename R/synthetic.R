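# Synthetic AID cohort generator.
#
# Emulates the statistical structure of automated-insulin-delivery device
# logs: irregular sub-hourly sampling, meal-driven carbohydrates-on-board
# (COB) pulses, bolus plus basal insulin-on-board (IOB) kinetics, a circadian
# interstitial-glucose (IG) baseline with meal excursions, hourly coverage
# gaps, and plantable effects whose ground-truth taxonomy code is recorded so
# downstream detection can be validated by recovery.

#' Describe a planted effect
#'
#' A planted effect adds a constant `shift` to one variable whenever the local
#' time falls into the given slots of a temporal granularity. Effects carry an
#' optional ground-truth taxonomy code (`"E1"`..`"E3"`, `"U1"`, `"U2"`) used
#' by recovery tests; the generator itself only applies the shift.
#'
#' @param variable one of `"iob"`, `"cob"`, `"ig"`.
#' @param granularity one of `"hour_of_day"`, `"day_of_week"`,
#'   `"month_of_year"`.
#' @param slots integer slots: hours 0-23, weekdays 0-6 (Monday = 0), or
#'   months 1-12.
#' @param shift signed shift in the variable's units (units of insulin, grams,
#'   or mmol/L).
#' @param taxonomy_truth optional intended pattern code, or `NA`.
#' @return A `planted_effect` list.
#' @export
#' @examples
#' planted_effect("ig", "hour_of_day", 3:5, shift = 3, taxonomy_truth = "U2")
planted_effect <- function(variable, granularity, slots, shift,
                           taxonomy_truth = NA_character_) {
  variable <- match.arg(variable, aid_variables())
  granularity <- match.arg(granularity,
    c("hour_of_day", "day_of_week", "month_of_year"))
  valid <- switch(granularity,
    hour_of_day = 0:23, day_of_week = 0:6, month_of_year = 1:12)
  slots <- as.integer(slots)
  if (length(slots) == 0 || !all(slots %in% valid)) {
    fail_field("slots", sprintf("must be a non-empty subset of %d..%d for %s",
      min(valid), max(valid), granularity))
  }
  if (!is.numeric(shift) || length(shift) != 1 || !is.finite(shift)) {
    fail_field("shift", "must be a single finite number")
  }
  structure(
    list(variable = variable, granularity = granularity, slots = slots,
         shift = shift, taxonomy_truth = taxonomy_truth),
    class = "planted_effect")
}

#' Simulation configuration for a synthetic AID cohort
#'
#' All time quantities are in hours unless stated otherwise. IOB and COB are
#' controller-computed quantities and carry no sensor noise by default; IG is
#' measured by a CGM sensor and receives hour-level noise (`noise_sd["ig"]`)
#' shared by all readings within an hour, plus smaller within-hour jitter
#' (`jitter_frac * noise_sd`). Hour-level noise makes the standard deviation
#' of hourly means approximately `noise_sd`, so a planted shift of
#' `k * noise_sd` corresponds to a standardized effect size of about `k`.
#'
#' @param n_participants number of participants.
#' @param days days of data per participant: a single count or a length-2
#'   range sampled uniformly per participant.
#' @param readings_per_hour mean sub-hourly sampling rate (readings arrive as
#'   a Poisson process).
#' @param meal_rate mean meals per day (Poisson).
#' @param meal_hours integer hours of day during which meals may start.
#' @param carb_mean_g,carb_sd_g meal carbohydrate size distribution (grams,
#'   truncated below at 5 g).
#' @param carb_ratio insulin-to-carbohydrate ratio (grams per unit); each meal
#'   triggers a bolus of `carbs / carb_ratio` units.
#' @param basal_rate continuous basal insulin delivery (units/hour).
#' @param iob_half_life_h half-life of insulin-on-board decay (hours).
#' @param cob_absorption_h linear carbohydrate absorption window (hours).
#' @param ig_baseline mean interstitial glucose (mmol/L).
#' @param circadian_amplitude amplitude of the sinusoidal circadian IG
#'   component (mmol/L); 0 removes it.
#' @param circadian_peak_h hour of day at which the circadian component peaks.
#' @param ig_meal_gain peak IG excursion per gram of carbohydrate
#'   (mmol/L per g); the excursion rises linearly for 1 h and decays over 2 h.
#' @param noise_sd named numeric vector of per-variable noise standard
#'   deviations (hour-level), names `iob`, `cob`, `ig`.
#' @param jitter_frac within-hour reading jitter, as a fraction of `noise_sd`.
#' @param missing_hour_prob probability that all readings of a wall-clock hour
#'   are dropped.
#' @param planted_effects list of [planted_effect()] objects.
#' @param demog_missing named list of per-field missingness probabilities for
#'   the demographics table.
#' @param start_date first calendar day of every participant's record
#'   (ISO date string or `Date`).
#' @param seed integer seed; the full cohort is a pure function of the
#'   configuration.
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, days = 10, seed = 1)
sim_config <- function(n_participants = 20,
                       days = c(30, 180),
                       readings_per_hour = 12,
                       meal_rate = 3,
                       meal_hours = 6:21,
                       carb_mean_g = 50,
                       carb_sd_g = 20,
                       carb_ratio = 10,
                       basal_rate = 0.8,
                       iob_half_life_h = 2,
                       cob_absorption_h = 3,
                       ig_baseline = 6.5,
                       circadian_amplitude = 0.5,
                       circadian_peak_h = 7,
                       ig_meal_gain = 0.03,
                       noise_sd = c(iob = 0, cob = 0, ig = 0.6),
                       jitter_frac = 0.5,
                       missing_hour_prob = 0.02,
                       planted_effects = list(),
                       demog_missing = list(sex = 0.9, default = 0.15),
                       start_date = "2021-01-04",
                       seed = 1L) {
  cfg <- structure(
    list(n_participants = n_participants, days = days,
         readings_per_hour = readings_per_hour, meal_rate = meal_rate,
         meal_hours = as.integer(meal_hours), carb_mean_g = carb_mean_g,
         carb_sd_g = carb_sd_g, carb_ratio = carb_ratio,
         basal_rate = basal_rate, iob_half_life_h = iob_half_life_h,
         cob_absorption_h = cob_absorption_h, ig_baseline = ig_baseline,
         circadian_amplitude = circadian_amplitude,
         circadian_peak_h = circadian_peak_h, ig_meal_gain = ig_meal_gain,
         noise_sd = noise_sd, jitter_frac = jitter_frac,
         missing_hour_prob = missing_hour_prob,
         planted_effects = planted_effects, demog_missing = demog_missing,
         start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos_scalar <- function(field, allow_zero = TRUE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v < 0 || (!allow_zero && v <= 0)) {
      fail_field(field, if (allow_zero) "must be a single finite number >= 0"
                 else "must be a single finite number > 0")
    }
  }
  if (!is.numeric(cfg$n_participants) || length(cfg$n_participants) != 1 ||
      cfg$n_participants < 1 || cfg$n_participants != round(cfg$n_participants)) {
    fail_field("n_participants", "must be a positive integer")
  }
  if (!is.numeric(cfg$days) || !length(cfg$days) %in% c(1, 2) ||
      any(cfg$days < 1)) {
    fail_field("days", "must be a positive count or a length-2 range")
  }
  if (length(cfg$days) == 2 && cfg$days[1] > cfg$days[2]) {
    fail_field("days", "range must be increasing")
  }
  for (f in c("readings_per_hour", "meal_rate", "carb_mean_g", "carb_sd_g",
              "basal_rate", "circadian_amplitude", "ig_meal_gain")) {
    pos_scalar(f)
  }
  for (f in c("carb_ratio", "iob_half_life_h", "cob_absorption_h",
              "ig_baseline")) {
    pos_scalar(f, allow_zero = FALSE)
  }
  if (!is.numeric(cfg$missing_hour_prob) || length(cfg$missing_hour_prob) != 1 ||
      cfg$missing_hour_prob < 0 || cfg$missing_hour_prob > 1) {
    fail_field("missing_hour_prob", "must be a probability in [0, 1]")
  }
  if (!all(aid_variables() %in% names(cfg$noise_sd)) ||
      any(!is.finite(cfg$noise_sd)) || any(cfg$noise_sd < 0)) {
    fail_field("noise_sd", "must be a named vector with iob, cob, ig >= 0")
  }
  if (length(cfg$meal_hours) == 0 || !all(cfg$meal_hours %in% 0:23)) {
    fail_field("meal_hours", "must be a non-empty subset of 0..23")
  }
  ok <- vapply(cfg$planted_effects, inherits, logical(1), "planted_effect")
  if (length(ok) && !all(ok)) {
    fail_field("planted_effects", "must be a list of planted_effect objects")
  }
  invisible(cfg)
}

# Per-day lookup vectors used to evaluate planted-effect slots and, later,
# calendar groupings. Monday = 0 matches the canonical weekday order.
day_calendar <- function(start_date, n_days) {
  dates <- start_date + seq_len(n_days) - 1L
  list(dates = dates,
       dow = (as.integer(format(dates, "%u")) - 1L),
       month = as.integer(format(dates, "%m")))
}

#' Simulate one participant's device record and demographics
#'
#' Readings arrive as a Poisson process at `readings_per_hour`. Meals arrive
#' as a Poisson process at `meal_rate` per day, restricted to `meal_hours`;
#' each meal adds a COB pulse absorbed linearly over `cob_absorption_h` hours,
#' a bolus of `carbs / carb_ratio` units decaying exponentially with half-life
#' `iob_half_life_h`, and an IG excursion proportional to its carbohydrates.
#' Basal insulin accumulates continuously toward its steady state under the
#' same exponential decay. Planted effects shift their variable inside their
#' slots; whole hours are dropped with probability `missing_hour_prob`.
#'
#' Identical `(config, participant_index)` always yields identical output.
#'
#' @param config a [sim_config()].
#' @param participant_index 1-based participant index within the cohort.
#' @return A list with elements `series` (a `participant_series` data frame
#'   with columns `participant_id`, `timestamp`, `iob`, `cob`, `ig`) and
#'   `demographics` (a one-row data frame).
#' @export
simulate_participant <- function(config, participant_index = 1L) {
  validate_sim_config(config)
  with_seed(mix_seed(config$seed, participant_index), {
    n_days <- if (length(config$days) == 2) {
      sample(seq(config$days[1], config$days[2]), 1)
    } else {
      as.integer(config$days)
    }
    horizon <- 24 * n_days # hours
    cal <- day_calendar(config$start_date, n_days)

    # irregular reading times (hours since local midnight of start_date)
    n_read <- stats::rpois(1, horizon * config$readings_per_hour)
    t <- sort(stats::runif(n_read, 0, horizon))

    # meal process
    n_meal <- stats::rpois(1, n_days * config$meal_rate)
    meal_day <- sample.int(n_days, n_meal, replace = TRUE) - 1L
    meal_hour <- sample(config$meal_hours, n_meal, replace = TRUE) +
      stats::runif(n_meal)
    tm <- sort(meal_day * 24 + meal_hour)
    carbs <- pmax(stats::rnorm(n_meal, config$carb_mean_g, config$carb_sd_g), 5)

    lambda <- log(2) / config$iob_half_life_h
    Wc <- config$cob_absorption_h

    cob <- numeric(n_read)
    iob <- config$basal_rate / lambda * (1 - exp(-lambda * t))
    ig <- config$ig_baseline + config$circadian_amplitude *
      cos(2 * pi * ((t %% 24) - config$circadian_peak_h) / 24)

    # per-meal contributions; each meal touches a short run of sorted readings
    iob_tail <- 8 * config$iob_half_life_h # decay below 0.4% afterwards
    for (k in seq_len(n_meal)) {
      u0 <- tm[k]
      # COB: linear absorption over [u0, u0 + Wc)
      i1 <- findInterval(u0, t) + 1L
      i2 <- findInterval(u0 + Wc, t)
      if (i2 >= i1) {
        idx <- i1:i2
        cob[idx] <- cob[idx] + carbs[k] * (1 - (t[idx] - u0) / Wc)
      }
      # IOB bolus: exponential decay, truncated once negligible
      i2 <- findInterval(u0 + iob_tail, t)
      if (i2 >= i1) {
        idx <- i1:i2
        iob[idx] <- iob[idx] + carbs[k] / config$carb_ratio *
          exp(-lambda * (t[idx] - u0))
      }
      # IG excursion: rise over 1 h, decay over the following 2 h
      i2 <- findInterval(u0 + 3, t)
      if (i2 >= i1) {
        idx <- i1:i2
        u <- t[idx] - u0
        shape <- ifelse(u < 1, u, (3 - u) / 2)
        ig[idx] <- ig[idx] + config$ig_meal_gain * carbs[k] * shape
      }
    }

    # hour-level noise plus within-hour jitter
    hr <- pmin(floor(t), horizon - 1) + 1L
    vals <- list(iob = iob, cob = cob, ig = ig)
    for (v in aid_variables()) {
      sdv <- config$noise_sd[[v]]
      if (sdv > 0) {
        hn <- stats::rnorm(horizon, 0, sdv)
        vals[[v]] <- vals[[v]] + hn[hr] +
          stats::rnorm(n_read, 0, sdv * config$jitter_frac)
      }
    }

    # planted effects
    day_idx <- pmin(floor(t / 24), n_days - 1) + 1L
    hod <- floor(t) %% 24
    for (eff in config$planted_effects) {
      in_slot <- switch(eff$granularity,
        hour_of_day = hod %in% eff$slots,
        day_of_week = cal$dow[day_idx] %in% eff$slots,
        month_of_year = cal$month[day_idx] %in% eff$slots)
      vals[[eff$variable]] <- vals[[eff$variable]] + eff$shift * in_slot
    }

    vals$iob <- pmax(vals$iob, 0)
    vals$cob <- pmax(vals$cob, 0)
    vals$ig <- pmax(vals$ig, 0.1)

    # drop whole hours
    keep <- rep(TRUE, n_read)
    if (config$missing_hour_prob > 0) {
      dropped <- stats::runif(horizon) < config$missing_hour_prob
      keep <- !dropped[hr]
    }

    pid <- sprintf("P%03d", participant_index)
    series <- data.frame(
      participant_id = pid,
      timestamp = as.POSIXct(as.numeric(config$start_date) * 86400 +
        t[keep] * 3600, origin = "1970-01-01", tz = "UTC"),
      iob = vals$iob[keep], cob = vals$cob[keep], ig = vals$ig[keep],
      stringsAsFactors = FALSE)
    class(series) <- c("participant_series", "data.frame")

    demographics <- simulate_demographics(pid, config)
    list(series = series, demographics = demographics)
  })
}

# Self-reported demographics with realistic marginals and configurable
# missingness; drawn inside the participant's seeded stream.
simulate_demographics <- function(pid, config) {
  age <- round(min(max(stats::rnorm(1, 40, 14), 18), 75))
  t1d_duration <- round(min(max(stats::rnorm(1, age * 0.5, 8), 1), age - 2))
  hba1c <- round(min(max(stats::rnorm(1, 46, 7), 30), 90), 1)
  avg_carbs <- round(max(stats::rnorm(1, 180, 50), 60))
  avg_insulin <- round(max(stats::rnorm(1, 45, 12), 15), 1)
  avg_basal <- round(avg_insulin * stats::runif(1, 0.35, 0.55), 1)
  pump_years <- stats::runif(1, 2, 20)
  cgm_years <- stats::runif(1, 1, pump_years)
  aid_years <- stats::runif(1, 0.5, min(cgm_years, 8))
  sex <- sample(c("female", "male"), 1)
  d <- data.frame(
    participant_id = pid, age = age, t1d_duration = t1d_duration,
    hba1c = hba1c, sex = sex, avg_carbs = avg_carbs,
    avg_insulin = avg_insulin, avg_basal = avg_basal,
    pump_since = config$start_date - round(pump_years * 365.25),
    cgm_since = config$start_date - round(cgm_years * 365.25),
    aid_since = config$start_date - round(aid_years * 365.25),
    stringsAsFactors = FALSE)
  miss_p <- function(field) {
    p <- config$demog_missing[[field]]
    if (is.null(p)) p <- config$demog_missing$default
    if (is.null(p)) p <- 0
    p
  }
  for (f in setdiff(names(d), "participant_id")) {
    if (stats::runif(1) < miss_p(f)) d[[f]] <- d[[f]][NA]
  }
  d
}

#' Simulate a full synthetic cohort
#'
#' Participants receive independent sub-seeds derived deterministically from
#' `config$seed`, so regenerating the cohort (or extending it with more
#' participants) reproduces earlier participants exactly.
#'
#' @param config a [sim_config()].
#' @return A list with `series` (list of `participant_series`) and
#'   `demographics` (one data frame for the cohort).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 2, days = 5, seed = 7))
#' names(cohort$series)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  sims <- lapply(seq_len(config$n_participants), function(i) {
    simulate_participant(config, i)
  })
  series <- lapply(sims, `[[`, "series")
  names(series) <- vapply(series, function(s) s$participant_id[1], character(1))
  demographics <- do.call(rbind, lapply(sims, `[[`, "demographics"))
  rownames(demographics) <- NULL
  list(series = series, demographics = demographics)
}

#' Estimate the planted shift needed for a target standardized effect size
#'
#' Standardized (Cohen's d) plant sizes require the variable's hourly-mean
#' standard deviation as the scale. The scale is estimated from a single
#' reference participant simulated from the same configuration with no
#' planted effects, using a seed outside the cohort's participant range, so
#' it is fixed before any detection is run.
#'
#' @param config a [sim_config()].
#' @param variable one of `"iob"`, `"cob"`, `"ig"`.
#' @param d target standardized effect size.
#' @return Shift in the variable's units.
#' @export
shift_for_effect_size <- function(config, variable, d) {
  variable <- match.arg(variable, aid_variables())
  ref_cfg <- config
  ref_cfg$planted_effects <- list()
  ref <- simulate_participant(ref_cfg, 0L)
  grid <- resample_hourly(ref$series)
  qd <- qualifying_days(grid)
  vals <- grid[[variable]][as.Date(grid$hour, tz = "UTC") %in% qd]
  d * stats::sd(vals, na.rm = TRUE)
}

#' Write a cohort to CSV files
#'
#' One device-log CSV per participant (columns `timestamp`, `iob`, `cob`,
#' `ig`; ISO-8601 timestamps; empty cells denote absent values) plus a
#' `demographics.csv`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$series, function(s) {
    path <- file.path(dir, paste0(s$participant_id[1], ".csv"))
    out <- data.frame(
      timestamp = format(s$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      iob = s$iob, cob = s$cob, ig = s$ig)
    utils::write.csv(out, path, row.names = FALSE, na = "")
    path
  }, character(1))
  dpath <- file.path(dir, "demographics.csv")
  utils::write.csv(cohort$demographics, dpath, row.names = FALSE, na = "")
  invisible(c(paths, dpath))
}

#' @export
print.participant_series <- function(x, ...) {
  cat(sprintf("<participant_series> %s: %d readings, %s to %s\n",
    x$participant_id[1], nrow(x),
    format(min(x$timestamp), "%Y-%m-%d"), format(max(x$timestamp), "%Y-%m-%d")))
  invisible(x)
}
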
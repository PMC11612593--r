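# Ingestion: device-log CSV reading, hourly resampling, eligibility filter.

#' Read a device-log CSV into a participant series
#'
#' Expects columns `timestamp,iob,cob,ig` with ISO-8601 timestamps. Rows are
#' sorted by time; duplicate timestamps are collapsed to the per-variable mean
#' of their non-missing values; empty cells become absent values. Interstitial
#' glucose may be recorded in mmol/L or mg/dL; with `ig_unit = "auto"` a
#' median above 30 is taken to indicate mg/dL and converted (divisor 18.016).
#'
#' @param path CSV file path.
#' @param participant_id identifier to attach; defaults to the file name.
#' @param ig_unit `"auto"`, `"mmol/L"` or `"mg/dL"`.
#' @return A `participant_series` data frame.
#' @export
read_device_csv <- function(path, participant_id = NULL,
                            ig_unit = c("auto", "mmol/L", "mg/dL")) {
  ig_unit <- match.arg(ig_unit)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.csv$", "", basename(path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = c("character", "numeric", "numeric", "numeric"))
  need <- c("timestamp", "iob", "cob", "ig")
  if (!all(need %in% names(raw))) {
    stop(sprintf("device CSV must have columns %s", paste(need, collapse = ", ")),
      call. = FALSE)
  }
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw$timestamp[todo], fmt, tz = "UTC"))
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable timestamp '%s' in row %d of %s",
      raw$timestamp[bad], bad, basename(path)), call. = FALSE)
  }
  for (v in c("iob", "cob")) {
    if (any(raw[[v]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative %s value in %s", v, basename(path)), call. = FALSE)
    }
  }
  ig <- raw$ig
  if (ig_unit == "mg/dL" ||
      (ig_unit == "auto" && isTRUE(stats::median(ig, na.rm = TRUE) > 30))) {
    ig <- ig / MGDL_PER_MMOL
  }
  df <- data.frame(participant_id = participant_id, timestamp = ts,
    iob = raw$iob, cob = raw$cob, ig = ig, stringsAsFactors = FALSE)
  df <- df[order(df$timestamp), , drop = FALSE]
  if (anyDuplicated(as.numeric(df$timestamp))) {
    key <- as.numeric(df$timestamp)
    agg <- function(v) {
      out <- tapply(df[[v]], key, function(z) {
        if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
      })
      as.numeric(out)
    }
    uk <- sort(unique(key))
    df <- data.frame(participant_id = participant_id,
      timestamp = as.POSIXct(uk, origin = "1970-01-01", tz = "UTC"),
      iob = agg("iob"), cob = agg("cob"), ig = agg("ig"),
      stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("participant_series", "data.frame")
  df
}

#' Resample an irregular series to an hourly grid
#'
#' For each wall-clock hour between the first and last reading, each variable
#' becomes the arithmetic mean of its readings within that hour; hours without
#' a reading for a variable are absent (`NA`) and their coverage flag is
#' `FALSE`. The hourly grid is the unit of all downstream statistics.
#'
#' @param series a `participant_series`.
#' @return An `hourly_grid` data frame with columns `hour` (POSIXct hour
#'   start), `iob`, `cob`, `ig` and logical `iob_covered`, `cob_covered`,
#'   `ig_covered`.
#' @export
resample_hourly <- function(series) {
  pid <- if (nrow(series)) series$participant_id[1] else NA_character_
  if (nrow(series) == 0) {
    g <- data.frame(hour = as.POSIXct(character(), tz = "UTC"),
      iob = numeric(), cob = numeric(), ig = numeric(),
      iob_covered = logical(), cob_covered = logical(), ig_covered = logical())
    attr(g, "participant_id") <- pid
    class(g) <- c("hourly_grid", "data.frame")
    return(g)
  }
  secs <- as.numeric(series$timestamp)
  hour_key <- floor(secs / 3600)
  hours <- seq(min(hour_key), max(hour_key))
  idx <- match(hour_key, hours)
  g <- data.frame(hour = as.POSIXct(hours * 3600, origin = "1970-01-01",
    tz = "UTC"))
  for (v in aid_variables()) {
    x <- series[[v]]
    ok <- !is.na(x)
    cnt <- tabulate(idx[ok], nbins = length(hours))
    tot <- numeric(length(hours))
    rs <- rowsum(x[ok], idx[ok]) # sorted unique group ids as rownames
    tot[as.integer(rownames(rs))] <- rs[, 1]
    covered <- cnt > 0
    g[[v]] <- ifelse(covered, tot / pmax(cnt, 1), NA_real_)
    g[[paste0(v, "_covered")]] <- covered
  }
  attr(g, "participant_id") <- pid
  class(g) <- c("hourly_grid", "data.frame")
  g
}

#' Calendar days with full three-variable coverage
#'
#' A day qualifies when all 24 of its hours have coverage for IOB, COB and IG.
#' Only qualifying days feed the downstream group statistics, avoiding biased
#' hourly means from partially observed days.
#'
#' @param grid an `hourly_grid`.
#' @return A `Date` vector of qualifying days.
#' @export
qualifying_days <- function(grid) {
  if (nrow(grid) == 0) return(as.Date(character()))
  full <- grid$iob_covered & grid$cob_covered & grid$ig_covered
  day <- as.Date(grid$hour, tz = "UTC")
  per_day <- tapply(full, day, sum)
  hours_in_day <- tapply(full, day, length)
  ok <- which(per_day == 24 & hours_in_day == 24)
  as.Date(names(per_day)[ok])
}

#' Apply the eligibility filter
#'
#' A participant is eligible when at least `min_days` (default 30) calendar
#' days have at least one recording of IOB, COB and IG in every hour.
#' Qualifying days need not be consecutive.
#'
#' @param grid an `hourly_grid`.
#' @param min_days minimum number of fully covered days.
#' @return An `eligibility_report` list with `participant_id`,
#'   `qualifying_days`, `eligible` and `reasons`.
#' @export
eligibility_filter <- function(grid, min_days = 30) {
  qd <- qualifying_days(grid)
  eligible <- length(qd) >= min_days
  reasons <- if (eligible) character() else {
    sprintf("only %d fully covered days (need %d)", length(qd), min_days)
  }
  structure(
    list(participant_id = attr(grid, "participant_id"),
         qualifying_days = length(qd), eligible = eligible, reasons = reasons),
    class = "eligibility_report")
}

#' @export
print.hourly_grid <- function(x, ...) {
  cat(sprintf("<hourly_grid> %s: %d hours, %d fully covered days\n",
    attr(x, "participant_id"), nrow(x), length(qualifying_days(x))))
  invisible(x)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("<eligibility_report> %s: %d qualifying days -> %s\n",
    x$participant_id, x$qualifying_days,
    if (x$eligible) "eligible" else paste("not eligible:", x$reasons)))
  invisible(x)
}

# Restrict a grid to rows belonging to qualifying days.
qualifying_hours <- function(grid) {
  qd <- qualifying_days(grid)
  grid[as.Date(grid$hour, tz = "UTC") %in% qd, , drop = FALSE]
}
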
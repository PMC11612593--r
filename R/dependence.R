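# Dependence analyses: Kendall tau-b associations between pattern
# frequencies and demographic/device factors, and pairwise Granger causality
# among IOB, COB and IG with a cohort consistency summary.

#' Kendall tau-b rank correlation with tie correction
#'
#' tau-b = S / sqrt((n0 - n1)(n0 - n2)) with S the concordant-minus-
#' discordant pair count and n1, n2 the tie corrections of each margin. The
#' p-value uses the normal approximation with tie-adjusted variance of S;
#' for n <= 10 without ties the exact null distribution is used instead.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list: `tau`, `p_value`, `n`.
#' @export
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)) # tau = 2/3
kendall_tau <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("tau is undefined for an all-tied sample", call. = FALSE)
  }
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  S <- sum(dx[lower.tri(dx)] * dy[lower.tri(dy)])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  if (n <= 10 && !has_ties) {
    p <- stats::cor.test(x, y, method = "kendall", exact = TRUE)$p.value
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(tau = tau, p_value = p, n = n)
}

#' Per-participant device-data factors
#'
#' Counts of distinct hours, days, months and years with full three-variable
#' coverage, plus overall mean IOB, COB and IG over qualifying days — the
#' device-derived factors entering the association scan.
#'
#' @param grids list of `hourly_grid`s.
#' @return A data frame, one row per participant.
#' @export
device_factors <- function(grids) {
  rows <- lapply(grids, function(grid) {
    full <- grid$iob_covered & grid$cob_covered & grid$ig_covered
    day <- as.Date(grid$hour, tz = "UTC")
    q <- qualifying_hours(grid)
    data.frame(
      participant_id = attr(grid, "participant_id"),
      n_hours = sum(full),
      n_days = length(unique(day[full])),
      n_months = length(unique(format(day[full], "%Y-%m"))),
      n_years = length(unique(format(day[full], "%Y"))),
      mean_iob = mean(q$iob), mean_cob = mean(q$cob), mean_ig = mean(q$ig),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Associate pattern frequencies with demographic and device factors
#'
#' One Kendall tau-b per (pattern code, granularity, factor) over pairwise-
#' complete participants. Demographic date fields (`pump_since`,
#' `cgm_since`, `aid_since`) are converted to years of use at `ref_date`.
#' Sex is excluded (categorical and almost entirely undisclosed in the data
#' this emulates). Factors with fewer than `min_n` complete pairs, or
#' all-tied margins, are skipped. The scan is exploratory, so no
#' multiplicity correction is applied by default; `p_adjust = "BH"` switches
#' on Benjamini-Hochberg within the scan.
#'
#' @param freq a `pattern_freq` from [tally_patterns()].
#' @param demographics cohort demographics data frame.
#' @param device device factors from [device_factors()] (optional).
#' @param ref_date reference date for converting device-start dates to years
#'   of use.
#' @param min_n minimum complete pairs (default 3).
#' @param p_adjust `"none"` or `"BH"`.
#' @return A data frame: `factor`, `code`, `granularity`, `tau_b`,
#'   `p_value`, `n`.
#' @export
relate_frequencies <- function(freq, demographics, device = NULL,
                               ref_date = NULL, min_n = 3,
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  fac <- demographics
  if (is.null(ref_date)) ref_date <- Sys.Date()
  for (f in c("pump_since", "cgm_since", "aid_since")) {
    if (f %in% names(fac)) {
      fac[[sub("_since", "_years", f)]] <-
        as.numeric(ref_date - as.Date(fac[[f]])) / 365.25
      fac[[f]] <- NULL
    }
  }
  fac$sex <- NULL
  if (!is.null(device)) {
    fac <- merge(fac, device, by = "participant_id", all = TRUE)
  }
  factor_names <- setdiff(names(fac), "participant_id")
  per <- freq$per_participant
  rows <- list()
  for (code in unique(per$code)) {
    for (gran in unique(per$granularity)) {
      sub <- per[per$code == code & per$granularity == gran, ]
      fr <- sub$normalized
      if (all(is.na(fr))) fr <- sub$count
      ids <- sub$participant_id
      for (fn in factor_names) {
        fv <- fac[[fn]][match(ids, fac$participant_id)]
        ok <- !is.na(fv) & !is.na(fr)
        if (sum(ok) < min_n) next
        if (length(unique(fv[ok])) == 1 || length(unique(fr[ok])) == 1) next
        kt <- kendall_tau(fr[ok], fv[ok])
        rows[[length(rows) + 1]] <- data.frame(
          factor = fn, code = code, granularity = gran, tau_b = kt$tau,
          p_value = kt$p_value, n = kt$n, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(factor = character(), code = character(),
      granularity = character(), tau_b = numeric(), p_value = numeric(),
      n = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

# Lagged design for a bivariate autoregression on the common sample
# (first max_lag rows trimmed once, so AIC is comparable across lags).
# rss_r is the restricted (own-lags-only) model's residual sum of squares.
granger_fits <- function(cause, effect, p, max_lag) {
  E <- stats::embed(cbind(effect, cause), max_lag + 1)
  y <- E[, 1]
  # embed layout: [effect_t, cause_t, effect_{t-1}, cause_{t-1}, ...]
  eff_lags <- E[, 2 * (1:p) + 1, drop = FALSE]
  cau_lags <- E[, 2 * (1:p) + 2, drop = FALSE]
  n <- length(y)
  Xu <- cbind(1, eff_lags, cau_lags)
  Xr <- cbind(1, eff_lags)
  fu <- stats::lm.fit(Xu, y)
  fr <- stats::lm.fit(Xr, y)
  rss_u <- sum(fu$residuals^2)
  rss_r <- sum(fr$residuals^2)
  list(n = n, k_u = ncol(Xu), rss_u = rss_u, rss_r = rss_r)
}

#' Pairwise Granger-causality test
#'
#' Does the history of `cause` improve prediction of `effect` beyond the
#' effect's own history? The lag order is chosen by minimum AIC of the
#' effect's own autoregression over `1..max_lag` (on the common sample
#' trimmed by `max_lag`), then the restriction "all lagged cause
#' coefficients are zero" is tested by an F test at that lag. Selecting the
#' lag from the restricted model keeps the selection independent of the
#' cause under the null, so the F test retains its nominal size; selecting
#' on the unrestricted model is a pretest on the tested coefficients and
#' inflates the type-1 error. Runs on level (undifferenced) hourly data by
#' default; `difference = TRUE` first-differences both series for users who
#' prefer a stationarity transform.
#'
#' @param cause,effect aligned numeric series without missing values, of
#'   length >= 10 * max_lag.
#' @param max_lag maximum lag in hours (default 12).
#' @param alpha significance level for the `significant` flag.
#' @param difference first-difference both series before testing.
#' @return A `granger_result` list: `lag`, `F`, `p_value`, `significant`,
#'   `n`.
#' @export
granger_test <- function(cause, effect, max_lag = 12, alpha = 0.05,
                         difference = FALSE) {
  if (anyNA(cause) || anyNA(effect) || any(!is.finite(c(cause, effect)))) {
    stop("series must be finite with no missing values", call. = FALSE)
  }
  if (length(cause) != length(effect)) {
    stop("cause and effect must be aligned (equal length)", call. = FALSE)
  }
  if (difference) {
    cause <- diff(cause); effect <- diff(effect)
  }
  if (length(effect) < 10 * max_lag) {
    stop(sprintf("series too short: need at least %d points for max_lag %d",
      10 * max_lag, max_lag), call. = FALSE)
  }
  aics <- vapply(seq_len(max_lag), function(p) {
    f <- granger_fits(cause, effect, p, max_lag)
    f$n * log(f$rss_r / f$n) + 2 * (p + 1)
  }, numeric(1))
  p_star <- which.min(aics)
  f <- granger_fits(cause, effect, p_star, max_lag)
  df2 <- f$n - f$k_u
  Fstat <- ((f$rss_r - f$rss_u) / p_star) / (f$rss_u / df2)
  pval <- stats::pf(Fstat, p_star, df2, lower.tail = FALSE)
  structure(list(lag = p_star, F = Fstat, p_value = pval,
    significant = pval < alpha, n = f$n, alpha = alpha),
    class = "granger_result")
}

#' Granger tests for all ordered variable pairs across a cohort
#'
#' For each participant and each ordered pair of IOB, COB and IG, runs
#' [granger_test()] on the longest contiguous stretch of hours in which all
#' three variables are covered. Participants whose stretch is too short for
#' `max_lag` are skipped.
#'
#' @param grids list of `hourly_grid`s.
#' @param max_lag,alpha,difference passed to [granger_test()].
#' @return A data frame: `participant_id`, `cause`, `effect`, `lag`, `F`,
#'   `p_value`, `significant`.
#' @export
cohort_granger <- function(grids, max_lag = 12, alpha = 0.05,
                           difference = FALSE) {
  rows <- list()
  for (grid in grids) {
    full <- grid$iob_covered & grid$cob_covered & grid$ig_covered
    if (!any(full)) next
    r <- rle(full); ends <- cumsum(r$lengths)
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    idx <- (ends[best] - r$lengths[best] + 1):ends[best]
    if (length(idx) < 10 * max_lag) next
    pid <- attr(grid, "participant_id")
    for (cv in aid_variables()) {
      for (ev in setdiff(aid_variables(), cv)) {
        gr <- try(granger_test(grid[[cv]][idx], grid[[ev]][idx],
          max_lag = max_lag, alpha = alpha, difference = difference),
          silent = TRUE)
        if (inherits(gr, "try-error")) next
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = pid, cause = cv, effect = ev, lag = gr$lag,
          F = gr$F, p_value = gr$p_value, significant = gr$significant,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), cause = character(),
      effect = character(), lag = integer(), F = numeric(),
      p_value = numeric(), significant = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Cross-participant consistency of Granger findings
#'
#' For each ordered variable pair, the fraction of participants with a
#' significant test. A direction is flagged inconsistent when the fraction
#' falls strictly between `lo` and `hi` — evidence in some participants but
#' not in most, the situation in which forecastability cannot be relied on.
#'
#' @param results data frame from [cohort_granger()].
#' @param lo,hi inconsistency band (default 0.2-0.8, exclusive).
#' @return A data frame: `cause`, `effect`, `n`, `fraction_significant`,
#'   `inconsistent`.
#' @export
consistency_summary <- function(results, lo = 0.2, hi = 0.8) {
  if (nrow(results) == 0) {
    return(data.frame(cause = character(), effect = character(),
      n = integer(), fraction_significant = numeric(),
      inconsistent = logical(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(significant ~ cause + effect, data = results,
    FUN = function(x) c(n = length(x), frac = mean(x)))
  out <- data.frame(cause = agg$cause, effect = agg$effect,
    n = as.integer(agg$significant[, "n"]),
    fraction_significant = agg$significant[, "frac"],
    stringsAsFactors = FALSE)
  out$inconsistent <- out$fraction_significant > lo &
    out$fraction_significant < hi
  out[order(out$cause, out$effect), ]
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf(
    "<granger_result> lag %d (AIC), F = %.3f, p = %.4g -> %s at alpha %.4g\n",
    x$lag, x$F, x$p_value,
    if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}
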
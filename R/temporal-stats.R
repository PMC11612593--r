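# Group statistics, Welch mean-difference tests under Bonferroni FWER
# control, Cohen's d, and power analysis.

#' Bonferroni-adjusted per-comparison significance level
#'
#' The comparison family at a temporal granularity is all unordered pairs of
#' its groups, so the per-comparison level is
#' `family_alpha / choose(n_groups, 2)`: 24 hourly groups give 0.05/276
#' (printed .0002), 7 weekdays 0.05/21 (.0024), 12 months 0.05/66 (.0008).
#'
#' @param n_groups number of groups at the granularity (>= 2).
#' @param family_alpha family-wise error rate to control (default 0.05).
#' @return The adjusted per-comparison alpha.
#' @export
#' @examples
#' round(bonferroni_alpha(24), 4)
bonferroni_alpha <- function(n_groups, family_alpha = 0.05) {
  if (!is.numeric(n_groups) || length(n_groups) != 1 || n_groups < 2 ||
      n_groups != round(n_groups)) {
    stop("n_groups must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(family_alpha) || family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must be in (0, 1)", call. = FALSE)
  }
  family_alpha / choose(n_groups, 2)
}

# Group label per hourly-grid row for a granularity. Cluster granularity
# needs a cluster_assignment mapping qualifying days to labels. Rows outside
# any group (e.g. spring/autumn for winter_summer) get NA.
grid_group_labels <- function(grid, granularity, assignment = NULL) {
  day <- as.Date(grid$hour, tz = "UTC")
  switch(granularity,
    hour_of_day = as.integer(format(grid$hour, "%H", tz = "UTC")),
    day_of_week = as.integer(format(day, "%u")) - 1L,
    month_of_year = as.integer(format(day, "%m")),
    weekday_weekend = ifelse(as.integer(format(day, "%u")) >= 6,
      "weekend", "weekday"),
    winter_summer = {
      m <- as.integer(format(day, "%m"))
      ifelse(m %in% c(12, 1, 2), "winter",
        ifelse(m %in% 6:8, "summer", NA_character_))
    },
    year1_year2 = {
      off <- as.numeric(day - min(day))
      ifelse(off < 365, "year1", ifelse(off < 730, "year2", NA_character_))
    },
    cluster = {
      if (is.null(assignment)) {
        stop("cluster granularity requires a cluster_assignment", call. = FALSE)
      }
      assignment$labels[match(day, assignment$dates)]
    },
    stop(sprintf("unknown granularity '%s'", granularity), call. = FALSE)
  )
}

# Hourly samples per (group, variable), qualifying days only.
granularity_samples <- function(grid, granularity, assignment = NULL) {
  q <- qualifying_hours(grid)
  lab <- grid_group_labels(q, granularity, assignment)
  keep <- !is.na(lab)
  groups <- canonical_groups(granularity,
    k = if (granularity == "cluster") assignment$k else NULL)
  out <- list()
  for (v in aid_variables()) {
    out[[v]] <- lapply(groups, function(g) q[[v]][keep & lab == g])
    names(out[[v]]) <- as.character(groups)
  }
  attr(out, "groups") <- groups
  out
}

#' Per-group summary statistics at a temporal granularity
#'
#' Means, standard deviations and Student-t confidence intervals of the
#' hourly values of each variable, grouped by hour of day, day of week,
#' month of year, weekday/weekend, winter/summer, first/second year, or
#' learned day cluster. Only fully covered (qualifying) days contribute.
#'
#' @param grid an `hourly_grid`.
#' @param granularity grouping name; see [canonical_groups()] choices
#'   `"hour_of_day"`, `"day_of_week"`, `"month_of_year"`, `"cluster"`,
#'   `"weekday_weekend"`, `"winter_summer"`, `"year1_year2"`.
#' @param assignment a `cluster_assignment`, required for `"cluster"`.
#' @param conf_level confidence level for the per-group CI (default 0.95).
#' @return A data frame with one row per (group, variable): `n`, `mean`,
#'   `sd`, `ci_low`, `ci_high` (the CI is `NA` when `n < 2`).
#' @export
group_stats <- function(grid, granularity, assignment = NULL,
                        conf_level = 0.95) {
  samples <- granularity_samples(grid, granularity, assignment)
  groups <- attr(samples, "groups")
  rows <- list()
  for (v in aid_variables()) {
    for (g in as.character(groups)) {
      x <- samples[[v]][[g]]
      n <- length(x)
      if (n == 0) next
      m <- mean(x)
      s <- if (n >= 2) stats::sd(x) else NA_real_
      half <- if (n >= 2) stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
              else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        granularity = granularity, group = g, variable = v, n = n,
        mean = m, sd = s, ci_low = m - half, ci_high = m + half,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Welch mean-difference with CI, Cohen's d and significance
#'
#' Two-sided Welch two-sample comparison of `a` minus `b`, with the
#' Welch-Satterthwaite degrees of freedom, a confidence interval at level
#' `1 - alpha_adj`, and Cohen's d using the pooled (n-1 weighted) standard
#' deviation. `significant` is `TRUE` exactly when the CI of the difference
#' excludes 0, equivalently when `p_value < alpha_adj`. When both samples
#' have zero variance and equal means, the difference is degenerate: d is 0
#' and the comparison is not significant.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param alpha_adj per-comparison significance level (e.g. a Bonferroni-
#'   adjusted alpha).
#' @return A one-row data frame: `diff`, `ci_low`, `ci_high`, `cohen_d`,
#'   `p_value`, `significant`, `n_a`, `n_b`, `df`.
#' @export
#' @examples
#' mean_diff(rnorm(30, 1), rnorm(30, 0), alpha_adj = 0.05)
mean_diff <- function(a, b, alpha_adj = 0.05) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs at least 2 values", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  d_raw <- ma - mb
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (va == 0 && vb == 0) {
    if (d_raw == 0) {
      return(data.frame(diff = 0, ci_low = 0, ci_high = 0, cohen_d = 0,
        p_value = 1, significant = FALSE, n_a = na, n_b = nb, df = NA_real_))
    }
    # perfectly separated constants: infinitely strong evidence
    return(data.frame(diff = d_raw, ci_low = d_raw, ci_high = d_raw,
      cohen_d = sign(d_raw) * Inf, p_value = 0, significant = TRUE,
      n_a = na, n_b = nb, df = NA_real_))
  }
  se <- sqrt(va / na + vb / nb)
  df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tstat <- d_raw / se
  p <- 2 * stats::pt(-abs(tstat), df)
  half <- stats::qt(1 - alpha_adj / 2, df) * se
  data.frame(diff = d_raw, ci_low = d_raw - half, ci_high = d_raw + half,
    cohen_d = d_raw / sqrt(sp2), p_value = p, significant = p < alpha_adj,
    n_a = na, n_b = nb, df = df)
}

#' All pairwise mean differences at a granularity
#'
#' Compares every unordered pair of groups, per variable, at the
#' Bonferroni-adjusted level for the granularity's nominal family (all
#' `choose(G, 2)` pairs, with G = 24 hours, 7 weekdays, 12 months, or k
#' clusters). Pairs are ordered canonically (earlier group first) and the
#' reported difference is later group minus earlier group, so a positive
#' significant difference means the later group runs higher. Pairs whose
#' groups have fewer than 2 hourly values are skipped.
#'
#' @param grid an `hourly_grid`.
#' @param granularity `"hour_of_day"`, `"day_of_week"`, `"month_of_year"` or
#'   `"cluster"`.
#' @param family_alpha family-wise error rate (default 0.05).
#' @param assignment a `cluster_assignment` for `"cluster"`.
#' @return A data frame of Welch comparisons with columns `participant_id`,
#'   `granularity`, `group_a` (earlier), `group_b` (later), `variable`,
#'   `diff`, `ci_low`, `ci_high`, `cohen_d`, `p_value`, `significant`,
#'   `alpha_adj`, `n_a`, `n_b`.
#' @export
detect_mean_diffs <- function(grid, granularity, family_alpha = 0.05,
                              assignment = NULL) {
  samples <- granularity_samples(grid, granularity, assignment)
  groups <- attr(samples, "groups")
  G <- length(groups)
  alpha_adj <- bonferroni_alpha(G, family_alpha)
  pid <- attr(grid, "participant_id")
  rows <- list()
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      ga <- as.character(groups[i]); gb <- as.character(groups[j])
      for (v in aid_variables()) {
        xa <- samples[[v]][[ga]]; xb <- samples[[v]][[gb]]
        if (length(xa) < 2 || length(xb) < 2) next
        md <- mean_diff(xb, xa, alpha_adj) # later minus earlier
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = pid, granularity = granularity,
          group_a = ga, group_b = gb, variable = v,
          diff = md$diff, ci_low = md$ci_low, ci_high = md$ci_high,
          cohen_d = md$cohen_d, p_value = md$p_value,
          significant = md$significant, alpha_adj = alpha_adj,
          n_a = md$n_b, n_b = md$n_a, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_mean_diff_table()
  class(out) <- c("mean_diff_table", "data.frame")
  out
}

empty_mean_diff_table <- function() {
  structure(
    data.frame(participant_id = character(), granularity = character(),
      group_a = character(), group_b = character(), variable = character(),
      diff = numeric(), ci_low = numeric(), ci_high = numeric(),
      cohen_d = numeric(), p_value = numeric(), significant = logical(),
      alpha_adj = numeric(), n_a = integer(), n_b = integer(),
      stringsAsFactors = FALSE),
    class = c("mean_diff_table", "data.frame"))
}

#' Power of the two-sided two-sample t test
#'
#' Evaluated under the noncentral t distribution with noncentrality
#' `d * sqrt(n_a * n_b / (n_a + n_b))` and `n_a + n_b - 2` degrees of
#' freedom. With `d = 0` the power equals `alpha`.
#'
#' @param d standardized effect size (Cohen's d).
#' @param n_a,n_b group sizes (>= 2).
#' @param alpha two-sided significance level.
#' @return Probability of rejecting the null.
#' @export
#' @examples
#' power_two_sample(1, 17, 17, 0.05)
power_two_sample <- function(d, n_a, n_b, alpha = 0.05) {
  if (n_a < 2 || n_b < 2) stop("group sizes must be >= 2", call. = FALSE)
  df <- n_a + n_b - 2
  ncp <- d * sqrt(n_a * n_b / (n_a + n_b))
  crit <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(crit, df, ncp)) + stats::pt(-crit, df, ncp)
}

#' Required per-group sample size for a target power
#'
#' Smallest integer `n` per group such that
#' `power_two_sample(d, n, n, alpha) >= target_power`.
#'
#' @param d nonzero standardized effect size.
#' @param alpha two-sided significance level.
#' @param target_power desired power in `(alpha, 1)`.
#' @return Integer sample size per group (>= 2).
#' @export
#' @examples
#' required_n(1, 0.05, 0.8) # 17 per group
required_n <- function(d, alpha = 0.05, target_power = 0.8) {
  if (d == 0) stop("d must be nonzero: power never exceeds alpha", call. = FALSE)
  if (target_power <= alpha || target_power >= 1) {
    stop("target_power must lie in (alpha, 1)", call. = FALSE)
  }
  hi <- 2L
  while (power_two_sample(d, hi, hi, alpha) < target_power) {
    hi <- hi * 2L
    if (hi > 1e7) stop("required n exceeds 1e7", call. = FALSE)
  }
  lo <- max(2L, hi %/% 2L)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (power_two_sample(d, mid, mid, alpha) >= target_power) hi <- mid
    else lo <- mid + 1L
  }
  hi
}

#' Cohort-level comparisons of overall means
#'
#' Each eligible participant contributes one overall mean per variable per
#' condition (weekday vs weekend, winter vs summer, first vs second year of
#' use, and each day-cluster); conditions are then compared across the cohort
#' with Welch tests at their configured Bonferroni-adjusted levels, together
#' with the achieved power at the observed effect size and the per-group n
#' required for 80% power. Conditions with fewer than 2 contributing
#' participants on either side are skipped.
#'
#' @param grids list of `hourly_grid`s (eligible participants).
#' @param assignments optional named list of `cluster_assignment`s keyed by
#'   participant id (enables the cluster condition).
#' @param alpha named vector of adjusted alphas per condition.
#' @param target_power power target for the required-n report.
#' @return A data frame of comparisons with power columns, or `NULL` when no
#'   condition is comparable.
#' @export
overall_comparisons <- function(grids, assignments = NULL,
                                alpha = c(weekday_weekend = 0.0018,
                                          winter_summer = 0.0063,
                                          year1_year2 = 0.0032,
                                          cluster = 0.0018),
                                target_power = 0.8) {
  conds <- intersect(names(alpha),
    c("weekday_weekend", "winter_summer", "year1_year2", "cluster"))
  rows <- list()
  for (cond in conds) {
    groups <- NULL
    per_part <- list() # per group: vector over participants, per variable
    for (grid in grids) {
      pid <- attr(grid, "participant_id")
      asg <- if (!is.null(assignments)) assignments[[pid]] else NULL
      if (cond == "cluster" && is.null(asg)) next
      samples <- granularity_samples(grid, cond, asg)
      groups <- attr(samples, "groups")
      for (v in aid_variables()) {
        for (g in as.character(groups)) {
          x <- samples[[v]][[g]]
          if (length(x) == 0) next
          key <- paste(v, g, sep = ".")
          per_part[[key]] <- c(per_part[[key]], mean(x))
        }
      }
    }
    if (is.null(groups)) next
    groups <- as.character(groups)
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        for (v in aid_variables()) {
          xa <- per_part[[paste(v, groups[i], sep = ".")]]
          xb <- per_part[[paste(v, groups[j], sep = ".")]]
          if (length(xa) < 2 || length(xb) < 2) next
          md <- mean_diff(xb, xa, alpha[[cond]])
          d_obs <- md$cohen_d
          pw <- if (is.finite(d_obs)) {
            power_two_sample(d_obs, length(xa), length(xb), alpha[[cond]])
          } else 1
          rn <- if (is.finite(d_obs) && d_obs != 0) {
            required_n(d_obs, alpha[[cond]], target_power)
          } else NA_integer_
          rows[[length(rows) + 1]] <- data.frame(
            condition = cond, group_a = groups[i], group_b = groups[j],
            variable = v, diff = md$diff, ci_low = md$ci_low,
            ci_high = md$ci_high, cohen_d = d_obs, p_value = md$p_value,
            significant = md$significant, alpha_adj = alpha[[cond]],
            n_a = length(xa), n_b = length(xb), achieved_power = pw,
            required_n_per_group = rn, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
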
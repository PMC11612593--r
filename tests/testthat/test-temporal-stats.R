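# Group statistics, Welch comparisons, Bonferroni control, power analysis.

test_that("Bonferroni adjustment divides by the number of unordered pairs", {
  expect_equal(bonferroni_alpha(24) * choose(24, 2), 0.05)
  expect_equal(round(bonferroni_alpha(24), 4), 2e-04)
  expect_equal(round(bonferroni_alpha(7), 4), 0.0024)
  expect_equal(round(bonferroni_alpha(12), 4), 8e-04)
  expect_equal(bonferroni_alpha(2), 0.05)
  expect_error(bonferroni_alpha(1), "n_groups")
  expect_error(bonferroni_alpha(24, 1.2), "family_alpha")
})

test_that("Welch comparison agrees with stats::t.test", {
  set.seed(101)
  for (rep in 1:20) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    alpha <- runif(1, 0.001, 0.2)
    md <- mean_diff(a, b, alpha)
    tt <- t.test(a, b, conf.level = 1 - alpha)
    expect_equal(md$diff, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
    expect_equal(md$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(c(md$ci_low, md$ci_high), as.numeric(tt$conf.int),
      tolerance = 1e-10)
    expect_equal(md$df, unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("significance, CI exclusion of zero, and p < alpha coincide", {
  set.seed(202)
  for (rep in 1:200) {
    a <- rnorm(10, mean = sample(0:1, 1))
    b <- rnorm(12)
    md <- mean_diff(a, b, 0.05)
    excl <- md$ci_low > 0 || md$ci_high < 0
    expect_identical(md$significant, excl)
    expect_identical(md$significant, md$p_value < 0.05)
  }
})

test_that("Cohen's d uses the pooled n-1 weighted standard deviation", {
  md <- mean_diff(c(0, 1), c(2, 3))
  expect_equal(md$cohen_d, -2 * sqrt(2), tolerance = 1e-12)
  same <- mean_diff(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$diff, 0)
  expect_equal(same$cohen_d, 0)
  expect_false(same$significant)
  # degenerate zero-variance pair
  const <- mean_diff(c(1, 1), c(1, 1))
  expect_equal(const$cohen_d, 0)
  expect_false(const$significant)
})

test_that("the Welch null is calibrated at the adjusted alpha", {
  set.seed(7)
  alpha <- 0.01
  reps <- 4000
  rej <- replicate(reps, mean_diff(rnorm(100), rnorm(100), alpha)$significant)
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(mean(rej) - alpha), 3 * se)
})

test_that("group statistics reproduce small hand-computed cases", {
  # two days, constant within hour-of-day groups except one hour
  ig <- rep(6, 48); ig[c(5, 29)] <- c(4, 6) # hour 4 has values 4 and 6
  g <- grid_from_values(iob = rep(1, 48), cob = rep(10, 48), ig = ig)
  gs <- group_stats(g, "hour_of_day")
  row <- gs[gs$variable == "ig" & gs$group == "4", ]
  expect_equal(row$mean, 5)
  expect_equal(row$sd, sqrt(2))
  expect_equal(row$n, 2)
  expect_true(row$ci_low <= row$mean && row$mean <= row$ci_high)
  # every hourly group has n = number of days
  expect_true(all(gs$n == 2))
})

test_that("grouping labels map weekdays, weekends and seasons correctly", {
  # 14 days starting Monday 2021-01-04
  n <- 14 * 24
  g <- grid_from_values(iob = rep(1, n), cob = rep(5, n), ig = rep(6, n))
  q <- aidpatterns:::qualifying_hours(g)
  lab_dow <- aidpatterns:::grid_group_labels(q, "day_of_week")
  expect_equal(sort(unique(lab_dow)), 0:6)
  expect_equal(sum(lab_dow == 0), 2 * 24) # two Mondays
  lab_ww <- aidpatterns:::grid_group_labels(q, "weekday_weekend")
  expect_equal(sum(lab_ww == "weekend"), 4 * 24)
  lab_ws <- aidpatterns:::grid_group_labels(q, "winter_summer")
  expect_true(all(lab_ws == "winter")) # January
})

test_that("power matches the noncentral t and stats::power.t.test", {
  expect_equal(power_two_sample(0, 20, 20, 0.05), 0.05, tolerance = 1e-10)
  for (d in c(0.3, 0.8, 1.5)) {
    for (n in c(10, 30)) {
      ours <- power_two_sample(d, n, n, 0.05)
      ref <- power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05)$power
      # power.t.test neglects the opposite rejection tail, so it can sit a
      # few thousandths below the exact two-sided power at small d and n
      expect_gte(ours, ref)
      expect_lt(ours - ref, 0.006)
    }
  }
  expect_gt(power_two_sample(2, 30, 30, 2e-04), 0.99)
  # monotone in |d| and n
  expect_gt(power_two_sample(1, 20, 20), power_two_sample(0.5, 20, 20))
  expect_gt(power_two_sample(0.5, 40, 40), power_two_sample(0.5, 20, 20))
})

test_that("required_n is the minimal per-group size reaching the target", {
  expect_equal(required_n(1, 0.05, 0.8), 17)
  for (d in c(0.4, 0.8, 1.6)) {
    for (alpha in c(0.05, 0.0002)) {
      n <- required_n(d, alpha, 0.8)
      expect_gte(power_two_sample(d, n, n, alpha), 0.8)
      if (n > 2) expect_lt(power_two_sample(d, n - 1, n - 1, alpha), 0.8)
    }
  }
  expect_lte(required_n(1.2, 0.05, 0.8), required_n(0.6, 0.05, 0.8))
  expect_error(required_n(0, 0.05, 0.8), "nonzero")
})

test_that("planted cohort-level weekend shift is found by overall comparison", {
  grids <- lapply(1:12, function(i) {
    cfg <- null_config(days = 40, seed = 100 + i)
    cfg$planted_effects <- list(
      planted_effect("ig", "day_of_week", c(5, 6), 1.5))
    resample_hourly(simulate_participant(cfg, 1)$series)
  })
  oc <- overall_comparisons(grids,
    alpha = c(weekday_weekend = 0.0018))
  row <- oc[oc$variable == "ig" & oc$condition == "weekday_weekend", ]
  expect_equal(row$group_a, "weekday")
  expect_true(row$significant)
  expect_gt(row$diff, 1) # weekend minus weekday
  expect_true(row$achieved_power > 0 && row$achieved_power <= 1)
  expect_gte(row$required_n_per_group, 2)
  # IOB and COB carry no planted effect: no significant difference
  other <- oc[oc$variable != "ig", ]
  expect_false(any(other$significant))
})
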
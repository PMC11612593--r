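# Kendall tau-b associations and Granger-causality forecastability.

test_that("tau-b handles perfect concordance, discordance, and the 4-point case", {
  expect_equal(kendall_tau(1:5, 1:5)$tau, 1)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1)
  # 5 concordant and 1 discordant of 6 pairs -> (5 - 1) / 6
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))$tau, 2 / 3)
  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3)), "all-tied")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("tau-b equals the exhaustive pair-counting oracle on tied vectors", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    x <- sample(1:6, n, replace = TRUE) # heavy ties
    y <- x + sample(0:3, n, replace = TRUE)
    ours <- kendall_tau(x, y)
    expect_equal(ours$tau, kendall_oracle(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "kendall"))
    expect_equal(ours$tau, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("tau p-values are exact for small untied samples", {
  set.seed(12)
  x <- rnorm(8); y <- rnorm(8)
  ours <- kendall_tau(x, y)
  ref <- cor.test(x, y, method = "kendall", exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("associations are invariant to participant order and monotone factor transforms", {
  inst <- data.frame(participant_id = paste0("P", 1:8),
    granularity = "hour_of_day", group_a = "3", group_b = "10",
    code = "U2", stringsAsFactors = FALSE)
  inst <- inst[rep(1:8, times = c(0, 1, 1, 2, 3, 4, 5, 6)), ]
  freq <- tally_patterns(inst, paste0("P", 1:8))
  demo <- data.frame(participant_id = paste0("P", 1:8),
    age = c(20, 25, 30, 35, 40, 45, 50, 55),
    stringsAsFactors = FALSE)
  a1 <- relate_frequencies(freq, demo)
  u2 <- a1[a1$code == "U2" & a1$granularity == "hour_of_day", ]
  expect_equal(u2$tau_b[u2$factor == "age"],
    kendall_tau(c(0, 1, 1, 2, 3, 4, 5, 6), demo$age)$tau)
  # permuted participants
  a2 <- relate_frequencies(freq, demo[8:1, ])
  expect_equal(a1[order(a1$factor, a1$code, a1$granularity), ],
    a2[order(a2$factor, a2$code, a2$granularity), ])
  # monotone transform of the factor leaves tau unchanged
  demo3 <- demo; demo3$age <- exp(demo3$age / 10)
  a3 <- relate_frequencies(freq, demo3)
  expect_equal(a3$tau_b[a3$factor == "age" & a3$code == "U2"],
    a1$tau_b[a1$factor == "age" & a1$code == "U2"])
})

test_that("constant factors and sex are excluded from the scan", {
  inst <- data.frame(participant_id = paste0("P", 1:5),
    granularity = "hour_of_day", group_a = "3", group_b = "10",
    code = c("E1", "E1", "E1", "U2", "U2"), stringsAsFactors = FALSE)
  freq <- tally_patterns(inst, paste0("P", 1:5))
  demo <- data.frame(participant_id = paste0("P", 1:5),
    age = c(20, 30, 40, 50, 60), hba1c = rep(46, 5),
    sex = c("female", "male", "male", "male", "male"),
    stringsAsFactors = FALSE)
  a <- relate_frequencies(freq, demo)
  expect_false("hba1c" %in% a$factor) # all tied
  expect_false("sex" %in% a$factor)
  expect_true("age" %in% a$factor)
})

test_that("a planted frequency-factor association is recovered", {
  # U2 frequency increases with pump recency across 12 participants
  set.seed(13)
  n <- 12
  pump_years <- seq(2, 18, length.out = n)
  u2_count <- round(seq(12, 1, length.out = n) + rnorm(n, 0, 0.5))
  rows <- lapply(1:n, function(i) {
    if (u2_count[i] <= 0) return(NULL)
    data.frame(participant_id = sprintf("P%02d", i),
      granularity = "hour_of_day",
      group_a = as.character(seq_len(u2_count[i])),
      group_b = "20", code = "U2", stringsAsFactors = FALSE)
  })
  freq <- tally_patterns(do.call(rbind, rows), sprintf("P%02d", 1:n))
  ref <- as.Date("2021-01-04")
  demo <- data.frame(participant_id = sprintf("P%02d", 1:n),
    pump_since = ref - round(pump_years * 365.25), stringsAsFactors = FALSE)
  a <- relate_frequencies(freq, demo, ref_date = ref)
  row <- a[a$factor == "pump_years" & a$code == "U2", ]
  expect_lt(row$tau_b, -0.6) # shorter pump use, more U2
  expect_lt(row$p_value, 0.05)
})

test_that("Granger detects a one-lag coupling and matches lmtest", {
  skip_if_not_installed("lmtest")
  set.seed(14)
  n <- 2000
  cause <- rnorm(n)
  effect <- 0.8 * c(0, cause[-n]) + rnorm(n)
  gr <- granger_test(cause, effect, max_lag = 4)
  expect_true(gr$significant)
  expect_equal(gr$lag, 1)
  # same F as the reference implementation on the aligned sample
  trim <- 4 - gr$lag
  ref <- lmtest::grangertest(effect[(trim + 1):n] ~ cause[(trim + 1):n],
    order = gr$lag)
  expect_equal(gr$F, ref$F[2], tolerance = 1e-8)
  expect_equal(gr$p_value, ref$`Pr(>F)`[2], tolerance = 1e-8)
  # reverse direction carries no signal
  rev <- granger_test(effect, cause, max_lag = 4)
  expect_gt(rev$p_value, 0.001)
})

test_that("Granger input contracts are enforced", {
  expect_error(granger_test(rnorm(50), rnorm(50), max_lag = 12), "too short")
  expect_error(granger_test(c(rnorm(199), NA), rnorm(200), max_lag = 4),
    "missing")
  expect_error(granger_test(rnorm(100), rnorm(99), max_lag = 4), "aligned")
})

test_that("consistency summary fractions and inconsistency band are right", {
  res <- data.frame(
    participant_id = rep(sprintf("P%d", 1:10), times = 2),
    cause = rep(c("cob", "iob"), each = 10), effect = "ig",
    lag = 1, F = 1, p_value = 0.5,
    significant = c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
    stringsAsFactors = FALSE)
  cs <- consistency_summary(res)
  cob_row <- cs[cs$cause == "cob", ]
  expect_equal(cob_row$fraction_significant, 1)
  expect_false(cob_row$inconsistent)
  iob_row <- cs[cs$cause == "iob", ]
  expect_equal(iob_row$fraction_significant, 0.5)
  expect_true(iob_row$inconsistent)
})

test_that("a cohort mixing coupled and decoupled participants shows partial consistency", {
  set.seed(15)
  mk <- function(coupled) {
    n <- 600
    cob <- abs(rnorm(n, 10, 3))
    ig <- if (coupled) 6 + 0.5 * c(0, cob[-n]) + rnorm(n, 0, 0.5)
          else rnorm(n, 6, 0.5)
    grid_from_values(iob = rnorm(n, 1, 0.2), cob = cob, ig = ig)
  }
  grids <- c(lapply(1:3, function(i) mk(TRUE)), lapply(1:3, function(i) mk(FALSE)))
  for (i in seq_along(grids)) attr(grids[[i]], "participant_id") <- paste0("P", i)
  res <- cohort_granger(grids, max_lag = 3)
  cs <- consistency_summary(res)
  row <- cs[cs$cause == "cob" & cs$effect == "ig", ]
  expect_equal(row$fraction_significant, 0.5, tolerance = 0.35)
  expect_true(row$inconsistent)
})
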
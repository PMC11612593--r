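# Pattern taxonomy: rule classification and frequency tallies.

sig_up <- data.frame(diff = 1, significant = TRUE)
sig_down <- data.frame(diff = -1, significant = TRUE)
nsig <- data.frame(diff = 0.05, significant = FALSE)

test_that("the quoted exemplars classify exactly", {
  # higher IOB with higher COB -> expected pattern
  expect_equal(classify_pattern(iob = sig_up, cob = sig_up, ig = nsig), "E1")
  # higher IG not due to higher COB -> U2
  expect_equal(classify_pattern(iob = nsig, cob = nsig, ig = sig_up), "U2")
  # nothing significant -> no pattern
  expect_true(is.na(classify_pattern(iob = nsig, cob = nsig, ig = nsig)))
})

test_that("rule precedence gives each pair at most one code", {
  # all three up together is E3, not E1/E2
  expect_equal(classify_pattern(iob = sig_up, cob = sig_up, ig = sig_up), "E3")
  # glucose and carbs up without insulin evidence is E2
  expect_equal(classify_pattern(iob = nsig, cob = sig_up, ig = sig_up), "E2")
  # insulin change without carb change is U1 (either direction)
  expect_equal(classify_pattern(iob = sig_down, cob = nsig, ig = nsig), "U1")
  expect_equal(classify_pattern(iob = sig_up, cob = nsig, ig = nsig), "U1")
  # U1 outranks U2 when both would match
  expect_equal(classify_pattern(iob = sig_up, cob = nsig, ig = sig_up), "U1")
})

test_that("classification is orientation-symmetric", {
  flip <- function(x) data.frame(diff = -x$diff, significant = x$significant)
  states <- list(sig_up, sig_down, nsig)
  for (i in states) for (c_ in states) for (g in states) {
    a <- classify_pattern(iob = i, cob = c_, ig = g)
    b <- classify_pattern(iob = flip(i), cob = flip(c_), ig = flip(g))
    expect_identical(a, b)
  }
})

test_that("mismatched group pairs are rejected", {
  up_ab <- data.frame(diff = 1, significant = TRUE, group_a = "1",
    group_b = "2")
  up_ac <- data.frame(diff = 1, significant = TRUE, group_a = "1",
    group_b = "3")
  expect_error(classify_pattern(iob = up_ab, cob = up_ac, ig = up_ab),
    "group pair")
})

test_that("detected instances are verifiable from their mean differences", {
  cfg <- recovery_config(days = 60, d = 2, seed = 21)
  g <- resample_hourly(simulate_participant(cfg, 1)$series)
  md <- detect_mean_diffs(g, "hour_of_day")
  inst <- detect_patterns(md)
  expect_gt(nrow(inst), 0)
  for (r in sample(seq_len(nrow(inst)), min(10, nrow(inst)))) {
    part <- md[md$group_a == inst$group_a[r] & md$group_b == inst$group_b[r], ]
    code <- classify_pattern(
      iob = part[part$variable == "iob", ],
      cob = part[part$variable == "cob", ],
      ig = part[part$variable == "ig", ])
    expect_identical(code, inst$code[r])
  }
})

test_that("tallies count, normalize, and aggregate per class", {
  inst <- data.frame(
    participant_id = rep("P1", 6), granularity = rep("hour_of_day", 6),
    group_a = as.character(1:6), group_b = as.character(11:16),
    code = c("E1", "E1", "E1", "U2", "U2", "U2"), stringsAsFactors = FALSE)
  ft <- tally_patterns(inst, participants = c("P1", "P2"))
  tot <- ft$totals
  expect_equal(tot$count[tot$class == "expected"],
    tot$count[tot$class == "unexpected"])
  per <- ft$per_participant
  e1 <- per[per$participant_id == "P1" & per$code == "E1" &
    per$granularity == "hour_of_day", ]
  expect_equal(e1$count, 3)
  expect_equal(e1$normalized, 3 / choose(24, 2))
  expect_true(all(per$count[per$participant_id == "P2"] == 0))
  coh <- ft$cohort
  expect_equal(coh$participant_fraction[coh$code == "E1" &
    coh$granularity == "hour_of_day"], 0.5)
})

test_that("an empty instance set tallies to zero everywhere", {
  inst <- detect_patterns(detect_mean_diffs(
    grid_from_values(rep(1, 72 * 24), rep(5, 72 * 24), rep(6, 72 * 24))[0, ],
    "hour_of_day")[0, ])
  ft <- tally_patterns(inst, participants = "P1")
  expect_true(all(ft$per_participant$count == 0))
  expect_true(all(ft$totals$count == 0))
})

test_that("permuting participants permutes the table contents only", {
  inst <- data.frame(
    participant_id = c("A", "B", "B"), granularity = "day_of_week",
    group_a = c("0", "0", "1"), group_b = c("5", "6", "5"),
    code = c("U1", "E1", "U2"), stringsAsFactors = FALSE)
  f1 <- tally_patterns(inst, c("A", "B"))
  f2 <- tally_patterns(inst[c(3, 1, 2), ], c("B", "A"))
  p1 <- f1$per_participant[order(f1$per_participant$participant_id,
    f1$per_participant$granularity, f1$per_participant$code), ]
  p2 <- f2$per_participant[order(f2$per_participant$participant_id,
    f2$per_participant$granularity, f2$per_participant$code), ]
  rownames(p1) <- rownames(p2) <- NULL
  attr(p1, "out.attrs") <- attr(p2, "out.attrs") <- NULL
  expect_equal(p1, p2)
  expect_equal(f1$totals, f2$totals)
})

test_that("rule sets round-trip through YAML", {
  rules <- default_pattern_rules()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pattern_rules(rules, path)
  back <- read_pattern_rules(path)
  expect_equal(back, rules)
})

test_that("a null cohort yields few pattern instances per participant", {
  set.seed(31)
  counts <- vapply(1:10, function(i) {
    g <- resample_hourly(simulate_participant(null_config(days = 40,
      seed = 400 + i), 1)$series)
    nrow(detect_patterns(detect_mean_diffs(g, "hour_of_day")))
  }, numeric(1))
  # Bonferroni bound: expected false patterns per participant well below 1
  expect_lte(mean(counts), 0.5)
})
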
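# Expected/unexpected pattern taxonomy: classify significant mean differences
# between two time slots into the codes E1-E3 (explainable by carbohydrates)
# and U1-U2 (not explainable by carbohydrates), and tally frequencies.

#' Default pattern rule set
#'
#' Rules are data, not code: each rule constrains the significance state of
#' IOB, COB and IG for one unordered slot pair, using the vocabulary
#' `"up"` (significantly higher), `"down"` (significantly lower), `"diff"`
#' (significantly different in either direction), `"none"` (not
#' significantly different), `"not_up"`, `"not_down"`, and `"any"`. Rules
#' are applied in order (E3 before E1/E2 before U1/U2) to both orientations
#' of the pair, so each pair yields at most one code:
#'
#' * `E3` — IOB, COB and IG all significantly higher together.
#' * `E1` — higher IOB with higher COB (more insulin needed for more carbs).
#' * `E2` — higher IG with higher COB (glucose rise explained by carbs).
#' * `U1` — IOB significantly different without a COB difference
#'   (an insulin-need change not explained by carbohydrates).
#' * `U2` — IG significantly higher without higher COB
#'   (a glucose rise not explained by carbohydrates).
#'
#' @return A data frame with columns `code`, `iob`, `cob`, `ig`,
#'   `description`, in precedence order. Edit or replace it to change the
#'   taxonomy; [write_pattern_rules()] and [read_pattern_rules()] round-trip
#'   it through YAML.
#' @export
default_pattern_rules <- function() {
  data.frame(
    code = c("E3", "E1", "E2", "U1", "U2"),
    iob = c("up", "up", "any", "diff", "any"),
    cob = c("up", "up", "up", "none", "not_up"),
    ig = c("up", "any", "up", "any", "up"),
    description = c(
      "insulin, carbohydrates and glucose all higher together",
      "higher insulin on board with higher carbohydrates on board",
      "higher glucose with higher carbohydrates on board",
      "insulin-on-board change without a carbohydrate change",
      "higher glucose not due to higher carbohydrates"),
    stringsAsFactors = FALSE)
}

#' Write / read a pattern rule set as YAML
#'
#' @param rules a rule data frame as from [default_pattern_rules()].
#' @param path YAML file path.
#' @return `write_pattern_rules` returns `path` invisibly;
#'   `read_pattern_rules` returns the rule data frame.
#' @export
write_pattern_rules <- function(rules, path) {
  yaml::write_yaml(lapply(seq_len(nrow(rules)), function(i) as.list(rules[i, ])),
    path)
  invisible(path)
}

#' @rdname write_pattern_rules
#' @export
read_pattern_rules <- function(path) {
  lst <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(lst, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Significance state of one comparison: "up", "down" or "none".
sig_state <- function(significant, diff) {
  ifelse(significant, ifelse(diff > 0, "up", "down"), "none")
}

cond_matches <- function(cond, state) {
  switch(cond,
    up = state == "up",
    down = state == "down",
    diff = state != "none",
    none = state == "none",
    not_up = state != "up",
    not_down = state != "down",
    any = TRUE,
    stop(sprintf("unknown rule condition '%s'", cond), call. = FALSE))
}

flip_state <- function(state) {
  c(up = "down", down = "up", none = "none")[[state]]
}

#' Classify one slot pair from its three mean differences
#'
#' Takes the IOB, COB and IG Welch comparisons of the same granularity and
#' group pair (differences oriented later group minus earlier group) and
#' returns the first rule code matching either orientation of the pair, or
#' `NA` when no rule matches (in particular when nothing is significant).
#'
#' @param iob,cob,ig one-row comparison data frames (from [mean_diff()] or
#'   rows of [detect_mean_diffs()] output) sharing granularity and pair.
#' @param rules rule set, default [default_pattern_rules()].
#' @return A pattern code (`"E1"`..`"U2"`) or `NA_character_`.
#' @export
#' @examples
#' up <- data.frame(diff = 1, significant = TRUE)
#' ns <- data.frame(diff = 0.1, significant = FALSE)
#' classify_pattern(iob = up, cob = up, ig = ns) # "E1"
#' classify_pattern(iob = ns, cob = ns, ig = up) # "U2"
classify_pattern <- function(iob, cob, ig, rules = default_pattern_rules()) {
  for (df in list(iob, cob, ig)) {
    if (!all(c("diff", "significant") %in% names(df)) || nrow(df) != 1) {
      stop("each of iob, cob, ig must be a one-row comparison", call. = FALSE)
    }
  }
  if (!is.null(iob$group_a)) {
    same <- identical(c(iob$group_a, iob$group_b), c(cob$group_a, cob$group_b)) &&
      identical(c(iob$group_a, iob$group_b), c(ig$group_a, ig$group_b))
    if (!same) stop("comparisons do not share the same group pair", call. = FALSE)
  }
  st <- c(iob = sig_state(iob$significant, iob$diff),
          cob = sig_state(cob$significant, cob$diff),
          ig = sig_state(ig$significant, ig$diff))
  st_flip <- vapply(st, flip_state, character(1))
  for (i in seq_len(nrow(rules))) {
    for (s in list(st, st_flip)) {
      if (cond_matches(rules$iob[i], s[["iob"]]) &&
          cond_matches(rules$cob[i], s[["cob"]]) &&
          cond_matches(rules$ig[i], s[["ig"]])) {
        return(rules$code[i])
      }
    }
  }
  NA_character_
}

#' Detect pattern instances in a table of mean differences
#'
#' Groups a [detect_mean_diffs()] table by (granularity, pair), classifies
#' each complete IOB/COB/IG triple, and returns the classified instances.
#'
#' @param meandiffs a `mean_diff_table`.
#' @param rules rule set, default [default_pattern_rules()].
#' @return A data frame of pattern instances: `participant_id`,
#'   `granularity`, `group_a`, `group_b`, `code`.
#' @export
detect_patterns <- function(meandiffs, rules = default_pattern_rules()) {
  empty <- data.frame(participant_id = character(), granularity = character(),
    group_a = character(), group_b = character(), code = character(),
    stringsAsFactors = FALSE)
  if (nrow(meandiffs) == 0) return(empty)
  key <- paste(meandiffs$participant_id, meandiffs$granularity,
    meandiffs$group_a, meandiffs$group_b, sep = "\r")
  rows <- lapply(split(seq_len(nrow(meandiffs)), key), function(idx) {
    part <- meandiffs[idx, , drop = FALSE]
    if (!all(aid_variables() %in% part$variable)) return(NULL)
    code <- classify_pattern(
      iob = part[part$variable == "iob", , drop = FALSE],
      cob = part[part$variable == "cob", , drop = FALSE],
      ig = part[part$variable == "ig", , drop = FALSE],
      rules = rules)
    if (is.na(code)) return(NULL)
    data.frame(participant_id = part$participant_id[1],
      granularity = part$granularity[1], group_a = part$group_a[1],
      group_b = part$group_b[1], code = code, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$participant_id, out$granularity, out$group_a, out$group_b), ,
      drop = FALSE]
}

#' Tally pattern frequencies per participant and across the cohort
#'
#' Frequency is ambiguous in the field, so three views are emitted: raw
#' instance counts, counts normalized by the number of compared pairs at the
#' granularity, and the cohort fraction of participants with at least one
#' instance. Expected (E) and unexpected (U) totals are reported side by
#' side.
#'
#' @param instances output of [detect_patterns()] (possibly row-bound over
#'   participants).
#' @param participants character vector of all cohort participant ids
#'   (including those without instances).
#' @param n_pairs named vector: number of compared pairs per granularity
#'   (used for normalization); defaults to the nominal `choose(G, 2)` family
#'   sizes for hour/day/month.
#' @return A `pattern_freq` list: `per_participant` (participant x
#'   granularity x code counts and normalized frequencies), `cohort`
#'   (per granularity x code: total count and fraction of participants with
#'   an instance), and `totals` (expected vs unexpected).
#' @export
tally_patterns <- function(instances, participants,
                           n_pairs = c(hour_of_day = choose(24, 2),
                                       day_of_week = choose(7, 2),
                                       month_of_year = choose(12, 2))) {
  codes <- default_pattern_rules()$code
  grans <- unique(c(names(n_pairs), unique(instances$granularity)))
  per <- expand.grid(participant_id = participants, granularity = grans,
    code = codes, stringsAsFactors = FALSE)
  cnt <- integer(nrow(per))
  if (nrow(instances)) {
    key_i <- paste(instances$participant_id, instances$granularity,
      instances$code, sep = "\r")
    tab <- table(key_i)
    key_p <- paste(per$participant_id, per$granularity, per$code, sep = "\r")
    hit <- match(key_p, names(tab))
    cnt <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  per$count <- cnt
  np <- n_pairs[per$granularity]
  per$normalized <- ifelse(is.na(np), NA_real_, per$count / np)

  cohort <- stats::aggregate(count ~ granularity + code, data = per, FUN = sum)
  frac <- stats::aggregate(count ~ granularity + code, data = per,
    FUN = function(x) mean(x > 0))
  cohort$participant_fraction <- frac$count

  per$class <- ifelse(startsWith(per$code, "E"), "expected", "unexpected")
  totals <- stats::aggregate(count ~ class, data = per, FUN = sum)

  structure(list(per_participant = per, cohort = cohort, totals = totals,
                 n_pairs = n_pairs),
            class = "pattern_freq")
}

#' @export
print.pattern_freq <- function(x, ...) {
  cat("<pattern_freq>\n")
  cat("Cohort totals by class:\n")
  print(x$totals, row.names = FALSE)
  cat("Participant fraction with >=1 instance, by granularity and code:\n")
  print(x$cohort[x$cohort$count > 0 | x$cohort$participant_fraction > 0, ],
    row.names = FALSE)
  invisible(x)
}
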
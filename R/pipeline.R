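# End-to-end orchestration: simulate (or read) a cohort, ingest and filter,
# cluster days, detect and classify patterns, relate frequencies to factors,
# and assess forecastability; all artifacts written as plain CSV/JSON.

#' Default analysis configuration
#'
#' A nested list mirroring the YAML configuration accepted by
#' [run_aid_analysis()]: a `sim` section (arguments of [sim_config()]) and an
#' `analysis` section (family-wise alpha, granularities, cluster k range,
#' matrix-profile windows, Granger maximum lag, eligibility threshold).
#'
#' @return A named list.
#' @export
default_analysis_config <- function() {
  list(
    sim = list(n_participants = 20, days = c(30, 180), seed = 1),
    analysis = list(
      family_alpha = 0.05,
      granularities = c("hour_of_day", "day_of_week", "month_of_year",
                        "cluster"),
      min_days = 30,
      k_range = 2:8,
      kmeans_restarts = 10,
      mp_windows = c(24, 6),
      mp_include_week = FALSE,
      granger_max_lag = 12,
      granger_alpha = 0.05,
      overall_alpha = c(weekday_weekend = 0.0018, winter_summer = 0.0063,
                        year1_year2 = 0.0032, cluster = 0.0018)))
}

read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_analysis_config()
  for (sec in names(raw)) {
    for (f in names(raw[[sec]])) cfg[[sec]][[f]] <- raw[[sec]][[f]]
  }
  # reproducibility fields must be stated explicitly, not defaulted
  for (f in c("n_participants", "seed")) {
    if (is.null(raw$sim[[f]])) {
      stop(sprintf("config missing required field sim.%s", f), call. = FALSE)
    }
  }
  cfg
}

#' Run the full temporal-pattern analysis
#'
#' Executes the pipeline stages in order — `simulate`, `ingest`, `cluster`,
#' `patterns`, `mp` (matrix profile), `relate`, `granger`, `report` — and
#' writes each stage's artifact as CSV/JSON under `outdir`, plus a run
#' manifest with the configuration snapshot, seeds, file digests and
#' versions. Identical configuration reproduces identical outputs.
#'
#' @param config a configuration list (see [default_analysis_config()]) or
#'   the path to a YAML file with `sim` and `analysis` sections.
#' @param outdir output directory (created if needed).
#' @param stages subset of stages to run (upstream artifacts must already be
#'   computed in this call; stage selection mainly skips downstream work).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_aid_analysis <- function(config = default_analysis_config(),
                             outdir = "aid_report",
                             stages = c("simulate", "ingest", "cluster",
                                        "patterns", "mp", "relate",
                                        "granger", "report")) {
  if (is.character(config)) config <- read_analysis_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  an <- config$analysis
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE, na = "")
  }
  log_line <- function(...) message(sprintf(...))
  res <- list()

  # simulate
  scfg <- do.call(sim_config, config$sim)
  cohort <- simulate_cohort(scfg)
  res$demographics <- cohort$demographics
  if ("simulate" %in% stages) {
    wcsv(cohort$demographics, "demographics.csv")
    log_line("simulate: %d participants", length(cohort$series))
  }

  # ingest + eligibility
  grids <- lapply(cohort$series, resample_hourly)
  reports <- lapply(grids, eligibility_filter, min_days = an$min_days)
  eligible <- vapply(reports, `[[`, logical(1), "eligible")
  elig_df <- data.frame(
    participant_id = vapply(reports, `[[`, character(1), "participant_id"),
    qualifying_days = vapply(reports, `[[`, numeric(1), "qualifying_days"),
    eligible = eligible, stringsAsFactors = FALSE)
  grids <- grids[eligible]
  res$eligibility <- elig_df
  res$grids <- grids
  if ("ingest" %in% stages) {
    writeLines(vapply(seq_len(nrow(elig_df)), function(i) {
      jsonlite::toJSON(as.list(elig_df[i, ]), auto_unbox = TRUE)
    }, character(1)), file.path(outdir, "eligibility.jsonl"))
    log_line("ingest: %d of %d participants eligible (>= %d covered days)",
      sum(eligible), length(eligible), an$min_days)
  }

  # cluster
  assignments <- NULL
  if ("cluster" %in% stages) {
    assignments <- lapply(grids, function(grid) {
      ft <- day_features(grid)
      if (nrow(ft$features) < 3) return(NULL)
      k <- choose_k(ft, k_range = an$k_range, seed = scfg$seed,
        restarts = an$kmeans_restarts)
      fit_kmeans(ft, k, seed = scfg$seed, restarts = an$kmeans_restarts)
    })
    assignments <- Filter(Negate(is.null), assignments)
    if (length(assignments)) {
      adf <- do.call(rbind, lapply(assignments, function(a) {
        data.frame(participant_id = a$participant_id,
          date = as.character(a$dates), cluster = a$labels,
          stringsAsFactors = FALSE)
      }))
      wcsv(adf, "clusters.csv")
    }
    log_line("cluster: day clusters for %d participants", length(assignments))
    res$assignments <- assignments
  }

  # patterns
  if ("patterns" %in% stages) {
    grans <- an$granularities
    if (is.null(assignments) && "cluster" %in% grans) {
      warning("cluster granularity skipped: no cluster assignments")
      grans <- setdiff(grans, "cluster")
    }
    md_all <- list(); gs_all <- list()
    for (grid in grids) {
      pid <- attr(grid, "participant_id")
      for (g in grans) {
        asg <- if (g == "cluster") assignments[[pid]] else NULL
        if (g == "cluster" && is.null(asg)) next
        md_all[[paste(pid, g)]] <- detect_mean_diffs(grid, g,
          family_alpha = an$family_alpha, assignment = asg)
        gs <- group_stats(grid, g, assignment = asg)
        gs$participant_id <- pid
        gs_all[[paste(pid, g)]] <- gs
      }
    }
    meandiffs <- do.call(rbind, md_all)
    if (is.null(meandiffs)) meandiffs <- empty_mean_diff_table()
    instances <- detect_patterns(meandiffs)
    n_pairs <- tapply(
      paste(meandiffs$group_a, meandiffs$group_b),
      meandiffs$granularity, function(x) length(unique(x)))
    freq <- tally_patterns(instances, names(grids),
      n_pairs = stats::setNames(as.numeric(n_pairs), names(n_pairs)))
    wcsv(do.call(rbind, gs_all), "group_stats.csv")
    wcsv(meandiffs, "mean_diffs.csv")
    wcsv(instances, "pattern_instances.csv")
    wcsv(freq$per_participant, "pattern_frequency.csv")
    wcsv(freq$cohort, "pattern_frequency_cohort.csv")
    log_line("patterns: %d instances across %d participants",
      nrow(instances), length(grids))
    res$meandiffs <- meandiffs; res$instances <- instances; res$freq <- freq

    oc <- overall_comparisons(grids, assignments, alpha = an$overall_alpha)
    if (!is.null(oc)) wcsv(oc, "overall_comparisons.csv")
    res$overall <- oc
  }

  # matrix profile
  if ("mp" %in% stages) {
    windows <- an$mp_windows
    if (isTRUE(an$mp_include_week)) windows <- c(windows, 168)
    mp_rows <- list()
    for (grid in grids) {
      pid <- attr(grid, "participant_id")
      for (v in aid_variables()) {
        x <- longest_covered_stretch(grid, v)
        for (m in windows) {
          if (length(x) < 2 * m) next
          mp <- matrix_profile(x, m)
          mot <- top_motif(mp); dis <- top_discord(mp)
          mp_rows[[length(mp_rows) + 1]] <- data.frame(
            participant_id = pid, variable = v, m = m,
            motif_1 = mot$positions[1], motif_2 = mot$positions[2],
            motif_distance = mot$distance, discord = dis$position,
            discord_distance = dis$distance, stringsAsFactors = FALSE)
        }
      }
    }
    mp_df <- do.call(rbind, mp_rows)
    if (!is.null(mp_df)) wcsv(mp_df, "matrix_profile_summary.csv")
    log_line("mp: %d motif/discord summaries", length(mp_rows))
    res$motifs <- mp_df
  }

  # relate
  if ("relate" %in% stages && !is.null(res$freq)) {
    dev <- device_factors(grids)
    assoc <- relate_frequencies(res$freq, cohort$demographics, dev,
      ref_date = scfg$start_date)
    wcsv(assoc, "associations.csv")
    log_line("relate: %d associations", nrow(assoc))
    res$associations <- assoc
  }

  # granger
  if ("granger" %in% stages) {
    gr <- cohort_granger(grids, max_lag = an$granger_max_lag,
      alpha = an$granger_alpha)
    cons <- consistency_summary(gr)
    wcsv(gr, "granger.csv")
    wcsv(cons, "granger_consistency.csv")
    log_line("granger: %d tests, %d direction(s) inconsistent", nrow(gr),
      sum(cons$inconsistent))
    res$granger <- gr; res$granger_consistency <- cons
  }

  # report + manifest
  if ("report" %in% stages) {
    files <- list.files(outdir, pattern = "\\.(csv|jsonl)$", full.names = TRUE)
    manifest <- list(
      config = config, seed = scfg$seed,
      files = as.list(tools::md5sum(files)),
      versions = list(r = R.version.string,
        aidpatterns = as.character(utils::packageVersion("aidpatterns"))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE)
    summary_lines <- c(
      sprintf("Participants simulated: %d", length(cohort$series)),
      sprintf("Eligible participants:  %d", sum(eligible)),
      if (!is.null(res$freq)) {
        c("Pattern totals:",
          utils::capture.output(print(res$freq$totals, row.names = FALSE)))
      },
      if (!is.null(res$granger_consistency)) {
        c("Granger consistency:",
          utils::capture.output(print(res$granger_consistency,
            row.names = FALSE)))
      })
    writeLines(summary_lines, file.path(outdir, "summary.txt"))
  }
  invisible(res)
}
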
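# Cohort-level orchestration: stage runners over a cohort directory,
# tabular reports, and a small command-line front end.

.load_manifest <- function(cohort_dir) {
  mf <- file.path(cohort_dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", cohort_dir, call. = FALSE)
  read.csv(mf, stringsAsFactors = FALSE)
}

.stim_times <- function(trials) {
  trials$onset_s[trials$kind == "stimulus" & trials$outcome != "aborted"]
}

#' Run the behavior stage over a cohort directory
#'
#' Per-session performance plus the per-mouse analysis-day selection
#' (trained criteria for the detection paradigm, last-3-days for neutral
#' exposure).
#'
#' @param cohort_dir directory written by [make_cohort()].
#' @param out_dir output directory for `behavior_summary.csv`.
#' @return the summary data.frame, invisibly.
#' @export
stage_behavior <- function(cohort_dir, out_dir) {
  man <- .load_manifest(cohort_dir)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    ses <- read_session(file.path(cohort_dir, man$file[i]))
    perf <- session_performance(ses$trials, day_index = man$day[i])
    cbind(data.frame(mouse = man$mouse[i]), as.data.frame(perf))
  })
  df <- do.call(rbind, rows)
  df$selected <- FALSE
  for (m in unique(df$mouse)) {
    rows_m <- df$mouse == m
    sel <- if (man$paradigm[1] == "neutral_exposure")
      select_exposed_sessions(max(df$day_index[rows_m]))
    else suppressWarnings(select_trained_sessions(df[rows_m, ]))
    df$selected[rows_m & df$day_index %in% sel] <- TRUE
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(df, file.path(out_dir, "behavior_summary.csv"), row.names = FALSE)
  message(sprintf("behavior: %d sessions, %d selected", nrow(df),
                  sum(df$selected)))
  invisible(df)
}

#' Run the SEP stage over a cohort directory
#'
#' Preprocesses every session, epochs each area, and measures the evoked
#' potential for all-stimulus, hit (premature excluded) and miss
#' conditions.
#'
#' @param cohort_dir directory written by [make_cohort()].
#' @param out_dir output directory for `sep_summary.csv`.
#' @return the summary data.frame, invisibly.
#' @export
stage_sep <- function(cohort_dir, out_dir) {
  man <- .load_manifest(cohort_dir)
  cfgpol <- function(area) if (area == "mPFC") 1 else -1
  out <- list()
  for (i in seq_len(nrow(man))) {
    ses <- read_session(file.path(cohort_dir, man$file[i]))
    rec <- preprocess_lfp(ses$lfp, .stim_times(ses$trials))
    for (area in rec$channel_area) {
      ep <- extract_epochs(rec, ses$trials, area)
      conds <- list(
        all_stim = trial_mask(ep, ses$trials, c("hit", "miss"),
                              exclude_premature = FALSE),
        hit = trial_mask(ep, ses$trials, "hit"),
        miss = trial_mask(ep, ses$trials, "miss"))
      for (cn in names(conds)) {
        if (!any(conds[[cn]])) next
        sep <- average_sep(ep, conds[[cn]])
        pk <- find_first_peak(sep, polarity = cfgpol(area))
        lat <- onset_latency(sep)
        out[[length(out) + 1]] <- data.frame(
          mouse = man$mouse[i], day = man$day[i], area = area,
          condition = cn, n_trials = sep$n_trials,
          peak_time_ms = 1000 * pk$peak_time_s,
          peak_amp_uv = pk$peak_amp_uv,
          latency_ms = 1000 * lat)
      }
    }
  }
  df <- do.call(rbind, out)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(df, file.path(out_dir, "sep_summary.csv"), row.names = FALSE)
  message(sprintf("sep: %d (session, area, condition) rows", nrow(df)))
  invisible(df)
}

#' Run the ROC decoding stage over a cohort directory
#'
#' Stimulus-probability curves per session and area, with label-shuffle
#' chance bands.
#'
#' @param cohort_dir directory written by [make_cohort()].
#' @param out_dir output directory for `sp_curves.csv`.
#' @param n_shuffle label permutations per curve.
#' @param seed RNG seed for the shuffles.
#' @return the long-format data.frame, invisibly.
#' @export
stage_roc <- function(cohort_dir, out_dir, n_shuffle = 100, seed = 1L) {
  man <- .load_manifest(cohort_dir)
  out <- list()
  for (i in seq_len(nrow(man))) {
    ses <- read_session(file.path(cohort_dir, man$file[i]))
    rec <- preprocess_lfp(ses$lfp, .stim_times(ses$trials))
    for (area in rec$channel_area) {
      ep <- extract_epochs(rec, ses$trials, area)
      labels <- ses$trials$kind[match(ep$trial_ids, ses$trials$trial_id)]
      sp <- sp_curve(ep, labels, n_shuffle = n_shuffle,
                     seed = derive_seed(seed, man$mouse[i], man$day[i], 9L))
      out[[length(out) + 1]] <- data.frame(
        mouse = man$mouse[i], day = man$day[i], area = area,
        time_ms = 1000 * sp$time_s, sp = sp$sp,
        shuffle_mean = sp$shuffle_mean, shuffle_sd = sp$shuffle_sd)
    }
  }
  df <- do.call(rbind, out)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(df, file.path(out_dir, "sp_curves.csv"), row.names = FALSE)
  message(sprintf("roc: %d SP points", nrow(df)))
  invisible(df)
}

#' Run the spike stage over a cohort directory
#'
#' RSU/FSU classification and the bootstrap modulation test per unit,
#' using non-premature hit trials.
#'
#' @param cohort_dir directory written by [make_cohort()] with spikes.
#' @param out_dir output directory for `units_summary.csv`.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return the per-unit data.frame, invisibly.
#' @export
stage_spikes <- function(cohort_dir, out_dir, n_boot = 1000, seed = 1L) {
  man <- .load_manifest(cohort_dir)
  out <- list()
  for (i in seq_len(nrow(man))) {
    ses <- read_session(file.path(cohort_dir, man$file[i]))
    if (length(ses$units) == 0) next
    hits <- ses$trials$onset_s[ses$trials$outcome == "hit" &
                                 !ses$trials$premature]
    if (length(hits) < 10) next
    for (u in ses$units) {
      mr <- modulation_test(u, hits, n_boot = n_boot,
                            seed = derive_seed(seed, man$mouse[i],
                                               man$day[i], 11L))
      out[[length(out) + 1]] <- data.frame(
        mouse = man$mouse[i], day = man$day[i], unit_id = u$unit_id,
        area = u$area, class = classify_unit(u$trough_to_peak_ms),
        mean_pre_hz = mr$mean_pre_hz, mean_post_hz = mr$mean_post_hz,
        delta_hz = mr$delta_hz, p_boot = mr$p_boot, klass = mr$klass)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) stop("no sessions with spikes and >= 10 hit trials",
                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(df, file.path(out_dir, "units_summary.csv"), row.names = FALSE)
  message(sprintf("spikes: %d units tested", nrow(df)))
  invisible(df)
}

#' Run the inactivation stage over an opto cohort directory
#'
#' Per-mouse light-on vs light-off hit and false-alarm rates (pooled over
#' that mouse's sessions) and the paired Wilcoxon comparison.
#'
#' @param cohort_dir directory written by [make_cohort()] for an
#'   `opto_inactivation` scenario.
#' @param out_dir output directory for `inactivation_summary.csv`.
#' @return one-row data.frame, invisibly.
#' @export
stage_inactivate <- function(cohort_dir, out_dir) {
  man <- .load_manifest(cohort_dir)
  per_mouse <- list()
  area <- NA_character_
  for (m in unique(man$mouse)) {
    files <- man$file[man$mouse == m]
    tts <- lapply(files, function(f) {
      ses <- read_session(file.path(cohort_dir, f))
      area <<- ses$meta$target_area %||% NA_character_
      ses$trials
    })
    tt <- do.call(rbind, lapply(tts, function(t) as.data.frame(
      t[c("trial_id", "kind", "onset_s", "outcome", "premature", "light_on",
          "reward_s")])))
    tt$lick_times_s <- do.call(c, lapply(tts, `[[`, "lick_times_s"))
    class(tt) <- c("trial_table", "data.frame")
    rate <- function(sub) {
      keep <- sub$outcome != "aborted"
      c(hit = sum(sub$outcome[keep] == "hit") /
          max(1, sum(sub$kind[keep] == "stimulus")),
        fa = sum(sub$outcome[keep] == "false_alarm") /
          max(1, sum(sub$kind[keep] == "catch")))
    }
    sides <- split_light_trials(tt)
    per_mouse[[as.character(m)]] <- data.frame(
      mouse = m, hit_on = rate(sides$on)["hit"], hit_off = rate(sides$off)["hit"],
      fa_on = rate(sides$on)["fa"], fa_off = rate(sides$off)["fa"])
  }
  pm <- do.call(rbind, per_mouse)
  cmp <- opto_compare(data.frame(hit_rate = pm$hit_on, fa_rate = pm$fa_on),
                      data.frame(hit_rate = pm$hit_off, fa_rate = pm$fa_off))
  df <- data.frame(area = area, n_mice = nrow(pm),
                   hit_on = mean(pm$hit_on), hit_off = mean(pm$hit_off),
                   fa_on = mean(pm$fa_on), fa_off = mean(pm$fa_off),
                   p_hit = cmp$p_hit, p_fa = cmp$p_fa)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(df, file.path(out_dir, "inactivation_summary.csv"),
            row.names = FALSE)
  message(sprintf("inactivate: %s, n = %d mice, p_hit = %.3g", area,
                  nrow(pm), cmp$p_hit))
  invisible(df)
}

#' Assemble a tabular summary report from stage outputs
#'
#' One markdown document with a section per analysis (behavior/learning,
#' SEP conditions, stimulus probability, unit modulation fractions,
#' inactivation). Missing stage outputs are flagged and the partial report
#' is still written; regeneration is idempotent.
#'
#' @param results_dir directory containing the stage CSVs.
#' @param out_file output file (default `report.md` inside `results_dir`).
#' @return path to the report, invisibly.
#' @export
build_report <- function(results_dir, out_file = file.path(results_dir, "report.md")) {
  sec <- function(title, file, fmt) {
    path <- file.path(results_dir, file)
    if (!file.exists(path))
      return(c(paste("##", title), "", paste0("MISSING: ", file), ""))
    c(paste("##", title), "", fmt(read.csv(path)), "")
  }
  lines <- c("# Cohort analysis report", "",
    sec("Behavior", "behavior_summary.csv", function(df) {
      agg <- stats::aggregate(cbind(hit_rate, fa_rate, dprime) ~ day_index,
                              df, mean)
      c("day-by-day cohort means:",
        sprintf("- day %d: hit %.2f, FA %.2f, d' %.2f", agg$day_index,
                agg$hit_rate, agg$fa_rate, agg$dprime))
    }),
    sec("Sensory-evoked potentials", "sep_summary.csv", function(df) {
      agg <- stats::aggregate(peak_amp_uv ~ area + condition, df, mean,
                              na.action = stats::na.omit)
      sprintf("- %s / %s: mean peak %.1f uV", agg$area, agg$condition,
              agg$peak_amp_uv)
    }),
    sec("Stimulus probability (ROC)", "sp_curves.csv", function(df) {
      agg <- stats::aggregate(sp ~ area, df[df$time_ms > 0, ], max)
      sprintf("- %s: max post-onset SP %.3f", agg$area, agg$sp)
    }),
    sec("Unit modulation", "units_summary.csv", function(df) {
      sprintf("- %s: %.1f%% (%d/%d)",
              c("positive", "negative", "none"),
              100 * vapply(c("positive", "negative", "none"),
                           function(k) mean(df$klass == k), numeric(1)),
              vapply(c("positive", "negative", "none"),
                     function(k) sum(df$klass == k), integer(1)), nrow(df))
    }),
    sec("Inactivation", "inactivation_summary.csv", function(df) {
      sprintf("- %s: hit %.2f -> %.2f (p = %.3g), FA %.2f -> %.2f (p = %.3g)",
              df$area, df$hit_off, df$hit_on, df$p_hit, df$fa_off, df$fa_on,
              df$p_fa)
    }))
  writeLines(lines, out_file)
  invisible(out_file)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (needs `--config` scenario YAML and `--out`),
#' `behavior` / `sep` / `roc` / `spikes` / `inactivate` (need `--cohort`
#' and `--out`), and `report` (needs `--out`, the results directory).
#' A `--seed` integer overrides the scenario seed and seeds the stochastic
#' stages. Returns an exit code rather than quitting, so it is scriptable
#' and testable; the wrapper script in `inst/cli` forwards the code to
#' `quit()`.
#'
#' @param argv character vector of arguments (e.g. from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code: 0 success, 2 usage/config error, 1 stage
#'   failure.
#' @export
cli_main <- function(argv) {
  usage <- paste("usage: whiskerlfp <simulate|behavior|sep|roc|spikes|",
                 "inactivate|report> [--config f] [--cohort d] [--out d]",
                 "[--seed n] [--spikes]")
  if (length(argv) < 1) { message(usage); return(2L) }
  cmd <- argv[1]
  opts <- list(seed = 1L, spikes = FALSE)
  i <- 2
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--spikes") { opts$spikes <- TRUE; i <- i + 1; next }
    if (!a %in% c("--config", "--cohort", "--out", "--seed") ||
        i == length(argv)) {
      message("bad argument: ", a, "\n", usage); return(2L)
    }
    opts[[sub("^--", "", a)]] <- argv[i + 1]
    i <- i + 2
  }
  opts$seed <- as.integer(opts$seed)
  need <- function(what) {
    if (is.null(opts[[what]])) {
      message("missing --", what, "\n", usage); return(TRUE)
    }
    FALSE
  }
  run <- function(expr) {
    tryCatch({ expr; 0L },
             error = function(e) {
               message(sprintf("stage '%s' failed: %s", cmd,
                               conditionMessage(e)))
               1L
             })
  }
  switch(cmd,
    simulate = {
      if (need("config") || need("out")) return(2L)
      run({
        sc <- scenario_from_yaml(opts$config)
        sc$seed <- opts$seed
        make_cohort(sc, opts$out, with_spikes = opts$spikes)
        manifest <- list(scenario = opts$config,
                         config_sha = unname(tools::md5sum(opts$config)),
                         seed = opts$seed,
                         package_version =
                           as.character(utils::packageVersion("whiskerlfp")))
        jsonlite::write_json(manifest,
                             file.path(opts$out, "run_manifest.json"),
                             auto_unbox = TRUE)
      })
    },
    behavior = {
      if (need("cohort") || need("out")) return(2L)
      run(stage_behavior(opts$cohort, opts$out))
    },
    sep = {
      if (need("cohort") || need("out")) return(2L)
      run(stage_sep(opts$cohort, opts$out))
    },
    roc = {
      if (need("cohort") || need("out")) return(2L)
      run(stage_roc(opts$cohort, opts$out, seed = opts$seed))
    },
    spikes = {
      if (need("cohort") || need("out")) return(2L)
      run(stage_spikes(opts$cohort, opts$out, seed = opts$seed))
    },
    inactivate = {
      if (need("cohort") || need("out")) return(2L)
      run(stage_inactivate(opts$cohort, opts$out))
    },
    report = {
      if (need("out")) return(2L)
      run(build_report(opts$out))
    },
    { message("unknown subcommand: ", cmd, "\n", usage); 2L })
}

#' In-memory SEP and behavior summary for a simulated cohort
#'
#' Simulates each requested (mouse, day) session, runs the full LFP
#' pipeline (artifact blanking, band-pass, epoching, baseline correction)
#' and measures the evoked potential per area and condition, without
#' touching disk. Returns per-session rows ready for learning-curve and
#' amplitude-versus-performance analyses.
#'
#' @param sc a [cohort_scenario()].
#' @param mice,days subsets of mouse/day indices (defaults: all).
#' @param conditions subset of `"all_stim"`, `"hit"`, `"miss"`.
#' @return data.frame with one row per (mouse, day, area, condition):
#'   measured performance (`hit_rate`, `fa_rate`, `dprime`), `n_trials`,
#'   `peak_time_ms`, `peak_amp_uv`, `latency_ms`.
#' @export
cohort_sep_summary <- function(sc, mice = seq_len(sc$n_mice),
                               days = seq_len(sc$n_days),
                               conditions = c("all_stim", "hit", "miss")) {
  out <- list()
  for (m in mice) {
    for (d in days) {
      ses <- simulate_session(sc, m, d)
      perf <- session_performance(ses$trials, d)
      rec <- preprocess_lfp(ses$lfp, .stim_times(ses$trials))
      for (area in rec$channel_area) {
        ep <- extract_epochs(rec, ses$trials, area)
        masks <- list(
          all_stim = trial_mask(ep, ses$trials, c("hit", "miss"),
                                exclude_premature = FALSE),
          hit = trial_mask(ep, ses$trials, "hit"),
          miss = trial_mask(ep, ses$trials, "miss"))[conditions]
        for (cn in names(masks)) {
          if (!any(masks[[cn]])) next
          sep <- average_sep(ep, masks[[cn]])
          pk <- find_first_peak(sep, polarity = if (area == "mPFC") 1 else -1)
          out[[length(out) + 1]] <- data.frame(
            mouse = m, day = d, area = area, condition = cn,
            hit_rate = perf$hit_rate, fa_rate = perf$fa_rate,
            dprime = perf$dprime, n_trials = sep$n_trials,
            peak_time_ms = 1000 * pk$peak_time_s,
            peak_amp_uv = pk$peak_amp_uv,
            latency_ms = 1000 * onset_latency(sep))
        }
      }
    }
  }
  do.call(rbind, out)
}

#' In-memory grand-average SEP waveforms for a simulated cohort
#'
#' Pools epochs across the requested sessions per mouse and returns the
#' per-mouse average waveform per area plus the across-mouse grand
#' average.
#'
#' @param sc a [cohort_scenario()].
#' @param mice mouse indices.
#' @param days day indices pooled per mouse.
#' @param condition `"all_stim"`, `"hit"` or `"miss"`.
#' @return list with `time_s`, `per_mouse` (list area -> mice x time
#'   matrix), and `grand` (list area -> `sep_result`-like waveform/sem).
#' @export
cohort_sep_waveforms <- function(sc, mice = seq_len(sc$n_mice), days,
                                 condition = "all_stim") {
  per_area <- NULL
  time_s <- NULL
  for (m in mice) {
    acc <- NULL
    n_acc <- 0
    for (d in days) {
      ses <- simulate_session(sc, m, d)
      rec <- preprocess_lfp(ses$lfp, .stim_times(ses$trials))
      for (area in rec$channel_area) {
        ep <- extract_epochs(rec, ses$trials, area)
        mask <- switch(condition,
                       all_stim = trial_mask(ep, ses$trials, c("hit", "miss"),
                                             exclude_premature = FALSE),
                       hit = trial_mask(ep, ses$trials, "hit"),
                       miss = trial_mask(ep, ses$trials, "miss"))
        if (is.null(acc)) {
          time_s <- ep$time_s
          acc <- stats::setNames(
            rep(list(numeric(length(time_s))), length(rec$channel_area)),
            rec$channel_area)
          nsel <- stats::setNames(numeric(length(rec$channel_area)),
                                  rec$channel_area)
        }
        acc[[area]] <- acc[[area]] + colSums(ep$data[mask, , drop = FALSE])
        nsel[area] <- nsel[area] + sum(mask)
      }
    }
    if (is.null(per_area))
      per_area <- stats::setNames(rep(list(NULL), length(names(acc))),
                                  names(acc))
    for (area in names(acc))
      per_area[[area]] <- rbind(per_area[[area]], acc[[area]] / nsel[area])
  }
  grand <- lapply(per_area, function(mat)
    list(waveform = colMeans(mat),
         sem = apply(mat, 2, sd) / sqrt(nrow(mat)), time_s = time_s))
  list(time_s = time_s, per_mouse = per_area, grand = grand)
}
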
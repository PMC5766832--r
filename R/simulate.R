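# Synthetic cohort generators: behavior, LFP, spikes, and whole cohorts.

#' Evoked-potential kernel (difference of exponentials)
#'
#' `k(t) = 0` before the onset latency; afterwards
#' `exp(-(t-lat)/tau_decay) - exp(-(t-lat)/tau_rise)`, normalized so the peak
#' magnitude is 1. Polarity and microvolt amplitude are applied by the
#' caller.
#'
#' @param t_s time grid in seconds (relative to stimulus onset).
#' @param latency_ms onset latency.
#' @param tau_rise_ms,tau_decay_ms time constants, `0 < rise < decay`.
#' @return numeric vector, unit peak magnitude.
#' @export
sep_kernel <- function(t_s, latency_ms, tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms / 1000
  td <- tau_decay_ms / 1000
  u <- t_s - latency_ms / 1000
  k <- ifelse(u >= 0, exp(-u / td) - exp(-u / tr), 0)
  tpk <- tr * td / (td - tr) * log(td / tr)
  k / (exp(-tpk / td) - exp(-tpk / tr))
}

# Lick-time generator for a responding trial (relative to onset).
# First lick inside the 1 s response window; occasional premature (< 100 ms)
# first licks; a short burst of follow-up licks.
.gen_licks <- function(premature) {
  first <- if (premature) runif(1, 0.02, 0.0999) else runif(1, 0.12, 0.9)
  n_more <- rpois(1, 2)
  sort(c(first, first + cumsum(runif(n_more, 0.08, 0.25))))
}

# One session of behavior for (mouse, day); internal worker.
.sim_session_behavior <- function(sc, mouse, day) {
  set.seed(derive_seed(sc$seed, mouse, day, stream = 1L))
  n <- sc$trials_per_session
  onset <- 10 + cumsum(runif(n, 6, 12))
  kind <- ifelse(runif(n) < 0.5, "stimulus", "catch")
  aborted <- runif(n) < sc$abort_rate
  light <- if (sc$paradigm == "opto_inactivation")
    runif(n) < sc$opto$light_fraction else rep(FALSE, n)

  if (sc$paradigm == "neutral_exposure") {
    p_resp <- rep(sc$neutral_lick_prob, n)
  } else {
    p_hit <- programmed_hit_prob(sc, day)
    p_fa <- sc$learning$fa_rate
    if (sc$paradigm == "opto_inactivation" && !is.null(sc$target_area)) {
      eff_h <- sc$opto$hit_effect[[sc$target_area]] %||% 1
      eff_f <- sc$opto$fa_effect[[sc$target_area]] %||% 1
      p_resp <- ifelse(kind == "stimulus",
                       ifelse(light, p_hit * eff_h, p_hit),
                       ifelse(light, p_fa * eff_f, p_fa))
    } else if (sc$paradigm == "muscimol" && !is.null(sc$target_area) &&
               isTRUE(sc$treated)) {
      eff <- sc$muscimol$hit_effect[[sc$target_area]] %||% 1
      p_resp <- ifelse(kind == "stimulus", p_hit * eff, p_fa)
    } else {
      p_resp <- ifelse(kind == "stimulus", p_hit, p_fa)
    }
  }
  responds <- runif(n) < p_resp & !aborted
  premature <- responds & kind == "stimulus" & runif(n) < sc$premature_rate
  licks <- rep(list(numeric(0)), n)
  for (i in which(responds)) licks[[i]] <- .gen_licks(premature[i])

  tt <- trial_table(seq_len(n), kind, onset, licks,
                    outcome = ifelse(aborted, "aborted", NA_character_),
                    premature = FALSE, light_on = light)
  classify_trials(tt)
}

#' Simulate cohort behavior
#'
#' Generates per-mouse, per-day trial tables under the scenario's paradigm:
#' a day-dependent logistic hit probability and constant false-alarm
#' probability (detection), a stimulus-independent lick process (neutral
#' exposure), or per-area hit-probability multipliers on flagged trials or
#' sessions (opto/muscimol). Deterministic given the scenario seed;
#' per-(mouse, day) substreams make results order-independent.
#'
#' @param sc a [cohort_scenario()].
#' @param mice,days subsets of mouse/day indices (defaults: all).
#' @return nested list `[[mouse]][[day]]` of classified [trial_table()]s.
#' @export
simulate_behavior <- function(sc, mice = seq_len(sc$n_mice),
                              days = seq_len(sc$n_days)) {
  validate_scenario(sc)
  out <- lapply(mice, function(m)
    stats::setNames(lapply(days, function(d) .sim_session_behavior(sc, m, d)),
                    paste0("day", days)))
  stats::setNames(out, sprintf("mouse%02d", mice))
}

#' Simulate a continuous multi-area LFP recording for one session
#'
#' Each delivered stimulus adds, per area, a difference-of-exponentials
#' kernel whose amplitude is `base + gain x day_dprime` (gain forced to zero
#' under neutral exposure), multiplied by the area's `hit_gain` on hit
#' trials, with the configured polarity. Stationary AR(1) Gaussian noise is
#' added, and a 1 ms artifact impulse is injected at every delivered
#' stimulus onset so downstream artifact removal is exercised. Catch trials
#' contribute no kernel or artifact (their virtual onsets are only used for
#' epoching).
#'
#' @param trials classified [trial_table()].
#' @param sc a [cohort_scenario()].
#' @param day_dprime session performance the coupled areas scale with
#'   (typically [programmed_dprime()]).
#' @param seed RNG seed for the noise (set by the caller for cohorts).
#' @return A [continuous_recording()].
#' @export
simulate_lfp <- function(trials, sc, day_dprime = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- sc$fs_hz
  n_samp <- ceiling((max(trials$onset_s) + 5) * fs)
  cfg <- sc$areas
  neutral <- sc$paradigm == "neutral_exposure"

  stim <- trials$kind == "stimulus" & trials$outcome != "aborted"
  onset_idx <- round(trials$onset_s[stim] * fs) + 1L
  is_hit <- trials$outcome[stim] == "hit"
  kt <- seq(0, 0.35, by = 1 / fs)

  mat <- matrix(0, n_samp, nrow(cfg))
  for (j in seq_len(nrow(cfg))) {
    a <- cfg[j, ]
    x <- .ar1_noise(n_samp, sc$noise$ar1, sc$noise$sd_uv)
    gain <- if (neutral) 0 else a$gain_uv_per_dprime
    amp <- (a$base_uv + gain * max(day_dprime, 0)) * a$polarity
    kern <- sep_kernel(kt, a$latency_ms, a$tau_rise_ms, a$tau_decay_ms)
    for (i in seq_along(onset_idx)) {
      g <- if (!neutral && is_hit[i]) a$hit_gain else 1
      idx <- onset_idx[i] + seq_along(kern) - 1L
      keep <- idx <= n_samp
      x[idx[keep]] <- x[idx[keep]] + amp * g * kern[keep]
    }
    # 1 ms stimulus artifact (2 samples at 2 kHz)
    art <- c(outer(onset_idx, 0:max(1, round(0.001 * fs) - 1), `+`))
    art <- art[art <= n_samp]
    x[art] <- x[art] + sc$artifact_uv
    mat[, j] <- x
  }
  continuous_recording(mat, fs, cfg$area, t0_s = 0)
}

# Biphasic stub waveform with the requested trough-to-peak duration.
.make_waveform <- function(dur_ms, fs = 30000) {
  t <- seq(-0.5, 1.5, by = 1000 / fs)  # ms
  -exp(-(t / 0.15)^2) + 0.5 * exp(-((t - dur_ms) / 0.3)^2)
}

#' Simulate a session's spiking population
#'
#' Units are inhomogeneous Poisson processes: a constant baseline rate, plus
#' (for positively modulated units) a rate increase or (negative units) a
#' partial silencing over the 1 s window after each delivered stimulus,
#' deeper on hit than miss trials. Waveform trough-to-peak durations are
#' drawn from a two-component (RSU long / FSU short) Gaussian mixture.
#'
#' @param trials classified [trial_table()].
#' @param sc a [cohort_scenario()].
#' @param seed RNG seed.
#' @return list of [unit_data()] with attribute `"programmed_class"` per
#'   unit (`"positive"`, `"negative"`, `"none"`).
#' @export
simulate_spikes <- function(trials, sc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- sc$spikes
  n_units <- sp$n_units
  if (n_units == 0) return(list())
  t_end <- max(trials$onset_s) + 5
  stim <- trials$kind == "stimulus" & trials$outcome != "aborted"
  stim_on <- trials$onset_s[stim]
  depth_tr <- ifelse(trials$outcome[stim] == "hit",
                     sp$mod_depth, sp$mod_depth * sp$miss_depth_frac)
  # sensory modulation is a learned response: absent under neutral exposure
  if (sc$paradigm == "neutral_exposure") depth_tr[] <- 0

  klass <- sample(rep(c("positive", "negative", "none"),
                      times = c(round(n_units * sp$frac_positive),
                                round(n_units * sp$frac_negative), n_units))[
                                  seq_len(n_units)])
  is_fsu <- runif(n_units) < sp$frac_fsu
  dur <- ifelse(is_fsu, rnorm(n_units, sp$fsu_ms, sp$fsu_sd_ms),
                rnorm(n_units, sp$rsu_ms, sp$rsu_sd_ms))
  dur <- pmax(dur, 0.05)

  units <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    n_base <- rpois(1, sp$baseline_hz * t_end)
    times <- runif(n_base, 0, t_end)
    if (klass[u] == "positive" && length(stim_on)) {
      extra <- rpois(length(stim_on), sp$baseline_hz * depth_tr)
      times <- c(times, rep(stim_on, extra) + runif(sum(extra), 0, 1))
    } else if (klass[u] == "negative" && length(stim_on)) {
      for (i in seq_along(stim_on)) {
        w <- in_window(times, stim_on[i], stim_on[i] + 1)
        drop <- w & runif(length(times)) < depth_tr[i]
        times <- times[!drop]
      }
    }
    units[[u]] <- unit_data(sprintf("u%03d", u), sort(times),
                            .make_waveform(dur[u]), 30000, dur[u], "mPFC")
    attr(units[[u]], "programmed_class") <- klass[u]
  }
  units
}

#' Simulate one full session bundle in memory
#'
#' Behavior, LFP and (optionally) spikes for one (mouse, day) under the
#' scenario's deterministic substreams; the LFP coupling uses the programmed
#' expected d-prime of that day.
#'
#' @param sc a [cohort_scenario()].
#' @param mouse,day indices.
#' @param with_spikes also simulate the spiking population.
#' @return `list(meta, trials, lfp, units)` as from [read_session()].
#' @export
simulate_session <- function(sc, mouse, day, with_spikes = FALSE) {
  trials <- .sim_session_behavior(sc, mouse, day)
  dp <- if (sc$paradigm == "detection") programmed_dprime(sc, day) else 0
  lfp <- simulate_lfp(trials, sc, dp,
                      seed = derive_seed(sc$seed, mouse, day, stream = 2L))
  units <- if (with_spikes)
    simulate_spikes(trials, sc,
                    seed = derive_seed(sc$seed, mouse, day, stream = 3L))
  else list()
  paradigm <- if (sc$paradigm == "neutral_exposure") "neutral_exposure" else "detection"
  manip <- switch(sc$paradigm, opto_inactivation = "opto",
                  muscimol = if (isTRUE(sc$treated)) "muscimol" else "ringer",
                  "none")
  meta <- session_meta(sprintf("mouse%02d", mouse), day, paradigm, manip,
                       sc$target_area %||% NULL)
  list(meta = meta, trials = trials, lfp = lfp, units = units)
}

#' Write a full synthetic cohort to disk
#'
#' One HDF5 session container per (mouse, day) via [write_session()], a CSV
#' trial-table mirror per session, and a manifest CSV.
#'
#' @param sc a [cohort_scenario()].
#' @param out_dir writable output directory (created if missing).
#' @param with_spikes include spiking populations.
#' @return character vector of session file paths (manifest at
#'   `manifest.csv`), invisibly.
#' @export
make_cohort <- function(sc, out_dir, with_spikes = FALSE) {
  validate_scenario(sc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  paths <- character(0)
  for (m in seq_len(sc$n_mice)) {
    for (d in seq_len(sc$n_days)) {
      ses <- simulate_session(sc, m, d, with_spikes = with_spikes)
      stem <- sprintf("mouse%02d_day%02d", m, d)
      p <- file.path(out_dir, paste0(stem, ".h5"))
      write_session(ses$meta, ses$trials, ses$lfp, ses$units, p)
      write_trials_csv(ses$trials, file.path(out_dir, paste0(stem, "_trials.csv")))
      paths <- c(paths, p)
      rows[[stem]] <- data.frame(mouse = m, day = d, paradigm = sc$paradigm,
                                 seed = derive_seed(sc$seed, m, d, 1L),
                                 file = basename(p))
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(paths)
}
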
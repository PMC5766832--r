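# Shared fixtures: small scenarios and hand-built objects.

# Two-area scenario small enough for fast unit tests.
tiny_scenario <- function(..., n_mice = 2, n_days = 2, trials_per_session = 40,
                          areas = area_defaults()[c(1, 6), ], seed = 11) {
  cohort_scenario(n_mice = n_mice, n_days = n_days,
                  trials_per_session = trials_per_session, areas = areas,
                  seed = seed, ...)
}

# Minimal hand-built trial table with licks relative to onset.
make_trials <- function(kinds, licks, onsets = NULL, light = FALSE,
                        outcome = NA_character_) {
  n <- length(kinds)
  onsets <- onsets %||% (10 + 9 * seq_len(n))
  tt <- trial_table(seq_len(n), kinds, onsets, licks, outcome = outcome,
                    light_on = light, validate = FALSE)
  validate_trial_table(tt, check_iti = FALSE)  # fixtures use ad hoc schedules
  tt
}

# Epoch array built directly from a matrix (bypasses the LFP path).
make_epochs <- function(data, fs = 2000, t_start = -0.05, area = "wS1",
                        baseline = c(-0.05, 0)) {
  time_s <- t_start + (seq_len(ncol(data)) - 1) / fs
  structure(list(data = data, time_s = time_s, area = area,
                 trial_ids = seq_len(nrow(data)), fs_hz = fs,
                 baseline = baseline),
            class = "epoch_array")
}

# sep_result from a bare waveform.
make_sep <- function(waveform, fs = 2000, t_start = -0.05,
                     baseline = c(-0.05, 0), area = "wS1") {
  structure(list(waveform = waveform,
                 sem = rep(0, length(waveform)),
                 time_s = t_start + (seq_along(waveform) - 1) / fs,
                 n_trials = 1L, area = area, fs_hz = fs,
                 baseline = baseline),
            class = "sep_result")
}

# Homogeneous-Poisson unit over [0, t_end).
make_poisson_unit <- function(rate_hz, t_end, id = "u001") {
  n <- rpois(1, rate_hz * t_end)
  unit_data(id, sort(runif(n, 0, t_end)), trough_to_peak_ms = 0.6)
}

# Unit with a rate multiplier in [onset, onset + 1) on given onsets.
make_modulated_unit <- function(base_hz, mult, onsets, t_end, id = "u001") {
  n <- rpois(1, base_hz * t_end)
  times <- runif(n, 0, t_end)
  if (mult > 1) {
    extra <- rpois(length(onsets), base_hz * (mult - 1))
    times <- c(times, rep(onsets, extra) + runif(sum(extra)))
  } else if (mult < 1) {
    for (o in onsets) {
      w <- times >= o & times < o + 1
      times <- times[!(w & runif(length(times)) < (1 - mult))]
    }
  }
  unit_data(id, sort(times), trough_to_peak_ms = 0.6)
}
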
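#' Default per-area evoked-kernel and coupling configuration
#'
#' Encodes the qualitative physiology the generator emulates: sensory areas
#' (wS1, wS2, wM1) respond earliest with large, learning-independent negative
#' deflections; PtA is intermediate; dCA1 and mPFC start near zero and grow
#' with performance (amplitude = base + gain x d'), mPFC with positive
#' polarity. `hit_gain` scales the kernel on hit trials relative to misses
#' (1 = no hit/miss difference, as in wS1).
#'
#' Kernels are differences of exponentials; `peak_ms` is derived from the
#' latency and time constants.
#'
#' @return data.frame with one row per area.
#' @export
area_defaults <- function() {
  cfg <- data.frame(
    area = AREAS,
    latency_ms = c(5, 7, 9, 12, 16, 18),
    tau_rise_ms = c(3, 3, 3.5, 4, 4, 5),
    tau_decay_ms = c(15, 18, 22, 25, 30, 35),
    polarity = c(-1, -1, -1, -1, -1, 1),
    base_uv = c(250, 200, 80, 70, 15, 10),
    gain_uv_per_dprime = c(0, 0, 15, 18, 40, 35),
    hit_gain = c(1.0, 1.1, 1.15, 1.2, 1.3, 1.3),
    stringsAsFactors = FALSE)
  tp <- with(cfg, tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
               log(tau_decay_ms / tau_rise_ms))
  cfg$peak_ms <- cfg$latency_ms + tp
  cfg
}

#' Define a synthetic cohort scenario
#'
#' A scenario fixes everything the generator needs: paradigm, cohort size,
#' trial schedule, the logistic learning curve, per-area evoked kernels and
#' their coupling to performance, the AR(1) LFP noise model, the spiking
#' population, and inactivation effects. Defaults emulate the detection-task
#' preparation: 50% catch trials, 6-12 s inter-trial intervals, a 1 s
#' response window, asymptotic hit rate 0.80 against a 0.16 false-alarm rate
#' (trained d' near 2), and one third each of positively and negatively
#' modulated units.
#'
#' @param paradigm `"detection"`, `"neutral_exposure"`, `"opto_inactivation"`
#'   or `"muscimol"`.
#' @param n_mice,n_days,trials_per_session cohort dimensions.
#' @param learning list: `day_half` (day of half-maximal learning),
#'   `slope_days`, `asymptote` (asymptotic hit rate), `fa_rate`.
#' @param areas per-area configuration as from [area_defaults()]; rows may be
#'   dropped to simulate a subset of areas.
#' @param noise list: `sd_uv` (marginal noise SD), `ar1` coefficient.
#' @param spikes list: `n_units`, `frac_positive`, `frac_negative`,
#'   `baseline_hz`, `mod_depth` (rate change in the 1 s post-stimulus window
#'   as a fraction of baseline, on hit trials), `miss_depth_frac` (modulation
#'   on miss relative to hit trials), `frac_fsu`, and waveform
#'   trough-to-peak mixture parameters `rsu_ms`, `rsu_sd_ms`, `fsu_ms`,
#'   `fsu_sd_ms`.
#' @param opto list: `light_fraction` of trials with photo-inhibition,
#'   `hit_effect`/`fa_effect` named per-area multipliers on the hit/FA
#'   probability for light-on trials.
#' @param muscimol list: `hit_effect` per-area multipliers on hit probability
#'   for injected sessions (Ringer control keeps 1).
#' @param fs_hz LFP sampling rate.
#' @param abort_rate probability a scheduled trial is aborted by a lick in
#'   the preceding no-lick window (unreported in this preparation; free).
#' @param premature_rate fraction of hits whose first lick falls before
#'   0.1 s.
#' @param neutral_lick_prob per-trial lick probability in the
#'   neutral-exposure paradigm (stimulus-independent).
#' @param artifact_uv amplitude of the 1 ms stimulus artifact injected at
#'   onset to exercise artifact removal.
#' @param target_area area targeted by an inactivation scenario, or `NULL`.
#' @param treated for the muscimol paradigm: `TRUE` for muscimol-injected
#'   cohorts, `FALSE` for Ringer controls.
#' @param seed master seed; per-(mouse, day) substreams are derived from it.
#' @return A validated `cohort_scenario` object.
#' @export
cohort_scenario <- function(paradigm = "detection",
                            n_mice = 14, n_days = 8, trials_per_session = 200,
                            learning = list(),
                            areas = area_defaults(),
                            noise = list(),
                            spikes = list(),
                            opto = list(),
                            muscimol = list(),
                            fs_hz = 2000,
                            abort_rate = 0.05,
                            premature_rate = 0.04,
                            neutral_lick_prob = 0.2,
                            artifact_uv = 1500,
                            target_area = NULL,
                            treated = FALSE,
                            seed = 1L) {
  learning <- modifyList(list(day_half = 3.0, slope_days = 0.8,
                              asymptote = 0.80, fa_rate = 0.16), learning)
  noise <- modifyList(list(sd_uv = 60, ar1 = 0.95), noise)
  spikes <- modifyList(list(n_units = 50, frac_positive = 1 / 3,
                            frac_negative = 1 / 3, baseline_hz = 5,
                            mod_depth = 0.5, miss_depth_frac = 0.5,
                            frac_fsu = 0.2, rsu_ms = 0.60, rsu_sd_ms = 0.08,
                            fsu_ms = 0.25, fsu_sd_ms = 0.04), spikes)
  full_effect <- stats::setNames(rep(1, length(AREAS)), AREAS)
  opto <- modifyList(list(light_fraction = 0.3,
                          hit_effect = full_effect, fa_effect = full_effect),
                     opto)
  muscimol <- modifyList(list(hit_effect = full_effect), muscimol)
  # peak time is implied by latency and kernel time constants
  areas$peak_ms <- areas$latency_ms +
    areas$tau_rise_ms * areas$tau_decay_ms /
    (areas$tau_decay_ms - areas$tau_rise_ms) *
    log(areas$tau_decay_ms / areas$tau_rise_ms)

  sc <- structure(list(paradigm = paradigm, n_mice = as.integer(n_mice),
                       n_days = as.integer(n_days),
                       trials_per_session = as.integer(trials_per_session),
                       learning = learning, areas = areas, noise = noise,
                       spikes = spikes, opto = opto, muscimol = muscimol,
                       fs_hz = fs_hz, abort_rate = abort_rate,
                       premature_rate = premature_rate,
                       neutral_lick_prob = neutral_lick_prob,
                       artifact_uv = artifact_uv,
                       target_area = target_area, treated = isTRUE(treated),
                       seed = as.integer(seed)),
                  class = "cohort_scenario")
  validate_scenario(sc)
}

#' Validate a cohort scenario
#'
#' @param sc a [cohort_scenario()].
#' @return `sc`, invisibly returned after checking invariants.
#' @export
validate_scenario <- function(sc) {
  if (!sc$paradigm %in% c("detection", "neutral_exposure",
                          "opto_inactivation", "muscimol"))
    stop_field("paradigm", "unknown paradigm '%s'", sc$paradigm)
  if (sc$n_mice < 1) stop_field("n_mice", "must be >= 1")
  if (sc$n_days < 1) stop_field("n_days", "must be >= 1")
  if (sc$trials_per_session < 1) stop_field("trials_per_session", "must be >= 1")
  with(sc$learning, {
    assert_prob(asymptote, "learning$asymptote")
    assert_prob(fa_rate, "learning$fa_rate")
    if (asymptote <= fa_rate)
      stop_field("learning$asymptote", "asymptotic hit rate must exceed the FA rate")
  })
  a <- sc$areas
  if (!all(a$tau_rise_ms > 0 & a$tau_decay_ms > a$tau_rise_ms))
    stop_field("areas", "kernel time constants need 0 < tau_rise < tau_decay")
  if (!all(a$latency_ms < a$peak_ms))
    stop_field("areas", "kernel latency must precede its peak time")
  sp <- sc$spikes
  assert_prob(sp$frac_positive, "spikes$frac_positive")
  assert_prob(sp$frac_negative, "spikes$frac_negative")
  if (sp$frac_positive + sp$frac_negative > 1)
    stop_field("spikes", "modulated fractions must sum to at most 1")
  if (sp$mod_depth < 0 || sp$mod_depth > 1)
    stop_field("spikes$mod_depth", "must be in [0, 1]")
  assert_prob(sc$abort_rate, "abort_rate")
  assert_prob(sc$opto$light_fraction, "opto$light_fraction")
  if (!is.null(sc$target_area) && !sc$target_area %in% AREAS)
    stop_field("target_area", "unknown area '%s'", sc$target_area)
  if (!(abs(sc$noise$ar1) < 1)) stop_field("noise$ar1", "must be in (-1, 1)")
  if (sc$noise$sd_uv < 0) stop_field("noise$sd_uv", "must be >= 0")
  invisible(sc)
}

#' Programmed hit probability on a given training day
#'
#' Logistic learning curve rising from the false-alarm rate to the
#' asymptotic hit rate. Neutral exposure has no learning: the lick
#' probability is stimulus-independent.
#'
#' @param sc a [cohort_scenario()].
#' @param day day index (>= 1).
#' @return hit probability.
#' @export
programmed_hit_prob <- function(sc, day) {
  l <- sc$learning
  l$fa_rate + (l$asymptote - l$fa_rate) *
    plogis((day - l$day_half) / l$slope_days)
}

#' Programmed (expected) d-prime on a given training day
#'
#' Uncorrected `Z(hit) - Z(FA)` at the programmed probabilities; this is the
#' value the LFP generator couples the dCA1/mPFC kernel amplitudes to.
#'
#' @inheritParams programmed_hit_prob
#' @return expected d-prime.
#' @export
programmed_dprime <- function(sc, day) {
  qnorm(programmed_hit_prob(sc, day)) - qnorm(sc$learning$fa_rate)
}

#' Read a scenario from a YAML file
#'
#' Top-level keys mirror the arguments of [cohort_scenario()]; omitted keys
#' keep their defaults. The per-area table may be given as a list of rows
#' under `areas`.
#'
#' @param path YAML file.
#' @return A [cohort_scenario()].
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$areas) && !is.data.frame(y$areas)) {
    y$areas <- do.call(rbind, lapply(y$areas, as.data.frame))
    def <- area_defaults()
    miss <- setdiff(names(def), names(y$areas))
    y$areas[miss] <- def[match(y$areas$area, def$area), miss]
  }
  do.call(cohort_scenario, y)
}
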
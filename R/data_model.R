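#' Construct a trial table
#'
#' One row per scheduled trial. All within-trial times (licks, reward) are in
#' seconds relative to trial onset; `t = 0` is the whisker-stimulus onset for
#' stimulus trials and the scheduled virtual onset for catch trials. Windows
#' throughout the package are half-open `[a, b)`.
#'
#' @param trial_id integer trial identifiers.
#' @param kind `"stimulus"` or `"catch"`.
#' @param onset_s trial onset on the session clock (s), strictly increasing.
#' @param lick_times_s list of numeric vectors of lick times relative to
#'   onset (may be empty).
#' @param outcome `"hit"`, `"miss"`, `"false_alarm"`, `"correct_rejection"`,
#'   `"aborted"`, or `NA` before classification.
#' @param premature logical; first lick earlier than 0.1 s after onset.
#' @param light_on logical; photo-inhibition applied on this trial.
#' @param reward_s reward delivery time relative to onset, or `NA`.
#' @param validate run invariant checks (default `TRUE`).
#' @return A `trial_table` (data.frame with a `lick_times_s` list column).
#' @export
trial_table <- function(trial_id, kind, onset_s, lick_times_s = NULL,
                        outcome = NA_character_, premature = FALSE,
                        light_on = FALSE, reward_s = NA_real_,
                        validate = TRUE) {
  n <- length(trial_id)
  lick_times_s <- lick_times_s %||% rep(list(numeric(0)), n)
  tt <- data.frame(trial_id = as.integer(trial_id),
                   kind = as.character(kind),
                   onset_s = as.numeric(onset_s),
                   outcome = rep_len(as.character(outcome), n),
                   premature = rep_len(as.logical(premature), n),
                   light_on = rep_len(as.logical(light_on), n),
                   reward_s = rep_len(as.numeric(reward_s), n),
                   stringsAsFactors = FALSE)
  tt$lick_times_s <- lapply(lick_times_s, as.numeric)
  class(tt) <- c("trial_table", "data.frame")
  if (validate) validate_trial_table(tt)
  tt
}

TRIAL_OUTCOMES <- c("hit", "miss", "false_alarm", "correct_rejection", "aborted")

#' Validate trial-table invariants
#'
#' Checks onset monotonicity, the 6-12 s inter-trial-interval schedule for
#' non-aborted trials, outcome/kind consistency and the premature-lick rule.
#' Errors name the offending field.
#'
#' @param tt a [trial_table()].
#' @param check_iti verify the 6-12 s inter-onset schedule (default `TRUE`).
#' @return `tt`, invisibly.
#' @export
validate_trial_table <- function(tt, check_iti = TRUE) {
  if (nrow(tt) == 0) return(invisible(tt))
  if (!all(tt$kind %in% c("stimulus", "catch")))
    stop_field("kind", "must be 'stimulus' or 'catch'")
  if (any(diff(tt$onset_s) <= 0))
    stop_field("onset_s", "onset times must be strictly increasing")
  if (check_iti && nrow(tt) > 1) {
    iti <- diff(tt$onset_s)
    ok <- iti >= 6 - 1e-9 & iti <= 12 + 1e-9
    if (!all(ok))
      stop_field("onset_s", "inter-onset interval outside [6, 12] s at trial %d",
                 tt$trial_id[which(!ok)[1] + 1])
  }
  known <- !is.na(tt$outcome)
  if (any(known & !(tt$outcome %in% TRIAL_OUTCOMES)))
    stop_field("outcome", "unknown outcome label")
  bad_stim <- known & tt$kind == "stimulus" &
    tt$outcome %in% c("false_alarm", "correct_rejection")
  bad_catch <- known & tt$kind == "catch" & tt$outcome %in% c("hit", "miss")
  if (any(bad_stim | bad_catch))
    stop_field("outcome", "outcome inconsistent with trial kind at trial %d",
               tt$trial_id[which(bad_stim | bad_catch)[1]])
  first_lick <- vapply(tt$lick_times_s, function(l)
    if (length(l)) min(l) else NA_real_, numeric(1))
  bad_prem <- tt$premature & (is.na(first_lick) | first_lick >= 0.1)
  if (any(bad_prem))
    stop_field("premature", "premature flag requires a first lick < 0.1 s (trial %d)",
               tt$trial_id[which(bad_prem)[1]])
  invisible(tt)
}

#' Construct a continuous multi-channel LFP recording
#'
#' @param samples numeric matrix, samples x channels, in microvolts. Negative
#'   deflections are compatible with membrane depolarization; the mPFC evoked
#'   response is the exception with positive polarity.
#' @param fs_hz sampling rate in Hz (2000 in the reference preparation).
#' @param channel_area character vector mapping each column to an area in
#'   [AREAS]; areas must be unique.
#' @param t0_s session-clock time of the first sample.
#' @return A `continuous_recording` object.
#' @export
continuous_recording <- function(samples, fs_hz, channel_area, t0_s = 0) {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop_field("fs_hz", "sampling rate must be a positive scalar")
  if (length(channel_area) != ncol(samples))
    stop_field("channel_area", "must map every channel (%d channels, %d areas)",
               ncol(samples), length(channel_area))
  if (anyDuplicated(channel_area))
    stop_field("channel_area", "mapped areas must be unique")
  if (!all(channel_area %in% AREAS))
    stop_field("channel_area", "unknown area label")
  structure(list(samples = samples, fs_hz = fs_hz,
                 channel_area = as.character(channel_area),
                 t0_s = as.numeric(t0_s)),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              nrow(x$samples) / x$fs_hz))
  cat(" areas:", paste(x$channel_area, collapse = ", "), "\n")
  invisible(x)
}

#' Session metadata
#'
#' @param mouse_id character mouse identifier.
#' @param day_index training/exposure day, starting at 1.
#' @param paradigm `"detection"` or `"neutral_exposure"`.
#' @param manipulation `"none"`, `"opto"`, `"muscimol"` or `"ringer"`.
#' @param target_area area targeted by the manipulation, or `NULL`.
#' @return A `session_meta` object.
#' @export
session_meta <- function(mouse_id, day_index, paradigm = "detection",
                         manipulation = "none", target_area = NULL) {
  if (!is.numeric(day_index) || day_index < 1)
    stop_field("day_index", "must be >= 1")
  if (!paradigm %in% c("detection", "neutral_exposure"))
    stop_field("paradigm", "unknown paradigm '%s'", paradigm)
  if (!manipulation %in% c("none", "opto", "muscimol", "ringer"))
    stop_field("manipulation", "unknown manipulation '%s'", manipulation)
  if (!is.null(target_area) && !target_area %in% AREAS)
    stop_field("target_area", "unknown area '%s'", target_area)
  structure(list(mouse_id = as.character(mouse_id),
                 day_index = as.integer(day_index),
                 paradigm = paradigm, manipulation = manipulation,
                 target_area = target_area),
            class = "session_meta")
}

#' Single-unit data
#'
#' @param unit_id character identifier.
#' @param spike_times_s sorted, non-negative spike times on the session clock.
#' @param waveform mean spike waveform (arbitrary units).
#' @param waveform_fs_hz waveform sampling rate.
#' @param trough_to_peak_ms waveform trough-to-peak duration (> 0), the basis
#'   of the regular-spiking / fast-spiking classification.
#' @param area recording area.
#' @return A `unit_data` object.
#' @export
unit_data <- function(unit_id, spike_times_s, waveform = numeric(0),
                      waveform_fs_hz = 30000, trough_to_peak_ms, area = "mPFC") {
  spike_times_s <- as.numeric(spike_times_s)
  if (is.unsorted(spike_times_s))
    stop_field("spike_times_s", "spike times must be sorted")
  if (length(spike_times_s) && min(spike_times_s) < 0)
    stop_field("spike_times_s", "spike times must be non-negative")
  if (!is.numeric(trough_to_peak_ms) || trough_to_peak_ms <= 0)
    stop_field("trough_to_peak_ms", "must be > 0")
  if (!area %in% AREAS) stop_field("area", "unknown area '%s'", area)
  structure(list(unit_id = as.character(unit_id),
                 spike_times_s = spike_times_s,
                 waveform = as.numeric(waveform),
                 waveform_fs_hz = waveform_fs_hz,
                 trough_to_peak_ms = as.numeric(trough_to_peak_ms),
                 area = area),
            class = "unit_data")
}

# ---- HDF5 session container -------------------------------------------------
# Layout: /meta (JSON string dataset "json"), /trials (one dataset per column,
# licks ragged as values + per-trial offsets), /lfp (data, fs_hz, areas, t0_s),
# /units/<unit_id> (spike_times_s, waveform, scalars).

#' Write a session bundle to an HDF5 container
#'
#' One file per session with groups `/meta`, `/trials`, `/lfp` and `/units`.
#' All invariants are validated before writing; the trial table can be
#' mirrored to CSV with [write_trials_csv()].
#'
#' @param meta a [session_meta()].
#' @param trials a [trial_table()].
#' @param lfp a [continuous_recording()].
#' @param units list of [unit_data()] (may be empty).
#' @param path output file path (`.h5`).
#' @return `path`, invisibly.
#' @export
write_session <- function(meta, trials, lfp, units, path) {
  validate_trial_table(trials)
  if (!inherits(lfp, "continuous_recording"))
    stop_field("lfp", "must be a continuous_recording")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(as.character(jsonlite::toJSON(unclass(meta),
                                               auto_unbox = TRUE,
                                               null = "null")),
                 path, "meta/json")

  rhdf5::h5createGroup(path, "trials")
  for (col in c("trial_id", "kind", "onset_s", "outcome", "premature",
                "light_on", "reward_s")) {
    v <- trials[[col]]
    if (is.logical(v)) v <- as.integer(v)
    if (col %in% c("outcome")) v <- ifelse(is.na(v), "NA", v)
    rhdf5::h5write(v, path, paste0("trials/", col))
  }
  licks <- trials$lick_times_s
  rhdf5::h5write(unlist(licks) %||% numeric(0), path, "trials/lick_values")
  rhdf5::h5write(as.integer(vapply(licks, length, integer(1))),
                 path, "trials/lick_counts")

  rhdf5::h5createGroup(path, "lfp")
  rhdf5::h5createDataset(path, "lfp/data", dims = dim(lfp$samples),
                         storage.mode = "double", chunk = NULL, level = 0)
  rhdf5::h5write(lfp$samples, path, "lfp/data")
  rhdf5::h5write(lfp$fs_hz, path, "lfp/fs_hz")
  rhdf5::h5write(lfp$channel_area, path, "lfp/channel_area")
  rhdf5::h5write(lfp$t0_s, path, "lfp/t0_s")

  rhdf5::h5createGroup(path, "units")
  for (u in units) {
    g <- paste0("units/", u$unit_id)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(u$spike_times_s, path, paste0(g, "/spike_times_s"))
    rhdf5::h5write(u$waveform, path, paste0(g, "/waveform"))
    rhdf5::h5write(u$waveform_fs_hz, path, paste0(g, "/waveform_fs_hz"))
    rhdf5::h5write(u$trough_to_peak_ms, path, paste0(g, "/trough_to_peak_ms"))
    rhdf5::h5write(u$area, path, paste0(g, "/area"))
  }
  invisible(path)
}

#' Read a session bundle from an HDF5 container
#'
#' Inverse of [write_session()]; all invariants are re-validated on load.
#'
#' @param path file written by [write_session()] or conforming to its layout.
#' @return `list(meta, trials, lfp, units)`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  have <- function(name) name %in% paste0(contents$group, "/", contents$name) |
    name %in% sub("^//", "/", paste0(contents$group, "/", contents$name))
  for (req in c("/meta/json", "/lfp/data", "/lfp/fs_hz", "/lfp/channel_area",
                "/trials/trial_id")) {
    if (!have(req))
      stop(sprintf("format error: missing dataset '%s' in %s", req, path),
           call. = FALSE)
  }
  mj <- jsonlite::fromJSON(rhdf5::h5read(path, "meta/json"))
  meta <- session_meta(mj$mouse_id, mj$day_index, mj$paradigm,
                       mj$manipulation, mj$target_area)

  rd <- function(n) as.vector(rhdf5::h5read(path, n))
  counts <- rd("trials/lick_counts")
  values <- rd("trials/lick_values")
  if (sum(counts) != length(values))
    stop("format error: lick offsets inconsistent with values", call. = FALSE)
  licks <- split(values, rep(seq_along(counts), counts))
  all_licks <- rep(list(numeric(0)), length(counts))
  all_licks[as.integer(names(licks))] <- licks
  outcome <- rd("trials/outcome")
  outcome[outcome == "NA"] <- NA_character_
  trials <- trial_table(rd("trials/trial_id"), rd("trials/kind"),
                        rd("trials/onset_s"), all_licks, outcome,
                        as.logical(rd("trials/premature")),
                        as.logical(rd("trials/light_on")),
                        rd("trials/reward_s"))

  dat <- rhdf5::h5read(path, "lfp/data")
  lfp <- continuous_recording(dat, rd("lfp/fs_hz"), rd("lfp/channel_area"),
                              rd("lfp/t0_s"))

  unit_ids <- contents$name[contents$group == "/units" & contents$otype == "H5I_GROUP"]
  units <- lapply(unit_ids, function(uid) {
    g <- paste0("units/", uid)
    unit_data(uid, rd(paste0(g, "/spike_times_s")), rd(paste0(g, "/waveform")),
              rd(paste0(g, "/waveform_fs_hz")),
              rd(paste0(g, "/trough_to_peak_ms")), rd(paste0(g, "/area")))
  })
  list(meta = meta, trials = trials, lfp = lfp, units = units)
}

#' Export a trial table to CSV
#'
#' Human-readable mirror of the HDF5 trial group with columns `trial_id`,
#' `kind`, `onset_s`, `outcome`, `premature`, `light_on`, `first_lick_s`.
#' The full ragged lick list lives only in the HDF5 container.
#'
#' @param tt a [trial_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(tt, path) {
  first_lick <- vapply(tt$lick_times_s, function(l)
    if (length(l)) min(l) else NA_real_, numeric(1))
  df <- data.frame(trial_id = tt$trial_id, kind = tt$kind,
                   onset_s = tt$onset_s, outcome = tt$outcome,
                   premature = tt$premature, light_on = tt$light_on,
                   first_lick_s = first_lick)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a trial table exported by [write_trials_csv()]
#'
#' Lick lists are reconstructed from `first_lick_s` alone (a single lick per
#' responding trial); outcome and flags are lossless.
#'
#' @param path CSV path.
#' @return A [trial_table()].
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  licks <- lapply(df$first_lick_s, function(t)
    if (is.na(t)) numeric(0) else t)
  trial_table(df$trial_id, df$kind, df$onset_s, licks, df$outcome,
              df$premature, df$light_on)
}
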
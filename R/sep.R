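# Sensory-evoked potential extraction, measurement and comparison.

#' Preprocess a continuous LFP recording
#'
#' The stimulus artifact is blanked by linear interpolation over a short
#' window after each stimulus onset, then every channel is band-pass
#' filtered 0.1-100 Hz with a 4th-order Butterworth applied
#' forward-backward (zero phase).
#'
#' @param rec a [continuous_recording()].
#' @param stim_times_s delivered-stimulus onsets on the session clock.
#' @param band filter band in Hz.
#' @param artifact_ms blanking window relative to onset (ms), half-open.
#' @return the filtered [continuous_recording()].
#' @export
preprocess_lfp <- function(rec, stim_times_s, band = c(0.1, 100),
                           artifact_ms = c(0, 2)) {
  fs <- rec$fs_hz
  if (fs < 500) stop("preprocessing assumes fs >= 500 Hz", call. = FALSE)
  n <- nrow(rec$samples)
  idx0 <- round((stim_times_s - rec$t0_s) * fs) + 1L
  if (length(idx0) && (min(idx0) < 1 || max(idx0) > n))
    stop("stimulus time outside recording", call. = FALSE)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  out <- rec$samples
  a0 <- round(artifact_ms[1] / 1000 * fs)
  a1 <- round(artifact_ms[2] / 1000 * fs)
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    for (i in idx0) {
      lo <- max(i + a0 - 1L, 1L)       # last clean sample before the window
      hi <- min(i + a1, n)             # first clean sample after it
      if (hi > lo + 1L)
        x[(lo + 1L):(hi - 1L)] <- x[lo] + (x[hi] - x[lo]) *
          seq_len(hi - lo - 1L) / (hi - lo)
    }
    out[, j] <- .iir_filtfilt(bf$b, bf$a, x)
  }
  continuous_recording(out, fs, rec$channel_area, rec$t0_s)
}

#' Extract baseline-corrected epochs around trial onsets
#'
#' Per-trial slices of one channel, each minus its own mean over the
#' baseline window (the 50 ms preceding onset by default). Catch trials are
#' epoched on their scheduled virtual onsets. Trials whose window exceeds
#' the recording bounds are dropped with a warning.
#'
#' @param rec a preprocessed [continuous_recording()].
#' @param trials a classified [trial_table()] (aborted trials are skipped).
#' @param area channel to extract.
#' @param window epoch window (s relative to onset), half-open.
#' @param baseline baseline-correction window (s), half-open.
#' @return An `epoch_array`: `data` (trials x time, uV), `time_s`, `area`,
#'   `trial_ids`, `fs_hz`, `baseline`.
#' @export
extract_epochs <- function(rec, trials, area, window = c(-0.05, 0.3),
                           baseline = c(-0.05, 0)) {
  fs <- rec$fs_hz
  ch <- match(area, rec$channel_area)
  if (is.na(ch)) stop_field("area", "'%s' not in recording", area)
  keep <- is.na(trials$outcome) | trials$outcome != "aborted"
  tt <- trials[keep, ]
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  time_s <- rel / fs
  bl <- in_window(time_s, baseline[1], baseline[2])
  n <- nrow(rec$samples)
  onset_idx <- round((tt$onset_s - rec$t0_s) * fs) + 1L
  ok <- onset_idx + rel[1] >= 1L & onset_idx + rel[length(rel)] <= n
  if (!all(ok))
    warning(sprintf("%d trial(s) dropped: epoch exceeds recording bounds",
                    sum(!ok)), call. = FALSE)
  tt <- tt[ok, ]
  onset_idx <- onset_idx[ok]
  dat <- matrix(0, nrow(tt), length(rel))
  x <- rec$samples[, ch]
  for (i in seq_len(nrow(tt))) {
    ep <- x[onset_idx[i] + rel]
    dat[i, ] <- ep - mean(ep[bl])
  }
  structure(list(data = dat, time_s = time_s, area = area,
                 trial_ids = tt$trial_id, fs_hz = fs, baseline = baseline),
            class = "epoch_array")
}

#' Logical trial mask over an epoch array
#'
#' Maps outcome/light conditions from the trial table onto the rows of an
#' [extract_epochs()] result. Hit masks exclude premature-lick trials by
#' default, since such licks may reflect chance licking rather than
#' detection.
#'
#' @param epochs an `epoch_array`.
#' @param trials the trial table the epochs were cut from.
#' @param outcome outcome label(s) to keep, or `NULL` for all.
#' @param exclude_premature drop premature hits (default `TRUE`).
#' @param light `"all"`, `"off"` or `"on"`.
#' @return logical vector over epochs.
#' @export
trial_mask <- function(epochs, trials, outcome = NULL,
                       exclude_premature = TRUE, light = c("all", "off", "on")) {
  light <- match.arg(light)
  tt <- trials[match(epochs$trial_ids, trials$trial_id), ]
  m <- rep(TRUE, nrow(tt))
  if (!is.null(outcome)) m <- m & tt$outcome %in% outcome
  if (exclude_premature) m <- m & !tt$premature
  if (light == "off") m <- m & !tt$light_on
  if (light == "on") m <- m & tt$light_on
  m
}

#' Average epochs into a sensory-evoked potential
#'
#' Pointwise mean and standard error over the selected trials.
#'
#' @param epochs an `epoch_array`.
#' @param mask logical/integer selection of trials (default: all).
#' @return A `sep_result`: `waveform`, `sem`, `time_s`, `n_trials`, `area`,
#'   `fs_hz`, `baseline`.
#' @export
average_sep <- function(epochs, mask = NULL) {
  dat <- epochs$data
  if (!is.null(mask)) dat <- dat[mask, , drop = FALSE]
  if (nrow(dat) == 0) stop("no trials selected for averaging", call. = FALSE)
  structure(list(waveform = colMeans(dat),
                 sem = apply(dat, 2, sd) / sqrt(nrow(dat)),
                 time_s = epochs$time_s, n_trials = nrow(dat),
                 area = epochs$area, fs_hz = epochs$fs_hz,
                 baseline = epochs$baseline),
            class = "sep_result")
}

#' @export
print.sep_result <- function(x, ...) {
  pk <- find_first_peak(x, polarity = if (x$area == "mPFC") 1 else -1)
  cat(sprintf("<sep_result> %s, n = %d trials, %.0f-%.0f ms\n", x$area,
              x$n_trials, 1000 * min(x$time_s), 1000 * max(x$time_s)))
  if (is.na(pk$peak_time_s)) cat(" no qualifying first peak\n")
  else cat(sprintf(" first peak: %.1f ms, %.1f uV\n",
                   1000 * pk$peak_time_s, pk$peak_amp_uv))
  invisible(x)
}

.baseline_sd <- function(sep) {
  bl <- in_window(sep$time_s, sep$baseline[1], sep$baseline[2])
  sd(sep$waveform[bl])
}

#' First peak of an evoked potential
#'
#' Earliest local extremum of the requested polarity inside the search
#' window whose magnitude exceeds `k_sd` times the baseline-period SD of
#' the waveform. Returns an explicit no-peak result (`NA` fields) when
#' nothing qualifies.
#'
#' @param sep a `sep_result`.
#' @param polarity `+1` (mPFC-like positive deflection) or `-1`.
#' @param search search window in seconds.
#' @param k_sd magnitude gate in baseline SDs.
#' @return list `(peak_time_s, peak_amp_uv)`; `NA`s if no peak qualifies.
#' @export
find_first_peak <- function(sep, polarity = -1, search = c(0.003, 0.1),
                            k_sd = 2) {
  w <- sep$waveform * polarity          # search positive-going extrema
  thr <- k_sd * .baseline_sd(sep)
  n <- length(w)
  idx <- which(in_window(sep$time_s, search[1], search[2]))
  idx <- idx[idx > 1 & idx < n]
  for (i in idx) {
    if (w[i] >= w[i - 1] && w[i] >= w[i + 1] && w[i] > thr)
      return(list(peak_time_s = sep$time_s[i],
                  peak_amp_uv = sep$waveform[i]))
  }
  list(peak_time_s = NA_real_, peak_amp_uv = NA_real_)
}

#' Waveform amplitude at a reference time
#'
#' Value at the sample nearest `t_ref_s`. Used to compare conditions (D1 vs
#' Trained, Hit vs Miss) at the peak time measured in the reference
#' condition.
#'
#' @param sep a `sep_result`.
#' @param t_ref_s reference time (s) within the waveform support.
#' @return amplitude in microvolts.
#' @export
measure_at <- function(sep, t_ref_s) {
  if (t_ref_s < min(sep$time_s) || t_ref_s > max(sep$time_s))
    stop("reference time outside waveform support", call. = FALSE)
  sep$waveform[which.min(abs(sep$time_s - t_ref_s))]
}

#' Evoked-response onset latency
#'
#' First time after onset at which the absolute waveform exceeds
#' `k_sd` baseline SDs for at least `min_run_ms` consecutively. This
#' threshold-crossing estimator is a documented convention of this package.
#'
#' @param sep a `sep_result`.
#' @param k_sd threshold in baseline SDs.
#' @param min_run_ms minimum supra-threshold run length.
#' @return latency in seconds, or `NA` if never exceeded.
#' @export
onset_latency <- function(sep, k_sd = 2, min_run_ms = 5) {
  thr <- k_sd * .baseline_sd(sep)
  run <- max(1L, round(min_run_ms / 1000 * sep$fs_hz))
  above <- abs(sep$waveform) > thr & sep$time_s >= 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run)
  if (length(hit) == 0) return(NA_real_)
  sep$time_s[starts[hit[1]]]
}

#' Windowed paired Wilcoxon comparison of two conditions
#'
#' For consecutive time windows (5 ms by default), the per-mouse mean
#' amplitude in the window is computed for each condition and the paired
#' Wilcoxon signed-rank test is run across mice. P-values are reported per
#' window without multiple-comparison correction, mirroring per-window
#' color-coded significance displays.
#'
#' @param pairs list (one element per mouse) of `list(a = , b = )`
#'   waveforms on a common time grid.
#' @param time_s the common time grid (s).
#' @param win_ms window length (ms).
#' @return data.frame with window centers `t_s` and two-sided `p`.
#' @export
windowed_paired_test <- function(pairs, time_s, win_ms = 5) {
  n_mice <- length(pairs)
  if (n_mice < 2) stop("need at least two mice for a paired test",
                       call. = FALSE)
  if (n_mice < 5)
    warning("fewer than 5 mice: the signed-rank test cannot reach p < 0.05",
            call. = FALSE)
  len <- length(time_s)
  dt <- time_s[2] - time_s[1]
  wn <- max(1L, round(win_ms / 1000 / dt))
  starts <- seq(1L, len - wn + 1L, by = wn)
  amat <- do.call(rbind, lapply(pairs, `[[`, "a"))
  bmat <- do.call(rbind, lapply(pairs, `[[`, "b"))
  res <- vapply(starts, function(s) {
    cols <- s:(s + wn - 1L)
    wilcoxon_signed_rank(rowMeans(amat[, cols, drop = FALSE]),
                         rowMeans(bmat[, cols, drop = FALSE]))$p
  }, numeric(1))
  data.frame(t_s = time_s[starts] + (wn / 2) * dt, p = res)
}

#' Correlation between SEP peak amplitude and performance
#'
#' Pearson correlation (with its t statistic) between day-by-day peak
#' amplitudes and d-prime, pooled over (mouse, day) points.
#'
#' @param df data.frame with columns `peak_amp` and `dprime`.
#' @return list `(r, p, n)`.
#' @export
peak_vs_dprime_correlation <- function(df) {
  x <- df$peak_amp
  y <- df$dprime
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare evoked-response latencies across areas
#'
#' Delegates per-mouse latencies (or peak times) by area to
#' [dunn_holland_wolfe()].
#'
#' @param lat_by_area named list, one numeric vector of per-mouse values
#'   per area.
#' @param alpha family-wise level.
#' @return A `pairwise_result`.
#' @export
latency_ordering_test <- function(lat_by_area, alpha = 0.05) {
  dunn_holland_wolfe(lat_by_area, alpha = alpha)
}
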
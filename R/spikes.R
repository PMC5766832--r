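# PSTHs, unit classification, bootstrap modulation tests, hit/miss contrasts.

#' Classify a unit as regular- or fast-spiking
#'
#' Waveform trough-to-peak durations separate putative pyramidal cells
#' (regular-spiking units, RSU, long) from putative inhibitory interneurons
#' (fast-spiking units, FSU, short). Durations equal to the threshold count
#' as RSU.
#'
#' @param trough_to_peak_ms waveform duration(s), > 0.
#' @param threshold_ms class boundary (default 0.35 ms, configurable).
#' @return `"RSU"` or `"FSU"` (vectorized).
#' @export
classify_unit <- function(trough_to_peak_ms, threshold_ms = 0.35) {
  if (any(trough_to_peak_ms <= 0))
    stop_field("trough_to_peak_ms", "must be > 0")
  ifelse(trough_to_peak_ms >= threshold_ms, "RSU", "FSU")
}

# Spike counts per onset inside [w1, w2) relative to each onset.
.counts_in_window <- function(spikes, onsets, w1, w2) {
  vapply(onsets, function(o)
    sum(in_window(spikes, o + w1, o + w2)), numeric(1))
}

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate around trial onsets: pooled spike counts per
#' bin divided by `n_trials x bin width`.
#'
#' @param unit a [unit_data()].
#' @param onsets_s trial onsets (session clock, s).
#' @param window PSTH window (s relative to onset), half-open.
#' @param bin_ms bin width (ms).
#' @return A `psth` object: `t_s` (bin centers), `rate_hz`, `bin_s`,
#'   `n_trials`.
#' @export
psth <- function(unit, onsets_s, window = c(-1, 2), bin_ms = 10) {
  if (length(onsets_s) == 0) stop("need at least one onset", call. = FALSE)
  bin_s <- bin_ms / 1000
  breaks <- seq(window[1], window[2], by = bin_s)
  counts <- numeric(length(breaks) - 1)
  sp <- unit$spike_times_s
  for (o in onsets_s) {
    rel <- sp[in_window(sp, o + window[1], o + window[2])] - o
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, breaks,
                                               rightmost.closed = FALSE),
                                  nbins = length(counts))
  }
  structure(list(t_s = breaks[-length(breaks)] + bin_s / 2,
                 rate_hz = counts / (length(onsets_s) * bin_s),
                 bin_s = bin_s, n_trials = length(onsets_s)),
            class = "psth")
}

#' Z-score a PSTH against its baseline
#'
#' `(rate - baseline mean) / baseline SD` per bin, baseline taken over the
#' pre-onset second by default.
#'
#' @param curve a [psth()].
#' @param baseline baseline window (s), half-open.
#' @return numeric z-scored rate curve (same bins).
#' @export
zscore_psth <- function(curve, baseline = c(-1, 0)) {
  bl <- in_window(curve$t_s, baseline[1], baseline[2])
  mu <- mean(curve$rate_hz[bl])
  sdv <- sd(curve$rate_hz[bl])
  if (!is.finite(sdv) || sdv == 0)
    stop("zero baseline SD: widen the baseline or exclude the unit",
         call. = FALSE)
  (curve$rate_hz - mu) / sdv
}

#' Bootstrap test for stimulus-evoked firing-rate modulation
#'
#' Per hit trial, the firing-rate difference between the 1 s window after
#' and the 1 s window before trial onset. Trials are resampled with
#' replacement `n_boot` times; `p_pos` is the fraction of bootstrap mean
#' differences at or below zero, `p_neg` at or above zero. The unit is
#' classed positive if `p_pos < alpha / 2`, negative if `p_neg < alpha / 2`
#' (two-sided level `alpha` overall), otherwise unmodulated.
#'
#' @param unit a [unit_data()].
#' @param hit_onsets_s onsets of the hit trials used for the test.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed (deterministic result).
#' @param alpha two-sided significance level.
#' @return A `modulation_result`: `unit_id`, `mean_pre_hz`, `mean_post_hz`,
#'   `delta_hz`, `p_boot` (two-sided), `klass`.
#' @export
modulation_test <- function(unit, hit_onsets_s, n_boot = 1000, seed = NULL,
                            alpha = 0.05) {
  n <- length(hit_onsets_s)
  if (n < 10) stop("need at least 10 trials for the bootstrap test",
                   call. = FALSE)
  post <- .counts_in_window(unit$spike_times_s, hit_onsets_s, 0, 1)
  pre <- .counts_in_window(unit$spike_times_s, hit_onsets_s, -1, 0)
  d <- post - pre                      # Hz: 1 s windows
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  bm <- colMeans(matrix(d[idx], nrow = n))
  p_pos <- mean(bm <= 0)
  p_neg <- mean(bm >= 0)
  klass <- "none"
  if (p_pos < alpha / 2 && mean(d) > 0) klass <- "positive"
  if (p_neg < alpha / 2 && mean(d) < 0) klass <- "negative"
  structure(list(unit_id = unit$unit_id, mean_pre_hz = mean(pre),
                 mean_post_hz = mean(post), delta_hz = mean(d),
                 p_boot = min(1, 2 * min(p_pos, p_neg)), klass = klass),
            class = "modulation_result")
}

#' Hit-versus-miss firing-rate contrast for one unit
#'
#' Difference of mean post-onset (0-1 s) firing rates between hit and miss
#' trials, with two-sided significance from `n_perm` random permutations of
#' the trial labels.
#'
#' @param unit a [unit_data()].
#' @param hit_onsets_s,miss_onsets_s onsets per class (>= 5 each).
#' @param n_perm label permutations.
#' @param seed RNG seed.
#' @param alpha significance level.
#' @return list `(delta_hz, p, significant)`.
#' @export
hit_miss_unit_test <- function(unit, hit_onsets_s, miss_onsets_s,
                               n_perm = 1000, seed = NULL, alpha = 0.05) {
  nh <- length(hit_onsets_s); nm <- length(miss_onsets_s)
  if (nh < 5 || nm < 5)
    stop("need at least 5 trials per class", call. = FALSE)
  rh <- .counts_in_window(unit$spike_times_s, hit_onsets_s, 0, 1)
  rm_ <- .counts_in_window(unit$spike_times_s, miss_onsets_s, 0, 1)
  obs <- mean(rh) - mean(rm_)
  pool <- c(rh, rm_)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    lab <- sample.int(nh + nm, nh)
    mean(pool[lab]) - mean(pool[-lab])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
  list(delta_hz = obs, p = p, significant = p < alpha)
}

#' Population fractions of modulated units
#'
#' @param results list of [modulation_test()] results.
#' @return data.frame with counts and fractions of positively, negatively
#'   and non-modulated units.
#' @export
population_summary <- function(results) {
  if (length(results) == 0) stop("no units", call. = FALSE)
  klass <- vapply(results, `[[`, character(1), "klass")
  n <- length(klass)
  data.frame(klass = c("positive", "negative", "none"),
             n = c(sum(klass == "positive"), sum(klass == "negative"),
                   sum(klass == "none")),
             fraction = c(mean(klass == "positive"),
                          mean(klass == "negative"), mean(klass == "none")))
}
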
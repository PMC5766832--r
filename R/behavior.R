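# Trial classification, signal-detection performance, session selection.

#' Classify trial outcomes from lick times
#'
#' A stimulus trial with at least one lick in the 1 s response window
#' `[0, 1)` s is a hit, otherwise a miss; a catch trial with a lick in the
#' window is a false alarm, otherwise a correct rejection. Hits whose first
#' lick falls before 0.1 s are flagged premature (they may reflect chance
#' licking rather than detection); trials already marked aborted are left
#' untouched.
#'
#' @param tt a [trial_table()] with lick times present.
#' @param response_window response window in seconds, half-open.
#' @param premature_s premature-lick threshold after onset.
#' @return the trial table with `outcome` and `premature` filled.
#' @export
classify_trials <- function(tt, response_window = c(0, 1), premature_s = 0.1) {
  if (any(is.na(tt$onset_s)))
    stop_field("onset_s", "missing trial onset")
  lick_in <- vapply(tt$lick_times_s, function(l)
    any(in_window(l, response_window[1], response_window[2])), logical(1))
  first_lick <- vapply(tt$lick_times_s, function(l)
    if (length(l)) min(l) else NA_real_, numeric(1))
  active <- is.na(tt$outcome) | tt$outcome != "aborted"
  tt$outcome[active] <- ifelse(tt$kind[active] == "stimulus",
                               ifelse(lick_in[active], "hit", "miss"),
                               ifelse(lick_in[active], "false_alarm",
                                      "correct_rejection"))
  tt$premature <- active & tt$outcome == "hit" &
    !is.na(first_lick) & first_lick < premature_s
  validate_trial_table(tt, check_iti = FALSE)
  tt
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = Z(hit rate) - Z(FA rate)` with `Z` the inverse standard-normal CDF.
#' The loglinear correction (`(n_hit + 0.5) / (n_stim + 1)`, likewise for
#' false alarms) is applied systematically by default so extreme rates (0 or
#' 1) yield finite values.
#'
#' @param n_hit,n_stim hit and stimulus-trial counts.
#' @param n_fa,n_catch false-alarm and catch-trial counts.
#' @param loglinear apply the loglinear correction (default `TRUE`).
#' @return d-prime (finite whenever the correction is applied).
#' @export
dprime <- function(n_hit, n_stim, n_fa, n_catch, loglinear = TRUE) {
  if (any(n_stim < 1) || any(n_catch < 1))
    stop("d-prime requires at least one stimulus and one catch trial",
         call. = FALSE)
  if (loglinear) {
    hr <- (n_hit + 0.5) / (n_stim + 1)
    fr <- (n_fa + 0.5) / (n_catch + 1)
  } else {
    hr <- n_hit / n_stim
    fr <- n_fa / n_catch
    if (any(hr <= 0 | hr >= 1 | fr <= 0 | fr >= 1))
      stop("rate of 0 or 1 gives infinite d-prime; use the loglinear correction",
           call. = FALSE)
  }
  inverse_normal_cdf(hr) - inverse_normal_cdf(fr)
}

#' Summarize session performance
#'
#' Hit and false-alarm rates over non-aborted trials plus the
#' loglinear-corrected d-prime. Premature hits count toward the hit rate
#' (their exclusion applies only to evoked-response averaging).
#'
#' @param tt a classified [trial_table()].
#' @param day_index training day carried into the summary.
#' @param light restrict to `"all"`, light-`"off"` or light-`"on"` trials.
#' @return A `session_performance` one-row data.frame: counts, rates,
#'   `dprime`, `day_index`.
#' @export
session_performance <- function(tt, day_index = NA_integer_,
                                light = c("all", "off", "on")) {
  light <- match.arg(light)
  keep <- !is.na(tt$outcome) & tt$outcome != "aborted"
  if (light == "off") keep <- keep & !tt$light_on
  if (light == "on") keep <- keep & tt$light_on
  if (!any(keep)) stop("no classified, non-aborted trials in session",
                       call. = FALSE)
  tt <- tt[keep, ]
  n_stim <- sum(tt$kind == "stimulus")
  n_catch <- sum(tt$kind == "catch")
  if (n_catch == 0) stop("session has no catch trials; rates undefined",
                         call. = FALSE)
  if (n_stim == 0) stop("session has no stimulus trials; rates undefined",
                        call. = FALSE)
  n_hit <- sum(tt$outcome == "hit")
  n_fa <- sum(tt$outcome == "false_alarm")
  out <- data.frame(n_stim = n_stim, n_catch = n_catch, n_hit = n_hit,
                    n_fa = n_fa, hit_rate = n_hit / n_stim,
                    fa_rate = n_fa / n_catch,
                    dprime = dprime(n_hit, n_stim, n_fa, n_catch),
                    day_index = as.integer(day_index))
  class(out) <- c("session_performance", "data.frame")
  out
}

#' Select trained sessions for evoked-response analysis
#'
#' The first three days satisfying `day_index > 4` and `d' > 1`. If fewer
#' than three qualify, those that do are returned with a warning.
#'
#' @param perf data.frame with `day_index` and `dprime` (e.g. rbind-ed
#'   [session_performance()] rows), sorted by day.
#' @return integer vector of selected day indices.
#' @export
select_trained_sessions <- function(perf) {
  if (is.null(nrow(perf)) || nrow(perf) == 0)
    stop("empty performance table", call. = FALSE)
  ok <- perf$day_index > 4 & perf$dprime > 1
  sel <- perf$day_index[ok]
  if (length(sel) < 3)
    warning(sprintf("only %d day(s) meet the trained criteria (day > 4, d' > 1)",
                    length(sel)), call. = FALSE)
  utils::head(sel, 3)
}

#' Select exposed sessions (neutral-exposure paradigm)
#'
#' The last three days of neutral exposure.
#'
#' @param n_days number of exposure days (>= 3).
#' @return integer vector of the last three day indices.
#' @export
select_exposed_sessions <- function(n_days) {
  if (n_days < 3) stop("need at least 3 exposure days", call. = FALSE)
  (n_days - 2L):n_days
}
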
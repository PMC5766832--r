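# Sliding-window ROC "Stimulus Probability" decoding from single-trial LFP.

#' Sliding-window mean-amplitude features
#'
#' Mean LFP amplitude in windows of `win_ms` slid by `step_ms`, starting at
#' the epoch start; each window `[t, t + win)` is labeled by its center.
#'
#' @param epochs an `epoch_array` from [extract_epochs()].
#' @param win_ms window length (ms).
#' @param step_ms step between window starts (ms).
#' @return matrix trials x windows with attribute `"time_s"` (window
#'   centers).
#' @export
window_features <- function(epochs, win_ms = 10, step_ms = 2.5) {
  fs <- epochs$fs_hz
  wn <- win_ms / 1000 * fs
  sn <- step_ms / 1000 * fs
  if (abs(wn - round(wn)) > 1e-8 || abs(sn - round(sn)) > 1e-8)
    stop(sprintf(paste("window/step must be whole samples: at fs = %g Hz the",
                       "sample period is %g ms"), fs, 1000 / fs), call. = FALSE)
  wn <- as.integer(round(wn)); sn <- as.integer(round(sn))
  len <- length(epochs$time_s)
  if (wn > len) stop("epoch shorter than one window", call. = FALSE)
  starts <- seq(1L, len - wn + 1L, by = sn)
  wmat <- matrix(0, len, length(starts))
  for (j in seq_along(starts)) wmat[starts[j]:(starts[j] + wn - 1L), j] <- 1 / wn
  feat <- epochs$data %*% wmat
  attr(feat, "time_s") <- epochs$time_s[starts] + (win_ms / 2) / 1000
  feat
}

#' Area under the ROC curve (stimulus vs catch)
#'
#' Probability that a stimulus-trial value exceeds a catch-trial value,
#' ties counted one half: `(#(s > c) + 0.5 #(s = c)) / (n_s n_c)`.
#' Computed from joint ranks; identical to the Mann-Whitney U statistic
#' divided by `n_s n_c`.
#'
#' @param stim_values,catch_values feature values per class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(stim_values, catch_values) {
  ns <- length(stim_values); nc <- length(catch_values)
  if (ns == 0 || nc == 0) stop("both classes must be non-empty", call. = FALSE)
  r <- rank(c(stim_values, catch_values))
  (sum(r[seq_len(ns)]) - ns * (ns + 1) / 2) / (ns * nc)
}

#' Time-resolved stimulus probability with shuffle chance band
#'
#' For every sliding window, the ROC area between stimulus- and catch-trial
#' mean amplitudes ("stimulus probability", SP). Chance level is estimated
#' by permuting trial labels within the session `n_shuffle` times;
#' deterministic given `seed`.
#'
#' @param epochs an `epoch_array` containing both trial classes.
#' @param labels character/logical per epoch: `"stimulus"`/`"catch"` or
#'   `TRUE` for stimulus.
#' @param n_shuffle number of label permutations.
#' @param seed RNG seed for the permutations.
#' @param win_ms,step_ms window parameters (see [window_features()]).
#' @return An `sp_curve`: data.frame fields `time_s`, `sp`, `shuffle_mean`,
#'   `shuffle_sd`, plus counts `n_stim`, `n_catch`.
#' @export
sp_curve <- function(epochs, labels, n_shuffle = 100, seed = NULL,
                     win_ms = 10, step_ms = 2.5) {
  if (is.character(labels)) labels <- labels == "stimulus"
  labels <- as.logical(labels)
  ns <- sum(labels); nc <- sum(!labels)
  if (ns == 0 || nc == 0) stop("both classes must be present", call. = FALSE)
  feat <- window_features(epochs, win_ms, step_ms)
  time_s <- attr(feat, "time_s")
  rk <- apply(feat, 2, rank)                      # trials x windows
  u0 <- colSums(rk[labels, , drop = FALSE]) - ns * (ns + 1) / 2
  sp <- u0 / (ns * nc)
  if (!is.null(seed)) set.seed(seed)
  perm <- matrix(0, nrow(feat), n_shuffle)
  for (s in seq_len(n_shuffle)) perm[sample.int(nrow(feat), ns), s] <- 1
  usums <- crossprod(rk, perm) - ns * (ns + 1) / 2  # windows x shuffles
  aucs <- usums / (ns * nc)
  structure(list(time_s = time_s, sp = as.numeric(sp),
                 shuffle_mean = rowMeans(aucs),
                 shuffle_sd = apply(aucs, 1, sd),
                 n_stim = ns, n_catch = nc),
            class = "sp_curve")
}

#' @export
print.sp_curve <- function(x, ...) {
  cat(sprintf("<sp_curve> %d windows, %d stim / %d catch trials\n",
              length(x$time_s), x$n_stim, x$n_catch))
  cat(sprintf(" max SP %.3f at %.1f ms (shuffle mean %.3f)\n",
              max(x$sp), 1000 * x$time_s[which.max(x$sp)],
              mean(x$shuffle_mean)))
  invisible(x)
}

#' Grand-average stimulus probability across mice
#'
#' @param curves list of `sp_curve`s on identical time grids.
#' @return data.frame `time_s`, `mean`, `sem` (0 for a single curve).
#' @export
grand_average_sp <- function(curves) {
  if (length(curves) == 0) stop("no curves", call. = FALSE)
  grids <- lapply(curves, `[[`, "time_s")
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])),
                  logical(1))))
    stop("time grids differ across curves", call. = FALSE)
  m <- do.call(rbind, lapply(curves, `[[`, "sp"))
  sem <- if (nrow(m) > 1) apply(m, 2, sd) / sqrt(nrow(m)) else rep(0, ncol(m))
  data.frame(time_s = grids[[1]], mean = colMeans(m), sem = sem)
}
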
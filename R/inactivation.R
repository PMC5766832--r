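# Behavioral statistics for optogenetic and pharmacological inactivation.

#' Split trials by the photo-inhibition flag
#'
#' Exhaustive, disjoint partition of the trial table by `light_on`.
#'
#' @param tt a [trial_table()].
#' @return list `(on, off)` of trial tables; warns if either side is empty.
#' @export
split_light_trials <- function(tt) {
  on <- tt[tt$light_on, ]
  off <- tt[!tt$light_on, ]
  if (nrow(on) == 0 || nrow(off) == 0)
    warning("all trials fall in one light class", call. = FALSE)
  list(on = on, off = off)
}

#' Paired comparison of light-on versus light-off performance
#'
#' Per-mouse hit and false-alarm rates are compared across the two light
#' conditions with paired Wilcoxon signed-rank tests.
#'
#' @param rates_on,rates_off data.frames with one row per mouse and columns
#'   `hit_rate`, `fa_rate`, in the same mouse order.
#' @return list `(p_hit, p_fa, n_mice)`.
#' @export
opto_compare <- function(rates_on, rates_off) {
  if (nrow(rates_on) != nrow(rates_off))
    stop("unpaired input: light-on and light-off mouse sets differ",
         call. = FALSE)
  n <- nrow(rates_on)
  if (n < 3) stop("need at least 3 paired mice", call. = FALSE)
  if (n < 5)
    warning("fewer than 5 mice: signed-rank test cannot reach p < 0.05",
            call. = FALSE)
  list(p_hit = wilcoxon_signed_rank(rates_on$hit_rate, rates_off$hit_rate)$p,
       p_fa = wilcoxon_signed_rank(rates_on$fa_rate, rates_off$fa_rate)$p,
       n_mice = n)
}

#' Extract the post-injection analysis block
#'
#' Trials whose onset falls in `[start_s, start_s + dur_s)` on a session
#' clock anchored to the end of the injection: by default the 5 min block
#' starting 30 min after injection, chosen to homogenize muscimol
#' diffusion.
#'
#' @param tt a [trial_table()].
#' @param start_s block start (s after injection end).
#' @param dur_s block duration (s).
#' @return the trial-table subset; errors (with counts) if empty.
#' @export
extract_muscimol_block <- function(tt, start_s = 1800, dur_s = 300) {
  keep <- in_window(tt$onset_s, start_s, start_s + dur_s)
  if (!any(keep))
    stop(sprintf("no trials in [%g, %g) s (session has %d trials spanning %.0f-%.0f s)",
                 start_s, start_s + dur_s, nrow(tt), min(tt$onset_s),
                 max(tt$onset_s)), call. = FALSE)
  tt[keep, ]
}

#' Compare muscimol-treated areas against pooled Ringer controls
#'
#' Per-area Mann-Whitney tests of per-mouse hit rates against a single
#' control group pooled across Ringer-injected areas, with Bonferroni-Holm
#' correction across the tested areas.
#'
#' @param treated_by_area named list: per tested area, the per-mouse hit
#'   rates of muscimol-injected mice (>= 3 each).
#' @param control per-mouse hit rates of the pooled Ringer group (>= 3).
#' @param alpha significance level on adjusted p-values.
#' @return data.frame `(area, n_treated, p_raw, p_adj, significant)`.
#' @export
muscimol_compare <- function(treated_by_area, control, alpha = 0.05) {
  if (length(control) < 3) stop("control group too small (need >= 3 mice)",
                                call. = FALSE)
  ns <- vapply(treated_by_area, length, integer(1))
  if (any(ns < 3)) stop("treated group too small (need >= 3 mice per area)",
                        call. = FALSE)
  praw <- vapply(treated_by_area, function(x) mann_whitney(x, control)$p,
                 numeric(1))
  padj <- holm_adjust(praw)
  data.frame(area = names(treated_by_area), n_treated = ns, p_raw = praw,
             p_adj = padj, significant = padj < alpha, row.names = NULL)
}
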
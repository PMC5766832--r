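# Nonparametric statistics used across the pipeline.

#' Inverse standard-normal CDF
#'
#' The `Z` function of signal detection theory: `Z(p)` with
#' `Phi(Z(p)) = p`. Thin validated interface over the standard-normal
#' quantile function; accuracy far exceeds the documented
#' `|Phi(z) - p| < 1e-9` contract.
#'
#' @param p probability strictly inside (0, 1).
#' @return z such that `pnorm(z) == p`.
#' @export
inverse_normal_cdf <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  qnorm(p)
}

#' Paired Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped (standard convention); if all differences
#' are zero the test carries no evidence and `p = 1` is returned. Exact
#' null enumeration is used for n <= 25 without ties in the absolute
#' differences; otherwise the normal approximation with continuity
#' correction.
#'
#' @param a,b paired numeric vectors.
#' @return list with `p`, statistic `V`, and `n` (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length",
                                   call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p = 1, V = NA_real_, n = 0L))
  ties <- anyDuplicated(abs(d)) > 0
  wt <- suppressWarnings(wilcox.test(d, exact = (n <= 25 && !ties),
                                     correct = TRUE))
  list(p = wt$p.value, V = unname(wt$statistic), n = n)
}

#' Mann-Whitney two-sample rank test (two-sided)
#'
#' Exact enumeration for small samples (min group size <= 8, no ties),
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @return list with `p`, the Mann-Whitney `U` statistic (for `a` over
#'   `b`), and group sizes.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = (min(length(a), length(b)) <= 8 && !ties),
                correct = TRUE))
  list(p = wt$p.value, U = unname(wt$statistic),
       n = c(length(a), length(b)))
}

#' Bonferroni-Holm step-down adjustment
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1), in input order.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "holm")
}

#' Dunn-Holland-Wolfe joint-rank multiple comparison
#'
#' All observations are ranked jointly; each pair of groups is compared by
#' the difference of mean ranks against a critical difference at family
#' level `alpha`, built from the large-sample normal approximation with tie
#' correction and a Bonferroni split over the `k(k-1)/2` comparisons. Used
#' to compare SEP latencies and peak times across cortical areas.
#'
#' @param groups named list of numeric samples (k >= 2; each n >= 3).
#' @param alpha family-wise error level.
#' @return A `pairwise_result`: group labels and sizes, mean ranks,
#'   mean-rank difference matrix, critical differences, symmetric logical
#'   `significant` matrix (diagonal `FALSE`), and Bonferroni-adjusted
#'   two-sided p-values.
#' @export
dunn_holland_wolfe <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- vapply(groups, length, integer(1))
  if (any(n < 3)) stop("each group needs at least 3 observations",
                       call. = FALSE)
  labels <- names(groups) %||% paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), n)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)

  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term

  m <- k * (k - 1) / 2
  zcrit <- qnorm(1 - alpha / (2 * m))
  diffm <- outer(rbar, rbar, `-`)
  sem <- sqrt(s2 * outer(1 / n, 1 / n, `+`))
  zm <- abs(diffm) / sem
  zm[!is.finite(zm)] <- 0
  praw <- 2 * pnorm(-zm)
  padj <- praw * m
  padj[padj > 1] <- 1
  sig <- abs(diffm) > zcrit * sem
  diag(sig) <- FALSE
  dimnames(diffm) <- dimnames(sig) <- dimnames(padj) <- list(labels, labels)
  structure(list(labels = labels, n = n, mean_ranks = as.numeric(rbar),
                 diff = diffm, crit = zcrit * sem, significant = sig,
                 p_adj = padj, alpha = alpha),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("<pairwise_result> %d groups, family alpha = %g\n",
              length(x$labels), x$alpha))
  cat(" mean ranks:", paste(sprintf("%s=%.1f", x$labels, x$mean_ranks),
                            collapse = ", "), "\n")
  sig <- which(x$significant & upper.tri(x$significant), arr.ind = TRUE)
  if (nrow(sig) == 0) {
    cat(" no significant pairs\n")
  } else {
    for (i in seq_len(nrow(sig)))
      cat(sprintf(" %s vs %s: |dR| = %.1f (p_adj = %.3g)\n",
                  x$labels[sig[i, 1]], x$labels[sig[i, 2]],
                  abs(x$diff[sig[i, 1], sig[i, 2]]),
                  x$p_adj[sig[i, 1], sig[i, 2]]))
  }
  invisible(x)
}
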
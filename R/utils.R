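`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-open window convention: t in [a, b).
in_window <- function(t, a, b) t >= a & t < b

#' Deterministic substream seed for (mouse, day, stream)
#'
#' Fixed affine offsets under a master seed keep cohorts reproducible and
#' order-independent (any session can be regenerated in isolation); the
#' result stays below 2^31 - 1 (R integers are 32-bit).
#'
#' @param master master seed.
#' @param mouse,day,stream non-negative integer substream coordinates.
#' @return an integer seed.
#' @export
derive_seed <- function(master, mouse = 0L, day = 0L, stream = 0L) {
  as.integer((as.double(master) * 7919 + mouse * 104729 + day * 1299709 +
                stream * 15485863) %% 2147483629)
}

stop_field <- function(field, fmt, ...) {
  stop(sprintf("invalid `%s`: %s", field, sprintf(fmt, ...)), call. = FALSE)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_field(name, "must be a probability in [0, 1]")
  invisible(x)
}
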
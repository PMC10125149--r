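#' Low-pass filter specification
#'
#' The trace-smoothing filter used throughout: a Butterworth low-pass
#' applied forward and backward (zero phase).  Two passes square the
#' single-pass magnitude response, so the gain at the cutoff frequency is
#' \eqn{(1/\sqrt{2})^2 = 1/2}.
#'
#' @param cutoff_ghz Cutoff frequency in GHz (must be below the trace's
#'   Nyquist frequency).
#' @param order Filter order (default 4).
#' @param kind Filter family; only `"butterworth"` is implemented.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_ghz, order = 4L, kind = "butterworth") {
  check_number(cutoff_ghz, "cutoff_ghz", positive = TRUE)
  order <- as.integer(order)
  if (is.na(order) || order < 1L) {
    stop_porepass("`order` must be a positive integer.", "porepass_input_error")
  }
  kind <- match.arg(kind, "butterworth")
  structure(list(cutoff_ghz = cutoff_ghz, order = order, kind = kind),
            class = "filter_spec")
}

#' Zero-phase low-pass filtering of a trace
#'
#' Applies the configured Butterworth design forward and backward so the
#' result has zero phase shift.  The series mean is removed before
#' filtering and restored afterwards, which preserves the DC component
#' exactly (a constant series passes through unchanged); odd-reflection
#' padding suppresses edge transients.
#'
#' @param x A `current_trace`, or a numeric series (then `delta_t` is
#'   required).
#' @param spec A [filter_spec()]; a bare number is taken as a cutoff in GHz
#'   with the default design.
#' @param delta_t Sample spacing in ps when `x` is a bare numeric series.
#' @return Same shape as the input: a `current_trace` with
#'   `filter_applied` set, or a numeric vector.
#' @export
#' @examples
#' tr <- current_trace(0:99, sin(2 * pi * 0.05 * 0:99) + rnorm(100, sd = 0.2))
#' smooth <- lowpass(tr, filter_spec(5))
lowpass <- function(x, spec, delta_t = NULL) {
  if (is.numeric(spec)) spec <- filter_spec(spec)
  if (!inherits(spec, "filter_spec")) {
    stop_porepass("`spec` must be a filter_spec.", "porepass_input_error")
  }
  if (inherits(x, "current_trace")) {
    dt <- attr(x, "delta_t")
    y <- lowpass_series(x$current, spec, dt)
    return(new_current_trace(tibble(time = x$time, current = y),
                             delta_t = dt, filter_applied = spec))
  }
  if (is.null(delta_t)) {
    stop_porepass("`delta_t` (ps) is required for a bare numeric series.",
                  "porepass_input_error")
  }
  lowpass_series(as.numeric(x), spec, delta_t)
}

lowpass_series <- function(x, spec, delta_t_ps) {
  fs_ghz <- 1000 / delta_t_ps          # sampling rate in GHz
  nyquist <- fs_ghz / 2
  if (spec$cutoff_ghz >= nyquist) {
    stop_porepass(sprintf(
      "cutoff %.3g GHz is not below the Nyquist frequency %.3g GHz.",
      spec$cutoff_ghz, nyquist), "porepass_input_error")
  }
  n <- length(x)
  bf <- signal::butter(spec$order, spec$cutoff_ghz / nyquist, type = "low")
  mu <- mean(x)
  xc <- x - mu
  # odd-reflection padding, then forward-backward passes
  pad <- min(n - 1L, max(9L * spec$order, 30L))
  left <- 2 * xc[1] - xc[seq(pad + 1L, 2L)]
  right <- 2 * xc[n] - xc[seq(n - 1L, n - pad)]
  ext <- c(left, xc, right)
  y1 <- signal::filter(bf, ext)
  y2 <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y1)))))
  y2[seq(pad + 1L, pad + n)] + mu
}

# Theoretical two-pass magnitude gain of the Butterworth design at a given
# frequency (used by the filter-contract tests).
butterworth_two_pass_gain <- function(freq_ghz, spec) {
  (1 / (1 + (freq_ghz / spec$cutoff_ghz)^(2 * spec$order)))
}
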
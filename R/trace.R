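#' Uniformly sampled current trace
#'
#' Container for a current record sampled at a fixed interval. The time of
#' sample `n` (1-based) is `t0_offset + (n - 1) * dt`, with `t0_offset`
#' expressing where the first sample lies relative to the stimulus step onset.
#' Synthetic traces place sample 1 exactly at the step onset (`t0_offset = 0`);
#' any delay of the recording path is introduced by the filter emulation, not
#' by the time base.
#'
#' @param samples Numeric vector of current values (A).
#' @param dt Sampling interval (s).
#' @param t0_offset Time of the first sample relative to step onset (s).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, dt, t0_offset = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    .stop_invalid("a current trace needs at least 2 samples")
  if (!all(is.finite(samples)))
    .stop_invalid("current trace samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    .stop_invalid("'dt' must be a single positive number")
  structure(
    list(samples = samples, dt = dt, t0_offset = as.numeric(t0_offset)),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> %d samples, dt = %.6g us (f_samp = %.6g kHz), t0 = %.6g us\n",
    length(x$samples), x$dt * 1e6, 1e-3 / x$dt, x$t0_offset * 1e6
  ))
  cat(sprintf("  range: [%.4g, %.4g] A\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.current_trace <- function(x) length(x$samples)

#' Sample times of a current trace
#'
#' @param trace A [current_trace()].
#' @return Numeric vector of sample times (s) relative to step onset.
#' @export
trace_times <- function(trace) {
  trace$t0_offset + (seq_along(trace$samples) - 1) * trace$dt
}

.assert_trace <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "current_trace"))
    .stop_invalid("'", arg, "' must be a current_trace")
  invisible(x)
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(a$dt, b$dt)) && length(a$samples) == length(b$samples)
}
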
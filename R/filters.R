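# Reverse Bessel polynomial of order 4: theta_4(s) = s^4 + 10 s^3 + 45 s^2
# + 105 s + 105. Its roots are the poles of the delay-normalized (unit group
# delay at DC) 4-pole Bessel low-pass prototype.
.bessel4_prototype <- function() {
  list(poles = polyroot(c(105, 105, 45, 10, 1)), gain = 105)
}

# -3 dB angular frequency of the delay-normalized order-4 prototype, solved
# numerically so the magnitude normalization carries no magic constant.
.bessel4_w3db <- function() {
  proto <- .bessel4_prototype()
  mag2 <- function(w) Mod(proto$gain / prod(1i * w - proto$poles))^2
  uniroot(function(w) mag2(w) - 0.5, c(0.5, 5), tol = 1e-14)$root
}

# multiply polynomials given as coefficient vectors (ascending powers of z^-1)
.pmul <- function(p, q) {
  out <- rep(0 + 0i, length(p) + length(q) - 1L)
  for (i in seq_along(p))
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  out
}

.poly_from_roots <- function(rt) {
  p <- c(1 + 0i)
  for (z in rt) p <- .pmul(p, c(1, -z))
  p
}

#' Digital emulation of the 10 kHz 4-pole Bessel output filter
#'
#' Designs the analog 4th-order Bessel low-pass prototype normalized so the
#' magnitude response is -3 dB at `f_c` (the convention of patch-clamp
#' amplifier output filters), then discretizes it by invariance of the impulse
#' response at sampling rate `f_samp` (including the conventional `1/f_samp`
#' gain factor) and rescales the numerator to exact unity DC gain.
#'
#' Magnitude normalization, rather than phase/delay normalization, is what
#' reproduces the measured step-response half-amplitude time of about 34 us
#' for the 10 kHz filter; a delay-normalized design would reach half amplitude
#' at about 16 us.
#'
#' @param f_c Corner (-3 dB) frequency (Hz).
#' @param f_samp Sampling rate (Hz); must exceed `2 * f_c`.
#' @return An object of class `digital_filter` with feedforward (`b`) and
#'   feedback (`a`) coefficients, analog pole set, `f_c`, `f_samp` and order.
#' @examples
#' filt <- design_bessel4(10e3, 100e3)
#' step_half_time(filt) * 1e6  # ~33 us
#' @export
design_bessel4 <- function(f_c, f_samp) {
  if (f_c <= 0 || f_samp <= 0) .stop_invalid("frequencies must be > 0")
  if (f_samp <= 2 * f_c)
    .stop_invalid("'f_samp' must exceed 2 * f_c for a usable emulation")
  proto <- .bessel4_prototype()
  scale <- 2 * pi * f_c / .bessel4_w3db()
  ps <- proto$poles * scale            # analog poles, rad/s
  ks <- proto$gain * scale^4           # analog gain for unity DC
  # partial fractions: H(s) = sum r_i / (s - p_i), distinct complex poles
  r <- vapply(1:4, function(i) ks / prod(ps[i] - ps[-i]), complex(1))
  T <- 1 / f_samp
  zp <- exp(ps * T)                    # digital poles, strictly inside |z|=1
  a <- Re(.poly_from_roots(zp))
  b <- rep(0 + 0i, 4)
  for (i in 1:4) b <- b + r[i] * T * .poly_from_roots(zp[-i])
  b <- Re(b)
  b <- b / (sum(b) / sum(a))           # exact unity DC gain
  structure(
    list(b = b, a = a, f_c = f_c, f_samp = f_samp, order = 4L,
         poles_analog = ps),
    class = "digital_filter"
  )
}

#' @export
print.digital_filter <- function(x, ...) {
  cat(sprintf("<digital_filter> order-%d Bessel emulation, f_c = %.4g kHz, f_samp = %.4g kHz\n",
              x$order, x$f_c * 1e-3, x$f_samp * 1e-3))
  invisible(x)
}

#' Apply a digital filter to a current trace
#'
#' Causal single-pass recursive filtering from zero initial state, emulating
#' how the amplifier's output filter and acquisition chain process the input
#' stream. Output length equals input length.
#'
#' With `steady = TRUE` the record is treated as one period of a signal that
#' has been running indefinitely (the situation of an acquisition started
#' mid-stream): the filter is run over two copies of the record and the
#' second pass is returned, which for a periodic record is the exact
#' steady-state (circular) filter output with no startup transient.
#'
#' @param trace A [current_trace()] (or bare numeric vector).
#' @param filt A [design_bessel4()] filter.
#' @param steady Start the filter in periodic steady state instead of from
#'   zero state.
#' @return Filtered trace of the same class and length as the input.
#' @export
apply_filter <- function(trace, filt, steady = FALSE) {
  if (!inherits(filt, "digital_filter"))
    .stop_invalid("'filt' must be a digital_filter")
  run <- function(x) {
    if (steady) {
      y <- as.numeric(signal::filter(filt$b, filt$a, c(x, x)))
      y[(length(x) + 1L):(2L * length(x))]
    } else {
      as.numeric(signal::filter(filt$b, filt$a, x))
    }
  }
  if (inherits(trace, "current_trace")) {
    if (abs(1 / trace$dt - filt$f_samp) > 1e-6 * filt$f_samp)
      .stop_invalid("trace sampling rate (", 1 / trace$dt,
                    " Hz) does not match the filter design rate (",
                    filt$f_samp, " Hz)")
    current_trace(run(trace$samples), dt = trace$dt,
                  t0_offset = trace$t0_offset)
  } else {
    run(as.numeric(trace))
  }
}

#' Impulse response of a digital filter
#'
#' @param filt A [design_bessel4()] filter.
#' @param n Number of samples.
#' @return Numeric vector: response to a discrete unit impulse.
#' @export
filter_impulse_response <- function(filt, n) {
  apply_filter(c(1, rep(0, n - 1)), filt)
}

#' Complex frequency response of a digital filter
#'
#' Evaluates `B(z)/A(z)` at `z = exp(2i pi f / f_samp)`.
#'
#' @param filt A [design_bessel4()] filter.
#' @param f Frequencies (Hz).
#' @return Complex vector of the same length as `f`.
#' @export
filter_frequency_response <- function(filt, f) {
  vapply(f, function(fi) {
    z <- exp(-2i * pi * fi / filt$f_samp)
    sum(filt$b * z^(seq_along(filt$b) - 1)) /
      sum(filt$a * z^(seq_along(filt$a) - 1))
  }, complex(1))
}

#' Time to half amplitude of the unit-step response
#'
#' Drives the filter with a unit step and returns the time at which the
#' response first crosses half of its final (unity) amplitude, with linear
#' interpolation between samples. Because the discrete convolution sum of the
#' impulse-invariant design approximates the continuous-time response at
#' mid-sample instants, sample `n` (0-based) is assigned time
#' `(n + 1/2) / f_samp`; this aligns the discrete crossing with the analog
#' filter's half-amplitude time independently of the sampling rate.
#'
#' @param filt A [design_bessel4()] filter.
#' @return Time (s) of the 50% crossing.
#' @export
step_half_time <- function(filt) {
  T <- 1 / filt$f_samp
  n <- max(64L, as.integer(ceiling(20 * filt$f_samp / filt$f_c)))
  y <- apply_filter(rep(1, n), filt)
  i <- which(y >= 0.5)[1]
  if (is.na(i) || i < 2L)
    .stop_invalid("step response does not reach half amplitude; unstable design?")
  frac <- (0.5 - y[i - 1]) / (y[i] - y[i - 1])
  ((i - 2) + frac + 0.5) * T
}

#' Export filter coefficients as plain text
#'
#' Two-column text (term index, coefficient) for cross-checking against other
#' tools; [read_filter_coefficients()] restores the filter bit-exactly.
#'
#' @param filt A [design_bessel4()] filter.
#' @param path Output file path.
#' @export
write_filter_coefficients <- function(filt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# capdecon digital_filter order=%d", filt$order),
    sprintf("# f_c_hz=%.17g", filt$f_c),
    sprintf("# f_samp_hz=%.17g", filt$f_samp),
    paste("b", paste(sprintf("%.17g", filt$b), collapse = " ")),
    paste("a", paste(sprintf("%.17g", filt$a), collapse = " "))
  ), con)
  invisible(path)
}

#' Import filter coefficients written by [write_filter_coefficients()]
#'
#' @param path Input file path.
#' @return A `digital_filter` object.
#' @export
read_filter_coefficients <- function(path) {
  lines <- readLines(path)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, "="), lines, value = TRUE)
    as.numeric(sub(paste0("^# ", key, "="), "", ln[1]))
  }
  ord <- as.integer(sub(".*order=", "", grep("order=", lines, value = TRUE)[1]))
  b <- as.numeric(strsplit(grep("^b ", lines, value = TRUE), " ")[[1]][-1])
  a <- as.numeric(strsplit(grep("^a ", lines, value = TRUE), " ")[[1]][-1])
  structure(
    list(b = b, a = a, f_c = get_meta("f_c_hz"), f_samp = get_meta("f_samp_hz"),
         order = ord, poles_analog = NULL),
    class = "digital_filter"
  )
}
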
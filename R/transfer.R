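#' Pointwise average of repeated current records
#'
#' Arithmetic mean over repeated acquisitions of the same stimulus, used to
#' suppress noise before estimating the impulse response (typically 4096
#' repeats of a 20 ms record).
#'
#' @param records List of [current_trace()] objects with equal `dt` and length.
#' @return A [current_trace()] holding the pointwise mean.
#' @export
average_records <- function(records) {
  if (length(records) == 0L) .stop_invalid("no records to average")
  lapply(records, .assert_trace, arg = "records[[i]]")
  ref <- records[[1]]
  for (r in records[-1])
    if (!.same_grid(ref, r))
      .stop_invalid("all records must share dt and length")
  m <- Reduce(`+`, lapply(records, `[[`, "samples")) / length(records)
  current_trace(m, dt = ref$dt, t0_offset = ref$t0_offset)
}

#' Net impulse response from an R+C / C record pair
#'
#' The impulse stimulus delivered with the calibration resistor grounded
#' yields the combined resistive + capacitive response (R+C); with the
#' resistor ungrounded only the capacitive component (C) of the parasitic
#' capacitance and amplifier circuitry remains. Their pointwise difference is
#' the net impulse response of the signal path through the resistor branch
#' (the R-response).
#'
#' @param rc_response [current_trace()] recorded with the resistor grounded.
#' @param c_response [current_trace()] recorded with the resistor ungrounded.
#' @return A [current_trace()]: the R-response.
#' @export
impulse_response <- function(rc_response, c_response) {
  .assert_trace(rc_response)
  .assert_trace(c_response)
  if (!.same_grid(rc_response, c_response))
    .stop_invalid("R+C and C responses must share dt and length")
  current_trace(rc_response$samples - c_response$samples,
                dt = rc_response$dt, t0_offset = rc_response$t0_offset)
}

#' Signal-path frequency characteristic from an impulse response
#'
#' Fast Fourier transform of the (zero-padded) impulse response, normalized by
#' its DC bin so that the characteristic has exactly unity gain at DC. For a
#' 20 ms record sampled at 100 kHz the characteristic covers the 0.05-50 kHz
#' band (frequency resolution `f_samp / nfft` up to the Nyquist frequency).
#'
#' @param impulse A [current_trace()] (measured R-response) or numeric vector.
#' @param nfft FFT length; must be >= the impulse length.
#' @return An object of class `transfer_function` with complex spectrum `h`
#'   over all `nfft` bins, `f_samp`, `nfft`, and the normalization gain that
#'   was divided out.
#' @export
compute_H <- function(impulse, nfft = NULL) {
  if (inherits(impulse, "current_trace")) {
    x <- impulse$samples
    f_samp <- 1 / impulse$dt
  } else {
    x <- as.numeric(impulse)
    f_samp <- NA_real_
  }
  if (is.null(nfft)) nfft <- length(x)
  if (nfft < length(x)) .stop_invalid("'nfft' must be >= the impulse length")
  if (all(x == 0)) .stop_invalid("impulse response is identically zero")
  xp <- c(x, rep(0, nfft - length(x)))
  H <- fft(xp)
  gain <- Re(H[1])
  if (gain == 0) .stop_invalid("impulse response has zero DC content")
  structure(
    list(h = H / gain, f_samp = f_samp, nfft = as.integer(nfft), gain = gain),
    class = "transfer_function"
  )
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %d bins, f_samp = %s, |H| range [%.3g, %.3g]\n",
              x$nfft,
              if (is.na(x$f_samp)) "unknown" else sprintf("%.4g kHz", x$f_samp * 1e-3),
              min(Mod(x$h)), max(Mod(x$h))))
  invisible(x)
}

#' Transfer function of a known digital filter
#'
#' Convenience wrapper used by the simulation experiments: the exact
#' frequency characteristic of a [design_bessel4()] emulation over `nfft`
#' bins, obtained from its impulse response the same way a measured
#' characteristic would be.
#'
#' @param filt A [design_bessel4()] filter.
#' @param nfft FFT length (the record length to be deconvolved).
#' @return A `transfer_function`.
#' @export
transfer_from_filter <- function(filt, nfft) {
  h <- filter_impulse_response(filt, nfft)
  H <- compute_H(h, nfft)
  H$f_samp <- filt$f_samp
  H
}

#' Frequencies of the transfer-function bins
#' @param H A `transfer_function`.
#' @return Numeric vector of bin frequencies (Hz), 0 to `f_samp * (n-1)/n`.
#' @export
transfer_frequencies <- function(H) {
  (seq_len(H$nfft) - 1) * H$f_samp / H$nfft
}

#' Reconstruct the input current by frequency-domain deconvolution
#'
#' Three-step reconstruction of the current at the amplifier input from a
#' recorded (low-pass-filtered) response: transform the record by FFT, divide
#' bin-wise by the signal-path characteristic `H`, and inverse-transform. The
#' record should contain an integer number of stimulation periods so that the
#' circular-convolution assumption of the FFT is exact for steady periodic
#' stimulation.
#'
#' With `epsilon > 0` a Tikhonov-style guard is applied, dividing by
#' `(|H|^2 + epsilon) / Conj(H)` instead, which suppresses blow-up at bins
#' where a measured characteristic is contaminated by high-frequency
#' interference. With `epsilon = 0` any exactly-zero bin of `H` raises an
#' error.
#'
#' `blank_head` does not modify the reconstructed signal; it is carried as an
#' attribute so that downstream fitting excludes the first `blank_head`
#' seconds of each half-period (the blanking mode used when parasitic
#' capacitance leaves damped oscillations at the onset of the reconstruction).
#'
#' @param trace Recorded [current_trace()]; its length must equal `H$nfft`.
#' @param H A [compute_H()] / [transfer_from_filter()] transfer function.
#' @param epsilon Non-negative regularization constant (dimensionless, on the
#'   scale of `|H|^2`).
#' @param blank_head Head-blanking duration (s) to be honoured by fitting.
#' @return A [current_trace()] with attribute `blank_head`.
#' @export
deconvolve <- function(trace, H, epsilon = 0, blank_head = 0) {
  .assert_trace(trace)
  if (!inherits(H, "transfer_function"))
    .stop_invalid("'H' must be a transfer_function")
  n <- length(trace$samples)
  if (n != H$nfft)
    .stop_invalid("trace length (", n, ") must equal the transfer-function FFT length (",
                  H$nfft, ")")
  if (epsilon < 0) .stop_invalid("'epsilon' must be >= 0")
  X <- fft(trace$samples)
  if (epsilon == 0) {
    if (any(Mod(H$h) == 0))
      .stop_invalid("transfer function has zero bins; use epsilon > 0")
    Y <- X / H$h
  } else {
    Y <- X * Conj(H$h) / (Mod(H$h)^2 + epsilon)
  }
  y <- fft(Y, inverse = TRUE) / n
  rms <- sqrt(mean(Re(y)^2))
  if (rms > 0 && max(abs(Im(y))) > 1e-9 * rms)
    warning("deconvolution: residual imaginary part exceeds 1e-9 of signal RMS",
            call. = FALSE)
  out <- current_trace(Re(y), dt = trace$dt, t0_offset = trace$t0_offset)
  attr(out, "blank_head") <- blank_head
  out
}

#' Subtract a cell-attached record to cancel parasitic charging current
#'
#' The parasitic capacitance of pipette and holder charges directly from the
#' command voltage; recording the response to the same protocol in
#' cell-attached configuration (before breaking the patch) and subtracting it
#' from the whole-cell record removes this component ahead of deconvolution.
#'
#' @param whole_cell Whole-cell [current_trace()].
#' @param cell_attached Cell-attached [current_trace()] under the same
#'   protocol.
#' @return A [current_trace()].
#' @export
subtract_cp_record <- function(whole_cell, cell_attached) {
  .assert_trace(whole_cell)
  .assert_trace(cell_attached)
  if (!.same_grid(whole_cell, cell_attached))
    .stop_invalid("whole-cell and cell-attached records must share protocol, dt and length")
  current_trace(whole_cell$samples - cell_attached$samples,
                dt = whole_cell$dt, t0_offset = whole_cell$t0_offset)
}

#' Write a transfer function as CSV
#'
#' Columns `freq_hz`, `re`, `im` at full precision; [read_transfer()] restores
#' the object bit-exactly.
#'
#' @param H A `transfer_function`.
#' @param path Output file path.
#' @export
write_transfer <- function(H, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# capdecon transfer_function nfft=%d", H$nfft),
    sprintf("# f_samp_hz=%.17g", H$f_samp),
    sprintf("# gain=%.17g", H$gain),
    "freq_hz,re,im",
    sprintf("%.17g,%.17g,%.17g", transfer_frequencies(H), Re(H$h), Im(H$h))
  ), con)
  invisible(path)
}

#' Read a transfer function written by [write_transfer()]
#' @param path Input file path.
#' @return A `transfer_function`.
#' @export
read_transfer <- function(path) {
  lines <- readLines(path)
  meta <- function(key) as.numeric(sub(paste0("^# ", key, "="), "",
                                       grep(paste0("^# ", key, "="), lines, value = TRUE)[1]))
  body <- lines[!startsWith(lines, "#")]
  df <- read.table(text = body, header = TRUE, sep = ",")
  structure(
    list(h = complex(real = df$re, imaginary = df$im),
         f_samp = meta("f_samp_hz"), nfft = nrow(df), gain = meta("gain")),
    class = "transfer_function"
  )
}
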
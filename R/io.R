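#' Write a current trace as two-column plain text
#'
#' Portable trace format: comment header lines carrying `dt`, sampling rate
#' and `t0_offset` at full precision, then CSV columns `time_s,current_A`.
#' [read_text_trace()] restores the trace bit-exactly.
#'
#' @param trace A [current_trace()].
#' @param path Output file path.
#' @param metadata Optional named character/numeric vector of extra header
#'   fields (e.g. protocol parameters), written as `# name=value` lines.
#' @export
write_text_trace <- function(trace, path, metadata = NULL) {
  .assert_trace(trace)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("# dt_s=%.17g", trace$dt),
    sprintf("# f_samp_hz=%.17g", 1 / trace$dt),
    sprintf("# t0_offset_s=%.17g", trace$t0_offset)
  )
  if (!is.null(metadata))
    hdr <- c(hdr, sprintf("# %s=%s", names(metadata), as.character(metadata)))
  t <- trace_times(trace)
  writeLines(c(hdr, "time_s,current_A",
               sprintf("%.17g,%.17g", t, trace$samples)), con)
  invisible(path)
}

#' Read a current trace written by [write_text_trace()]
#'
#' Also accepts bare two-column text without a header (then `dt` is taken
#' from the time column). Malformed rows raise a parse error naming the line.
#'
#' @param path Input file path.
#' @return A [current_trace()]; header metadata beyond the time base is
#'   attached as the `metadata` attribute.
#' @export
read_text_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  if (length(body) && grepl("^time_s", body[1])) body <- body[-1]
  body_lineno <- which(!is_hdr)
  if (length(body) && grepl("^time_s", lines[body_lineno[1]]))
    body_lineno <- body_lineno[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    .stop_invalid("malformed trace row at line ", body_lineno[bad[1]],
                  ": ", body[bad[1]])
  tvals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  ivals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(!is.finite(tvals) | !is.finite(ivals))
  if (length(bad))
    .stop_invalid("non-numeric trace row at line ", body_lineno[bad[1]],
                  ": ", body[bad[1]])
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  dt <- if (!is.null(meta$dt_s)) as.numeric(meta$dt_s) else median(diff(tvals))
  t0 <- if (!is.null(meta$t0_offset_s)) as.numeric(meta$t0_offset_s) else tvals[1]
  out <- current_trace(ivals, dt = dt, t0_offset = t0)
  attr(out, "metadata") <- meta[setdiff(names(meta),
                                        c("dt_s", "f_samp_hz", "t0_offset_s"))]
  out
}

#' Read an Axon Binary Format (.abf) file
#'
#' ABF is the proprietary acquisition format of Axon/Molecular Devices
#' amplifier software. No ABF reader is available to this package, so this
#' entry point exists to give a clear, typed error; convert ABF records to
#' the two-column text format (see [write_text_trace()]) for analysis. The
#' rest of the package is fully functional without ABF support.
#'
#' @param path Path to an .abf file.
#' @export
read_abf <- function(path) {
  stop(structure(
    class = c("capdecon_unsupported_format", "error", "condition"),
    list(message = paste0(
      "ABF reading is not supported in this build; export '", path,
      "' to two-column text (time_s,current_A) and use read_text_trace()"),
      call = NULL)
  ))
}

#' Write an impedance series as CSV
#'
#' Columns `time_s`, `C_M_F`, `R_M_ohm`, `R_A_ohm`, `Q_C_C`, `sse`, `flags`
#' (the portable substitute for spreadsheet output).
#'
#' @param series An `impedance_series`.
#' @param path Output file path.
#' @export
write_impedance_series <- function(series, path) {
  df <- data.frame(
    time_s = series$t_s,
    C_M_F = series$c_m,
    R_M_ohm = series$r_m,
    R_A_ohm = series$r_a,
    Q_C_C = series$q_c,
    sse = series$sse,
    flags = ifelse(series$converged, "", "nonconverged")
  )
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key=value`); `#` starts a comment.
#' Values that parse as numbers are returned numeric.
#'
#' @param path Input file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) .stop_invalid("config line without '=': ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Build a stimulus protocol from a configuration list
#'
#' Documented keys: `v_stim_mV` (full step amplitude), `period_ms`,
#' `f_samp_kHz`, `n_periods`, `holding_mV`.
#'
#' @param config Named list from [read_config()].
#' @return A [stimulus_protocol()].
#' @export
protocol_from_config <- function(config) {
  need <- c("v_stim_mV", "period_ms", "f_samp_kHz")
  miss <- setdiff(need, names(config))
  if (length(miss)) .stop_invalid("config missing keys: ",
                                  paste(miss, collapse = ", "))
  stimulus_protocol(
    v_stim = config$v_stim_mV * 1e-3,
    period = config$period_ms * 1e-3,
    f_samp = config$f_samp_kHz * 1e3,
    n_periods = if (!is.null(config$n_periods)) config$n_periods else 1L,
    holding = if (!is.null(config$holding_mV)) config$holding_mV * 1e-3 else 0
  )
}
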
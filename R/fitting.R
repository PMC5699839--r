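#' Segment a square-wave record into re-referenced half-periods
#'
#' Cuts the record at half-period boundaries and re-references each
#' half-period by subtracting the steady level of the PRECEDING half-period
#' (mean of its last 10% of samples, at least 2), folding the sign so that
#' every segment is a positive-going relaxation. Under symmetric bipolar
#' stimulation this convention makes the full step amplitude `V_Stim` the
#' correct voltage in the impedance formulas: the re-referenced peak is
#' `V_Stim / R_A` and the re-referenced steady level
#' `V_Stim / (R_M + R_A)` (plus `V_Stim / R_Seal` for a leaky seal). The
#' first half-period has no predecessor and is dropped.
#'
#' The tail mean is only a first-pass estimate of the preceding steady
#' level: with a 6 tau half-period the predecessor's transient still
#' contributes about `exp(-6)` of its amplitude to the tail, which matters
#' whenever the peak dwarfs the steady current (`R_M >> R_A`). Fitting
#' refines the reference from the predecessor's fitted asymptote; see
#' [fit_record_halves()].
#'
#' @param trace A [current_trace()] covering an integer number of
#'   half-periods.
#' @param protocol The [stimulus_protocol()] of the record.
#' @param drop_first Drop the first half-period (default). With
#'   `drop_first = FALSE` it is retained, referenced to its own tail mean, so
#'   that its fitted asymptote can serve as the refined reference for the
#'   second half-period.
#' @return List of segments; each is a list with `samples` (re-referenced,
#'   positive-going), `dt`, `index` (half-period number in the record),
#'   `polarity`, and `ref` (the steady level subtracted). The `blank_head`
#'   attribute of `trace` (if any) is propagated to each segment.
#' @export
segment_half_periods <- function(trace, protocol, drop_first = TRUE) {
  .assert_trace(trace)
  nh <- samples_per_half_period(protocol)
  n <- length(trace$samples)
  k <- n %/% nh
  if (k * nh != n)
    .stop_invalid("record length (", n, ") is not an integer number of half-periods (",
                  nh, " samples each)")
  if (k < 2L) .stop_invalid("need at least 2 half-periods to re-reference")
  ntail <- max(2L, as.integer(floor(nh * 0.1)))
  blank <- attr(trace, "blank_head")
  if (is.null(blank)) blank <- 0
  first <- if (drop_first) 2L else 1L
  out <- vector("list", k - first + 1L)
  for (j in first:k) {
    cur <- trace$samples[((j - 1) * nh + 1):(j * nh)]
    ref <- if (j == 1L) mean(tail(cur, ntail)) else {
      prev <- trace$samples[((j - 2) * nh + 1):((j - 1) * nh)]
      mean(tail(prev, ntail))
    }
    s <- if (cur[1] >= ref) 1 else -1
    seg <- list(samples = s * (cur - ref), dt = trace$dt,
                index = j, polarity = s, ref = ref)
    attr(seg, "blank_head") <- blank
    out[[j - first + 1L]] <- seg
  }
  out
}

#' Fit every half-period of a record with refined re-referencing
#'
#' Two-pass record fitting. First pass: every half-period (including the
#' first) is segmented and fitted against the tail-mean reference of its
#' predecessor. Second pass: each fit's steady current is corrected so that
#' the reference is the predecessor's fitted asymptote — the steady level
#' the predecessor would have reached — rather than its tail mean, which
#' still contains about `exp(-6)` of the transient amplitude at the optimal
#' 6 tau half-period. Only the steady current needs the correction: the time
#' constant and the transient amplitude of an exponential fit are invariant
#' under a constant offset of the data.
#'
#' @param trace A [current_trace()] (already deconvolved if applicable).
#' @param protocol The record's [stimulus_protocol()].
#' @param blank_head Head-blanking duration (s) passed to the fits; defaults
#'   to the trace's `blank_head` attribute.
#' @return List with `segments` and `fits` (class `fit3`, steady current
#'   corrected; the segment's own fitted asymptote is kept as `i_s_own` for
#'   charge integration), both excluding the first half-period.
#' @export
fit_record_halves <- function(trace, protocol, blank_head = NULL) {
  segs <- segment_half_periods(trace, protocol, drop_first = FALSE)
  fits <- lapply(segs, fit_three_element, blank_head = blank_head)
  # absolute asymptote of each half-period
  asym <- mapply(function(s, f) {
    is_own <- if (is.finite(f$i_s)) f$i_s else 0
    s$polarity * is_own + s$ref
  }, segs, fits)
  n <- length(segs)
  for (k in 2:n) {
    f <- fits[[k]]
    f$i_s_own <- f$i_s
    f$i_s <- f$i_s + segs[[k]]$polarity * (segs[[k]]$ref - asym[k - 1])
    fits[[k]] <- f
  }
  list(segments = segs[-1], fits = fits[-1])
}

# residuals + analytic jacobian for I_S + I_P exp(-t/tau)
.resid3 <- function(p, t, y) p[1] + p[2] * exp(-t / p[3]) - y
.jac3 <- function(p, t, y) {
  e <- exp(-t / p[3])
  cbind(1, e, p[2] * t / p[3]^2 * e)
}

.fit_lm <- function(par, fn, jac, ...) {
  minpack.lm::nls.lm(
    par = par, fn = fn, jac = jac, ...,
    control = minpack.lm::nls.lm.control(
      maxiter = 200, ftol = 1e-15, ptol = 1e-12, gtol = 0
    )
  )
}

#' Fit the three-element current model to one half-period
#'
#' Nonlinear least squares of `I(t) = I_S + I_P * exp(-t / tau)` over the
#' samples with `t >= blank_head` (`t` measured from the step onset at the
#' start of the segment). Initial guesses: `I_S` from the mean of the last
#' 10% of samples, `I_P` from the first usable sample minus `I_S`, and `tau`
#' from a log-linear regression of `I - I_S`. Non-convergence and degenerate
#' inputs (no resolvable transient) are flagged, not raised.
#'
#' @param segment A segment from [segment_half_periods()], or a
#'   [current_trace()], or a bare numeric vector (then `dt` is required).
#' @param blank_head Duration (s) to exclude at the segment head; defaults to
#'   the segment's own `blank_head` attribute (0 if absent).
#' @param dt Sampling interval, only for bare numeric input.
#' @return List of class `fit3`: `i_p`, `i_s`, `tau`, `sse`, `converged`,
#'   `n_used`.
#' @export
fit_three_element <- function(segment, blank_head = NULL, dt = NULL) {
  if (is.numeric(segment)) {
    if (is.null(dt)) .stop_invalid("'dt' required for numeric input")
    segment <- list(samples = as.numeric(segment), dt = dt)
  }
  if (is.null(blank_head)) {
    blank_head <- attr(segment, "blank_head")
    if (is.null(blank_head)) blank_head <- 0
  }
  y <- segment$samples
  dt <- segment$dt
  t <- (seq_along(y) - 1) * dt
  use <- t >= blank_head - 1e-12
  if (sum(use) < 4L)
    .stop_invalid("need at least 4 usable samples after blanking")
  t <- t[use]; y <- y[use]

  ntail <- max(2L, as.integer(floor(length(y) * 0.1)))
  i_s0 <- mean(tail(y, ntail))
  i_p0 <- y[1] - i_s0
  dev <- y - i_s0
  scale <- max(abs(y), 1e-300)
  flagged <- function() {
    structure(list(i_p = i_p0, i_s = i_s0, tau = NA_real_,
                   sse = sum(dev^2), converged = FALSE, n_used = length(y)),
              class = "fit3")
  }
  # degenerate: no resolvable transient (pure resistor step)
  if (abs(i_p0) < 1e-10 * scale || all(abs(dev) < 1e-12 * scale))
    return(flagged())
  # log-linear tau guess from same-signed early deviations
  pos <- which(sign(dev) == sign(i_p0) & abs(dev) > 1e-3 * abs(i_p0))
  tau0 <- if (length(pos) >= 3L) {
    fitl <- stats::lm.fit(cbind(1, t[pos]), log(abs(dev[pos])))
    sl <- fitl$coefficients[2]
    if (is.finite(sl) && sl < 0) -1 / sl else length(y) * dt / 4
  } else {
    length(y) * dt / 4
  }
  tau0 <- min(max(tau0, dt / 10), 100 * length(y) * dt)

  res <- tryCatch(
    .fit_lm(c(i_s0, i_p0, tau0), .resid3, .jac3, t = t, y = y),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$par[3]) || res$par[3] <= 0)
    return(flagged())
  structure(
    list(i_p = res$par[2], i_s = res$par[1], tau = res$par[3],
         sse = res$deviance, converged = res$info %in% 1:4,
         n_used = length(y)),
    class = "fit3"
  )
}

#' Circuit parameters from a three-element fit
#'
#' Applies the closed-form conversion `R_A = V_Stim / (I_P + I_S)`,
#' `R_M = V_Stim / I_S - R_A`, `C_M = tau * (1/R_M + 1/R_A)`, with `V_Stim`
#' the full step amplitude and `(I_P, I_S)` from the re-referenced fit of
#' [segment_half_periods()] / [fit_three_element()]. The formulas contain
#' `I_S` in the peak term because the peak is referenced to the preceding
#' half-period's steady level, not to zero current. Non-positive denominators
#' yield a flagged, non-physical estimate rather than an error.
#'
#' @param fit A `fit3` result.
#' @param v_stim Full step amplitude (V).
#' @return List of class `impedance_estimate`: `r_a`, `r_m`, `c_m` (SI),
#'   `sse`, `physical` flag.
#' @export
circuit_from_fit <- function(fit, v_stim) {
  bad <- function() structure(
    list(r_a = NA_real_, r_m = NA_real_, c_m = NA_real_,
         sse = fit$sse, physical = FALSE),
    class = "impedance_estimate"
  )
  if (!isTRUE(fit$converged) || !is.finite(fit$tau)) return(bad())
  denom_a <- fit$i_p + fit$i_s
  if (denom_a <= 0 || fit$i_s <= 0) return(bad())
  r_a <- v_stim / denom_a
  r_m <- v_stim / fit$i_s - r_a
  if (r_m <= 0) return(bad())
  c_m <- fit$tau * (1 / r_m + 1 / r_a)
  structure(
    list(r_a = r_a, r_m = r_m, c_m = c_m, sse = fit$sse, physical = TRUE),
    class = "impedance_estimate"
  )
}

#' Capacitive charge of a half-period response
#'
#' Charge under the capacitive transient above the steady current:
#' `Q_C = dt * sum(I(n) - I_S)`. Because the seal-leak term is constant
#' within a half-period and therefore absorbed into `I_S`, `Q_C` is invariant
#' under seal-resistance changes — the signature that separates true
#' membrane-capacitance events from seal artefacts.
#'
#' @param segment Segment (from [segment_half_periods()]) or numeric vector.
#' @param i_s Steady current (A) from the segment's fit.
#' @param dt Sampling interval, only for bare numeric input.
#' @return Charge (C).
#' @export
charge_integral <- function(segment, i_s, dt = NULL) {
  if (is.numeric(segment)) {
    if (is.null(dt)) .stop_invalid("'dt' required for numeric input")
    segment <- list(samples = as.numeric(segment), dt = dt)
  }
  segment$dt * sum(segment$samples - i_s)
}

#' Fit the five-element fusion-pore model
#'
#' Least squares of `I(t) = I_S + I_P exp(-t/tau) + I_P2 exp(-t/tau2)`,
#' seeded from a converged three-element fit with the slow component
#' initialized at `I_P2 = 0.1 * I_P`, `tau2 = 5 * tau`. The five-element
#' model is preferred over the three-element one when it improves the SSE by
#' at least `sse_ratio` (default 2). When `c_v` (the vesicle capacitance,
#' equal to the amplitude of the capacitance increase) is supplied, the pore
#' conductance is reported as `G_p = c_v / tau2`. A `tau2` collapsing below
#' the sampling interval is reported with `pore_open = TRUE` (the pore has
#' opened wide; its conductance is no longer calculable).
#'
#' @param segment Segment or numeric vector (then `dt` required).
#' @param seed A converged `fit3` result for the same segment.
#' @param c_v Optional vesicle capacitance (F) fixing the `G_p` conversion.
#' @param sse_ratio Improvement factor required to prefer the bi-exponential
#'   model.
#' @param blank_head,dt As in [fit_three_element()].
#' @return List of class `fit5`: `i_p`, `i_s`, `tau`, `i_p2`, `tau2`, `sse`,
#'   `converged`, `selected` ("five" or "three"), `c_v`, `g_p`, `pore_open`.
#' @export
fit_five_element <- function(segment, seed, c_v = NULL, sse_ratio = 2,
                             blank_head = NULL, dt = NULL) {
  if (!isTRUE(seed$converged))
    .stop_invalid("'seed' three-element fit must have converged")
  if (is.numeric(segment)) {
    if (is.null(dt)) .stop_invalid("'dt' required for numeric input")
    segment <- list(samples = as.numeric(segment), dt = dt)
  }
  if (is.null(blank_head)) {
    blank_head <- attr(segment, "blank_head")
    if (is.null(blank_head)) blank_head <- 0
  }
  y <- segment$samples
  dt <- segment$dt
  t <- (seq_along(y) - 1) * dt
  use <- t >= blank_head - 1e-12
  t <- t[use]; y <- y[use]

  resid5 <- function(p, t, y)
    p[1] + p[2] * exp(-t / p[3]) + p[4] * exp(-t / p[5]) - y
  jac5 <- function(p, t, y) {
    e1 <- exp(-t / p[3]); e2 <- exp(-t / p[5])
    cbind(1, e1, p[2] * t / p[3]^2 * e1, e2, p[4] * t / p[5]^2 * e2)
  }
  start <- c(seed$i_s, seed$i_p, seed$tau, 0.1 * seed$i_p, 5 * seed$tau)
  res <- tryCatch(.fit_lm(start, resid5, jac5, t = t, y = y),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(structure(
      list(i_p = seed$i_p, i_s = seed$i_s, tau = seed$tau,
           i_p2 = 0, tau2 = NA_real_, sse = seed$sse, converged = FALSE,
           selected = "three", c_v = c_v, g_p = NA_real_, pore_open = FALSE),
      class = "fit5"
    ))
  }
  p <- res$par
  # keep the fast component first
  if (is.finite(p[5]) && p[5] < p[3]) p <- p[c(1, 4, 5, 2, 3)]
  pore_open <- is.finite(p[5]) && p[5] < dt
  selected <- if (res$deviance > 0 && seed$sse / res$deviance >= sse_ratio)
    "five" else "three"
  if (seed$sse == 0 && res$deviance == 0) selected <- "three"
  g_p <- if (!is.null(c_v) && is.finite(p[5]) && p[5] > 0) c_v / p[5] else NA_real_
  if (pore_open) g_p <- Inf
  structure(
    list(i_p = p[2], i_s = p[1], tau = p[3], i_p2 = p[4], tau2 = p[5],
         sse = res$deviance, converged = res$info %in% 1:4,
         selected = selected, c_v = c_v, g_p = g_p, pore_open = pore_open),
    class = "fit5"
  )
}

#' Standard (non-deconvolved) fitting procedure with zero-time tuning
#'
#' The comparison baseline used by conventional square-wave capacitance
#' analysis on FILTERED records: the first 60 us of each half-period are
#' disregarded, the remainder is fitted by the three-element model, and the
#' peak current is extrapolated back to a candidate zero time on a sub-us
#' grid. The zero time actually used is the grid value minimizing the
#' absolute Pearson correlation between the resulting `C_M` and `R_A` series
#' over the record — correlated changes in the two traces being the signature
#' of a wrongly projected zero time.
#'
#' @param segments Output of [segment_half_periods()] on the filtered record.
#' @param v_stim Full step amplitude (V).
#' @param blank_head Blanked head duration (s); 60 us by default.
#' @param zero_time_grid Candidate zero times (s) relative to the nominal
#'   step onset; default 0.1 us steps spanning +/- one sample.
#' @param base_fits Optional precomputed per-segment fits (e.g. the refined
#'   fits of [fit_record_halves()]); when missing the segments are fitted
#'   here with `blank_head` blanking.
#' @return List with `zero_time` (chosen), `fits` (per-segment `fit3` with
#'   `i_p` extrapolated to the chosen zero time), `estimates` (per-segment
#'   [circuit_from_fit()] results), `correlation` (at the chosen zero time)
#'   and `flagged` (TRUE when the correlation criterion was unusable and the
#'   procedure fell back to zero time 0).
#' @export
standard_procedure_fit <- function(segments, v_stim, blank_head = 60e-6,
                                   zero_time_grid = NULL, base_fits = NULL) {
  if (length(segments) == 0L) .stop_invalid("no segments")
  dt <- segments[[1]]$dt
  if (is.null(zero_time_grid))
    zero_time_grid <- seq(-dt, dt, by = 1e-7)
  base <- if (is.null(base_fits))
    lapply(segments, fit_three_element, blank_head = blank_head)
  else base_fits
  ok <- vapply(base, function(f) isTRUE(f$converged), TRUE)

  est_at <- function(z) {
    lapply(base, function(f) {
      if (!isTRUE(f$converged)) return(f)
      f$i_p <- f$i_p * exp(-z / f$tau)
      f
    })
  }
  score <- function(z) {
    ests <- lapply(est_at(z), circuit_from_fit, v_stim = v_stim)
    cm <- vapply(ests, `[[`, 0, "c_m")
    ra <- vapply(ests, `[[`, 0, "r_a")
    keep <- is.finite(cm) & is.finite(ra)
    if (sum(keep) < 8L) return(NA_real_)
    # genuine variation only: guard against correlating numerical noise
    if (sd(cm[keep]) <= 1e-9 * abs(mean(cm[keep])) ||
        sd(ra[keep]) <= 1e-9 * abs(mean(ra[keep]))) return(NA_real_)
    abs(cor(cm[keep], ra[keep]))
  }
  scores <- vapply(zero_time_grid, score, 0)
  flagged <- all(is.na(scores))
  z <- if (flagged) 0 else zero_time_grid[which.min(scores)]
  fits <- est_at(z)
  list(
    zero_time = z,
    fits = fits,
    estimates = lapply(fits, circuit_from_fit, v_stim = v_stim),
    correlation = if (flagged) NA_real_ else min(scores, na.rm = TRUE),
    flagged = flagged || any(!ok)
  )
}

#' Thermal-noise resolution limit of capacitance measurement
#'
#' Standard deviation of the membrane-capacitance estimate imposed by the
#' Johnson noise of the access resistance within the analysis bandwidth:
#' `sigma_C_M = C_M * sqrt(4 k T B R_A) / V_Stim`.
#'
#' @param c_m Membrane capacitance (F).
#' @param r_a Access resistance (Ohm).
#' @param v_stim Full step amplitude (V).
#' @param b Analysis bandwidth (Hz).
#' @param t_abs Absolute temperature (K).
#' @return Capacitance standard deviation (F).
#' @export
thermal_limit <- function(c_m, r_a, v_stim, b, t_abs = 295) {
  if (any(c(c_m, r_a, v_stim, b, t_abs) <= 0))
    .stop_invalid("all arguments must be positive")
  c_m * sqrt(4 * .k_B * t_abs * b * r_a) / v_stim
}

#' Optimal stimulation period for a given time constant
#'
#' `T_S = 12 * tau` (6 time constants per half-period): long enough for the
#' transient to settle to about 0.25% of its amplitude, short enough to
#' maximize the estimate rate.
#'
#' @param tau Relaxation time constant (s), > 0.
#' @return Optimal period (s).
#' @export
optimal_period <- function(tau) {
  if (any(tau <= 0)) .stop_invalid("'tau' must be > 0")
  12 * tau
}
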
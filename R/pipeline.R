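#' Analyse a square-wave record into an impedance series
#'
#' Record-level driver: optionally deconvolves the record with a
#' transfer function, segments it into re-referenced half-periods, fits the
#' three-element model to each, converts fit parameters to circuit parameters
#' and capacitive charge, and returns one row per half-period.
#'
#' @param trace Recorded [current_trace()] (an integer number of periods).
#' @param protocol The record's [stimulus_protocol()].
#' @param transfer Optional [compute_H()] transfer function; when supplied the
#'   record is deconvolved before fitting (`method = "deconvolution"`).
#' @param method `"deconvolution"` (requires `transfer`), `"standard"` (the
#'   60 us blanking + zero-time-tuning baseline applied to the record as
#'   given, i.e. without deconvolution), or `"direct"` (fit the record as
#'   given with no blanking).
#' @param epsilon,blank_head Passed to [deconvolve()] / fitting.
#' @param per_period Average the two half-period estimates of each period
#'   (the convention for reported series) instead of returning one row per
#'   half-period.
#' @return An `impedance_series`: a data.frame with columns `index`, `t_s`,
#'   `i_p`, `i_s`, `tau`, `r_a`, `r_m`, `c_m`, `q_c`, `sse`, `converged`,
#'   carrying attributes `f_s` (stimulation frequency), `bandwidth`,
#'   `v_stim` and `f_samp`.
#' @export
analyze_record <- function(trace, protocol, transfer = NULL,
                           method = c("deconvolution", "standard", "direct"),
                           epsilon = 0, blank_head = 0, per_period = FALSE) {
  method <- match.arg(method)
  if (method == "deconvolution") {
    if (is.null(transfer))
      .stop_invalid("method 'deconvolution' requires a transfer function")
    trace <- deconvolve(trace, transfer, epsilon = epsilon,
                        blank_head = blank_head)
  }
  v_stim <- protocol$v_stim
  if (method == "standard") {
    rh <- fit_record_halves(trace, protocol, blank_head = 60e-6)
    std <- standard_procedure_fit(rh$segments, v_stim,
                                  base_fits = rh$fits)
    segments <- rh$segments
    fits <- std$fits
    ests <- std$estimates
  } else {
    rh <- fit_record_halves(trace, protocol, blank_head = blank_head)
    segments <- rh$segments
    fits <- rh$fits
    ests <- lapply(fits, circuit_from_fit, v_stim = v_stim)
  }
  # charge above the half-period's own fitted asymptote (leak-independent)
  q_c <- mapply(function(seg, f) {
    i_s_own <- if (!is.null(f$i_s_own)) f$i_s_own else f$i_s
    if (is.finite(f$tau)) charge_integral(seg, i_s_own) else NA_real_
  }, segments, fits)

  half <- protocol$period / 2
  df <- data.frame(
    index = vapply(segments, `[[`, 0L, "index"),
    t_s = vapply(segments, function(s) (s$index - 1) * half, 0),
    i_p = vapply(fits, `[[`, 0, "i_p"),
    i_s = vapply(fits, `[[`, 0, "i_s"),
    tau = vapply(fits, `[[`, 0, "tau"),
    r_a = vapply(ests, `[[`, 0, "r_a"),
    r_m = vapply(ests, `[[`, 0, "r_m"),
    c_m = vapply(ests, `[[`, 0, "c_m"),
    q_c = q_c,
    sse = vapply(fits, `[[`, 0, "sse"),
    converged = vapply(fits, function(f) isTRUE(f$converged), TRUE)
  )
  if (per_period) {
    # half-periods 2k-1 and 2k belong to period k; the first period
    # contributes only its second half (the first half has no predecessor)
    per <- (df$index + 1L) %/% 2L
    agg <- lapply(split(df, per), function(d) {
      data.frame(index = (d$index[1] + 1L) %/% 2L, t_s = mean(d$t_s),
                 i_p = mean(d$i_p), i_s = mean(d$i_s), tau = mean(d$tau),
                 r_a = mean(d$r_a), r_m = mean(d$r_m), c_m = mean(d$c_m),
                 q_c = mean(d$q_c), sse = mean(d$sse),
                 converged = all(d$converged))
    })
    df <- do.call(rbind, agg)
    rownames(df) <- NULL
  }
  impedance_series(df, f_s = 1 / protocol$period,
                   bandwidth = 1 / protocol$period,
                   v_stim = v_stim, f_samp = protocol$f_samp)
}

#' Impedance time series container
#'
#' A data.frame of per-half-period (or per-period) impedance estimates with
#' the stimulation frequency, current analysis bandwidth and stimulus
#' amplitude attached as attributes.
#'
#' @param df Data frame of estimates.
#' @param f_s Stimulation frequency (Hz).
#' @param bandwidth Analysis bandwidth (Hz).
#' @param v_stim Full step amplitude (V).
#' @param f_samp Sampling rate (Hz).
#' @return An object of classes `impedance_series` and `data.frame`.
#' @export
impedance_series <- function(df, f_s, bandwidth = f_s, v_stim = NA_real_,
                             f_samp = NA_real_) {
  structure(df, f_s = f_s, bandwidth = bandwidth, v_stim = v_stim,
            f_samp = f_samp, class = c("impedance_series", "data.frame"))
}

#' Reduce the analysis bandwidth of an impedance series
#'
#' Non-overlapping block means of size `m = round(f_S / B)` (minimum 1)
#' applied to every numeric column, trading temporal resolution for noise;
#' trailing rows that do not fill a block are dropped. `B = f_S` is the
#' identity.
#'
#' @param series An `impedance_series`.
#' @param b Target bandwidth (Hz), `0 < b <= f_S`.
#' @return A reduced `impedance_series` with updated `bandwidth` attribute.
#' @export
reduce_bandwidth <- function(series, b) {
  f_s <- attr(series, "f_s")
  if (b > f_s) .stop_invalid("'b' must not exceed the stimulation frequency f_S")
  if (b <= 0) .stop_invalid("'b' must be > 0")
  m <- max(1L, as.integer(round(f_s / b)))
  if (m == 1L) {
    attr(series, "bandwidth") <- b
    return(series)
  }
  n_blocks <- nrow(series) %/% m
  if (n_blocks < 1L) .stop_invalid("series shorter than one averaging block")
  idx <- rep(seq_len(n_blocks), each = m)
  df <- as.data.frame(series)[seq_len(n_blocks * m), , drop = FALSE]
  out <- lapply(df, function(col) {
    if (is.numeric(col)) as.numeric(tapply(col, idx, mean))
    else if (is.logical(col)) as.logical(tapply(col, idx, all))
    else tapply(col, idx, `[`, 1L)
  })
  impedance_series(as.data.frame(out), f_s = f_s, bandwidth = b,
                   v_stim = attr(series, "v_stim"),
                   f_samp = attr(series, "f_samp"))
}

# ---- experiment plumbing ----------------------------------------------------

# Simulate a record with `warmup` leading periods (repeating the first
# period's parameters), filter it causally from zero state, and drop the
# warmup so the retained portion carries the filter in (periodic) steady
# state; then deconvolve and analyse. `params` may be per-period.
.run_paths <- function(params, protocol, filt, warmup = 1L,
                       paths = c("deconvolution"), carry_state = FALSE,
                       per_period = TRUE) {
  n_per <- protocol$n_periods
  plist <- if (inherits(params, "circuit_params"))
    rep(list(params), n_per) else params
  proto_w <- stimulus_protocol(protocol$v_stim, protocol$period,
                               protocol$f_samp, n_per + warmup,
                               protocol$holding)
  plist_w <- c(rep(plist[1], warmup), plist)
  x <- simulate_square_wave(plist_w, proto_w, carry_state = carry_state)
  y <- apply_filter(x, filt)
  nh <- samples_per_half_period(protocol)
  keep <- (2L * nh * warmup + 1L):length(y$samples)
  y <- current_trace(y$samples[keep], dt = y$dt)
  out <- list()
  if ("deconvolution" %in% paths) {
    H <- transfer_from_filter(filt, length(y$samples))
    out$deconvolution <- analyze_record(y, protocol, transfer = H,
                                        per_period = per_period)
  }
  if ("standard" %in% paths) {
    out$standard <- analyze_record(y, protocol, method = "standard",
                                   per_period = per_period)
  }
  out
}

.default_filter <- function(f_samp = 1e5, f_c = 1e4) design_bessel4(f_c, f_samp)

# period of 12*tau rounded to an even number of samples, >= 16
.period_for_tau <- function(tau, f_samp, n_tau = 12) {
  spp <- max(16L, 2L * as.integer(round(n_tau * tau * f_samp / 2)))
  spp / f_samp
}

#' Accuracy experiment on random circuit triplets
#'
#' Full round trip per triplet: simulate the bipolar square-wave response
#' (period `12 tau`, noiseless), low-pass filter it with the Bessel
#' emulation, reconstruct by deconvolution, fit, and convert to circuit
#' parameters; tabulates absolute errors of the current parameters and
#' relative errors of the circuit parameters against the seeded values.
#'
#' @param n_triplets Number of random triplets.
#' @param seed Integer seed for the triplet draw.
#' @param v_stim Full step amplitude (V); 80 mV (a +/-40 mV protocol).
#' @param f_samp,f_c Sampling rate and filter corner (Hz).
#' @param n_periods Retained periods per record.
#' @return Data frame with seeded values, estimates, `tau_s`, absolute
#'   current-parameter errors and relative circuit-parameter errors.
#' @export
accuracy_experiment <- function(n_triplets = 100, seed = 1, v_stim = 0.08,
                                f_samp = 1e5, f_c = 1e4, n_periods = 2) {
  trip <- random_triplets(n_triplets, seed = seed)
  filt <- .default_filter(f_samp, f_c)
  rows <- lapply(seq_len(n_triplets), function(i) {
    p <- triplet_params(trip[i, ])
    tau <- time_constant(p)
    proto <- stimulus_protocol(v_stim, .period_for_tau(tau, f_samp), f_samp,
                               n_periods)
    res <- .run_paths(p, proto, filt)$deconvolution
    est <- lapply(res[, c("i_p", "i_s", "tau", "r_a", "r_m", "c_m")],
                  mean)
    i_p_true <- v_stim / p$r_a - v_stim / (p$r_m + p$r_a)
    i_s_true <- v_stim / (p$r_m + p$r_a)
    data.frame(
      c_m_pF = trip$c_m_pF[i], r_m_GOhm = trip$r_m_GOhm[i],
      r_a_MOhm = trip$r_a_MOhm[i], tau_s = tau,
      d_tau = est$tau - tau, d_i_s = est$i_s - i_s_true,
      d_i_p = est$i_p - i_p_true,
      rel_c_m = est$c_m / p$c_m - 1,
      rel_r_m = est$r_m / p$r_m - 1,
      rel_r_a = est$r_a / p$r_a - 1
    )
  })
  do.call(rbind, rows)
}

#' Cross-talk experiment with parameter-perturbed sibling records
#'
#' For each random triplet, simulates a sibling record in which one circuit
#' parameter is perturbed (by default `R_A + 1 MOhm`), analyses both records
#' through the deconvolution path (and optionally the standard path), and
#' tabulates the apparent changes of all circuit parameters. A perfect method
#' shows the seeded change in the perturbed parameter and nothing elsewhere.
#'
#' @param n_pairs Number of sibling pairs.
#' @param seed Integer seed.
#' @param delta Named list giving the perturbation in SI units, e.g.
#'   `list(r_a = 1e6)` or `list(r_m = 1e8)`.
#' @param v_stim,f_samp,f_c As in [accuracy_experiment()].
#' @param paths Analysis paths to run (`"deconvolution"`, `"standard"`).
#' @return Data frame with the seeded triplet, `tau_s` and, per path, the
#'   measured changes `d_c_m`, `d_r_m`, `d_r_a` (columns suffixed `_std` for
#'   the standard path).
#' @export
crosstalk_experiment <- function(n_pairs = 100, seed = 1,
                                 delta = list(r_a = 1e6),
                                 v_stim = 0.08, f_samp = 1e5, f_c = 1e4,
                                 paths = "deconvolution") {
  trip <- random_triplets(n_pairs, seed = seed)
  filt <- .default_filter(f_samp, f_c)
  rows <- lapply(seq_len(n_pairs), function(i) {
    p1 <- triplet_params(trip[i, ])
    args <- list(c_m = p1$c_m, r_m = p1$r_m, r_a = p1$r_a)
    for (nm in names(delta)) args[[nm]] <- args[[nm]] + delta[[nm]]
    p2 <- do.call(circuit_params, args)
    tau <- time_constant(p1)
    proto <- stimulus_protocol(v_stim, .period_for_tau(tau, f_samp), f_samp, 2)
    mean_of <- function(res) lapply(res[, c("r_a", "r_m", "c_m")], mean)
    out <- data.frame(c_m_pF = trip$c_m_pF[i], r_m_GOhm = trip$r_m_GOhm[i],
                      r_a_MOhm = trip$r_a_MOhm[i], tau_s = tau)
    r1 <- .run_paths(p1, proto, filt, paths = paths)
    r2 <- .run_paths(p2, proto, filt, paths = paths)
    if ("deconvolution" %in% paths) {
      e1 <- mean_of(r1$deconvolution); e2 <- mean_of(r2$deconvolution)
      out$d_r_a <- e2$r_a - e1$r_a
      out$d_r_m <- e2$r_m - e1$r_m
      out$d_c_m <- e2$c_m - e1$c_m
    }
    if ("standard" %in% paths) {
      e1 <- mean_of(r1$standard); e2 <- mean_of(r2$standard)
      out$d_r_a_std <- e2$r_a - e1$r_a
      out$d_r_m_std <- e2$r_m - e1$r_m
      out$d_c_m_std <- e2$c_m - e1$c_m
    }
    out
  })
  do.call(rbind, rows)
}

#' Capacitance resolution under access-resistance fluctuation
#'
#' Simulates noiseless records of a 50 pF / 200 MOhm / 5 MOhm cell whose
#' access resistance fluctuates randomly (normally) around its mean from
#' period to period, analyses each period through the deconvolution and
#' standard paths, reduces the resulting capacitance series to the target
#' bandwidth, and reports the capacitance standard deviation per
#' access-resistance jitter level alongside the thermal-noise floor. Each
#' period's waveform is the exact periodic orbit for its own parameter set
#' (closed-form generation), so the only capacitance variability is
#' cross-talk leaking from the access-resistance fluctuation through the
#' analysis itself.
#'
#' @param seed Integer seed.
#' @param sigma_ra Standard deviations of the `R_A` jitter (Ohm).
#' @param n_periods Periods (independent `R_A` draws) per jitter level.
#' @param b Analysis bandwidth (Hz).
#' @param c_m,r_m,r_a_mean Cell parameters (SI).
#' @param v_stim Full step amplitude (V); 20 mV (a +/-10 mV protocol).
#' @param f_samp,f_c Sampling and filter-corner rates (Hz).
#' @param paths Analysis paths to run.
#' @return Data frame with `sigma_ra_ohm`, `sd_c_m_decon`, `sd_c_m_std`
#'   (when run) and `thermal_f` (the thermal floor, F).
#' @export
resolution_vs_ra_fluctuation <- function(seed = 1,
                                         sigma_ra = c(22.6, 45.2, 90.4, 135.6,
                                                      180.8, 361.7, 452.1) * 1e3,
                                         n_periods = 500, b = 50,
                                         c_m = 50e-12, r_m = 200e6,
                                         r_a_mean = 5e6, v_stim = 0.02,
                                         f_samp = 1e5, f_c = 1e4,
                                         paths = c("deconvolution", "standard")) {
  set.seed(seed)
  filt <- .default_filter(f_samp, f_c)
  tau0 <- time_constant(circuit_params(c_m, r_m, r_a_mean))
  period <- .period_for_tau(tau0, f_samp)
  proto <- stimulus_protocol(v_stim, period, f_samp, 2)
  thermal <- thermal_limit(c_m, r_a_mean, v_stim, b)
  f_s <- 1 / period
  rows <- lapply(sigma_ra, function(s) {
    ra <- rnorm(n_periods, r_a_mean, s)
    ra <- pmax(ra, 0.1 * r_a_mean)  # guard against nonphysical draws
    per <- lapply(ra, function(r) {
      res <- .run_paths(circuit_params(c_m, r_m, r), proto, filt,
                        paths = paths)
      vapply(res, function(series) mean(series$c_m), 0)
    })
    cm <- do.call(rbind, per)
    sd_at_b <- function(x) {
      series <- impedance_series(data.frame(c_m = x), f_s = f_s)
      red <- reduce_bandwidth(series, b)
      sd(red$c_m[is.finite(red$c_m)])
    }
    out <- data.frame(sigma_ra_ohm = s, thermal_f = thermal)
    if ("deconvolution" %in% paths)
      out$sd_c_m_decon <- sd_at_b(cm[, "deconvolution"])
    if ("standard" %in% paths)
      out$sd_c_m_std <- sd_at_b(cm[, "standard"])
    out
  })
  do.call(rbind, rows)
}

#' Seal-resistance sweep experiment
#'
#' Simulates the leaky-seal circuit for a sweep of seal-resistance values
#' (default 1 to 150 GOhm in 100 MOhm steps, one value per period, for the
#' 140 pF / 500 MOhm / 4 MOhm cell driven at a 6 tau period), analyses each
#' period through the deconvolution path, and tabulates the apparent circuit
#' parameters and the capacitive charge. Reducing the seal resistance below
#' about 10 GOhm distorts the apparent `C_M` and `R_M` while `R_A` barely
#' moves and `Q_C` does not move at all.
#'
#' @param r_seal Seal-resistance values (Ohm).
#' @param c_m,r_m,r_a Cell parameters (SI).
#' @param v_stim Full step amplitude (V); 20 mV (a +/-10 mV protocol).
#' @param n_tau Period length in units of `tau`; 6 for this experiment.
#' @param f_samp,f_c Sampling and filter-corner rates (Hz).
#' @return Data frame with `r_seal_ohm` and apparent `c_m`, `r_m`, `r_a`,
#'   `q_c` (SI units) per sweep value.
#' @export
seal_sweep_experiment <- function(r_seal = seq(1e9, 150e9, by = 1e8),
                                  c_m = 140e-12, r_m = 500e6, r_a = 4e6,
                                  v_stim = 0.02, n_tau = 6,
                                  f_samp = 1e5, f_c = 1e4) {
  filt <- .default_filter(f_samp, f_c)
  tau <- time_constant(circuit_params(c_m, r_m, r_a))
  period <- .period_for_tau(tau, f_samp, n_tau = n_tau)
  proto <- stimulus_protocol(v_stim, period, f_samp, 2)
  rows <- lapply(r_seal, function(rs) {
    p <- circuit_params(c_m, r_m, r_a, r_seal = rs)
    res <- .run_paths(p, proto, filt)$deconvolution
    data.frame(r_seal_ohm = rs,
               c_m = mean(res$c_m), r_m = mean(res$r_m),
               r_a = mean(res$r_a), q_c = mean(res$q_c))
  })
  do.call(rbind, rows)
}

# ---- event detection and classification ------------------------------------

#' Detect a step change in a series by two-sided CUSUM
#'
#' Deterministic change-point detector: the candidate change point maximizes
#' the absolute cumulative sum of deviations from the series mean, and the
#' step is accepted when the pre/post mean difference exceeds `k` times the
#' robust noise scale (MAD of the first differences divided by `sqrt(2)`),
#' or `min_step` if larger.
#'
#' @param x Numeric series.
#' @param k Threshold multiplier.
#' @param min_step Absolute minimum step size to accept.
#' @return List with `index` (last point before the change), `size`
#'   (post minus pre mean) and `detected`.
#' @export
detect_step <- function(x, k = 5, min_step = 0) {
  n <- length(x)
  if (n < 4L) .stop_invalid("series too short for step detection")
  cs <- cumsum(x - mean(x))
  i <- which.max(abs(cs[-n]))
  pre <- x[seq_len(i)]
  post <- x[(i + 1):n]
  size <- mean(post) - mean(pre)
  noise <- mad(diff(x)) / sqrt(2)
  thr <- max(k * noise, min_step)
  list(index = i, size = size, detected = abs(size) > thr)
}

#' Classify a step event in an impedance series
#'
#' Applies the artefact-signature rules to a window containing one step
#' change (change point detected on the `c_m` column):
#' * significant `d_c_m` with a consistent (same-sign, significant) `d_q_c`
#'   and quiet `r_m`, `r_a` — a true membrane-capacitance event;
#' * anti-correlated significant `d_c_m` and `d_r_m` with quiet `r_a` and
#'   `q_c` — a seal-resistance artefact;
#' * small correlated `d_c_m` and `d_r_a` — a parasitic-capacitance artefact;
#' * anything else — unclassified.
#'
#' Default "quiet" thresholds are 3x the thermal-noise floor for `c_m` (and
#' its charge equivalent for `q_c`) and 3x the robust pre-window scatter for
#' `r_m` and `r_a`, each with a 0.1% relative floor guarding noiseless
#' synthetic series.
#'
#' @param series An `impedance_series` window containing one step.
#' @param thresholds Optional named list (`c_m`, `r_m`, `r_a`, `q_c`) of
#'   absolute significance thresholds overriding the defaults.
#' @param k CUSUM multiplier for the change-point detection.
#' @return List of class `event_call`: `onset` (row index of the last
#'   pre-step sample), `d_c_m`, `d_r_m`, `d_r_a`, `d_q_c`, `classification`,
#'   `thresholds`.
#' @export
classify_event <- function(series, thresholds = NULL, k = 5) {
  cm <- series$c_m
  st <- detect_step(cm, k = k,
                    min_step = if (is.null(thresholds)) 0 else thresholds$c_m)
  if (!st$detected) .stop_invalid("no step detected in the c_m series")
  i <- st$index
  n <- nrow(series)
  pre <- seq_len(i)
  post <- (i + 1):n
  d <- function(col) mean(series[[col]][post]) - mean(series[[col]][pre])
  robust <- function(col) mad(series[[col]][pre])
  d_c_m <- d("c_m"); d_r_m <- d("r_m"); d_r_a <- d("r_a"); d_q_c <- d("q_c")

  if (is.null(thresholds)) {
    v_stim <- attr(series, "v_stim")
    b <- attr(series, "bandwidth")
    med <- function(col) median(series[[col]][pre])
    thermal <- if (is.finite(v_stim) && is.finite(b))
      thermal_limit(med("c_m"), med("r_a"), v_stim, b) else 0
    # c_m/q_c: the thermal floor sets the scale; r_m/r_a: robust scatter with
    # a 0.1% relative guard for noiseless synthetic series
    thresholds <- list(
      c_m = max(3 * thermal, 3 * robust("c_m"), 1e-6 * med("c_m")),
      q_c = max(3 * thermal * abs(med("q_c")) / med("c_m"),
                3 * robust("q_c"), 1e-6 * abs(med("q_c"))),
      r_m = max(3 * robust("r_m"), 1e-3 * med("r_m")),
      r_a = max(3 * robust("r_a"), 1e-3 * med("r_a"))
    )
  }
  sig <- function(x, nm) abs(x) > thresholds[[nm]]
  classification <-
    if (sig(d_c_m, "c_m") && sig(d_q_c, "q_c") &&
        sign(d_q_c) == sign(d_c_m) && !sig(d_r_m, "r_m") && !sig(d_r_a, "r_a"))
      "true-capacitance"
    else if (sig(d_c_m, "c_m") && sig(d_r_m, "r_m") &&
             sign(d_r_m) == -sign(d_c_m) && !sig(d_r_a, "r_a") &&
             !sig(d_q_c, "q_c"))
      "seal-artefact"
    else if (sig(d_c_m, "c_m") && sig(d_r_a, "r_a") &&
             sign(d_r_a) == sign(d_c_m) && !sig(d_q_c, "q_c"))
      "parasitic-artefact"
    else "unclassified"
  structure(
    list(onset = i, d_c_m = d_c_m, d_r_m = d_r_m, d_r_a = d_r_a,
         d_q_c = d_q_c, classification = classification,
         thresholds = thresholds),
    class = "event_call"
  )
}

#' @export
print.event_call <- function(x, ...) {
  cat(sprintf("<event_call> %s at row %d: dC_M = %.4g fF, dR_M = %.4g MOhm, dR_A = %.4g kOhm, dQ_C = %.4g fC\n",
              x$classification, x$onset, x$d_c_m * 1e15, x$d_r_m * 1e-6,
              x$d_r_a * 1e-3, x$d_q_c * 1e15))
  invisible(x)
}
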
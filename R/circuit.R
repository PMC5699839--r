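#' Equivalent-circuit parameters of a whole-cell recording configuration
#'
#' The three-element cell model (membrane capacitance `c_m` in parallel with
#' membrane resistance `r_m`, both behind the access resistance `r_a` of the
#' pipette) optionally extended by a seal-leak resistance `r_seal` from the
#' pipette node to ground and a parasitic (stray) capacitance `c_p` charged
#' directly by the command voltage.
#'
#' @param c_m Membrane capacitance (F). Must be > 0 for cell simulations.
#' @param r_m Membrane resistance (Ohm), > 0.
#' @param r_a Access resistance (Ohm), > 0.
#' @param r_seal Seal resistance (Ohm); `Inf` (default) for an ideal seal.
#' @param c_p Parasitic capacitance (F), >= 0; 0 (default) when compensated.
#' @return An object of class `circuit_params`.
#' @examples
#' cell <- circuit_params(c_m = 10e-12, r_m = 500e6, r_a = 4.7e6)
#' time_constant(cell)
#' @export
circuit_params <- function(c_m, r_m, r_a, r_seal = Inf, c_p = 0) {
  num1 <- function(x, nm, pos = TRUE, finite = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      .stop_invalid("'", nm, "' must be a single number")
    if (pos && x <= 0) .stop_invalid("'", nm, "' must be > 0")
    if (!pos && x < 0) .stop_invalid("'", nm, "' must be >= 0")
    if (finite && !is.finite(x)) .stop_invalid("'", nm, "' must be finite")
    as.numeric(x)
  }
  structure(
    list(
      c_m = num1(c_m, "c_m"),
      r_m = num1(r_m, "r_m"),
      r_a = num1(r_a, "r_a"),
      r_seal = num1(r_seal, "r_seal", finite = FALSE),
      c_p = num1(c_p, "c_p", pos = FALSE)
    ),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf(
    "<circuit_params> C_M = %.4g pF, R_M = %.4g MOhm, R_A = %.4g MOhm, R_Seal = %.4g GOhm, C_P = %.4g pF\n",
    x$c_m * 1e12, x$r_m * 1e-6, x$r_a * 1e-6, x$r_seal * 1e-9, x$c_p * 1e12
  ))
  invisible(x)
}

#' Bipolar square-wave stimulation protocol
#'
#' Describes the symmetric bipolar voltage stimulus used for square-wave
#' impedance measurements. `v_stim` is the FULL step amplitude (peak-to-peak
#' of the bipolar wave): a "+/-40 mV" protocol alternating between -40 and
#' +40 mV around the holding level corresponds to `v_stim = 0.08`. This is
#' the amplitude entering the impedance formulas, consistent with estimating
#' each half-period's peak from the preceding half-period's steady level.
#'
#' @param v_stim Full step amplitude (V), peak-to-peak of the bipolar wave.
#' @param period Stimulation period `T_S` (s); for a relaxation time constant
#'   `tau` the optimal choice is `12 * tau` (see [optimal_period()]).
#' @param f_samp Sampling rate (Hz). `period * f_samp` must be an even integer
#'   with at least 8 samples per half-period.
#' @param n_periods Number of stimulation periods, >= 1.
#' @param holding Holding potential (V) about which the wave alternates.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(v_stim, period, f_samp, n_periods = 1L,
                              holding = 0) {
  if (v_stim <= 0) .stop_invalid("'v_stim' must be > 0")
  if (period <= 0 || f_samp <= 0) .stop_invalid("'period' and 'f_samp' must be > 0")
  spp <- period * f_samp
  if (abs(spp - round(spp)) > 1e-6 * spp || round(spp) %% 2L != 0L)
    .stop_invalid("'period' must span an even integer number of samples")
  if (round(spp) < 16L)
    .stop_invalid("need at least 8 samples per half-period")
  if (n_periods < 1L) .stop_invalid("'n_periods' must be >= 1")
  structure(
    list(v_stim = as.numeric(v_stim), period = as.numeric(period),
         f_samp = as.numeric(f_samp), n_periods = as.integer(n_periods),
         holding = as.numeric(holding)),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> +/-%.4g mV (V_Stim = %.4g mV), T_S = %.4g ms (f_S = %.4g Hz), f_samp = %.4g kHz, %d period(s)\n",
    x$v_stim * 500, x$v_stim * 1e3, x$period * 1e3, 1 / x$period,
    x$f_samp * 1e-3, x$n_periods
  ))
  invisible(x)
}

#' Samples per half-period of a protocol
#' @param protocol A [stimulus_protocol()].
#' @return Integer number of samples in one half-period.
#' @export
samples_per_half_period <- function(protocol) {
  as.integer(round(protocol$period * protocol$f_samp / 2))
}

#' Membrane charging time constant
#'
#' `tau = C_M * R_M * R_A / (R_M + R_A)`: the relaxation time constant of the
#' whole-cell current response, i.e. the membrane capacitance discharging
#' through the parallel combination of membrane and access resistances.
#'
#' @param params A [circuit_params()] object.
#' @return Time constant (s).
#' @export
time_constant <- function(params) {
  if (!inherits(params, "circuit_params"))
    .stop_invalid("'params' must be a circuit_params object")
  if (params$c_m <= 0) .stop_invalid("'c_m' must be > 0 for a cell simulation")
  params$c_m * params$r_m * params$r_a / (params$r_m + params$r_a)
}

#' Current response to a single voltage step
#'
#' Closed-form current through the recording pipette for a voltage step of
#' amplitude `v_step` applied at `t = 0` to a cell initially at rest:
#' `I(t) = v_step * (exp(-t/tau)/R_A + (1 - exp(-t/tau))/(R_M + R_A) + 1/R_Seal)`.
#' The peak is `I(0) = v_step/R_A + v_step/R_Seal` and the steady level
#' `v_step/(R_M + R_A) + v_step/R_Seal`. A finite `r_seal` only adds the
#' constant leak term; a nonzero `c_p` adds a one-sample charging impulse of
#' charge `c_p * v_step` at the step-onset sample (the physical parasitic
#' charging is faster than one sample because it is not attenuated by the
#' access resistance).
#'
#' @param params A [circuit_params()] object.
#' @param v_step Step amplitude (V).
#' @param duration Trace duration (s), >= `dt`.
#' @param dt Sampling interval (s).
#' @return A [current_trace()] with sample 1 at the step onset.
#' @export
simulate_step <- function(params, v_step, duration, dt) {
  if (duration < dt) .stop_invalid("'duration' must be >= 'dt'")
  tau <- time_constant(params)
  n <- as.integer(floor(duration / dt + 1e-9))
  t <- (seq_len(n) - 1) * dt
  e <- exp(-t / tau)
  i <- v_step * (e / params$r_a +
                   (1 - e) / (params$r_m + params$r_a) +
                   1 / params$r_seal)
  if (params$c_p > 0)
    i[1] <- i[1] + params$c_p * v_step / dt
  current_trace(i, dt = dt, t0_offset = 0)
}

# periodic-orbit membrane voltage at the start of a positive-going half-period
# for a symmetric bipolar wave of full amplitude v about holding h
.orbit_v_start <- function(params, v_stim, holding, half_period) {
  tau <- time_constant(params)
  theta <- params$r_m / (params$r_m + params$r_a)
  e <- exp(-half_period / tau)
  holding * theta - theta * (v_stim / 2) * (1 - e) / (1 + e)
}

#' Current response to a bipolar square-wave stimulus
#'
#' Simulates the whole-cell current under symmetric bipolar square-wave
#' stimulation by analytic exponential update of the membrane-capacitor
#' voltage per half-period; no steady-state assumption is made. Parameters may
#' change at period boundaries by passing a list of [circuit_params()] of
#' length `n_periods` (e.g. for cross-talk siblings or seal-resistance
#' sweeps).
#'
#' With `carry_state = TRUE` (default) the membrane voltage is carried across
#' all half-period boundaries, so a parameter change produces the physically
#' transient re-equilibration of the membrane voltage. Note that on the
#' periodic orbit with a finite half-period `T_h` the previous half-period
#' has not fully settled, so the re-referenced peak falls short of the ideal
#' `V_Stim / R_A` by a relative `theta * exp(-T_h / tau)` (about 0.24% at the
#' optimal 6 tau half-period) — an intrinsic, constant bias of square-wave
#' stimulation at finite period. With `carry_state = FALSE` the record is the
#' idealized closed-form concatenation instead: every half-period starts from
#' the fully settled level of the opposite command, i.e. each half-period is
#' exactly the single-step response re-referenced, which is the generation
#' the impedance conversion formulas are exact for (and the one used by the
#' validation experiments).
#'
#' @param params A [circuit_params()] object, or a list of them with one
#'   element per period.
#' @param protocol A [stimulus_protocol()].
#' @param carry_state Carry the membrane-capacitor voltage across period
#'   boundaries (TRUE) or restart each period on its own periodic orbit
#'   (FALSE).
#' @param init Initial membrane-voltage state for `carry_state = TRUE`:
#'   `"orbit"` starts on the periodic orbit of the first period's parameters,
#'   `"holding"` starts from rest at the holding potential.
#' @return A [current_trace()]; sample 1 lies at the first step onset.
#' @export
simulate_square_wave <- function(params, protocol,
                                 carry_state = TRUE,
                                 init = c("orbit", "holding")) {
  init <- match.arg(init)
  if (!inherits(protocol, "stimulus_protocol"))
    .stop_invalid("'protocol' must be a stimulus_protocol")
  if (inherits(params, "circuit_params")) {
    plist <- rep(list(params), protocol$n_periods)
  } else if (is.list(params) && all(vapply(params, inherits, TRUE, "circuit_params"))) {
    if (length(params) != protocol$n_periods)
      .stop_invalid("per-period parameter list must have length n_periods (",
                    protocol$n_periods, "), got ", length(params))
    plist <- params
  } else {
    .stop_invalid("'params' must be a circuit_params or a list of them")
  }

  dt <- 1 / protocol$f_samp
  nh <- samples_per_half_period(protocol)
  t_half <- nh * dt
  v <- protocol$v_stim
  h <- protocol$holding
  tin <- (seq_len(nh) - 1) * dt

  p1 <- plist[[1]]
  v_m <- if (init == "orbit") {
    .orbit_v_start(p1, v, h, t_half)
  } else {
    h * p1$r_m / (p1$r_m + p1$r_a)
  }

  out <- numeric(2L * nh * protocol$n_periods)
  # command level before the first step: on the orbit the wave has been
  # running forever, so the previous half-period sat at the negative level
  v_cmd_prev <- if (init == "orbit") h - v / 2 else h
  pos <- 0L
  for (k in seq_len(protocol$n_periods)) {
    p <- plist[[k]]
    tau <- time_constant(p)
    theta <- p$r_m / (p$r_m + p$r_a)
    for (s in c(1, -1)) {
      v_cmd <- h + s * v / 2
      v_inf <- v_cmd * theta
      if (!carry_state)        # settled at the opposite command level
        v_m <- (h - s * v / 2) * theta
      vm_t <- v_inf + (v_m - v_inf) * exp(-tin / tau)
      seg <- (v_cmd - vm_t) / p$r_a + v_cmd / p$r_seal
      if (p$c_p > 0)
        seg[1] <- seg[1] + p$c_p * (v_cmd - v_cmd_prev) / dt
      out[pos + seq_len(nh)] <- seg
      pos <- pos + nh
      v_m <- v_inf + (v_m - v_inf) * exp(-t_half / tau)
      v_cmd_prev <- v_cmd
    }
  }
  current_trace(out, dt = dt, t0_offset = 0)
}

#' Bi-exponential fusion-pore current transient
#'
#' Five-element model of a half-period current response during vesicle fusion:
#' `I(t) = I_S + I_P * exp(-t/tau) + I_P2 * exp(-t/tau2)`, where the slow
#' component reflects charging of the vesicle capacitance `C_v` through the
#' fusion-pore conductance `G_p`, with `tau2 = C_v / G_p`. Supply either
#' `tau2` directly or both `c_v` and `g_p`.
#'
#' @param base List with elements `i_s`, `i_p`, `tau` (the three-element
#'   component), e.g. a [fit_three_element()] result.
#' @param i_p2 Amplitude of the slow component (A).
#' @param tau2 Slow time constant (s); derived as `c_v / g_p` when missing.
#' @param c_v Vesicle capacitance (F), used with `g_p` to derive `tau2`.
#' @param g_p Fusion-pore conductance (S).
#' @param duration Trace duration (s).
#' @param dt Sampling interval (s).
#' @return A [current_trace()].
#' @export
simulate_fusion_current <- function(base, i_p2, tau2 = NULL,
                                    c_v = NULL, g_p = NULL,
                                    duration, dt) {
  if (is.null(tau2)) {
    if (is.null(c_v) || is.null(g_p))
      .stop_invalid("supply 'tau2' or both 'c_v' and 'g_p'")
    tau2 <- c_v / g_p
  }
  if (tau2 <= 0) .stop_invalid("'tau2' must be > 0")
  n <- as.integer(floor(duration / dt + 1e-9))
  t <- (seq_len(n) - 1) * dt
  i <- base$i_s + base$i_p * exp(-t / base$tau) + i_p2 * exp(-t / tau2)
  current_trace(i, dt = dt, t0_offset = 0)
}

#' Add Johnson (thermal) current noise to a trace
#'
#' Adds zero-mean white Gaussian current noise with per-sample standard
#' deviation `sqrt(4 k T (f_samp/2) / R)`: the thermal noise of resistance `R`
#' within the Nyquist band of the sampled record.
#'
#' @param trace A [current_trace()].
#' @param r Noise-generating resistance (Ohm), > 0.
#' @param t_abs Absolute temperature (K); 295 K (room temperature) by default.
#' @param seed Optional integer seed for reproducibility.
#' @return A [current_trace()] with noise added.
#' @export
add_thermal_noise <- function(trace, r, t_abs = 295, seed = NULL) {
  .assert_trace(trace)
  if (r <= 0) .stop_invalid("'r' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  f_nyq <- 0.5 / trace$dt
  sigma <- sqrt(4 * .k_B * t_abs * f_nyq / r)
  current_trace(trace$samples + rnorm(length(trace$samples), 0, sigma),
                dt = trace$dt, t0_offset = trace$t0_offset)
}

#' Random circuit-parameter triplets
#'
#' Seeding set of independent uniform draws used by the validation
#' experiments: `C_M` in \[5, 200\] pF, `R_M` in \[0.02, 2\] GOhm, `R_A` in
#' \[2, 20\] MOhm.
#'
#' @param n Number of triplets, >= 1.
#' @param seed Optional integer seed.
#' @param c_m_range,r_m_range,r_a_range Ranges in pF, GOhm and MOhm.
#' @return A data.frame with columns `c_m_pF`, `r_m_GOhm`, `r_a_MOhm`.
#' @export
random_triplets <- function(n, seed = NULL,
                            c_m_range = c(5, 200),
                            r_m_range = c(0.02, 2),
                            r_a_range = c(2, 20)) {
  if (n < 1) .stop_invalid("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    c_m_pF  = runif(n, c_m_range[1], c_m_range[2]),
    r_m_GOhm = runif(n, r_m_range[1], r_m_range[2]),
    r_a_MOhm = runif(n, r_a_range[1], r_a_range[2])
  )
}

#' Convert one reported triplet row to SI circuit parameters
#'
#' @param triplet One-row data.frame (or list) with `c_m_pF`, `r_m_GOhm`,
#'   `r_a_MOhm`.
#' @param r_seal,c_p Passed to [circuit_params()].
#' @return A [circuit_params()] object in SI units.
#' @export
triplet_params <- function(triplet, r_seal = Inf, c_p = 0) {
  circuit_params(c_m = triplet$c_m_pF * 1e-12,
                 r_m = triplet$r_m_GOhm * 1e9,
                 r_a = triplet$r_a_MOhm * 1e6,
                 r_seal = r_seal, c_p = c_p)
}
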
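test_that("segmentation folds symmetric half-periods onto one relaxation", {
  p <- circuit_params(40e-12, 250e6, 5e6)
  proto <- proto_for(p, n_periods = 3)
  x <- simulate_square_wave(p, proto, carry_state = FALSE)
  segs <- segment_half_periods(x, proto)
  expect_length(segs, 5L)
  for (s in segs[-1])
    expect_equal(s$samples, segs[[1]]$samples, tolerance = 1e-12)
  expect_true(all(vapply(segs, function(s) s$samples[1] > 0, TRUE)))
  expect_error(segment_half_periods(current_trace(rnorm(10), DT), proto),
               "integer number")
})

test_that("three-element fit recovers exact generator parameters", {
  p <- circuit_params(40e-12, 250e6, 5e6)
  proto <- proto_for(p)
  x <- simulate_square_wave(p, proto, carry_state = FALSE)
  rh <- fit_record_halves(x, proto)
  th <- theory_params(p, proto$v_stim)
  for (f in rh$fits) {
    expect_true(f$converged)
    expect_equal(f$i_p, th$i_p, tolerance = 1e-6)
    expect_equal(f$i_s, th$i_s, tolerance = 1e-6)
    expect_equal(f$tau, th$tau, tolerance = 1e-6)
  }
})

test_that("degenerate pure-resistor input is flagged, not raised", {
  flat <- list(samples = rep(2e-9, 64), dt = DT)
  f <- fit_three_element(flat)
  expect_false(f$converged)
  expect_true(is.na(f$tau))
})

test_that("impedance conversion inverts the theoretical current parameters", {
  p <- circuit_params(80e-12, 150e6, 8e6)
  v <- 0.08
  th <- theory_params(p, v)
  fit <- structure(list(i_p = th$i_p, i_s = th$i_s, tau = th$tau,
                        sse = 0, converged = TRUE), class = "fit3")
  est <- circuit_from_fit(fit, v)
  expect_equal(est$r_a, p$r_a, tolerance = 1e-12)
  expect_equal(est$r_m, p$r_m, tolerance = 1e-12)
  expect_equal(est$c_m, p$c_m, tolerance = 1e-12)

  # R_M >> R_A: R_A -> V/(I_P + I_S) ~ V/I_P and C_M -> tau/R_A
  p_inf <- circuit_params(10e-12, 1e13, 5e6)
  th_inf <- theory_params(p_inf, v)
  fit_inf <- structure(list(i_p = th_inf$i_p, i_s = th_inf$i_s,
                            tau = th_inf$tau, sse = 0, converged = TRUE),
                       class = "fit3")
  est_inf <- circuit_from_fit(fit_inf, v)
  expect_equal(est_inf$r_a, v / (th_inf$i_p + th_inf$i_s), tolerance = 1e-12)
  expect_equal(est_inf$c_m, p_inf$c_m, tolerance = 1e-6)

  # non-physical fits are flagged
  bad <- structure(list(i_p = 1e-9, i_s = -1e-10, tau = 1e-4,
                        sse = 0, converged = TRUE), class = "fit3")
  expect_false(circuit_from_fit(bad, v)$physical)
})

test_that("five-element fit separates the fusion-pore component", {
  base <- list(i_s = 2e-10, i_p = 8e-9, tau = 2e-4)
  i_p2 <- 0.8e-9
  tau2 <- 2e-3
  tr <- simulate_fusion_current(base, i_p2, tau2 = tau2,
                                duration = 1e-2, dt = DT)
  # SNR 100 relative to the total transient amplitude
  set.seed(31)
  noisy <- tr$samples + rnorm(length(tr$samples), 0, (base$i_p + i_p2) / 100)
  seed3 <- fit_three_element(noisy, dt = DT)
  f5 <- fit_five_element(noisy, seed3, c_v = 100e-15, dt = DT)
  expect_true(f5$converged)
  expect_equal(f5$selected, "five")
  expect_equal(f5$i_p2, i_p2, tolerance = 0.01)
  expect_equal(f5$tau2, tau2, tolerance = 0.01)
  expect_equal(f5$g_p, 100e-15 / f5$tau2)

  # degenerate truth: the three-element model is retained
  mono <- simulate_fusion_current(base, 0, tau2 = 1e-3,
                                  duration = 1e-2, dt = DT)
  noisy0 <- mono$samples + rnorm(length(mono$samples), 0, base$i_p / 100)
  seed0 <- fit_three_element(noisy0, dt = DT)
  f50 <- fit_five_element(noisy0, seed0, dt = DT)
  expect_equal(f50$selected, "three")
  expect_error(fit_five_element(noisy0, list(converged = FALSE), dt = DT),
               "converged")
})

test_that("pore-conductance trajectory is recovered across a fusion event", {
  # synthetic analogue of a pore opening from 0.1 to 0.5 nS within 250 ms
  c_v <- 100e-15
  base <- list(i_s = 2e-10, i_p = 8e-9, tau = 1e-4)
  g_true <- seq(0.1e-9, 0.5e-9, length.out = 6)
  g_est <- vapply(g_true, function(g) {
    tr <- simulate_fusion_current(base, i_p2 = 0.5e-9, c_v = c_v, g_p = g,
                                  duration = 5e-3, dt = DT)
    s3 <- fit_three_element(tr$samples, dt = DT)
    f5 <- fit_five_element(tr$samples, s3, c_v = c_v, dt = DT)
    f5$g_p
  }, 0)
  expect_equal(g_est, g_true, tolerance = 0.01)
  expect_true(all(diff(g_est) > 0))
})

test_that("capacitive charge matches the closed-form integral and flat input", {
  p <- circuit_params(60e-12, 400e6, 5e6)
  v <- 0.08
  th <- theory_params(p, v)
  n <- as.integer(round(6 * th$tau / DT))
  t <- (0:(n - 1)) * DT
  seg <- list(samples = th$i_s + th$i_p * exp(-t / th$tau), dt = DT)
  q <- charge_integral(seg, th$i_s)
  # discrete-sum value of the closed form (left Riemann sum of the transient)
  q_closed <- th$i_p * DT * (1 - exp(-n * DT / th$tau)) /
    (1 - exp(-DT / th$tau))
  expect_equal(q, q_closed, tolerance = 1e-12)
  # continuum limit: Q_C ~ C_M V_Stim (R_M/(R_M+R_A))^2
  expect_equal(q, p$c_m * v * (p$r_m / (p$r_m + p$r_a))^2, tolerance = 0.01)
  expect_equal(charge_integral(rep(3e-9, 50), 3e-9, dt = DT), 0)
})

test_that("standard procedure finds a known zero-time shift via decorrelation", {
  # segments with the true onset 2 us before the first sample; R_A varies
  # across the record so a wrong zero time projects into correlated C_M/R_A
  set.seed(41)
  shift <- 2e-6
  v <- 0.02
  n <- 160
  t <- (0:(n - 1)) * DT
  segs <- lapply(1:60, function(i) {
    p <- circuit_params(50e-12, 200e6, 5e6 + rnorm(1, 0, 2e5))
    th <- theory_params(p, v)
    y <- th$i_s + th$i_p * exp(-(t + shift) / th$tau)
    y <- y + rnorm(n, 0, th$i_p * 1e-5)
    list(samples = y, dt = DT)
  })
  res <- standard_procedure_fit(segs, v, blank_head = 60e-6,
                                zero_time_grid = seq(-4e-6, 4e-6, by = 2e-7))
  expect_false(res$flagged)
  expect_equal(res$zero_time, -shift, tolerance = 0.3)
  cm <- vapply(res$estimates, `[[`, 0, "c_m")
  expect_equal(mean(cm), 50e-12, tolerance = 0.005)

  # on an unshifted noiseless record the procedure is consistent with the
  # plain three-element fit (zero-time falls back to 0, flagged)
  p <- circuit_params(50e-12, 200e6, 5e6)
  proto <- proto_for(p, v_stim = v)
  x <- simulate_square_wave(p, proto, carry_state = FALSE)
  rh <- fit_record_halves(x, proto, blank_head = 60e-6)
  std <- standard_procedure_fit(rh$segments, v, base_fits = rh$fits)
  expect_true(std$flagged)
  expect_equal(std$zero_time, 0)
  expect_equal(std$fits[[1]]$i_p, rh$fits[[1]]$i_p)
})

test_that("thermal resolution limit scales as the closed form dictates", {
  s0 <- thermal_limit(50e-12, 5e6, 0.02, 50)
  expect_equal(thermal_limit(50e-12, 5e6, 0.04, 50), s0 / 2)
  expect_equal(thermal_limit(50e-12, 5e6, 0.02, 200), 2 * s0)
  expect_equal(thermal_limit(50e-12, 20e6, 0.02, 50), 2 * s0)
  expect_equal(thermal_limit(100e-12, 5e6, 0.02, 50), 2 * s0)
  expect_error(thermal_limit(-1, 5e6, 0.02, 50), "positive")
  expect_equal(thermal_limit(50e-12, 5e6, 0.02, 50),
               50e-12 * sqrt(4 * 1.380649e-23 * 295 * 50 * 5e6) / 0.02)
})

test_that("optimal stimulation period is twelve time constants", {
  expect_equal(optimal_period(62e-6), 0.744e-3, tolerance = 1e-12)
  expect_equal(optimal_period(1e-3), 12e-3)
  taus <- c(2e-5, 1e-4, 5e-4)
  expect_equal(optimal_period(taus), 12 * taus)
  expect_error(optimal_period(0), "tau")
})
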
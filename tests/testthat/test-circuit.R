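test_that("time constant matches the parallel-RC closed form", {
  # smallest reliable cell of the method: 2 pF behind 10 MOhm
  small <- circuit_params(2e-12, 2e9, 10e6)
  expect_equal(time_constant(small) * 1e6, 19.9, tolerance = 1e-3)
  expect_equal(time_constant(small) * 1e6, 20, tolerance = 0.01)

  # R_M >> R_A limit: tau -> C_M * R_A
  big_rm <- circuit_params(50e-12, 1e15, 5e6)
  expect_equal(time_constant(big_rm), 50e-12 * 5e6, tolerance = 1e-8)

  # hand-evaluated closed form for the seal-sweep cell
  sweep_cell <- circuit_params(140e-12, 500e6, 4e6)
  expect_equal(time_constant(sweep_cell),
               140e-12 * (500e6 * 4e6) / (504e6), tolerance = 1e-15)

  expect_error(circuit_params(-1e-12, 1e6, 1e6), "c_m")
  expect_error(circuit_params(1e-12, 0, 1e6), "r_m")
})

test_that("step response has the theoretical peak, steady level and leak", {
  p <- circuit_params(20e-12, 300e6, 5e6)
  v <- 0.08
  tr <- simulate_step(p, v, 5e-3, DT)
  expect_equal(tr$samples[1], v / p$r_a, tolerance = 1e-12)
  expect_equal(tail(tr$samples, 1), v / (p$r_m + p$r_a), tolerance = 1e-6)

  # at t >= 10 tau the response is within 5e-5 of the peak-to-steady span
  tau <- time_constant(p)
  t <- trace_times(tr)
  i_p <- v / p$r_a
  i_s <- v / (p$r_m + p$r_a)
  late <- t >= 10 * tau
  expect_true(all(abs(tr$samples[late] - i_s) <= 5e-5 * abs(i_p - i_s)))

  # a finite seal adds exactly a constant leak at every sample
  p_leak <- circuit_params(20e-12, 300e6, 5e6, r_seal = 2e9)
  tr_leak <- simulate_step(p_leak, v, 5e-3, DT)
  expect_equal(tr_leak$samples - tr$samples,
               rep(v / 2e9, length(tr$samples)), tolerance = 1e-12)

  # parasitic capacitance: one-sample impulse of charge C_P * dV at onset
  p_cp <- circuit_params(20e-12, 300e6, 5e6, c_p = 2e-12)
  tr_cp <- simulate_step(p_cp, v, 5e-3, DT)
  expect_equal(tr_cp$samples[1] - tr$samples[1], 2e-12 * v / DT)
  expect_equal(tr_cp$samples[-1], tr$samples[-1])
})

test_that("square wave converges to a periodic orbit and obeys superposition", {
  p <- circuit_params(30e-12, 400e6, 6e6)
  proto <- proto_for(p, n_periods = 7)
  nh <- samples_per_half_period(proto)

  # from rest: half-periods k and k+2 agree to < 1e-9 relative after 5 periods
  x <- simulate_square_wave(p, proto, carry_state = TRUE, init = "holding")
  h11 <- x$samples[(10 * nh + 1):(11 * nh)]
  h13 <- x$samples[(12 * nh + 1):(13 * nh)]
  expect_lt(max(abs(h13 - h11)) / max(abs(h11)), 1e-9)

  # on the orbit every period repeats exactly
  xo <- simulate_square_wave(p, proto, carry_state = TRUE, init = "orbit")
  per1 <- xo$samples[1:(2 * nh)]
  per3 <- xo$samples[(4 * nh + 1):(6 * nh)]
  expect_lt(max(abs(per3 - per1)) / max(abs(per1)), 1e-12)

  # superposition: the first half-period from rest is the single-step response
  step <- simulate_step(p, proto$v_stim / 2, nh * DT, DT)
  expect_equal(x$samples[1:nh], step$samples, tolerance = 1e-12)

  # idealized generation: every half-period is the re-referenced step response
  xs <- simulate_square_wave(p, proto, carry_state = FALSE)
  th <- theory_params(p, proto$v_stim)
  t <- (seq_len(nh) - 1) * DT
  ideal <- th$i_s + th$i_p * exp(-t / th$tau)
  ref <- -(proto$v_stim / 2) / (p$r_m + p$r_a)  # settled opposite steady
  expect_equal(xs$samples[(2 * nh + 1):(3 * nh)] - ref, ideal,
               tolerance = 1e-12)
})

test_that("per-period parameter sequences are honoured and validated", {
  p1 <- circuit_params(30e-12, 400e6, 6e6)
  p2 <- circuit_params(30e-12, 400e6, 7e6)
  proto <- proto_for(p1, n_periods = 2)
  x <- simulate_square_wave(list(p1, p2), proto, carry_state = FALSE)
  nh <- samples_per_half_period(proto)
  # second period's peak reflects the larger access resistance
  ref <- -(proto$v_stim / 2) / (p2$r_m + p2$r_a)
  expect_equal(x$samples[2 * nh + 1] - ref, proto$v_stim / p2$r_a,
               tolerance = 1e-12)
  expect_error(simulate_square_wave(list(p1), proto), "n_periods")
})

test_that("fusion-pore transients reduce to mono-exponential when I_P2 = 0", {
  base <- list(i_s = 1e-10, i_p = 5e-9, tau = 2e-4)
  mono <- simulate_fusion_current(base, i_p2 = 0, tau2 = 1e-3,
                                  duration = 2e-3, dt = DT)
  t <- trace_times(mono)
  expect_equal(mono$samples, base$i_s + base$i_p * exp(-t / base$tau),
               tolerance = 1e-14)
  # tau2 = C_v / G_p: 100 fF through 0.5 nS opens over 200 us
  bi <- simulate_fusion_current(base, i_p2 = 5e-10, c_v = 100e-15,
                                g_p = 0.5e-9, duration = 2e-3, dt = DT)
  expect_equal(bi$samples - mono$samples, 5e-10 * exp(-t / 200e-6),
               tolerance = 1e-12)
  expect_error(simulate_fusion_current(base, 1e-10, tau2 = -1,
                                       duration = 1e-3, dt = DT), "tau2")
})

test_that("thermal noise has the Nyquist-band Johnson variance and is seedable", {
  flat <- current_trace(rep(0, 2e5), DT)
  r <- 5e6
  noisy1 <- add_thermal_noise(flat, r, t_abs = 295, seed = 42)
  noisy2 <- add_thermal_noise(flat, r, t_abs = 295, seed = 42)
  expect_identical(noisy1$samples, noisy2$samples)

  var_expected <- 4 * 1.380649e-23 * 295 * (FS / 2) / r
  expect_equal(var(noisy1$samples), var_expected, tolerance = 0.02)

  # zero temperature: identity
  cold <- add_thermal_noise(flat, r, t_abs = 0, seed = 1)
  expect_identical(cold$samples, flat$samples)
})

test_that("random triplets stay in the seeding ranges with uniform moments", {
  for (s in c(1, 7, 123)) {
    tr <- random_triplets(500, seed = s)
    expect_true(all(tr$c_m_pF >= 5 & tr$c_m_pF <= 200))
    expect_true(all(tr$r_m_GOhm >= 0.02 & tr$r_m_GOhm <= 2))
    expect_true(all(tr$r_a_MOhm >= 2 & tr$r_a_MOhm <= 20))
  }
  big <- random_triplets(1e5, seed = 9)
  expect_equal(mean(big$c_m_pF), 102.5, tolerance = 0.01)
  expect_equal(mean(big$r_m_GOhm), 1.01, tolerance = 0.01)
  expect_equal(mean(big$r_a_MOhm), 11, tolerance = 0.01)
})
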
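test_that("record averaging is the pointwise mean and suppresses noise as 1/sqrt(n)", {
  base <- current_trace(sin(seq(0, 4 * pi, length.out = 500)) * 1e-9, DT)
  expect_equal(average_records(list(base, base, base))$samples,
               base$samples, tolerance = 1e-15)
  set.seed(11)
  n_rep <- 1024
  sigma <- 1e-10
  noisy <- lapply(seq_len(n_rep), function(i)
    current_trace(base$samples + rnorm(500, 0, sigma), DT))
  avg <- average_records(noisy)
  resid_sd <- sd(avg$samples - base$samples)
  expect_equal(resid_sd, sigma / sqrt(n_rep), tolerance = 0.1)
  expect_error(average_records(list()), "no records")
  expect_error(average_records(list(base, current_trace(1:10, DT))), "length")
})

test_that("R-response is the R+C minus C difference and recovers a known filter", {
  filt <- bessel10k()
  h_true <- filter_impulse_response(filt, 256)
  artefact <- 2e-9 * exp(-(0:255) / 3)  # fast capacitive component
  rc <- current_trace(h_true + artefact, DT)
  cc <- current_trace(artefact, DT)
  r <- impulse_response(rc, cc)
  expect_equal(r$samples, h_true, tolerance = 1e-15)

  zero_c <- current_trace(rep(0, 256), DT)
  expect_identical(impulse_response(rc, zero_c)$samples, rc$samples)
})

test_that("transfer function of an ideal impulse is unity and DC-normalized", {
  H <- compute_H(current_trace(c(1, rep(0, 63)), DT))
  expect_equal(H$h, rep(1 + 0i, 64), tolerance = 1e-15)
  # scaling the impulse changes only the stored gain
  H2 <- compute_H(current_trace(c(2.5, rep(0, 63)), DT))
  expect_equal(H2$h, H$h, tolerance = 1e-15)
  expect_equal(H2$gain, 2.5)
  expect_error(compute_H(current_trace(rep(0, 16), DT)), "zero")
  expect_error(compute_H(current_trace(rep(1, 16), DT), nfft = 8), "nfft")
})

test_that("transfer of the Bessel emulation equals its closed-form response", {
  filt <- bessel10k()
  nfft <- 1024
  H <- transfer_from_filter(filt, nfft)
  f <- transfer_frequencies(H)
  H_closed <- filter_frequency_response(filt, f)
  expect_lt(max(Mod(H$h - H_closed)), 1e-9)
  # a 20 ms record at 100 kHz resolves 50 Hz; band extends to 50 kHz Nyquist
  H20 <- transfer_from_filter(filt, 2000)
  fr <- transfer_frequencies(H20)
  expect_equal(fr[2], 50)
  expect_equal(max(fr[fr <= FS / 2]), 50e3)
})

test_that("deconvolution inverts filtering on periodic records to < 1e-6 RMS", {
  p <- circuit_params(25e-12, 600e6, 5e6)
  run <- run_pipeline(p, proto_for(p, n_periods = 2))
  expect_lt(rel_rms(run$rec$samples, run$x$samples), 1e-6)
  # the filtered record is biphasic at the onset; the reconstruction is not
  expect_lt(max(run$rec$samples), max(run$y$samples) * 5)

  # H == 1 is the identity
  H1 <- compute_H(c(1, rep(0, length(run$y$samples) - 1)))
  H1$f_samp <- FS
  expect_equal(deconvolve(run$y, H1)$samples, run$y$samples,
               tolerance = 1e-12)
})

test_that("deconvolution is linear and preserves sums of zero-mean inputs", {
  filt <- bessel10k()
  n <- 256
  set.seed(5)
  x1 <- current_trace(rnorm(n), DT)
  x2 <- current_trace(rnorm(n), DT)
  H <- transfer_from_filter(filt, n)
  mix <- current_trace(2 * x1$samples - 3 * x2$samples, DT)
  lhs <- deconvolve(mix, H)$samples
  rhs <- 2 * deconvolve(x1, H)$samples - 3 * deconvolve(x2, H)$samples
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # treat the record as one period of an indefinitely running signal so that
  # the circular-convolution assumption of the deconvolution holds exactly
  xz <- current_trace(x1$samples - mean(x1$samples), DT)
  y <- apply_filter(xz, filt, steady = TRUE)
  back <- deconvolve(y, H)
  expect_lt(abs(sum(back$samples) - sum(xz$samples)) /
              sqrt(mean(xz$samples^2)), 1e-9)
})

test_that("frequency-domain deconvolution matches the circulant linear system", {
  set.seed(21)
  n <- 64
  h <- exp(-(0:(n - 1)) / 4)
  h <- h / sum(h)  # unity DC so both routes share the scale
  x <- rnorm(n)
  # direct circular convolution
  y <- vapply(0:(n - 1), function(k)
    sum(h * x[((k - (0:(n - 1))) %% n) + 1]), 0)
  # direct solution of the circulant system as the independent oracle
  C <- matrix(0, n, n)
  for (i in 0:(n - 1)) C[i + 1, ] <- h[((i - (0:(n - 1))) %% n) + 1]
  x_direct <- solve(C, y)
  H <- compute_H(y * 0 + h, nfft = n)
  x_fft <- deconvolve(current_trace(y, DT), H)$samples
  expect_lt(rel_rms(x_fft, x_direct), 1e-8)
  expect_lt(rel_rms(x_fft, x), 1e-8)
})

test_that("zero transfer bins require regularization", {
  # two-tap averager: exact null at the Nyquist bin
  H <- compute_H(c(0.5, 0.5), nfft = 2)
  tr <- current_trace(c(1, -1), DT)
  expect_error(deconvolve(tr, H), "zero bins")
  reg <- deconvolve(tr, H, epsilon = 1e-6)
  expect_true(all(is.finite(reg$samples)))
  expect_error(deconvolve(tr, H, epsilon = -1), "epsilon")
  expect_error(deconvolve(current_trace(1:3, DT), H), "length")
})

test_that("cell-attached subtraction cancels the parasitic component exactly", {
  p <- circuit_params(20e-12, 300e6, 5e6, c_p = 1.5e-12)
  p0 <- circuit_params(20e-12, 300e6, 5e6)
  proto <- proto_for(p)
  wc <- simulate_square_wave(p, proto, carry_state = FALSE)
  clean <- simulate_square_wave(p0, proto, carry_state = FALSE)
  cp_only <- current_trace(wc$samples - clean$samples, DT)
  expect_identical(subtract_cp_record(wc, cp_only)$samples, clean$samples)
  zero <- current_trace(rep(0, length(wc$samples)), DT)
  expect_identical(subtract_cp_record(wc, zero)$samples, wc$samples)
  expect_error(subtract_cp_record(wc, current_trace(1:4, DT)), "protocol")
})

test_that("transfer functions survive a CSV round trip bit-exactly", {
  H <- transfer_from_filter(bessel10k(), 128)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transfer(H, path)
  back <- read_transfer(path)
  expect_identical(back$h, H$h)
  expect_identical(back$f_samp, H$f_samp)
  expect_identical(back$nfft, H$nfft)
  expect_identical(back$gain, H$gain)
})
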
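# Shared fixtures built in code. The 10 kHz / 100 kHz Bessel emulation is the
# reference recording path of all pipeline tests.
FS <- 1e5
DT <- 1 / FS

bessel10k <- local({
  filt <- NULL
  function() {
    if (is.null(filt)) filt <<- design_bessel4(10e3, FS)
    filt
  }
})

# protocol with the optimal 12 tau period rounded to an even sample count
proto_for <- function(params, v_stim = 0.08, n_periods = 2, n_tau = 12) {
  tau <- time_constant(params)
  spp <- max(16L, 2L * as.integer(round(n_tau * tau * FS / 2)))
  stimulus_protocol(v_stim, spp / FS, FS, n_periods)
}

# simulate (idealized closed-form generation) -> filter causally -> trim one
# warmup period -> deconvolve; returns list(x = input, y = filtered,
# rec = reconstruction, proto = retained-protocol)
run_pipeline <- function(params, proto, filt = bessel10k()) {
  proto_w <- stimulus_protocol(proto$v_stim, proto$period, proto$f_samp,
                               proto$n_periods + 1L, proto$holding)
  plist <- if (inherits(params, "circuit_params"))
    rep(list(params), proto_w$n_periods) else c(params[1], params)
  x <- simulate_square_wave(plist, proto_w, carry_state = FALSE)
  y <- apply_filter(x, filt)
  nh <- samples_per_half_period(proto)
  keep <- (2L * nh + 1L):length(x$samples)
  xt <- current_trace(x$samples[keep], x$dt)
  yt <- current_trace(y$samples[keep], y$dt)
  H <- transfer_from_filter(filt, length(yt$samples))
  list(x = xt, y = yt, rec = deconvolve(yt, H), H = H, proto = proto)
}

rel_rms <- function(a, b) {
  sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
}

# theoretical current parameters of the re-referenced half-period
theory_params <- function(params, v_stim) {
  list(i_p = v_stim / params$r_a - v_stim / (params$r_m + params$r_a),
       i_s = v_stim / (params$r_m + params$r_a),
       tau = time_constant(params))
}
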
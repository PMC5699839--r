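---
title: "Reconstructing whole-cell currents by deconvolution: models, parameters and validation"
author: "capdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing whole-cell currents by deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdecon)
```

## The measurement problem

In the whole-cell patch-clamp configuration a cell is, to a good
approximation, the three-element circuit: membrane capacitance $C_M$ in
parallel with membrane resistance $R_M$, both reached through the pipette's
access resistance $R_A$. A voltage step of amplitude $V_{Stim}$ should draw
the current

$$I(t) = V_{Stim}\left[\frac{1}{R_A}e^{-t/\tau} +
\frac{1}{R_M+R_A}\left(1-e^{-t/\tau}\right)\right],\qquad
\tau = \frac{C_M R_M R_A}{R_M+R_A},$$

so that fitting the relaxation $I(t) = I_S + I_P e^{-t/\tau}$ and inverting

$$R_A = \frac{V_{Stim}}{I_P+I_S},\qquad R_M = \frac{V_{Stim}}{I_S}-R_A,\qquad
C_M = \tau\left(\frac{1}{R_M}+\frac{1}{R_A}\right)$$

returns the circuit. In practice the recorded current is the convolution of
this input with the impulse response of the recording path — dominated by the
amplifier's anti-aliasing low-pass filter (a 4-pole Bessel, typically 10 kHz,
sampled at 100 kHz). The filter turns the exponential into a biphasic,
ringing transient whose early samples cannot be fitted by the model; working
around it (blanking the first 60 µs and extrapolating the peak to a tuned
"zero time") is exactly what limits the accuracy and resolution of
conventional square-wave capacitance measurements, and what couples access
resistance fluctuations into spurious capacitance signals (cross-talk).

The package implements the alternative: measure (or model) the signal-path
frequency characteristic $H_S$, and reconstruct the input current by
frequency-domain deconvolution — FFT the record, divide bin-wise by $H_S$,
inverse-FFT. The reconstruction restores a clean exponential that the
three-element model fits without blanking or zero-time heuristics.

## The bipolar square-wave convention

Stimulation is a symmetric bipolar square wave. Throughout the package
`v_stim` is the **full step amplitude** (peak-to-peak): a "±40 mV" protocol
has `v_stim = 0.08`. This is the voltage that belongs in the conversion
formulas, because each half-period's peak current is referenced not to zero
but to the steady current of the *preceding* half-period, which sits at the
opposite polarity. Under this re-referencing every folded half-period is a
positive-going relaxation with peak $V_{Stim}/R_A$ and steady level
$V_{Stim}/(R_M+R_A)$, and the formulas above are exact.

Two re-referencing subtleties matter numerically:

* **Tail means are not steady levels.** At the optimal period
  $T_S = 12\tau$ each half-period spans $6\tau$, so the predecessor's
  transient still contributes $e^{-6}\approx 0.25\%$ of its amplitude to its
  final samples. When $R_M \gg R_A$ the steady current is tiny compared with
  the peak and this residue corrupts $I_S$ by tens of percent. The analysis
  therefore uses a two-pass scheme (`fit_record_halves()`): segments are cut
  and first fitted against the predecessor's tail mean, then each steady
  current is corrected to the predecessor's *fitted asymptote*. Only $I_S$
  needs the correction — an additive offset changes neither the fitted
  $\tau$ nor the transient amplitude.
* **Finite periods bias the orbit.** On the true periodic orbit the membrane
  voltage never quite reaches its asymptote, so the re-referenced peak falls
  short of $V_{Stim}/R_A$ by a relative $\theta e^{-6}\approx 0.24\%$
  ($\theta = R_M/(R_M+R_A)$). This is an intrinsic, constant property of
  square-wave stimulation at finite period, not of the reconstruction. The
  validation experiments therefore generate records in the idealized
  closed-form convention (`simulate_square_wave(carry_state = FALSE)`),
  where every half-period starts from the fully settled opposite level and
  the conversion formulas are exact; `carry_state = TRUE` remains available
  as the physically exact carried-state simulator.

## The filter emulation

`design_bessel4()` builds the analog 4th-order Bessel prototype from the
reverse Bessel polynomial $s^4+10s^3+45s^2+105s+105$, scales it so the
**magnitude** response is $-3$ dB at the corner (the convention of amplifier
output filters; a delay-normalized design would halve the apparent rise
time), and discretizes by invariance of the impulse response with the
conventional $1/f_{samp}$ gain, renormalized to exact unity DC gain. All
poles lie strictly inside the unit circle for any valid design.

`step_half_time()` reports when the unit-step response first crosses 50%,
with linear interpolation. Because the discrete convolution sum approximates
the continuous response at mid-sample instants, sample $n$ is assigned time
$(n+\tfrac12)/f_{samp}$; with this alignment the 10 kHz / 100 kHz design
crosses at 32.9 µs, independent of sampling rate and consistent with the
analog prototype (the measured value on real hardware is ~1 µs longer, the
residue of the stimulus and digitizer path that the equivalent-circuit model
does not include).

## Deconvolution: conventions and guards

* The FFT length is the full record length and records must contain an
  integer number of stimulation periods. For a periodic record processed by
  a filter in steady state, circular convolution is then *exact* and the
  round trip filter → deconvolve recovers the input to better than
  $10^{-6}$ relative RMS (in practice $\sim 10^{-13}$). Synthetic records
  reach the steady-filter condition either by prepending a warm-up period
  and trimming it after causal filtering, or with
  `apply_filter(steady = TRUE)`.
* With a modelled $H_S$ the division uses $\varepsilon = 0$. For measured
  characteristics, which can carry high-frequency interference, a
  Tikhonov-style guard (`epsilon > 0`, dividing by
  $(|H|^2+\varepsilon)/\bar H$) is available; an exactly-zero bin with
  $\varepsilon = 0$ raises an error rather than silently blowing up.
* The real part is returned after the inverse FFT; a residual imaginary
  component above $10^{-9}$ of the signal RMS triggers a warning as a
  health check.
* `blank_head` (e.g. 60 µs) does not zero the signal; it is honoured by the
  fitting layer, reproducing the blanking option used when uncompensated
  parasitic capacitance leaves damped oscillations at the reconstruction
  onset. The cleaner remedy — subtracting a cell-attached record before
  deconvolution — is `subtract_cp_record()`.

## Fitting and derived quantities

Transient fits use Levenberg–Marquardt least squares with analytic
Jacobians, a log-linear regression for the initial $\tau$, convergence
tolerances of $10^{-15}$ (relative SSE) / $10^{-12}$ (parameters) and a cap
of 200 iterations. Degenerate inputs (a pure resistor step with no
resolvable transient) are returned flagged, never raised. The five-element
fusion-pore fit seeds its slow component at $I_{P2} = 0.1 I_P$,
$\tau_2 = 5\tau$ and is preferred over the three-element model only when it
improves the SSE at least 2-fold (configurable); a $\tau_2$ collapsing below
the sampling interval is reported as the pore-fully-open sentinel with
$G_p = \infty$. With the vesicle capacitance $C_v$ supplied (the amplitude
of the capacitance step), the pore conductance is $G_p = C_v/\tau_2$.

The capacitive charge $Q_C = \Delta t\sum(I - I_S)$ integrates the transient
above the half-period's *own* fitted asymptote. Because a seal leak is
constant within a half-period it cancels in this difference, which is what
makes $Q_C$ the discriminating signature between true capacitance events
(mirrored in $Q_C$) and seal-resistance artefacts (anti-correlated
$C_M$/$R_M$ steps with $Q_C$ flat).

The standard-procedure baseline (`standard_procedure_fit()`) reproduces
conventional analysis of *filtered* records: 60 µs blanking, peak
extrapolation to a candidate zero time on a 0.1 µs grid spanning ±1 sample,
and selection of the zero time minimizing the absolute Pearson correlation
between the $C_M$ and $R_A$ series. The correlation criterion is this
package's concrete choice for a step the original description leaves
qualitative; it requires at least 8 usable estimates and genuine variation
(relative scatter above $10^{-9}$), otherwise it falls back, flagged, to
zero correction.

## The synthetic-data generator and the validation experiments

The generator emulates: the three-element response, the seal-leak variant
(adding $V_{Stim}/R_{Seal}$), parasitic capacitance as a one-sample charge
impulse $C_P\,\Delta V$ at each step onset (the physical charging is faster
than one 10 µs sample because it bypasses $R_A$), bi-exponential fusion
transients, and Johnson current noise with per-sample variance
$4kT(f_{samp}/2)/R$ (white within the Nyquist band). It does not emulate
1/f noise, dielectric loss, voltage-dependent capacitance, solution-exchange
or temperature drifts, or multi-compartment (non-isopotential) cells — so
passing tests validate the *procedure*, not those confounders.

The validation experiments run noiseless except where noise is the subject,
matching the near-zero residuals they are checked against:

* **Accuracy** (`accuracy_experiment()`): 100 random triplets drawn
  uniformly from $C_M\in[5,200]$ pF, $R_M\in[0.02,2]$ GΩ,
  $R_A\in[2,20]$ MΩ, each simulated at $T_S = 12\tau$ (even sample counts,
  at least 8 samples per half-period), filtered, reconstructed, fitted.
  Relative errors recovered here are at numerical precision
  ($\sim 10^{-13}$), far inside the sub-0.02% band expected for $C_M$.
* **Cross-talk** (`crosstalk_experiment()`): sibling records differing by
  +1 MΩ in $R_A$ (or +100 MΩ in $R_M$); the deconvolution path reads the
  seeded change and leaks nothing detectable ($\ll$ 1 fF) into $C_M$.
* **Resolution under $R_A$ fluctuation**
  (`resolution_vs_ra_fluctuation()`): a 50 pF / 200 MΩ / 5 MΩ cell at
  ±10 mV with per-period $R_A$ jitter at the seven nominal spreads from
  22.6 to 452.1 kΩ, 200 draws each (500 at full scale), capacitance series
  reduced to 50 Hz bandwidth. Each period is generated *and analysed*
  self-contained on its own orbit: carrying membrane state across a
  parameter change would make the first half-period's re-reference inherit
  an $O(V\,\delta R_A/(R_M+R_A)^2)$ offset amounting to fF-scale artefacts —
  orders above what the method itself contributes — whereas closed-form
  per-period generation isolates the analysis cross-talk proper, which sits
  many orders below the thermal floor
  $\sigma C_M = C_M\sqrt{4kTBR_A}/V_{Stim}$. The standard path, analysed on
  the same records, converts its deterministic $C_M(R_A)$ bias into
  capacitance noise that grows with the jitter and exceeds the thermal
  floor throughout.
* **Seal sweep** (`seal_sweep_experiment()`): the 140 pF / 500 MΩ / 4 MΩ
  cell (one report prints 140 fF for the same configuration; the pF value
  is the consistent one) at ±10 mV, $6\tau$ period, $R_{Seal}$ stepped
  1 → 150 GΩ in 100 MΩ increments. Below ~10 GΩ the apparent $C_M$ and
  $R_M$ distort strongly, $R_A$ moves by well under 0.5%, and $Q_C$ is
  invariant to $<10^{-9}$ relative.
* **Event classification** (`classify_event()`): a two-sided CUSUM
  change-point on the $C_M$ series (threshold $5\times$ the robust noise
  scale) followed by the deterministic signature rules. "Quiet" defaults
  are $3\times$ the thermal floor for $C_M$ (and its charge equivalent for
  $Q_C$) and $3\times$ the robust pre-window scatter for $R_M$/$R_A$, with
  relative guards ($10^{-6}$ for $C_M$/$Q_C$, $10^{-3}$ for $R_M$/$R_A$)
  so that noiseless synthetic series behave; these defaults are package
  choices where the original account is qualitative.

Problem sizes above (100 triplets, 200 jitter draws, 2 retained periods per
record with one warm-up) are the package's default desk-scale settings; all
experiments accept larger values, and every experiment is bit-reproducible
under a fixed seed.

## Known limitations

* fF-scale vesicular events and pore trajectories measured on living cells
  involve noise sources (1/f, membrane-conductance activity) the generator
  does not model; the synthetic analogues validate parameter recovery, not
  in-vivo detectability.
* The standard-procedure baseline implements one defensible reading of
  zero-time tuning; other laboratories' variants may differ in detail.
* ABF acquisition files are not readable in this build; records are
  exchanged as two-column text traces.
* The impedance model assumes a homogeneously voltage-clamped cell; no
  multi-compartment corrections are attempted.
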
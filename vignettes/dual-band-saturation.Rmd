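---
title: "Quasi-adiabatic dual-band saturation pulses and ATP flux quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-adiabatic dual-band saturation pulses and ATP flux quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phosphorus saturation-transfer spectroscopy measures metabolic fluxes by
nulling one exchange partner's resonance with selective RF irradiation and
watching the exchange-mediated signal loss of its partner.  The forward
creatine-kinase rate `kf` needs only a single saturation band on gamma-ATP.
Measuring the *total* ATP turnover `(kr + kr')` instead requires
simultaneous saturation of phosphocreatine (PCr) and inorganic phosphate
(Pi) — two bands 950 Hz apart at 11.7 T — while leaving the nearby
gamma-ATP resonance (about −1000 Hz from the PCr/Pi midpoint) untouched.
Conventional hard-cosine DANTE trains do this only inside a narrow window
of B1 amplitudes: too little B1 under-saturates the bands, too much spills
onto gamma-ATP and silently biases the measured flux.

`mrsat` implements the full chain from pulse design to cohort statistics:

1. a time-domain Bloch simulator in the rotating frame (`bloch.R`,
   compiled core);
2. the forward/inverse Shinnar-Le Roux (SLR) transform and a
   quadratic-phase imposition in the Cayley-Klein domain (`slr.R`);
3. optimal-control design of the dual-band pulse with an exact
   adjoint-state gradient (`design.R`);
4. quantitative pulse metrics: B1 immunity fold-range, minimum effective
   B1, spillover, deposited power (`metrics.R`);
5. saturation-transfer curve fitting, flux computation and first-order
   error propagation, absolute quantification against an internal
   reference, and deterministic synthetic-data generators
   (`sattransfer.R`, `quantify.R`, `fixtures.R`).

## Simulation model

Magnetization evolves per RF sample by an exact rotation about the
effective field `(γB1x, γB1y, 2π·Δf)` followed by exponential T1/T2
relaxation toward equilibrium (operator splitting; error O(dt²), exact
whenever either part vanishes).  `γ(³¹P) = 17.235 Hz/μT`.  The simulation
is purely spectral: an applied gradient would enter exactly like the
off-resonance term, so the spatial axis of slice-selective formulations
and the spectral axis here are interchangeable.  Gradient crushers are
ideal — transverse magnetization zeroed instantaneously, `Mz` untouched —
because no crusher areas are available to model dephasing more finely.

Relaxation defaults to `T1 = T2 = ∞` in all simulation-based metrics: the
metabolite relaxation times used in the original simulations of this
experiment are not published, and supplying invented defaults would bury
an arbitrary choice inside headline numbers.  Consequently all pulse
comparisons are phrased as ratios and order relations, and users with
known T1/T2 can pass a `spin_system` everywhere.  What this excludes: with
infinite relaxation times, off-resonant spillover is rotation-only and far
smaller than in tissue, so absolute spillover levels here underestimate
in-vivo spillover for both the designed and the reference pulse; their
*ratio* is the meaningful quantity.

## SLR transform and the quadratic phase

The hard-pulse approximation maps an n-sample pulse to complex
polynomials `A(z), B(z)` of degree n−1 with `|A|² + |B|² = 1` on the unit
circle; evaluation at `z = e^{iω}` is a zero-padded DFT, and the
relaxation-free longitudinal response obeys `mz(ω) = 1 − 2|B(ω)|²`.  A
physical offset f maps to `ω = −2πf·dwell` under the simulator's sign
convention (verified against the Bloch oracle to 1e-8 on random pulses).

Quasi-adiabaticity is imposed by multiplying the B-profile by
`e^{ik·(2πf)²}` and transforming back.  `k` is in seconds²: the group
delay added at offset f is `2k·2πf`, so `k = 4.1e-6 s²` sweeps a 150 Hz
band over about 7.7 ms of a 25 ms pulse.  Two numerical choices matter:

* **Circular (native-grid) multiplication.**  At the band centers
  (±475 Hz) the linear part of the quadratic phase corresponds to a
  ±24.5 ms delay — nearly the full pulse duration.  On the native n-point
  circular grid this wraps to ∓0.5 ms and only the in-band chirp remains;
  on an oversampled grid the bands would be shifted out of the window and
  truncated away.  The transform is therefore circular by default
  (`oversample = 1`), which also makes `|B′(ω)| = |B(ω)|` exact on the
  evaluation grid and the k → −k round trip exact to machine precision.
* **A-polynomial handling.**  By default the original A is reused;
  the pair is then exactly unimodular on the native grid but deviates in
  between (at the few-percent level for chirped B), so validation happens
  on the native grid.  `recompute_a = TRUE` replaces A by the minimum-phase
  spectral factor of `1 − |B′|²` via the complex-cepstrum construction,
  restoring off-grid unimodularity at the cost of a different (minimum-energy)
  pulse phase.

For a transform-limited input (compact b impulse response) the
hybridized pulse shows the textbook signature: a single linear frequency
ramp (R² > 0.999 for the instantaneous frequency) and a reduced peak
amplitude.  For a dispersed input — such as a converged optimal-control
pulse — the chirp can interfere constructively and raise the peak, and the
two-band beat structure dominates `∂φ/∂t`; the end-to-end designer
therefore rescales its output into the hardware B1 box.  This is a known
departure from the idealized single-band picture and is why the
chirp-signature tests use the transform-limited reference case.

## Optimal-control design

The design minimizes

`J(u) = ½ Σ_f w(f) ‖M(T; f, u) − Md(f)‖² + (λ/2) ∫ ‖u‖² dt`

over the complex samples u with `|u| ≤ B1max`.  The gradient is computed
by the adjoint-state method with the closed-form derivative of the SO(3)
rotation map, exact for the discrete stepped model; it matches central
finite differences to better than 1e-5 relative (asserted in the test
suite on every run).  Optimization is box-constrained L-BFGS-B in
50-iteration chunks with a best-so-far cost history (non-increasing by
construction); it stops on optimizer convergence, gradient tolerance,
cost stagnation or the iteration budget, and the `converged` flag
additionally requires the passband criterion — relative excitation
`|Mxy|/M0` at 0 Hz below `stopband_max`.

The target is two saturation slabs (mz = 0) of 150 Hz FWHM with 2.5 Hz
linear edge ramps, convolved with a Gaussian kernel, equilibrium
elsewhere.  Weights follow the filter-design convention of one weight per
ripple region:

* band core (saturation fraction > 0.99): longitudinal component only —
  a crusher follows the pulse, so the transverse state inside a band is
  irrelevant;
* stopband (saturation fraction < 0.001): all components, weighted by
  `(0.05 / stopband_max)²` so band and stopband approach their
  respective ripple targets together;
* transition: zero weight.  Edges steeper than the pulse's spectral
  resolution (≈ 1/duration = 40 Hz for 25 ms) are not realizable, and
  keeping them in the objective both stalls the optimizer and inflates
  pulse energy severalfold.

Tunable parameters and defaults: band centers ±475 Hz (950 Hz gap), FWHM
150 Hz, duration 25 ms, 2500 samples, nominal B1 1.3 μT, `k = 4.1e-6 s²`,
passband criterion 1e-7, smoothing σ 5 Hz, λ = 0.05 (the SAR/fidelity
trade; with region weighting the design is insensitive to λ over two
orders of magnitude).  `design_spec_desk()` is the reduced-resolution
variant used throughout the tests: 512 samples, passband criterion 1e-4,
objective grid 10 Hz, smoothing σ 15 Hz.  The wider desk-scale σ follows
the time-bandwidth argument above — with it the 512-sample design is
well-posed and converges in under a minute; the full-resolution default
(σ 5 Hz, criterion 1e-7) is an overnight run reproduced by
`scripts/full_design.R`.

## Evaluation metrics

All chain metrics simulate the full back-to-back train (183 repeats of
25 ms in 4.575 s; crushers between repeats) over a 41-point log-spaced B1
scan spanning 0.1–10× the subpulse peak, with bisection refinement to 1%
at decision boundaries:

* *minimum effective B1*: smallest peak B1 with ≥ 99% saturation at both
  band centers after the chain;
* *spillover*: fraction of equilibrium `Mz` destroyed at the gamma-ATP
  checkpoint, fixed at −1000 Hz from the band midpoint;
* *B1-immunity fold-range*: (largest B1 keeping spillover ≤ 1%) /
  (minimum effective B1).  When spillover never reaches 1% in the scan,
  the scan ceiling is reported and flagged as a lower bound;
* *deposited power* `∫|B1|² dt` and `B1rms` over the total chain duration
  including idle time (`power = B1rms² · T` is asserted as an identity).

At desk scale the designed train reaches a fold-range of ≈ 33 against
≈ 17 for the 19 ms / 0.32 μT hard-cosine train, needs ≈ 2× the
hard-cosine's minimum effective B1, and shows 2–3 orders of magnitude
less gamma-ATP spillover at its minimum effective B1.  Its deposited
power at minimum effective B1 is comparable to (slightly above) the
hard-cosine's rather than half of it: with full-duty trains and
band-center efficiency criteria, a flat 150 Hz saturation band
intrinsically costs more energy than a cosine whose response is probed
only at its center, and the 25-vs-19 ms subpulse advantage is not enough
to overcome it.  A lower ratio requires either a duty-cycled reference
train or in-band responses peaked at the centers; both are definitional
choices, not physics, and the package keeps the transparent full-duty
definition.

## Saturation-transfer kinetics

The observed amplitude after saturating the partner pool for time t is
the integrated two-pool exchange solution

`Y(t) = M0 (1 − k·τ (1 − e^{−t/τ}))`, with `1/τ = 1/T1 + k`,

whose asymptote is `M0/(1 + k·T1)`.  Fitting is bounded nonlinear least
squares in `(m0, k, ρ)` with `ρ = 1/T1 ≥ 0` and `τ = 1/(k + ρ)` — the
physical constraint (T1 ≥ 0, equivalently apparent rate ≥ k) expressed as
simple bounds — from 20 Latin-hypercube starts under a fixed seed,
keeping the best optimum; uncertainties come from the weighted Jacobian
at the solution.  Noiseless curves are recovered to 1e-6.  At 2%
amplitude noise on the six-duration protocol
`[0, 0.15, 0.275, 0.575, 2.25, 4.575] s` the median bias of k̂ is below
5% at k = 0.3 s⁻¹, but individual estimates scatter by 15–20% — an
identifiability limit of the six-point design (k and τ trade against each
other once the curve reaches its asymptote), not an optimizer artifact;
equilibrium amplitudes are determined to a few percent.

Fluxes are `Synth = kf·[PCr] + kf′·[Pi]` and `Deg = (kr+kr′)·[ATP]`, with
relative uncertainties propagated by quadrature of the contributing
relative errors.  For the degradation flux (a single product) the
quadrature is exact and matches Monte-Carlo propagation; for the
synthesis flux (a sum of products) it is the first-order form with unit
sensitivity per term and is accurate when one term dominates, which is
the regime of the intended application (the Pi term carries most of the
uncertainty).  Cohort summaries report mean ± SEM (sample sd / √n) plus
paired and unpaired t statistics and the Wilcoxon signed-rank statistic
comparing synthesis against degradation flux — diagnostics, not decision
rules, at n = 5.

Absolute quantification uses the internal 100 mM reference in the
left-ventricular balloon: spiked known volumes give a linear calibration
`signal = slope·(V0 + v_added)` whose intercept/slope ratio is the
baseline volume; metabolite amplitude ratios then convert to
intracellular millimolar using a 52% intracellular volume fraction and
1.05 g/ml tissue density.  The quantification formula is the standard
internal-reference construction (reference moles scaled by the amplitude
ratio over the intracellular water volume); it is reconstructed here from
the stated constants, as no closed formula is published for this
protocol.  Whether extracellular Pi should be subtracted before applying
the 52% fraction is left to the caller (amplitudes are inputs).

## Synthetic data

`gen_st_dataset()` evaluates the signal model and adds i.i.d. Gaussian
amplitude noise (spectral-fit amplitude estimates are approximately
Gaussian at these SNRs); `gen_cohort()` draws per-heart rates and
concentrations uniformly from ranges emulating the healthy perfused rat
heart (kf 0.15–0.45 s⁻¹, kf′ 0.08–0.4 s⁻¹, kr+kr′ 0.6–1.8 s⁻¹, ATP 6–9,
PCr 10–14, Pi 3–7 mM) with apparent τ derived from assumed intrinsic T1
values at 11.7 T (PCr 3.5 s, Pi 2.5 s, gamma-ATP 1.0 s).  Everything is
reproducible from a single integer seed without touching the caller's
RNG stream.  The generator emulates amplitude noise only: no baseline
distortion, no lineshape overlap, no B0 drift, no partial saturation of
the reference — so passing recovery tests demonstrate the estimator's
correctness and noise response, not robustness to spectral-fitting
artifacts upstream.

## Known limitations

* Chemical exchange *during* the pulse is not simulated (the kinetics use
  the integrated closed form, not Bloch-McConnell dynamics).
* Relaxation-free defaults understate absolute spillover (see above).
* The desk-scale (512-sample) design reproduces the comparative claims
  as ratios/properties; the printed full-resolution figures (1e-7
  passband, 1e-9 spillover excitation) require the overnight
  full-resolution run.
* The composite instantaneous-frequency ramp structure of the dual-band
  hybridized pulse is masked by band beating; the chirp signature is
  verified on the single-band transform-limited case.
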
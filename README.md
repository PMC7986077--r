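# mrsat

Design and evaluation of quasi-adiabatic, dual-band frequency-selective
saturation RF pulses for phosphorus (³¹P) magnetic-resonance spectroscopy,
and the downstream saturation-transfer kinetics needed to quantify
myocardial ATP synthesis and degradation fluxes.

## Who this is for

MR physicists and spectroscopists who need to saturate phosphocreatine
(PCr) and inorganic phosphate (Pi) simultaneously — two resonances
950 Hz apart at 11.7 T — without touching the nearby γ-ATP resonance, and
cardiac-metabolism researchers who fit the resulting saturation-transfer
curves to rate constants and fluxes.

## What it implements

**Pulse design.**  A hybrid of optimal control and the Shinnar–Le Roux
(SLR) transform:

1. minimize
   `J(u) = ½ Σ_f w(f) ‖M(T; f, u) − M_d(f)‖² + (λ/2)∫‖u(t)‖² dt`
   over the complex RF samples u with `|u| ≤ B1max`, where `M(T; f, u)`
   is the Bloch solution at offset f and `M_d` is a dual-band saturation
   target (mz = 0 inside two 150 Hz bands at ±475 Hz, equilibrium
   elsewhere).  The gradient is the exact adjoint-state gradient of the
   discrete model;
2. transform the converged pulse to its Cayley–Klein polynomial pair
   `(A(z), B(z))`, multiply the B-profile by a quadratic spectral phase
   `e^{ik(2πf)²}` (k = 4.1×10⁻⁶ s²), and invert — giving the pulse a
   frequency sweep and therefore a degree of adiabaticity (insensitivity
   to B1 above a threshold) without changing its spectral bandwidth.

**Evaluation.**  A compiled time-domain Bloch simulator (rotating frame,
exact per-sample rotations, T1/T2, ideal crushers) drives all metrics:
saturation efficiency and γ-ATP spillover of full back-to-back DANTE
trains, minimum effective B1, deposited power `∫|B1|²dt`, B1rms, and the
B1-immunity fold-range — the factor by which B1 can vary while both bands
stay ≥ 99% saturated and spillover stays ≤ 1%.

**Kinetics.**  Saturation-transfer curves are fitted to
`Y(t) = M0(1 − kτ(1 − e^{−t/τ}))` with `1/τ = 1/T1 + k` by bounded
multi-start nonlinear least squares; fluxes follow as
`Synth = kf[PCr] + kf′[Pi]` and `Deg = (kr+kr′)[ATP]` with first-order
error propagation, cohort mean ± SEM summaries, and absolute
quantification against a 100 mM internal reference.  Deterministic
synthetic-data generators make the whole pipeline testable offline.

## Worked example

```r
library(mrsat)

# design the dual-band pulse at reduced resolution (512 samples, ~1 min)
res <- design_dual_band_saturation(design_spec_desk())
print(res$pulse)
rep <- res$report
cat(sprintf("minimum effective B1: %.3f uT\nB1-immunity fold-range: %.1f\n",
            rep$min_effective_b1_ut, as.numeric(rep$immunity_fold)))

# simulate a gamma-ATP saturation-transfer experiment and fit it
curve <- gen_st_dataset(m0 = 7.2, k = 1.1, tau = 1 / (1 / 1.0 + 1.1),
                        noise_sd = 0.02, seed = 42)
fit <- fit_st_curve(curve)
cat(sprintf("fit: k = %.3f 1/s, T1 = %.2f s\n", fit$k_per_s, fit$t1_seconds))
cat(sprintf("degradation flux: %.2f mM/s\n",
            degradation_flux(fit$k_per_s, 7.31)))
```

prints

```
RF pulse 'qa-dual-band': 512 samples, 25 ms, dwell 48.83 us, peak 1.3 uT
minimum effective B1: 0.391 uT
B1-immunity fold-range: 33.0
fit: k = 1.148 1/s, T1 = 0.97 s
degradation flux: 8.39 mM/s
```

The minimum effective B1 is the smallest peak amplitude at which a
4.575 s train of the pulse saturates both bands to ≥ 99%; the fold-range
says B1 may then grow 33-fold before γ-ATP spillover exceeds 1% — the
property that removes the need for a separate control experiment.  In the
kinetics example the generator's truth was k = 1.1 s⁻¹ and T1 = 1.0 s;
the fit recovers them within the noise, and multiplying k by the ATP
concentration (7.31 mM) gives the total ATP degradation flux.

A command-line surface wraps the same functions
(`inst/cli/mrsat design|simulate|evaluate|dante|fit-st|flux|quantify|make-fixtures`),
and `scripts/full_design.R` runs the full-resolution 2500-sample design
(an overnight computation).

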
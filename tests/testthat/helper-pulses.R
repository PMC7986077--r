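# Shared fixture builders.  Everything is generated in code; no files.

random_pulse <- function(n, dwell = 1e-5, sd = 0.2, seed = 1) {
  set.seed(seed)
  pulse_waveform(complex(real = rnorm(n, 0, sd), imaginary = rnorm(n, 0, sd)),
                 dwell, label = "random")
}

# Compact linear-phase single-band pulse built directly in the Cayley-Klein
# domain: Gaussian |B| profile at +center_hz, minimum-phase A.  Its b
# impulse response is transform-limited, which makes it the clean reference
# case for quadratic-phase chirp behavior.
gaussian_band_pulse <- function(n = 256, dwell = 0.025 / 256,
                                center_hz = 475, sigma_hz = 60,
                                bmax = 0.6) {
  m <- 0:(n - 1)
  om <- 2 * pi * m / n
  om[om > pi] <- om[om > pi] - 2 * pi
  f <- -om / (2 * pi * dwell)
  Bg <- bmax * exp(-(f - center_hz)^2 / (2 * sigma_hz^2)) *
    exp(1i * om * (n / 2))
  b <- stats::fft(Bg, inverse = TRUE) / n
  a <- mrsat:::.min_phase_a(b, n)
  inverse_slr(ab_polynomials(a, b, dwell, tol = 1e-6, n_grid = n),
              label = "gaussian-band")
}

# Printed per-heart rates, concentrations and fluxes of the reference
# cohort (n = 5 perfused rat hearts) used by the arithmetic checks.
reference_cohort <- function() {
  data.frame(
    heart_id = 1:5,
    gamma_atp_mm = c(7.56, 7.02, 6.90, 9.12, 5.96),
    pcr_mm = c(10.44, 10.95, 10.15, 12.59, 13.78),
    pcr_atp_ratio = c(1.38, 1.56, 1.47, 1.38, 2.31),
    pi_mm = c(6.93, 7.01, 4.38, 5.21, 2.98),
    kf_per_s = c(0.43, 0.25, 0.28, 0.26, 0.14),
    kf_prime_per_s = c(0.42, 0.21, 0.11, 0.09, 0.22),
    kr_sum_per_s = c(1.77, 0.99, 0.92, 0.60, 0.96),
    synth_flux_mm_s = c(7.35, 4.23, 3.30, 3.72, 2.58),
    deg_flux_mm_s = c(13.39, 6.93, 6.34, 5.52, 2.22))
}

relaxation_free <- function(offset_hz = 0) spin_system(offset_hz = offset_hz)
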
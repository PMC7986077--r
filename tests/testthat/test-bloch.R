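# Bloch simulator: rotations, relaxation, profiles, chains.

test_that("hard-pulse flip-angle identity gives a 90 degree rotation", {
  # gamma * B1 * dt = 17.235 * 14.51 * 1e-3 = 0.2501 cycles
  m <- rotate_relax_step(magnetization(0, 0, 1), 14.51 + 0i, 0, 1e-3,
                         relaxation_free())
  expect_lt(abs(m[["mz"]]), 2e-3)
  expect_equal(abs(m[["my"]]), 1, tolerance = 1e-4)
})

test_that("free precession leaves the longitudinal state untouched", {
  m <- rotate_relax_step(magnetization(0, 0, 1), 0 + 0i, 100, 0.0123,
                         relaxation_free())
  expect_equal(unclass(m), c(mx = 0, my = 0, mz = 1))
})

test_that("pure T2 decay follows the closed form", {
  s <- spin_system(t1_seconds = Inf, t2_seconds = 0.1)
  m <- rotate_relax_step(magnetization(1, 0, 0), 0 + 0i, 0, 0.1, s)
  expect_equal(m[["mx"]], exp(-1), tolerance = 1e-12)
})

test_that("T1 recovery with no RF matches the closed form at every step", {
  s <- spin_system(t1_seconds = 0.8, t2_seconds = 0.3)
  zero <- pulse_waveform(rep(0 + 0i, 200), 5e-4)
  m <- simulate_pulse(zero, s, initial = magnetization(0, 0, -1))
  t_tot <- 200 * 5e-4
  expect_equal(m[["mz"]], 1 + (-1 - 1) * exp(-t_tot / 0.8),
               tolerance = 1e-12)
})

test_that("rotation-only evolution conserves the magnetization norm", {
  set.seed(42)
  for (i in 1:10) {
    n <- 1000
    p <- random_pulse(n, dwell = 1e-5, sd = 2, seed = i)
    m0 <- magnetization(rnorm(1), rnorm(1), rnorm(1))
    norm0 <- sqrt(sum(m0^2))
    m <- simulate_pulse(p, spin_system(offset_hz = runif(1, -2000, 2000)),
                        initial = m0)
    expect_lt(abs(sqrt(sum(m^2)) - norm0), 1e-9 * n)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(rotate_relax_step(magnetization(0, 0, 1), NaN + 0i, 0, 1e-3,
                                 relaxation_free()),
               class = "mrsat_invalid_input")
  expect_error(spin_system(t1_seconds = -1), class = "mrsat_invalid_input")
  expect_error(pulse_waveform(complex(0), 1e-5),
               class = "mrsat_invalid_input")
  expect_error(pulse_waveform(c(1 + 0i), -1e-5),
               class = "mrsat_invalid_input")
  expect_error(pulse_waveform(c(2 + 0i), 1e-5, nominal_peak_b1_ut = 1),
               class = "mrsat_invalid_input")
})

test_that("zero B1 scale returns the initial state; 90 degree pulse nulls mz", {
  p <- pulse_waveform(rep(14.51 + 0i, 10), 1e-4)
  init <- magnetization(0.2, -0.1, 0.9)
  expect_equal(as.numeric(simulate_pulse(p, relaxation_free(), b1_scale = 0,
                                         initial = init)),
               as.numeric(init))
  m <- simulate_pulse(p, relaxation_free())
  expect_lt(abs(m[["mz"]]), 2e-3)
})

test_that("scaling the pulse equals scaling the samples, and runs repeat", {
  p <- random_pulse(64, seed = 7)
  s <- relaxation_free(offset_hz = 321)
  m1 <- simulate_pulse(p, s, b1_scale = 0.37)
  p2 <- p
  p2$samples <- p2$samples * 0.37
  m2 <- simulate_pulse(p2, s)
  expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-12)
  expect_identical(simulate_pulse(p, s, b1_scale = 0.37), m1)
})

test_that("small-tip Bloch profile matches the discrete Fourier transform", {
  n <- 128
  dwell <- 1e-4
  set.seed(5)
  raw <- complex(real = rnorm(n), imaginary = rnorm(n))
  # normalize to a 5 degree total on-resonance flip
  flip <- 2 * pi * 17.235 * sum(Mod(raw)) * dwell
  u <- raw * (5 / 180 * pi) / flip
  p <- pulse_waveform(u, dwell)
  offs <- seq(-20, 20, by = 1) / (n * dwell)   # DFT frequencies
  prof <- frequency_profile(p, offs)
  # under the rotating-frame sign convention the response at offset f is
  # the Fourier component at +f: sum_j u_j exp(+2i pi f t_j)
  ft <- vapply(offs, function(f) {
    Mod(sum(u * exp(2i * pi * f * (0:(n - 1)) * dwell)))
  }, numeric(1))
  a <- prof$abs_mxy / sqrt(sum(prof$abs_mxy^2))
  b <- ft / sqrt(sum(ft^2))
  expect_lt(sqrt(sum((a - b)^2)) / sqrt(sum(b^2)), 0.02)
})

test_that("frequency profile of a real pulse is symmetric and reduces to
           simulate_pulse at a single offset", {
  p <- make_hard_cosine_pulse(0.019, 475, 0.32, 256)
  offs <- seq(25, 1500, by = 125)
  pr_pos <- frequency_profile(p, offs)
  pr_neg <- frequency_profile(p, -offs)
  expect_equal(pr_pos$abs_mxy, pr_neg$abs_mxy, tolerance = 1e-9)
  one <- frequency_profile(p, 210)
  m <- simulate_pulse(p, relaxation_free(offset_hz = 210))
  expect_equal(one$mz, m[["mz"]], tolerance = 1e-12)
})

test_that("hard-cosine response concentrates at the modulation sidebands", {
  p <- make_hard_cosine_pulse(0.019, 475, 0.32, 512)
  prof <- frequency_profile(p, c(-1000, -475, 0, 475))
  expect_gt(prof$abs_mxy[2] / prof$abs_mxy[1], 50)
  expect_gt(prof$abs_mxy[4] / prof$abs_mxy[3], 50)
})

test_that("B1-frequency map: zero-scale row at equilibrium, deterministic,
           smooth on a refined grid", {
  p <- make_hard_cosine_pulse(0.019, 475, 0.32, 128)
  scales <- c(0, 0.5, 1)
  offs <- seq(-600, 600, by = 100)
  map1 <- b1_frequency_map(p, scales, offs)
  expect_true(all(map1$mz[map1$b1_scale == 0] == 1))
  expect_true(all(map1$mz >= -1 - 1e-9 & map1$mz <= 1 + 1e-9))
  expect_identical(map1, b1_frequency_map(p, scales, offs))
  fine <- b1_frequency_map(p, seq(0.5, 1, by = 0.02 * 0.5),
                           seq(-600, 600, by = 10))
  for (sc in unique(fine$b1_scale)) {
    dmz <- diff(fine$mz[fine$b1_scale == sc])
    expect_lt(max(abs(dmz)), 0.5)
  }
})

test_that("saturation chains: ideal 90+crush zeroes mz, zero scale is inert,
           and schedules validate", {
  p90 <- pulse_waveform(rep(14.51 + 0i, 10), 1e-4)
  chain <- chain_schedule(p90, 5 * p90$duration_seconds)
  mz <- simulate_saturation_chain(chain, relaxation_free())
  expect_equal(length(mz), 5L)
  expect_true(all(abs(mz) < 2e-3))
  expect_true(all(simulate_saturation_chain(chain, relaxation_free(),
                                            b1_scale = 0) == 1))
  expect_error(chain_schedule(p90, 0.5 * p90$duration_seconds),
               class = "mrsat_invalid_input")
  empty <- chain_schedule(p90, 0)
  expect_identical(simulate_saturation_chain(empty, relaxation_free()), 1)
})
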
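# Optimal-control design, hybridization, and reference pulses.

toy_target <- function() {
  # small hand-built target: saturate around -500/+500 Hz loosely
  offs <- seq(-800, 800, by = 200)
  md <- rbind(mx = rep(0, 9), my = rep(0, 9),
              mz = c(1, 0, 1, 1, 1, 1, 1, 0, 1))
  w <- rbind(rep(1, 9), rep(1, 9), rep(1, 9)) / 9
  structure(list(offsets_hz = offs, md = md, weights = w),
            class = "target_profile")
}

test_that("design specifications validate their geometry", {
  spec <- design_spec()
  expect_equal(spec$band_centers_hz, c(-475, 475))
  expect_equal(spec$spill_offset_hz, -1000)
  expect_true(all(c(-475, 475, -1000, 0) %in% spec$offsets_grid_hz))
  expect_error(design_spec(band_centers_hz = c(-50, 50), band_fwhm_hz = 150),
               class = "mrsat_invalid_spec")
  expect_error(design_spec(n_points = 8), class = "mrsat_invalid_spec")
  expect_error(design_spec(stopband_max = 2), class = "mrsat_invalid_spec")
})

test_that("the target profile saturates at band centers and rests elsewhere", {
  spec <- design_spec_desk()
  tg <- build_target_profile(spec)
  at <- function(f) which(tg$offsets_hz == f)
  expect_lt(abs(tg$md[3, at(-475)]), 1e-6)
  expect_lt(abs(tg$md[3, at(475)]), 1e-6)
  expect_equal(unname(tg$md[1:2, at(475)]), c(0, 0))
  expect_lt(abs(tg$md[3, at(0)] - 1), 1e-9)
  # quadrature of the saturation fraction: two bands of band_fwhm width
  on_grid <- tg$offsets_hz >= -2000 & tg$offsets_hz <= 2000
  spacing <- diff(sort(unique(tg$offsets_hz)))
  integral <- sum((1 - tg$md[3, on_grid])) * stats::median(spacing)
  expect_equal(integral, 2 * spec$band_fwhm_hz, tolerance = 0.05 * integral)
  expect_true(all(tg$weights >= 0))
})

test_that("the cost functional behaves like a weighted least-squares misfit", {
  tg <- toy_target()
  zero <- pulse_waveform(rep(0 + 0i, 32), 1e-4)
  eq <- tg
  eq$md <- rbind(rep(0, 9), rep(0, 9), rep(1, 9))
  expect_equal(oc_cost(zero, eq, 0), 0)
  p <- random_pulse(32, dwell = 1e-4, seed = 3)
  j1 <- oc_cost(p, tg, 0.1)
  j2 <- oc_cost(p, tg, 0.2)
  pen <- 0.05 * sum(Mod(p$samples)^2) * p$dwell_seconds
  expect_equal(j2 - j1, pen, tolerance = 1e-12)
  expect_identical(oc_cost(p, tg, 0.1), j1)
  expect_gte(j1, 0)
})

test_that("the adjoint gradient matches central finite differences", {
  tg <- toy_target()
  p <- random_pulse(32, dwell = 1e-4, sd = 0.3, seed = 8)
  for (spins in list(NULL, spin_system(t1_seconds = 0.5, t2_seconds = 0.05))) {
    g <- oc_gradient(p, tg, 0.02, spins = spins)
    h <- 1e-6
    set.seed(2)
    coords <- sample(32, 10)
    fd <- an <- numeric(0)
    for (j in coords) {
      for (chan in c("re", "im")) {
        dp <- if (chan == "re") h else 1i * h
        up <- p; up$samples[j] <- up$samples[j] + dp
        dn <- p; dn$samples[j] <- dn$samples[j] - dp
        fd <- c(fd, (oc_cost(up, tg, 0.02, spins) -
                       oc_cost(dn, tg, 0.02, spins)) / (2 * h))
        an <- c(an, if (chan == "re") Re(g[j]) else Im(g[j]))
      }
    }
    expect_lt(sqrt(sum((fd - an)^2)) / sqrt(sum(an^2)), 1e-5)
  }
})

test_that("the gradient reduces to the penalty term when the misfit is zero", {
  p <- random_pulse(16, dwell = 1e-4, seed = 5)
  tg <- toy_target()
  # make the achieved state the target: misfit term vanishes
  prof <- frequency_profile(p, tg$offsets_hz)
  tg$md <- rbind(prof$mx, prof$my, prof$mz)
  g <- oc_gradient(p, tg, 0.3)
  expect_equal(g, 0.3 * p$samples * p$dwell_seconds, tolerance = 1e-9)
})

test_that("a single-band toy design converges to a selective saturation
           profile with monotone cost", {
  spec <- design_spec(band_centers_hz = 150, band_fwhm_hz = 200,
                      transition_width_hz = 20,
                      gaussian_kernel_sigma_hz = 25,
                      duration_seconds = 0.016, n_points = 64,
                      nominal_b1_ut = 3, stopband_max = 1e-3,
                      offsets_grid_hz = seq(-800, 800, by = 50),
                      max_iterations = 1500)
  init <- make_single_band_pulse(0.016, 150, 1, 64)
  oc <- oc_optimize(spec, init)
  expect_true(all(diff(oc$cost_history) <= 1e-12))
  tg <- build_target_profile(spec)
  prof <- frequency_profile(oc$pulse, tg$offsets_hz)
  sat <- 1 - tg$md[3, ]
  expect_lte(max(prof$mz[sat > 0.99]), 0.05)
  expect_gte(min(prof$mz[sat < 0.001]), 0.95)
  expect_lte(max(Mod(oc$pulse$samples)), spec$nominal_b1_ut * (1 + 1e-9))
  # deterministic: identical spec and init give identical pulses
  oc2 <- oc_optimize(spec, init)
  expect_identical(oc2$pulse$samples, oc$pulse$samples)
})

test_that("a dominant penalty drives the optimal pulse toward zero", {
  spec <- design_spec(band_centers_hz = 150, band_fwhm_hz = 200,
                      transition_width_hz = 20,
                      gaussian_kernel_sigma_hz = 25,
                      duration_seconds = 0.016, n_points = 64,
                      nominal_b1_ut = 3, stopband_max = 1e-3,
                      lambda_reg = 1e4,
                      offsets_grid_hz = seq(-800, 800, by = 100),
                      max_iterations = 300)
  oc <- oc_optimize(spec, make_single_band_pulse(0.016, 150, 1, 64))
  expect_lt(sqrt(mean(Mod(oc$pulse$samples)^2)), 0.02)
})

test_that("oc_optimize validates the initializer length", {
  spec <- design_spec_desk()
  expect_error(oc_optimize(spec, random_pulse(16)),
               class = "mrsat_invalid_input")
})

test_that("hybridization at k = 0 is the identity and preserves the
           saturation profile at the design k", {
  p <- gaussian_band_pulse(n = 256)
  expect_lt(max(Mod(hybridize_quasi_adiabatic(p, 0)$samples - p$samples)),
            1e-9)
  qa <- hybridize_quasi_adiabatic(p, 4.1e-6)
  expect_equal(qa$duration_seconds, p$duration_seconds)
  expect_equal(length(qa$samples), length(p$samples))
  offs <- seq(-1500, 1500, by = 60)
  s0 <- 1 - frequency_profile(p, offs)$mz
  s1 <- 1 - frequency_profile(qa, offs)$mz
  expect_lt(sqrt(sum((s1 - s0)^2)) / sqrt(sum(s0^2)), 0.05)
})

test_that("hybridizing a transform-limited pulse produces a linear frequency
           ramp and lowers the peak amplitude", {
  p <- gaussian_band_pulse(n = 512, dwell = 0.025 / 512)
  qa <- hybridize_quasi_adiabatic(p, 4.1e-6)
  fi0 <- instantaneous_frequency(p)
  fi1 <- instantaneous_frequency(qa)
  seg <- 120:400                       # central window, away from edges
  r2 <- function(y) summary(lm(y ~ seq_along(y)))$r.squared
  expect_gt(r2(fi1[seg]), 0.98)
  expect_lt(r2(fi0[seg]), 0.5)
  expect_lt(max(Mod(qa$samples)), max(Mod(p$samples)))
})

test_that("hard-cosine reference pulse has the stated shape", {
  p <- make_hard_cosine_pulse(0.019, 475, 0.32, 512)
  expect_equal(Re(p$samples[1]), 0.32)
  expect_equal(Im(p$samples), rep(0, 512))
  expect_lt(abs(sqrt(mean(Mod(p$samples)^2)) - 0.32 / sqrt(2)),
            2 * 0.32 / 512)
  expect_error(make_hard_cosine_pulse(-1, 475, 0.32),
               class = "mrsat_invalid_input")
})

test_that("DANTE trains repeat by floor division", {
  p25 <- make_hard_cosine_pulse(0.025, 475, 0.32, 64)
  expect_equal(make_dante_train(p25, 4.575)$n_repeats, 183L)
  p19 <- make_hard_cosine_pulse(0.019, 475, 0.32, 64)
  expect_equal(make_dante_train(p19, 0.019)$n_repeats, 1L)
  empty <- make_dante_train(p19, 0)
  expect_equal(empty$n_repeats, 0L)
  expect_identical(simulate_saturation_chain(empty, relaxation_free()), 1)
  expect_error(make_dante_train(p19, -1), class = "mrsat_invalid_input")
})
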
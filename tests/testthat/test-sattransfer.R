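# Saturation-transfer kinetics: model, fitting, fluxes, error propagation,
# cohort statistics.

test_that("the signal model evaluates its closed form and limits", {
  expect_equal(st_model(0, 2.5, 0.3, 0.8), 2.5)
  expect_equal(st_model(1, 1, 0.5, 1), 1 - 0.5 * (1 - exp(-1)))
  expect_equal(st_model(1, 1, 0.5, 1), 0.68394, tolerance = 1e-5)
  # asymptote m0 (1 - k tau)
  expect_equal(st_model(1e3, 1, 0.5, 1), 0.5, tolerance = 1e-9)
  t <- seq(0, 10, by = 0.1)
  y <- st_model(t, 1.3, 0.4, 0.9)
  expect_true(all(diff(y) <= 0))
  expect_equal(y[length(y)], 1.3 * (1 - 0.4 * 0.9), tolerance = 1e-4)
  expect_error(st_model(1, -1, 0.5, 1), class = "mrsat_invalid_input")
})

test_that("curve containers validate their invariants", {
  expect_error(saturation_curve(c(0.1, 0.2), c(1, 1)),
               class = "mrsat_invalid_input")        # missing t = 0
  expect_error(saturation_curve(c(0, 0.1, 0.1), c(1, 1, 1)),
               class = "mrsat_invalid_input")        # not strictly increasing
  expect_error(saturation_curve(c(0, 0.1), c(1, -1)),
               class = "mrsat_invalid_input")
})

test_that("noiseless curves are recovered exactly and edge cases error", {
  truth <- c(m0 = 2.3, k = 0.3, tau = 0.8)
  cv <- gen_st_dataset(truth[1], truth[2], truth[3])
  fit <- fit_st_curve(cv)
  expect_equal(fit$m0, truth[["m0"]], tolerance = 1e-6)
  expect_equal(fit$k_per_s, truth[["k"]], tolerance = 1e-6)
  expect_equal(fit$tau_seconds, truth[["tau"]], tolerance = 1e-6)
  # derived T1 under 1/tau = 1/T1 + k
  expect_equal(fit$t1_seconds, 1 / (1 / 0.8 - 0.3), tolerance = 1e-5)
  litt <- fit_st_curve(cv, tau_literal = TRUE)
  expect_equal(litt$t1_seconds, 1 / (0.8 - 0.3), tolerance = 1e-5)
  expect_error(fit_st_curve(saturation_curve(c(0, 1), c(1, 0.5))),
               class = "mrsat_insufficient_data")
  expect_error(
    fit_st_curve(saturation_curve(st_protocol_durations(), rep(0, 6))),
    class = "mrsat_degenerate_curve")
})

test_that("a flat curve fits k near zero with m0 at the mean amplitude", {
  cv <- saturation_curve(c(0, 0.5, 1, 2, 4), rep(1.7, 5))
  fit <- fit_st_curve(cv)
  expect_lt(fit$k_per_s * fit$tau_seconds, 1e-6)
  expect_equal(fit$m0, 1.7, tolerance = 1e-6)
})

test_that("the fitted apparent rate constraint (T1 >= 0) holds and weighting
           uses the provided uncertainties", {
  cv <- gen_st_dataset(1, 0.4, 0.9, noise_sd = 0.03, seed = 12)
  fit <- fit_st_curve(cv)
  expect_gte(1 / fit$tau_seconds - fit$k_per_s, -1e-9)
  expect_lte(fit$k_per_s * fit$tau_seconds, 1 + 1e-9)
  cvw <- saturation_curve(cv$durations_seconds, cv$amplitudes,
                          amplitude_sds = rep(0.03, 6))
  fitw <- fit_st_curve(cvw)
  expect_true(all(is.finite(fitw$sigmas)))
})

test_that("Monte-Carlo k estimates at 2% noise carry small median bias", {
  errs <- vapply(1:500, function(i) {
    cv <- gen_st_dataset(1, 0.3, 0.8, noise_sd = 0.02, seed = i)
    (fit_st_curve(cv, n_starts = 8)$k_per_s - 0.3) / 0.3
  }, numeric(1))
  expect_lte(abs(median(errs)), 0.05)
})

test_that("spillover correction scales m0 and composes to the identity", {
  expect_equal(spillover_correction(10, 0.9), 9)
  expect_equal(spillover_correction(7.3, 1), 7.3)
  expect_equal(spillover_correction(spillover_correction(3, 0.8), 1.25), 3)
  expect_error(spillover_correction(1, 0), class = "mrsat_invalid_input")
})

test_that("flux operations are the stated bilinear forms", {
  expect_equal(degradation_flux(0, 7), 0)
  expect_equal(synthesis_flux(0, 5, 0, 3), 0)
  expect_equal(synthesis_flux(2 * 0.3, 5, 2 * 0.2, 3),
               2 * synthesis_flux(0.3, 5, 0.2, 3))
  expect_error(degradation_flux(-1, 7), class = "mrsat_invalid_input")
})

test_that("reference-cohort arithmetic reproduces the printed fluxes", {
  rc <- reference_cohort()
  expect_equal(degradation_flux(1.77, 7.56), 13.39, tolerance = 0.01 * 13.39)
  expect_equal(degradation_flux(0.92, 6.90), 6.34, tolerance = 0.01 * 6.34)
  expect_equal(synthesis_flux(0.25, 10.95, 0.21, 7.01), 4.23,
               tolerance = 0.02 * 4.23)
  # hearts 1-4 are internally consistent to 2%; heart 5's printed
  # degradation flux equals kr_sum times the PCr/ATP ratio instead of
  # kr_sum times [ATP] and is excluded as a transcription slip
  for (i in 1:4) {
    expect_equal(degradation_flux(rc$kr_sum_per_s[i], rc$gamma_atp_mm[i]),
                 rc$deg_flux_mm_s[i], tolerance = 0.02 * rc$deg_flux_mm_s[i])
    expect_equal(synthesis_flux(rc$kf_per_s[i], rc$pcr_mm[i],
                                rc$kf_prime_per_s[i], rc$pi_mm[i]),
                 rc$synth_flux_mm_s[i],
                 tolerance = 0.02 * rc$synth_flux_mm_s[i])
  }
  expect_equal(degradation_flux(rc$kr_sum_per_s[5], rc$pcr_atp_ratio[5]),
               rc$deg_flux_mm_s[5], tolerance = 0.01 * rc$deg_flux_mm_s[5])
})

test_that("flux uncertainty propagation matches its single-term identities
           and a Monte-Carlo oracle", {
  rec <- cohort_record(1, gamma_atp_mm = 7, pcr_mm = 11, pi_mm = 5,
                       kf_per_s = 0.3, kf_prime_per_s = 0.2,
                       kr_sum_per_s = 1.0,
                       sigmas = c(gamma_atp_mm = 0, pcr_mm = 0, pi_mm = 0,
                                  kf_per_s = 0, kf_prime_per_s = 0,
                                  kr_sum_per_s = 0))
  expect_equal(propagate_flux_uncertainty(rec),
               list(rel_sigma_synth = 0, rel_sigma_deg = 0))
  rec$sigmas <- c(gamma_atp_mm = 0.7, pcr_mm = 0, pi_mm = 0, kf_per_s = 0,
                  kf_prime_per_s = 0, kr_sum_per_s = 0)
  expect_equal(propagate_flux_uncertainty(rec)$rel_sigma_deg, 0.1)
  # Monte-Carlo oracle for the degradation flux (exact product form)
  rec$sigmas <- c(gamma_atp_mm = 0.7, pcr_mm = 0.5, pi_mm = 0.4,
                  kf_per_s = 0.02, kf_prime_per_s = 0.015,
                  kr_sum_per_s = 0.12)
  prop <- propagate_flux_uncertainty(rec)
  set.seed(99)
  n <- 1e5
  deg <- (rec$kr_sum_per_s + rnorm(n, 0, 0.12)) *
    (rec$gamma_atp_mm + rnorm(n, 0, 0.7))
  mc_deg <- sd(deg) / mean(deg)
  expect_equal(prop$rel_sigma_deg, mc_deg, tolerance = 0.1 * mc_deg)
  rec$sigmas[["gamma_atp_mm"]] <- 0.01   # missing field check
  rec$sigmas <- rec$sigmas[-1]
  expect_error(propagate_flux_uncertainty(rec),
               class = "mrsat_incomplete_record")
})

test_that("cohort summaries reproduce the printed means and SEMs and the
           flux comparison statistics", {
  rc <- reference_cohort()
  recs <- lapply(1:5, function(i) {
    cohort_record(i, rc$gamma_atp_mm[i], rc$pcr_mm[i], rc$pi_mm[i],
                  rc$kf_per_s[i], rc$kf_prime_per_s[i], rc$kr_sum_per_s[i])
  })
  df <- cohort_table(recs)
  # override derived fluxes with the printed ones for the summary check
  df$synth_flux_mm_s <- rc$synth_flux_mm_s
  df$deg_flux_mm_s <- rc$deg_flux_mm_s
  s <- cohort_summary(df)
  get <- function(v, col) s$table[[col]][s$table$variable == v]
  expect_equal(get("deg_flux_mm_s", "mean"), 6.88, tolerance = 0.005)
  expect_equal(get("deg_flux_mm_s", "sem"), 1.82, tolerance = 0.005)
  expect_equal(get("kf_per_s", "mean"), 0.27, tolerance = 0.01)
  expect_equal(get("kr_sum_per_s", "mean"), 1.05, tolerance = 0.01)
  expect_equal(get("synth_flux_mm_s", "mean"), 4.24, tolerance = 0.01)
  expect_true(all(c("paired_t", "unpaired_t", "wilcoxon") %in%
                    names(s$flux_tests)))
  # identical records give zero SEM
  same <- cohort_summary(cohort_table(recs[c(1, 1, 1)]))
  expect_equal(same$table$sem[same$table$variable == "pcr_mm"], 0)
  # brute-force cross-check on random data
  set.seed(31)
  x <- rnorm(5)
  df2 <- df
  df2$pi_mm <- x
  s2 <- cohort_summary(df2)
  expect_equal(s2$table$mean[s2$table$variable == "pi_mm"], sum(x) / 5)
  expect_equal(s2$table$sem[s2$table$variable == "pi_mm"],
               sqrt(sum((x - mean(x))^2) / 4) / sqrt(5))
  expect_error(cohort_summary(df[1, ]), class = "mrsat_insufficient_data")
})
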
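# Quantitative evaluation of pulses and saturation trains: deposited
# power, B1rms, instantaneous frequency, saturation efficiency, spillover,
# minimum effective B1, and the B1-immunity fold-range.
#
# Sign convention: spillover (like band efficiency) is the fraction of the
# equilibrium longitudinal magnetization destroyed at the probed offset
# after the chain (0 = untouched, 1 = fully saturated).

#' Root-mean-square B1 of a saturation chain
#'
#' `sqrt((1/T) * integral |B1(t)|^2 dt)` over the full chain duration,
#' including idle time after the last repeat.
#'
#' @param chain A [chain_schedule()].
#' @param b1_scale Dimensionless B1 multiplier.
#' @return B1rms in uT.
#' @export
b1rms <- function(chain, b1_scale = 1) {
  stopifnot(inherits(chain, "chain_schedule"))
  if (chain$total_duration_seconds <= 0) {
    .stop_mrsat("mrsat_invalid_input", "chain has zero duration")
  }
  sqrt(integrated_power(chain, b1_scale) / chain$total_duration_seconds)
}

#' Integrated RF power of a saturation chain
#'
#' The deposited-power surrogate `integral |B1(t)|^2 dt` (uT^2 s): the sum
#' of squared sample magnitudes times the dwell, times the number of
#' repeats.  Scales with `b1_scale^2`.
#'
#' @inheritParams b1rms
#' @return Power in uT^2 s.
#' @export
integrated_power <- function(chain, b1_scale = 1) {
  stopifnot(inherits(chain, "chain_schedule"))
  p <- chain$subpulse
  b1_scale^2 * chain$n_repeats * sum(Mod(p$samples)^2) * p$dwell_seconds
}

#' Instantaneous frequency of a pulse
#'
#' Unwrapped phase differentiated by central differences; samples with
#' `|B1|` below 1% of the peak are masked (`NA`) because the phase is
#' undefined there.
#'
#' @param pulse A [pulse_waveform()] with at least 2 samples.
#' @return Numeric vector of dphi/dt in Hz, one value per sample.
#' @export
instantaneous_frequency <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_waveform"))
  s <- pulse$samples
  n <- length(s)
  if (n < 2L) .stop_mrsat("mrsat_invalid_input", "need at least 2 samples")
  ph <- Arg(s)
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))   # unwrap increments
  phu <- cumsum(c(ph[1], d))
  f <- rep(NA_real_, n)
  dt <- pulse$dwell_seconds
  if (n > 2L) {
    f[2:(n - 1)] <- (phu[3:n] - phu[1:(n - 2)]) / (2 * dt) / (2 * pi)
  }
  f[1] <- (phu[2] - phu[1]) / dt / (2 * pi)
  f[n] <- (phu[n] - phu[n - 1]) / dt / (2 * pi)
  f[Mod(s) < 0.01 * max(Mod(s))] <- NA_real_
  f
}

#' Band saturation efficiencies and spillover of a chain
#'
#' Bloch-simulates the chain and reports `efficiency = 1 - mz/m0` at each
#' band center and `spillover = 1 - mz/m0` at the protected offset.
#'
#' @param chain A [chain_schedule()].
#' @param band_centers_hz Band-center offsets, Hz.
#' @param spill_offset_hz Protected offset; default -1000 Hz from the
#'   midpoint of the bands (the gamma-ATP checkpoint).
#' @param b1_scale B1 multiplier.
#' @param spin Relaxation template (default relaxation-free).
#' @return List with `band_efficiencies` (named by offset) and
#'   `spillover_fraction`.
#' @export
saturation_and_spillover <- function(chain, band_centers_hz,
                                     spill_offset_hz =
                                       mean(band_centers_hz) - 1000,
                                     b1_scale = 1, spin = spin_system()) {
  stopifnot(inherits(chain, "chain_schedule"))
  offs <- c(band_centers_hz, spill_offset_hz)
  grid <- .chain_map(chain, offs, b1_scale, spin)
  vals <- 1 - grid$mz[1, ] / spin$m0
  nb <- length(band_centers_hz)
  list(band_efficiencies = setNames(vals[seq_len(nb)],
                                    paste0(band_centers_hz, "Hz")),
       spillover_fraction = vals[nb + 1L])
}

# Scan grid used by the B1 searches: 41 log-spaced multipliers covering
# 0.1x to 10x nominal.
.b1_scan_scales <- function(n = 41L, lo = 0.1, hi = 10) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Efficiency worst-case over bands as a function of scale (vectorized).
.band_min_efficiency <- function(chain, band_centers_hz, scales, spin) {
  grid <- .chain_map(chain, band_centers_hz, scales, spin)
  eff <- 1 - grid$mz / spin$m0
  apply(eff, 1, min)
}

.spillover_at <- function(chain, spill_offset_hz, scales, spin) {
  grid <- .chain_map(chain, spill_offset_hz, scales, spin)
  as.vector(1 - grid$mz[, 1] / spin$m0)
}

#' Minimum effective B1 of a saturation chain
#'
#' Smallest peak B1 at which every band reaches at least `threshold`
#' saturation efficiency after the chain, located on a 41-point
#' log-spaced scan of 0.1x-10x the subpulse peak and refined by bisection
#' to 1% relative precision.
#'
#' @param chain A [chain_schedule()].
#' @param band_centers_hz Band-center offsets, Hz.
#' @param threshold Efficiency threshold (default 0.99).
#' @param spin Relaxation template.
#' @return Minimum effective peak B1 in uT.  Raises an
#'   `mrsat_not_achievable` error when the threshold is never reached in
#'   the scan range.
#' @export
min_effective_b1 <- function(chain, band_centers_hz, threshold = 0.99,
                             spin = spin_system()) {
  peak <- max(Mod(chain$subpulse$samples))
  scales <- .b1_scan_scales()
  eff <- .band_min_efficiency(chain, band_centers_hz, scales, spin)
  ok <- which(eff >= threshold)
  if (length(ok) == 0L) {
    .stop_mrsat("mrsat_not_achievable",
                "saturation threshold %g not reached in B1 scan range",
                threshold)
  }
  i <- ok[1]
  if (i == 1L) return(scales[1] * peak)
  lo <- scales[i - 1]
  hi <- scales[i]
  while ((hi - lo) / hi > 0.01) {
    mid <- sqrt(lo * hi)
    e <- .band_min_efficiency(chain, band_centers_hz, mid, spin)
    if (e >= threshold) hi <- mid else lo <- mid
  }
  hi * peak
}

#' B1-immunity fold-range of a saturation chain
#'
#' Ratio of the largest peak B1 at which spillover at the protected offset
#' stays within `spillover_limit` to the minimum effective B1.  When the
#' spillover limit is never exceeded over the scan range the scan ceiling
#' is used and the result carries `attr(, "lower_bound") = TRUE`.
#'
#' @param chain A [chain_schedule()].
#' @param band_centers_hz Band-center offsets, Hz.
#' @param spill_offset_hz Protected offset (default gamma-ATP checkpoint).
#' @param spillover_limit Spillover ceiling (default 0.01).
#' @param threshold Saturation-efficiency threshold (default 0.99).
#' @param spin Relaxation template.
#' @return Fold ratio (>= 1 when both quantities are defined).
#' @export
b1_immunity_fold <- function(chain, band_centers_hz,
                             spill_offset_hz = mean(band_centers_hz) - 1000,
                             spillover_limit = 0.01, threshold = 0.99,
                             spin = spin_system()) {
  peak <- max(Mod(chain$subpulse$samples))
  min_b1 <- min_effective_b1(chain, band_centers_hz, threshold, spin)
  scales <- .b1_scan_scales()
  spill <- .spillover_at(chain, spill_offset_hz, scales, spin)
  bad <- which(spill > spillover_limit)
  lower_bound <- FALSE
  if (length(bad) == 0L) {
    b1_ceiling <- scales[length(scales)] * peak
    lower_bound <- TRUE
  } else if (bad[1] == 1L) {
    b1_ceiling <- scales[1] * peak
  } else {
    lo <- scales[bad[1] - 1]
    hi <- scales[bad[1]]
    while ((hi - lo) / hi > 0.01) {
      mid <- sqrt(lo * hi)
      sp <- .spillover_at(chain, spill_offset_hz, mid, spin)
      if (sp <= spillover_limit) lo <- mid else hi <- mid
    }
    b1_ceiling <- lo * peak
  }
  fold <- b1_ceiling / min_b1
  attr(fold, "lower_bound") <- lower_bound
  fold
}

#' Full metric set for a saturation chain
#'
#' @param chain A [chain_schedule()].
#' @param band_centers_hz Band-center offsets, Hz.
#' @param spill_offset_hz Protected offset.
#' @param spin Relaxation template.
#' @return A list of class `"chain_metrics"`: `b1rms_ut`,
#'   `integrated_power_rel`, `min_effective_b1_ut`, `immunity_fold`,
#'   `spillover_fraction_at_min_b1`, `band_efficiencies` (at the minimum
#'   effective B1).
#' @export
chain_metrics <- function(chain, band_centers_hz,
                          spill_offset_hz = mean(band_centers_hz) - 1000,
                          spin = spin_system()) {
  peak <- max(Mod(chain$subpulse$samples))
  min_b1 <- tryCatch(
    min_effective_b1(chain, band_centers_hz, spin = spin),
    mrsat_not_achievable = function(e) NA_real_)
  fold <- if (is.na(min_b1)) NA_real_ else {
    b1_immunity_fold(chain, band_centers_hz, spill_offset_hz, spin = spin)
  }
  ss <- if (is.na(min_b1)) {
    list(band_efficiencies = NA, spillover_fraction = NA_real_)
  } else {
    saturation_and_spillover(chain, band_centers_hz, spill_offset_hz,
                             b1_scale = min_b1 / peak, spin = spin)
  }
  structure(list(b1rms_ut = b1rms(chain),
                 integrated_power_rel = integrated_power(chain),
                 min_effective_b1_ut = min_b1,
                 immunity_fold = fold,
                 spillover_fraction_at_min_b1 = ss$spillover_fraction,
                 band_efficiencies = ss$band_efficiencies),
            class = "chain_metrics")
}
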
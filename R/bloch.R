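# Time-domain Bloch simulation in the rotating frame.
#
# All magnetization components are dimensionless relative to the thermal
# equilibrium magnitude m0 carried by the spin system.  RF amplitudes are in
# microtesla; the x channel is the real part of a sample and the y channel
# the imaginary part.  Off-resonance enters as 2*pi*offset_hz about z; an
# applied gradient is not modeled because for purely spectral work the
# spatial and spectral axes are interchangeable.

#' Magnetization vector
#'
#' @param mx,my,mz Cartesian components relative to equilibrium `m0`.
#' @return A named numeric vector of class `"magnetization"`.
#' @export
magnetization <- function(mx = 0, my = 0, mz = 1) {
  m <- c(mx = mx, my = my, mz = mz)
  .check_finite(m, "magnetization components")
  structure(m, class = "magnetization")
}

#' Spin system parameters
#'
#' @param t1_seconds,t2_seconds Longitudinal and transverse relaxation times
#'   in seconds; both must be positive and may be `Inf` (no relaxation, the
#'   default used by the simulation-based pulse metrics).
#' @param offset_hz Chemical-shift offset from the carrier in Hz.
#' @param m0 Equilibrium magnetization magnitude.
#' @return A list of class `"spin_system"`.
#' @export
spin_system <- function(t1_seconds = Inf, t2_seconds = Inf, offset_hz = 0,
                        m0 = 1) {
  if (!is.numeric(t1_seconds) || t1_seconds <= 0 ||
      !is.numeric(t2_seconds) || t2_seconds <= 0) {
    .stop_mrsat("mrsat_invalid_input", "t1_seconds and t2_seconds must be > 0")
  }
  .check_finite(offset_hz, "offset_hz")
  .check_finite(m0, "m0")
  structure(list(t1_seconds = t1_seconds, t2_seconds = t2_seconds,
                 offset_hz = offset_hz, m0 = m0), class = "spin_system")
}

#' RF pulse waveform
#'
#' @param samples Complex vector of B1 samples in microtesla (real part: x
#'   channel, imaginary part: y channel).  A numeric vector is promoted to
#'   complex.
#' @param dwell_seconds Sample dwell time in seconds.
#' @param nominal_peak_b1_ut Optional nominal peak amplitude in microtesla;
#'   when given, `max(abs(samples))` must not exceed it (1e-6 relative
#'   headroom for rounding).
#' @param label Free-text label.
#' @return A list of class `"pulse_waveform"` with a `duration_seconds`
#'   field equal to `length(samples) * dwell_seconds`.
#' @export
pulse_waveform <- function(samples, dwell_seconds, nominal_peak_b1_ut = NULL,
                           label = "") {
  if (length(samples) < 1L) {
    .stop_mrsat("mrsat_invalid_input", "pulse must contain at least 1 sample")
  }
  samples <- as.complex(samples)
  .check_finite(c(Re(samples), Im(samples)), "pulse samples")
  if (!is.numeric(dwell_seconds) || dwell_seconds <= 0) {
    .stop_mrsat("mrsat_invalid_input", "dwell_seconds must be > 0")
  }
  if (!is.null(nominal_peak_b1_ut)) {
    if (max(Mod(samples)) > nominal_peak_b1_ut * (1 + 1e-6)) {
      .stop_mrsat("mrsat_invalid_input",
                  "peak |B1| (%g) exceeds nominal_peak_b1_ut (%g)",
                  max(Mod(samples)), nominal_peak_b1_ut)
    }
  }
  structure(list(samples = samples, dwell_seconds = dwell_seconds,
                 nominal_peak_b1_ut = nominal_peak_b1_ut, label = label,
                 duration_seconds = length(samples) * dwell_seconds),
            class = "pulse_waveform")
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf(
    "RF pulse '%s': %d samples, %.4g ms, dwell %.4g us, peak %.4g uT\n",
    x$label, length(x$samples), 1e3 * x$duration_seconds,
    1e6 * x$dwell_seconds, max(Mod(x$samples))))
  invisible(x)
}

#' Saturation chain schedule
#'
#' A subpulse repeated back-to-back for a total saturation duration, with
#' ideal gradient crushers (transverse magnetization zeroed, longitudinal
#' untouched, zero duration) optionally applied between and after repeats.
#'
#' @param subpulse A [pulse_waveform()].
#' @param total_duration_seconds Total chain duration; must be 0 (empty
#'   chain, no saturation) or at least one subpulse duration.
#' @param crusher_between,crusher_after Logical crusher flags.
#' @return A list of class `"chain_schedule"` with `n_repeats =
#'   floor(total / subpulse duration)` and the residual `idle_seconds`.
#' @export
chain_schedule <- function(subpulse, total_duration_seconds,
                           crusher_between = TRUE, crusher_after = FALSE) {
  stopifnot(inherits(subpulse, "pulse_waveform"))
  if (!is.numeric(total_duration_seconds) || total_duration_seconds < 0) {
    .stop_mrsat("mrsat_invalid_input", "total_duration_seconds must be >= 0")
  }
  sub_dur <- subpulse$duration_seconds
  n_rep <- floor(total_duration_seconds / sub_dur + 1e-9)
  if (total_duration_seconds > 0 && n_rep < 1) {
    .stop_mrsat("mrsat_invalid_input",
                "total duration (%g s) is shorter than one subpulse (%g s)",
                total_duration_seconds, sub_dur)
  }
  structure(list(subpulse = subpulse,
                 total_duration_seconds = total_duration_seconds,
                 n_repeats = as.integer(n_rep),
                 idle_seconds = total_duration_seconds - n_rep * sub_dur,
                 crusher_between = isTRUE(crusher_between),
                 crusher_after = isTRUE(crusher_after)),
            class = "chain_schedule")
}

.relax_pars <- function(spin) {
  c(t1 = spin$t1_seconds, t2 = spin$t2_seconds, m0 = spin$m0)
}

#' Single Bloch step: rotation about the effective field plus relaxation
#'
#' Propagates one piecewise-constant step: an exact rotation about the
#' effective field `(gamma*B1x, gamma*B1y, 2*pi*offset)` composed with
#' exponential T1/T2 decay toward `(0, 0, m0)` (operator splitting, error
#' O(dt^2)).  `gamma(31P) = 17.235` Hz/uT.
#'
#' @param m A [magnetization()].
#' @param b1_ut Complex B1 sample in microtesla.
#' @param offset_hz Off-resonance in Hz.
#' @param dt_seconds Step duration (> 0).
#' @param spin A [spin_system()] supplying T1, T2 and m0.
#' @return The magnetization after the step.
#' @export
rotate_relax_step <- function(m, b1_ut, offset_hz, dt_seconds, spin) {
  .check_finite(c(Re(b1_ut), Im(b1_ut), offset_hz, dt_seconds), "step inputs")
  if (dt_seconds <= 0) .stop_mrsat("mrsat_invalid_input", "dt must be > 0")
  b1_ut <- as.complex(b1_ut)
  out <- .cpp_simulate_pulse(Re(b1_ut), Im(b1_ut), dt_seconds, offset_hz,
                             1.0, spin$t1_seconds, spin$t2_seconds, spin$m0,
                             as.numeric(m))
  magnetization(out[1, 1], out[2, 1], out[3, 1])
}

#' Simulate a full pulse
#'
#' Sequential [rotate_relax_step()] over all samples with B1 multiplied by
#' `b1_scale`.
#'
#' @param pulse A [pulse_waveform()].
#' @param spin A [spin_system()]; its `offset_hz` is used.
#' @param b1_scale Dimensionless B1 multiplier (>= 0).
#' @param initial Initial magnetization; defaults to equilibrium.
#' @return Final [magnetization()].
#' @export
simulate_pulse <- function(pulse, spin = spin_system(), b1_scale = 1,
                           initial = magnetization(0, 0, spin$m0)) {
  stopifnot(inherits(pulse, "pulse_waveform"))
  if (b1_scale < 0) .stop_mrsat("mrsat_invalid_input", "b1_scale must be >= 0")
  s <- pulse$samples
  out <- .cpp_simulate_pulse(Re(s), Im(s), pulse$dwell_seconds,
                             spin$offset_hz, b1_scale, spin$t1_seconds,
                             spin$t2_seconds, spin$m0, as.numeric(initial))
  magnetization(out[1, 1], out[2, 1], out[3, 1])
}

#' Frequency response of a pulse
#'
#' Bloch-simulates the pulse at each requested offset starting from
#' equilibrium.
#'
#' @param pulse A [pulse_waveform()].
#' @param offsets_hz Numeric vector of offsets.
#' @param b1_scale B1 multiplier.
#' @param spin_template A [spin_system()]; its `offset_hz` is ignored.
#' @return A data frame with columns `offset_hz`, `mx`, `my`, `mz`,
#'   `abs_mxy`.
#' @export
frequency_profile <- function(pulse, offsets_hz, b1_scale = 1,
                              spin_template = spin_system()) {
  stopifnot(inherits(pulse, "pulse_waveform"))
  .check_finite(offsets_hz, "offsets_hz")
  s <- pulse$samples
  out <- .cpp_simulate_pulse(Re(s), Im(s), pulse$dwell_seconds, offsets_hz,
                             b1_scale, spin_template$t1_seconds,
                             spin_template$t2_seconds, spin_template$m0,
                             c(0, 0, spin_template$m0))
  data.frame(offset_hz = offsets_hz, mx = out[1, ], my = out[2, ],
             mz = out[3, ], abs_mxy = sqrt(out[1, ]^2 + out[2, ]^2))
}

#' B1-by-frequency response map
#'
#' Grid of final `mz` and `|mxy|` over B1 scales and offsets for a single
#' pulse or a full saturation chain (crushers included for chains).
#'
#' @param x A [pulse_waveform()] or [chain_schedule()].
#' @param b1_scales Non-empty vector of dimensionless B1 multipliers.
#' @param offsets_hz Non-empty vector of offsets in Hz.
#' @param spin A [spin_system()] template (offset ignored).
#' @return Long-format data frame with columns `b1_scale`, `offset_hz`,
#'   `mz`, `abs_mxy`.
#' @export
b1_frequency_map <- function(x, b1_scales, offsets_hz,
                             spin = spin_system()) {
  if (length(b1_scales) < 1L || length(offsets_hz) < 1L) {
    .stop_mrsat("mrsat_invalid_input", "scan grids must be non-empty")
  }
  .check_finite(c(b1_scales, offsets_hz), "scan grids")
  if (inherits(x, "pulse_waveform")) {
    ch <- chain_schedule(x, x$duration_seconds, crusher_between = FALSE)
  } else {
    stopifnot(inherits(x, "chain_schedule"))
    ch <- x
  }
  grid <- .chain_map(ch, offsets_hz, b1_scales, spin)
  data.frame(b1_scale = rep(b1_scales, times = length(offsets_hz)),
             offset_hz = rep(offsets_hz, each = length(b1_scales)),
             mz = as.vector(grid$mz), abs_mxy = as.vector(grid$abs_mxy))
}

# Internal: chain endpoint grid over (scales x offsets).
.chain_map <- function(chain, offsets_hz, b1_scales, spin = spin_system()) {
  s <- chain$subpulse$samples
  if (chain$n_repeats < 1L) {
    n <- length(b1_scales) * length(offsets_hz)
    return(list(mz = matrix(spin$m0, length(b1_scales), length(offsets_hz)),
                abs_mxy = matrix(0, length(b1_scales), length(offsets_hz))))
  }
  .cpp_chain_map(Re(s), Im(s), chain$subpulse$dwell_seconds, chain$n_repeats,
                 offsets_hz, b1_scales, spin$t1_seconds, spin$t2_seconds,
                 spin$m0, chain$crusher_between, chain$crusher_after,
                 chain$idle_seconds)
}

#' Simulate a saturation chain
#'
#' Plays the subpulse `n_repeats` times back-to-back with ideal crushers
#' between repeats (when enabled) and returns `mz` sampled after each
#' subpulse.  The final value is the steady-state saturation level.
#'
#' @param chain A [chain_schedule()].
#' @param spin A [spin_system()]; relaxation applies throughout.
#' @param offset_hz Offset at which to simulate (defaults to the spin's).
#' @param b1_scale B1 multiplier.
#' @return Numeric vector of `mz` after each repeat (length `n_repeats`);
#'   for an empty chain, the equilibrium `m0` as a single value.
#' @export
simulate_saturation_chain <- function(chain, spin = spin_system(),
                                      offset_hz = spin$offset_hz,
                                      b1_scale = 1) {
  stopifnot(inherits(chain, "chain_schedule"))
  if (chain$n_repeats < 1L) return(spin$m0)
  s <- chain$subpulse$samples
  .cpp_chain_traj(Re(s), Im(s), chain$subpulse$dwell_seconds,
                  chain$n_repeats, offset_hz, b1_scale, spin$t1_seconds,
                  spin$t2_seconds, spin$m0, chain$crusher_between)
}
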
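# Shinnar-Le Roux transform between RF waveforms and Cayley-Klein (A, B)
# polynomial pairs, plus the quadratic-phase imposition used to give a
# designed pulse a degree of adiabaticity.
#
# Conventions.  For n samples the A and B coefficient vectors have length n
# (polynomials in z^-1 of degree n-1).  Profiles are evaluated at
# z = exp(i*omega) with omega the per-sample precession angle; a physical
# offset f (Hz) maps to omega = -2*pi*f*dwell under the rotating-frame sign
# convention used by the Bloch simulator.  Unimodularity
# |A(z)|^2 + |B(z)|^2 = 1 on the unit circle encodes rotation normalization.

#' Cayley-Klein polynomial pair
#'
#' @param a_coeffs,b_coeffs Complex coefficient vectors of equal length.
#' @param dwell_seconds Dwell time of the generating pulse.
#' @param tol Tolerance for the unit-circle magnitude invariant
#'   `|A|^2 + |B|^2 = 1`.
#' @param n_grid Number of unit-circle points for the invariant check
#'   (default 4n).  Pairs produced by [impose_quadratic_phase()] with a
#'   reused A polynomial are exactly unimodular on the native n-point grid
#'   but only approximately in between; they are validated on the native
#'   grid.
#' @return A list of class `"ab_polynomials"`.
#' @export
ab_polynomials <- function(a_coeffs, b_coeffs, dwell_seconds, tol = 1e-6,
                           n_grid = 4L * length(a_coeffs)) {
  a_coeffs <- as.complex(a_coeffs)
  b_coeffs <- as.complex(b_coeffs)
  if (length(a_coeffs) != length(b_coeffs) || length(a_coeffs) < 1L) {
    .stop_mrsat("mrsat_invalid_input",
                "a_coeffs and b_coeffs must have equal positive length")
  }
  .check_finite(c(Re(a_coeffs), Im(a_coeffs), Re(b_coeffs), Im(b_coeffs)),
                "polynomial coefficients")
  if (dwell_seconds <= 0) {
    .stop_mrsat("mrsat_invalid_input", "dwell_seconds must be > 0")
  }
  dev <- max(abs(Mod(.eval_on_circle(a_coeffs, n_grid))^2 +
                 Mod(.eval_on_circle(b_coeffs, n_grid))^2 - 1))
  if (dev > tol) {
    .stop_mrsat("mrsat_inconsistent_polynomials",
                "|A|^2 + |B|^2 deviates from 1 by %g (tolerance %g)",
                dev, tol)
  }
  structure(list(a_coeffs = a_coeffs, b_coeffs = b_coeffs,
                 dwell_seconds = dwell_seconds),
            class = "ab_polynomials")
}

# Values of the polynomial sum(c_j z^-j) at z = exp(i*omega_m),
# omega_m = 2*pi*m/N in DFT order: exactly the zero-padded DFT.
.eval_on_circle <- function(coeffs, n_grid) {
  stats::fft(c(coeffs, rep(0 + 0i, n_grid - length(coeffs))))
}

#' Evaluate a coefficient vector on the unit circle
#'
#' Zero-padded discrete Fourier transform of the coefficients, returned on
#' an increasing normalized angular frequency grid in `(-pi, pi]`.
#'
#' @param coeffs Complex coefficients (a or b).
#' @param n_grid Number of evaluation points (>= `length(coeffs)`).
#' @return A list of class `"frequency_profile"` with fields `omegas` and
#'   `values`.
#' @export
evaluate_profile <- function(coeffs, n_grid = 4L * length(coeffs)) {
  if (n_grid < length(coeffs)) {
    .stop_mrsat("mrsat_invalid_input", "n_grid must be >= length(coeffs)")
  }
  vals <- .eval_on_circle(as.complex(coeffs), n_grid)
  m <- seq_len(n_grid) - 1L
  omega <- 2 * pi * m / n_grid
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  ord <- order(omega)
  structure(list(omegas = omega[ord], values = vals[ord]),
            class = "frequency_profile")
}

#' Forward Shinnar-Le Roux transform
#'
#' Hard-pulse-approximation recursion mapping an RF waveform to its
#' Cayley-Klein polynomial pair.  For an initial state (0, 0, 1) the
#' relaxation-free longitudinal response satisfies
#' `mz(omega) = 1 - 2 |B(omega)|^2`.
#'
#' @param pulse A [pulse_waveform()].
#' @return An [ab_polynomials()] pair of length `length(pulse$samples)`.
#' @export
forward_slr <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_waveform"))
  u <- pulse$samples
  n <- length(u)
  dt <- pulse$dwell_seconds
  g <- 2 * pi * GAMMA_P31_HZ_PER_UT
  phi <- g * Mod(u) * dt            # flip per sample, radians
  theta <- Arg(u)
  cj <- cos(phi / 2)
  sj <- 1i * exp(1i * theta) * sin(phi / 2)
  a <- c(1 + 0i, rep(0 + 0i, n - 1L))
  b <- rep(0 + 0i, n)
  for (j in seq_len(n)) {
    bshift <- c(0 + 0i, b[-n])      # z^-1 B
    anew <- cj[j] * a - Conj(sj[j]) * bshift
    b <- sj[j] * a + cj[j] * bshift
    a <- anew
  }
  ab_polynomials(a, b, dt, tol = 1e-4)
}

#' Inverse Shinnar-Le Roux transform
#'
#' Inverts the hard-pulse recursion, recovering the RF waveform whose
#' forward transform reproduces the given coefficients.
#'
#' @param ab An [ab_polynomials()] pair (magnitude invariant satisfied to
#'   at most 1e-4; a worse violation signals a B polynomial whose magnitude
#'   exceeds what A permits and raises an `mrsat_inconsistent_polynomials`
#'   error).
#' @param label Label for the reconstructed pulse.
#' @return A [pulse_waveform()].
#' @export
inverse_slr <- function(ab, label = "slr-inverse") {
  stopifnot(inherits(ab, "ab_polynomials"))
  n_grid <- length(ab$a_coeffs)
  dev <- max(abs(Mod(.eval_on_circle(ab$a_coeffs, n_grid))^2 +
                 Mod(.eval_on_circle(ab$b_coeffs, n_grid))^2 - 1))
  if (dev > 1e-4) {
    .stop_mrsat("mrsat_inconsistent_polynomials",
                "cannot invert: |A|^2+|B|^2 deviates from 1 by %g", dev)
  }
  a <- ab$a_coeffs
  b <- ab$b_coeffs
  n <- length(a)
  dt <- ab$dwell_seconds
  g <- 2 * pi * GAMMA_P31_HZ_PER_UT
  u <- complex(n)
  for (j in rev(seq_len(n))) {
    # the j-th rotation is fixed by the constant coefficients
    phi <- 2 * atan2(Mod(b[1]), Mod(a[1]))
    theta <- Arg(-1i * b[1] / a[1])
    if (!is.finite(theta)) theta <- 0
    cj <- cos(phi / 2)
    sj <- 1i * exp(1i * theta) * sin(phi / 2)
    u[j] <- phi * exp(1i * theta) / (g * dt)
    aprev <- cj * a + Conj(sj) * b
    btmp <- -sj * a + cj * b        # equals z^-1 B_{j-1}: constant term ~ 0
    b <- c(btmp[-1], 0 + 0i)
    a <- aprev
  }
  pulse_waveform(u, dt, label = label)
}

#' Impose a quadratic spectral phase on the B polynomial
#'
#' Multiplies the frequency response of the B coefficients by
#' `exp(i * k_phase * w^2)`, with `w = 2*pi*f` the physical angular
#' frequency in rad/s, and transforms back to coefficients.  `k_phase` is
#' therefore in seconds squared; the group delay added at frequency f is
#' `2 * k_phase * 2*pi*f`.  The multiplication is performed on the native
#' n-point circular grid so that the large linear-phase component at each
#' band center wraps around the pulse window instead of shifting the band
#' out of it; the residual in-band quadratic phase is the desired chirp.
#' The operation preserves `|B(omega)|` on the evaluation grid exactly and
#' does not affect the spectral bandwidth.
#'
#' @param ab An [ab_polynomials()] pair.
#' @param k_phase Quadratic-phase constant in s^2 (0 returns the input
#'   unchanged).
#' @param oversample Integer grid oversampling factor for the forward and
#'   inverse transforms.  The default 1 keeps the transform circular on the
#'   pulse window (see above); larger values trade wraparound for
#'   truncation of out-of-window chirp energy.
#' @param recompute_a If `TRUE`, replace the A polynomial by the
#'   minimum-phase spectral factor of `1 - |B'|^2` (standard SLR practice);
#'   if `FALSE` (default) the original A is reused verbatim.
#' @param tol Unimodularity tolerance for the returned pair.
#' @return An [ab_polynomials()] pair with the modified B.
#' @export
impose_quadratic_phase <- function(ab, k_phase, oversample = 1L,
                                   recompute_a = FALSE, tol = 1e-3) {
  stopifnot(inherits(ab, "ab_polynomials"))
  .check_finite(k_phase, "k_phase")
  if (k_phase == 0 && !recompute_a) return(ab)
  n <- length(ab$b_coeffs)
  N <- as.integer(oversample) * n
  bgrid <- .eval_on_circle(ab$b_coeffs, N)
  m <- seq_len(N) - 1L
  omega <- 2 * pi * m / N
  omega[omega > pi] <- omega[omega > pi] - 2 * pi   # signed, DFT order
  w_phys <- omega / ab$dwell_seconds                # rad/s
  bnew_full <- stats::fft(bgrid * exp(1i * k_phase * w_phys^2),
                          inverse = TRUE) / N
  bnew <- bnew_full[seq_len(n)]
  anew <- if (recompute_a) {
    .min_phase_a(bnew, n)
  } else {
    ab$a_coeffs
  }
  ab_polynomials(anew, bnew, ab$dwell_seconds, tol = tol, n_grid = n)
}

# Minimum-phase spectral factor of 1 - |B(omega)|^2 via the real-cepstrum
# folding construction; roots effectively reflected inside the unit circle.
.min_phase_a <- function(b_coeffs, n_out) {
  n <- length(b_coeffs)
  N <- 16L * n
  mag2 <- pmax(1 - Mod(.eval_on_circle(b_coeffs, N))^2, 1e-18)
  cep <- stats::fft(log(mag2) / 2, inverse = TRUE) / N
  fold <- cep
  fold[2:(N / 2)] <- 2 * cep[2:(N / 2)]
  fold[(N / 2 + 2):N] <- 0
  amin <- stats::fft(exp(stats::fft(fold)), inverse = TRUE) / N
  as.complex(amin[seq_len(n_out)])
}
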
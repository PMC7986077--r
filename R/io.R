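# File formats: pulse shapes as CSV with a JSON sidecar, saturation curves
# and cohort tables as CSV, design specifications and reports as JSON.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a pulse waveform to CSV plus JSON sidecar
#'
#' The CSV has columns `time_s`, `b1x_ut`, `b1y_ut`; the sidecar carries
#' `dwell_seconds`, `nominal_peak_b1_ut` and `label`.
#'
#' @param pulse A [pulse_waveform()].
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_pulse <- function(pulse, path) {
  stopifnot(inherits(pulse, "pulse_waveform"))
  t <- (seq_along(pulse$samples) - 1L) * pulse$dwell_seconds
  df <- data.frame(time_s = t, b1x_ut = Re(pulse$samples),
                   b1y_ut = Im(pulse$samples))
  write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dwell_seconds = pulse$dwell_seconds,
         nominal_peak_b1_ut = pulse$nominal_peak_b1_ut,
         label = pulse$label),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a pulse waveform from CSV plus JSON sidecar
#'
#' Accepts the native `time_s`, `b1x_ut`, `b1y_ut` dialect and the legacy
#' two-column `amplitude_ut`, `phase_deg` dialect.
#'
#' @param path CSV path; the sidecar must exist next to it.
#' @return A [pulse_waveform()].
#' @export
read_pulse <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(path)) {
    .stop_mrsat("mrsat_format_error", "pulse file not found: %s", path)
  }
  if (!file.exists(side)) {
    .stop_mrsat("mrsat_format_error", "missing JSON sidecar: %s", side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$dwell_seconds)) {
    .stop_mrsat("mrsat_format_error", "sidecar lacks dwell_seconds")
  }
  df <- read.csv(path)
  if (all(c("b1x_ut", "b1y_ut") %in% names(df))) {
    samples <- complex(real = df$b1x_ut, imaginary = df$b1y_ut)
    if ("time_s" %in% names(df) && nrow(df) > 1L) {
      dt <- median(diff(df$time_s))
      if (abs(dt - meta$dwell_seconds) > 1e-9 * max(dt, meta$dwell_seconds)) {
        .stop_mrsat("mrsat_consistency_error",
                    "CSV time step (%g) disagrees with sidecar dwell (%g)",
                    dt, meta$dwell_seconds)
      }
    }
  } else if (all(c("amplitude_ut", "phase_deg") %in% names(df))) {
    samples <- df$amplitude_ut * exp(1i * df$phase_deg * pi / 180)
  } else {
    missing_col <- setdiff(c("b1x_ut", "b1y_ut"), names(df))
    .stop_mrsat("mrsat_format_error", "missing pulse column(s): %s",
                paste(missing_col, collapse = ", "))
  }
  pulse_waveform(samples, meta$dwell_seconds,
                 nominal_peak_b1_ut = meta$nominal_peak_b1_ut,
                 label = if (is.null(meta$label)) "" else meta$label)
}

#' Write a saturation curve to CSV
#'
#' Columns `duration_s`, `amplitude` and, when present, `amplitude_sd`.
#'
#' @param curve A [saturation_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_st_curve <- function(curve, path) {
  stopifnot(inherits(curve, "saturation_curve"))
  df <- data.frame(duration_s = curve$durations_seconds,
                   amplitude = curve$amplitudes)
  if (!is.null(curve$amplitude_sds)) df$amplitude_sd <- curve$amplitude_sds
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a saturation curve from CSV
#'
#' @param path CSV with columns `duration_s`, `amplitude`, optional
#'   `amplitude_sd`.
#' @param metabolite_label Label attached to the curve.
#' @return A [saturation_curve()].
#' @export
read_st_curve <- function(path, metabolite_label = "") {
  if (!file.exists(path)) {
    .stop_mrsat("mrsat_format_error", "curve file not found: %s", path)
  }
  df <- read.csv(path)
  need <- setdiff(c("duration_s", "amplitude"), names(df))
  if (length(need)) {
    .stop_mrsat("mrsat_format_error", "missing curve column(s): %s",
                paste(need, collapse = ", "))
  }
  saturation_curve(df$duration_s, df$amplitude,
                   amplitude_sds = df$amplitude_sd,
                   metabolite_label = metabolite_label)
}

#' Write a cohort table to CSV
#'
#' @param records List of [cohort_record()]s or a [cohort_table()] data
#'   frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  df <- if (is.data.frame(records)) records else cohort_table(records)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV in [cohort_table()] column layout.
#' @return List of [cohort_record()]s.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    .stop_mrsat("mrsat_format_error", "cohort file not found: %s", path)
  }
  df <- read.csv(path)
  need <- setdiff(c("gamma_atp_mm", "pcr_mm", "pi_mm", "kf_per_s",
                    "kf_prime_per_s", "kr_sum_per_s"), names(df))
  if (length(need)) {
    .stop_mrsat("mrsat_format_error", "missing cohort column(s): %s",
                paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    cohort_record(
      heart_id = if ("heart_id" %in% names(df)) r$heart_id else i,
      gamma_atp_mm = r$gamma_atp_mm, pcr_mm = r$pcr_mm, pi_mm = r$pi_mm,
      kf_per_s = r$kf_per_s, kf_prime_per_s = r$kf_prime_per_s,
      kr_sum_per_s = r$kr_sum_per_s,
      heart_weight_g = if ("heart_weight_g" %in% names(df))
        r$heart_weight_g else NA_real_)
  })
}

#' Read a design specification from a JSON config file
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path JSON file whose keys are [design_spec()] arguments.
#' @return A [design_spec()].
#' @export
read_design_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(design_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    .stop_mrsat("mrsat_format_error", "unknown config field(s): %s",
                paste(bad, collapse = ", "))
  }
  do.call(design_spec, cfg)
}

#' Persist a polynomial pair to JSON
#'
#' Complex coefficients stored as `[re, im]` pairs for reproducibility of
#' intermediate design stages.
#'
#' @param ab An [ab_polynomials()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ab_polynomials <- function(ab, path) {
  stopifnot(inherits(ab, "ab_polynomials"))
  jsonlite::write_json(
    list(dwell_seconds = ab$dwell_seconds,
         a = cbind(Re(ab$a_coeffs), Im(ab$a_coeffs)),
         b = cbind(Re(ab$b_coeffs), Im(ab$b_coeffs))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a polynomial pair from JSON
#'
#' @param path File written by [write_ab_polynomials()].
#' @param tol Unimodularity tolerance.
#' @return An [ab_polynomials()].
#' @export
read_ab_polynomials <- function(path, tol = 1e-4) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ab_polynomials(complex(real = x$a[, 1], imaginary = x$a[, 2]),
                 complex(real = x$b[, 1], imaginary = x$b[, 2]),
                 x$dwell_seconds, tol = tol)
}
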
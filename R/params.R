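#' Biophysical constants of the electroporation-threshold model
#'
#' Bundles the two constants of the charging-corrected Schwan threshold model:
#' the critical induced transmembrane potential and the membrane charging time
#' constant. The defaults (0.2 V, 2 us) are the values conventionally used for
#' mammalian cells.
#'
#' @param dv_threshold Critical transmembrane potential in volts (default 0.2).
#' @param tau_charge Membrane charging time constant in seconds (default 2e-6).
#' @return An object of class `"threshold_params"`.
#' @examples
#' threshold_params()
#' threshold_params(dv_threshold = 0.25)
#' @export
threshold_params <- function(dv_threshold = 0.2, tau_charge = 2e-6) {
  stopifnot(is.numeric(dv_threshold), length(dv_threshold) == 1L,
            is.numeric(tau_charge), length(tau_charge) == 1L)
  if (!is.finite(dv_threshold) || dv_threshold <= 0)
    stop("'dv_threshold' must be a positive, finite voltage")
  if (!is.finite(tau_charge) || tau_charge <= 0)
    stop("'tau_charge' must be a positive, finite time")
  structure(list(dv_threshold = dv_threshold, tau_charge = tau_charge),
            class = "threshold_params")
}

#' @export
print.threshold_params <- function(x, ...) {
  cat("Electroporation threshold model parameters\n")
  cat(sprintf("  dV threshold : %.3g V\n", x$dv_threshold))
  cat(sprintf("  tau (charge) : %.3g s\n", x$tau_charge))
  invisible(x)
}

#' Pulse-train protocol description
#'
#' Defaults describe a train of 200 nearly rectangular 300-ns pulses at 1 kV
#' delivered at 10 Hz.
#'
#' @param pulse_duration Single-pulse duration in seconds.
#' @param n_pulses Number of pulses in the train.
#' @param frequency Repetition rate in Hz.
#' @param amplitude Generator voltage in volts.
#' @return An object of class `"pulse_protocol"`.
#' @export
pulse_protocol <- function(pulse_duration = 300e-9, n_pulses = 200,
                           frequency = 10, amplitude = 1000) {
  vals <- c(pulse_duration, n_pulses, frequency, amplitude)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all pulse protocol fields must be positive and finite")
  structure(list(pulse_duration = pulse_duration, n_pulses = as.integer(n_pulses),
                 frequency = frequency, amplitude = amplitude),
            class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("Pulse protocol: %d x %.3g ns at %.3g Hz, %.3g V\n",
              x$n_pulses, x$pulse_duration * 1e9, x$frequency, x$amplitude))
  invisible(x)
}

#' Two-wire electrode geometry
#'
#' Parallel cylindrical rod electrodes characterised by wire radius and
#' center-to-center spacing. Defaults: 0.5 mm diameter tungsten rods at 1.5 mm
#' spacing.
#'
#' @param wire_radius Rod radius in metres (default 0.25e-3).
#' @param center_spacing Center-to-center spacing in metres (default 1.5e-3).
#' @param applied_voltage Voltage between the rods in volts (default 1, so that
#'   fields scale linearly to any drive).
#' @return An object of class `"electrode_geometry"`.
#' @export
electrode_geometry <- function(wire_radius = 0.25e-3, center_spacing = 1.5e-3,
                               applied_voltage = 1) {
  vals <- c(wire_radius, center_spacing, applied_voltage)
  if (any(!is.finite(vals)) || wire_radius <= 0 || center_spacing <= 0)
    stop("geometry fields must be positive and finite")
  if (center_spacing <= 2 * wire_radius)
    stop("'center_spacing' must exceed the wire diameter (2 * wire_radius)")
  structure(list(wire_radius = wire_radius, center_spacing = center_spacing,
                 applied_voltage = applied_voltage),
            class = "electrode_geometry")
}

#' @export
print.electrode_geometry <- function(x, ...) {
  cat(sprintf("Two-wire electrodes: radius %.3g mm, spacing %.3g mm, %.3g V\n",
              x$wire_radius * 1e3, x$center_spacing * 1e3, x$applied_voltage))
  invisible(x)
}

#' Imaging region-of-interest specification
#'
#' A rectangular ROI placed with one long edge on the line connecting the
#' electrode tips, extending away from the gap, and divided into equal
#' sub-regions (subROIs) along its depth. Defaults: 800 x 600 um split into
#' three 800 x 200 um bands.
#'
#' @param roi_width ROI width in metres (edge parallel to the electrode axis).
#' @param roi_depth ROI depth in metres (extent away from the gap).
#' @param n_subrois Number of equal sub-regions along the depth.
#' @param offset_from_gap Distance of the near edge from the electrode axis (m).
#' @return An object of class `"roi_spec"`.
#' @export
roi_spec <- function(roi_width = 800e-6, roi_depth = 600e-6, n_subrois = 3,
                     offset_from_gap = 0) {
  if (!is.finite(roi_width) || roi_width <= 0 ||
      !is.finite(roi_depth) || roi_depth <= 0)
    stop("ROI dimensions must be positive")
  n_subrois <- as.integer(n_subrois)
  if (is.na(n_subrois) || n_subrois < 1L) stop("'n_subrois' must be >= 1")
  if (!is.finite(offset_from_gap) || offset_from_gap < 0)
    stop("'offset_from_gap' must be non-negative")
  structure(list(roi_width = roi_width, roi_depth = roi_depth,
                 n_subrois = n_subrois, offset_from_gap = offset_from_gap),
            class = "roi_spec")
}

# unit display helpers -------------------------------------------------------

#' Unit conversion helpers
#'
#' Internally all quantities are SI (V/m, m, s). These helpers render the
#' field-customary units.
#'
#' @param e_v_per_m Field strength in V/m.
#' @param x Length in metres (`as_um`) or micrometres (`um`).
#' @return Numeric vector in the target unit.
#' @export
as_kv_per_cm <- function(e_v_per_m) e_v_per_m / 1e5

#' @rdname as_kv_per_cm
#' @export
as_um <- function(x) x * 1e6

#' @rdname as_kv_per_cm
#' @export
um <- function(x) x * 1e-6
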
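#' Steady-state Schwan field for a target transmembrane potential
#'
#' For a spherical cell of radius \eqn{R} in a uniform external field, the
#' steady-state induced transmembrane potential at the cathode-facing pole is
#' \eqn{\Delta V = (3/2) E R}. Inverting, the external field needed to induce a
#' potential \eqn{\Delta V} is
#' \deqn{E = \frac{2}{3}\,\frac{\Delta V}{R}.}
#' Larger cells therefore reach a given transmembrane potential at lower
#' external fields.
#'
#' @param dv Target induced transmembrane potential in volts (> 0).
#' @param radius Cell radius in metres (> 0). Vectorised.
#' @return External field strength in V/m.
#' @examples
#' steady_state_schwan_field(0.2, um(10))   # 13333.33 V/m
#' steady_state_schwan_field(0.2, um(15))   #  8888.89 V/m
#' @export
steady_state_schwan_field <- function(dv, radius) {
  if (any(!is.finite(dv)) || any(dv <= 0))
    stop("'dv' must be positive and finite")
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("'radius' must be positive and finite")
  (2 / 3) * dv / radius
}

#' Fractional membrane charging during a finite pulse
#'
#' The induced transmembrane potential builds exponentially during the pulse,
#' \eqn{\Delta V(t) = \Delta V_{max} (1 - e^{-t/\tau})}, with \eqn{\tau} the
#' membrane charging time constant (about 2 us for mammalian cells). This
#' returns the dimensionless fraction \eqn{1 - e^{-t/\tau}} reached after a
#' pulse of duration `t`.
#'
#' @param t Pulse duration in seconds (>= 0). Vectorised.
#' @param tau_charge Membrane charging time constant in seconds (> 0).
#' @return Fraction in \[0, 1).
#' @examples
#' charging_factor(300e-9, 2e-6)  # 0.139292
#' @export
charging_factor <- function(t, tau_charge) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be non-negative and finite")
  if (any(!is.finite(tau_charge)) || any(tau_charge <= 0))
    stop("'tau_charge' must be positive and finite")
  1 - exp(-t / tau_charge)
}

#' Electroporation-threshold field for a spherical cell
#'
#' Combines the steady-state Schwan relation with the finite-pulse charging
#' correction: the field needed to drive the pole potential to the
#' electroporation threshold `dv_threshold` within a pulse of duration `t` is
#' \deqn{E_{thr}(R, t) = \frac{2}{3}\,\frac{\Delta V_{thr}}{R}\,
#'   \frac{1}{1 - e^{-t/\tau}}.}
#' The threshold is strictly decreasing in both the cell radius and the pulse
#' duration; the ratio of thresholds for two radii is independent of the pulse
#' duration.
#'
#' @param radius Cell radius in metres (> 0). Vectorised.
#' @param pulse_duration Pulse duration in seconds (> 0). Vectorised.
#' @param params A [threshold_params()] object.
#' @return Threshold field strength in V/m.
#' @examples
#' # a 20-um cell needs ~1.5x the field of a 30-um cell, at any duration
#' threshold_field(um(10), 300e-9) / threshold_field(um(15), 300e-9)
#' @export
threshold_field <- function(radius, pulse_duration, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"))
  if (any(!is.finite(pulse_duration)) || any(pulse_duration <= 0))
    stop("'pulse_duration' must be strictly positive (zero gives no charging)")
  e_ss <- steady_state_schwan_field(params$dv_threshold, radius)
  e_ss / charging_factor(pulse_duration, params$tau_charge)
}

#' Threshold-field table over cell diameters and pulse durations
#'
#' Evaluates [threshold_field()] on the full cross-product of cell diameters
#' and pulse durations, the layout used to chart how the electroporation
#' threshold falls with cell size across sub-microsecond pulses.
#'
#' @param diameters_um Cell diameters in micrometres (conventionally 10-40).
#' @param durations_s Pulse durations in seconds.
#' @param params A [threshold_params()] object.
#' @param file Optional path; when given the table is written as CSV.
#' @return A data frame with columns `diameter_um`, `pulse_duration_s`,
#'   `e_threshold_v_per_m`, `e_threshold_kv_per_cm`.
#' @examples
#' threshold_curve(c(20, 30), c(100e-9, 300e-9, 1e-6))
#' @export
threshold_curve <- function(diameters_um, durations_s,
                            params = threshold_params(), file = NULL) {
  if (length(diameters_um) == 0L || length(durations_s) == 0L)
    stop("'diameters_um' and 'durations_s' must be non-empty")
  grid <- expand.grid(diameter_um = sort(diameters_um),
                      pulse_duration_s = sort(durations_s),
                      KEEP.OUT.ATTRS = FALSE)
  e <- threshold_field(um(grid$diameter_um) / 2, grid$pulse_duration_s, params)
  out <- data.frame(grid,
                    e_threshold_v_per_m = e,
                    e_threshold_kv_per_cm = as_kv_per_cm(e))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Fraction of a cell population above the electroporation threshold
#'
#' Given a population of cell radii and a local field strength, returns the
#' fraction of cells whose threshold field (at the given pulse duration) is at
#' or below the local field, i.e. the expected permeabilized fraction under
#' the deterministic threshold model.
#'
#' @param radii Cell radii in metres (non-empty).
#' @param local_field Local field strength in V/m (>= 0).
#' @param pulse_duration Pulse duration in seconds.
#' @param params A [threshold_params()] object.
#' @return Fraction in \[0, 1\]; non-decreasing in `local_field`.
#' @export
permeabilized_fraction <- function(radii, local_field, pulse_duration,
                                   params = threshold_params()) {
  if (length(radii) == 0L) stop("'radii' must be non-empty")
  if (!is.finite(local_field) || local_field < 0)
    stop("'local_field' must be a non-negative field strength")
  if (local_field == 0) return(0)
  mean(threshold_field(radii, pulse_duration, params) <= local_field)
}
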
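# Post-exposure stiffness decay.
#
# Normalized Young's modulus after membrane permeabilization follows
#   y(t) = p + (1 - p) * exp(-t / tau),  y(0) = 1,
# where p is the fraction of the initial stiffness retained at equilibrium
# and tau (minutes) sets how fast the loss develops. Given tau the model is
# linear in p, so p is profiled out and tau found by bounded 1-D search,
# mirroring the uptake fit.

.decay_rss <- function(log_tau, tt, y) {
  b <- exp(-tt / exp(log_tau))
  g <- 1 - b
  p <- sum(g * (y - b)) / sum(g * g)
  p <- min(max(p, 0), 1)
  sum((y - (p + (1 - p) * b))^2)
}

#' Fit the single-exponential stiffness-decay model
#'
#' Fits \eqn{y(t) = p + (1 - p) e^{-t/\tau}} to stiffness values normalized
#' to the pre-exposure baseline (\eqn{y(0) = 1}). The plateau fraction
#' \eqn{p \in [0, 1]} is the stiffness retained once the decay equilibrates;
#' \eqn{1 - y(t)} is the fractional stiffness loss at time \eqn{t}.
#'
#' @param times Timepoints in minutes post-exposure (>= 0, ascending, at
#'   least 3 distinct).
#' @param moduli Young's moduli at those timepoints, in Pa, or already
#'   normalized values if `baseline = 1`.
#' @param baseline Pre-exposure (t = 0) modulus used for normalization
#'   (default: the modulus at the earliest timepoint).
#' @param loss_at Timepoints (min) at which to report the predicted percent
#'   stiffness loss (default `c(4, 10)`).
#' @param tau_bounds Search bounds for tau in minutes.
#' @return An object of class `"stiffness_decay_fit"` with
#'   `plateau_fraction`, `tau_decay`, `r_squared`, and `loss_percent` (named
#'   vector of predicted losses at `loss_at`).
#' @examples
#' t <- c(0, 1, 4, 7, 10)
#' y <- 0.4 + 0.6 * exp(-t / 2.2326)
#' fit <- fit_stiffness_decay(t, y, baseline = 1)
#' fit$loss_percent  # ~50% at 4 min, ~59% at 10 min
#' @export
fit_stiffness_decay <- function(times, moduli, baseline = NULL,
                                loss_at = c(4, 10), tau_bounds = c(0.05, 1e3)) {
  if (length(times) != length(moduli)) stop("'times' and 'moduli' lengths differ")
  if (length(unique(times)) < 3L) stop("need at least 3 distinct timepoints")
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times))
    stop("'times' must be non-negative and ascending (minutes post-exposure)")
  if (any(!is.finite(moduli)) || any(moduli <= 0))
    stop("'moduli' must be positive and finite")
  if (is.null(baseline)) baseline <- moduli[1]
  if (!is.finite(baseline) || baseline <= 0) stop("'baseline' must be positive")
  y <- moduli / baseline

  if (max(abs(y - y[1])) < 1e-12) {
    # constant series: no decay
    fit <- list(plateau_fraction = y[1], tau_decay = NA_real_, r_squared = 1)
  } else {
    lg <- seq(log(tau_bounds[1]), log(tau_bounds[2]), length.out = 200L)
    rss <- vapply(lg, .decay_rss, numeric(1), tt = times, y = y)
    i <- which.min(rss)
    opt <- stats::optimize(.decay_rss, c(lg[max(1L, i - 1L)], lg[min(200L, i + 1L)]),
                           tt = times, y = y, tol = .Machine$double.eps^0.5)
    tau <- exp(opt$minimum)
    b <- exp(-times / tau); g <- 1 - b
    p <- min(max(sum(g * (y - b)) / sum(g * g), 0), 1)
    ss_tot <- sum((y - mean(y))^2)
    fit <- list(plateau_fraction = p, tau_decay = tau,
                r_squared = 1 - opt$objective / ss_tot)
  }
  yp <- function(t) {
    if (is.na(fit$tau_decay)) rep(fit$plateau_fraction, length(t))
    else fit$plateau_fraction + (1 - fit$plateau_fraction) * exp(-t / fit$tau_decay)
  }
  loss <- 100 * (1 - yp(loss_at))
  names(loss) <- paste0(loss_at, "min")
  structure(c(fit, list(loss_percent = loss, times = times, normalized = y,
                        baseline = baseline)),
            class = "stiffness_decay_fit")
}

#' @export
print.stiffness_decay_fit <- function(x, digits = 4, ...) {
  cat("Stiffness decay fit: y(t) = p + (1 - p) exp(-t/tau)\n")
  cat(sprintf("  p (plateau fraction) : %s\n", format(x$plateau_fraction, digits = digits)))
  cat(sprintf("  tau (decay)          : %s min\n", format(x$tau_decay, digits = digits)))
  cat(sprintf("  R^2                  : %s\n", format(x$r_squared, digits = digits)))
  for (nm in names(x$loss_percent))
    cat(sprintf("  predicted loss at %-5s: %.1f%%\n", nm, x$loss_percent[[nm]]))
  invisible(x)
}

#' @export
coef.stiffness_decay_fit <- function(object, ...) {
  c(plateau_fraction = object$plateau_fraction, tau_decay = object$tau_decay)
}

#' @export
predict.stiffness_decay_fit <- function(object, times = object$times, ...) {
  if (is.na(object$tau_decay)) return(rep(object$plateau_fraction, length(times)))
  object$plateau_fraction +
    (1 - object$plateau_fraction) * exp(-times / object$tau_decay)
}

#' Run the full force-map stiffness pipeline
#'
#' Hertz-fits every curve, takes the per-map (spheroid x timepoint) median,
#' normalizes each spheroid's series to its earliest timepoint, fits the
#' decay model to the across-spheroid mean normalized series, and reports
#' predicted losses.
#'
#' @param curves Long data frame with columns `curve_id`, `z_m`,
#'   `deflection_m` (as written by [generate_force_maps()] or loaded from
#'   CSV).
#' @param metadata Data frame with columns `curve_id`, `spring_constant`,
#'   `tip_radius`, `spheroid_id`, `timepoint_min`.
#' @param loss_at Timepoints (min) for predicted-loss reporting.
#' @return List with `map_moduli` (data frame `spheroid_id`,
#'   `timepoint_min`, `modulus_pa`, `normalized`) and `decay_fit`
#'   (a `"stiffness_decay_fit"` of the mean normalized series).
#' @export
analyze_force_maps <- function(curves, metadata, loss_at = c(4, 10)) {
  need <- c("curve_id", "z_m", "deflection_m")
  if (!all(need %in% names(curves)))
    stop("'curves' must have columns ", paste(need, collapse = ", "))
  needm <- c("curve_id", "spring_constant", "tip_radius", "spheroid_id",
             "timepoint_min")
  if (!all(needm %in% names(metadata)))
    stop("'metadata' must have columns ", paste(needm, collapse = ", "))
  fits_by_curve <- lapply(split(curves, curves$curve_id), function(d) {
    m <- metadata[match(d$curve_id[1], metadata$curve_id), ]
    hertz_fit(force_curve(d$z_m, d$deflection_m,
                          spring_constant = m$spring_constant,
                          tip_radius = m$tip_radius))
  })
  meta1 <- metadata[match(names(fits_by_curve), metadata$curve_id), ]
  key <- interaction(meta1$spheroid_id, meta1$timepoint_min, drop = TRUE)
  map_moduli <- do.call(rbind, lapply(split(seq_along(fits_by_curve), key),
    function(ix) data.frame(
      spheroid_id = meta1$spheroid_id[ix[1]],
      timepoint_min = meta1$timepoint_min[ix[1]],
      modulus_pa = map_representative(fits_by_curve[ix]))))
  rownames(map_moduli) <- NULL
  map_moduli <- map_moduli[order(map_moduli$spheroid_id, map_moduli$timepoint_min), ]
  map_moduli$normalized <- stats::ave(
    map_moduli$modulus_pa, map_moduli$spheroid_id,
    FUN = function(v) v / v[1])
  mean_series <- stats::aggregate(normalized ~ timepoint_min, map_moduli, mean)
  fit <- fit_stiffness_decay(mean_series$timepoint_min,
                             mean_series$normalized, baseline = 1,
                             loss_at = loss_at)
  list(map_moduli = map_moduli, decay_fit = fit)
}
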
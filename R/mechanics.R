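#' Construct an AFM approach force curve
#'
#' One approach segment of an AFM force-distance acquisition: piezo
#' displacement toward the sample and the measured cantilever deflection,
#' together with the probe constants needed to convert to force and
#' indentation. Defaults describe a soft cantilever (0.04 N/m) carrying a
#' 1-um-radius spherical tip, with the incompressible-tissue Poisson ratio.
#'
#' @param piezo_displacement Piezo z positions in metres, strictly increasing
#'   toward contact.
#' @param deflection Cantilever deflection in metres, same length.
#' @param spring_constant Cantilever spring constant in N/m (default 0.04).
#' @param tip_radius Spherical tip radius in metres (default 1e-6).
#' @param poisson_ratio Sample Poisson ratio in \[0, 0.5\] (default 0.5).
#' @param meta Named list of metadata (curve_id, spheroid_id, timepoint_min, ...).
#' @return An object of class `"force_curve"`.
#' @export
force_curve <- function(piezo_displacement, deflection, spring_constant = 0.04,
                        tip_radius = 1e-6, poisson_ratio = 0.5, meta = list()) {
  z <- as.numeric(piezo_displacement); d <- as.numeric(deflection)
  if (length(z) != length(d)) stop("displacement and deflection lengths differ")
  if (any(!is.finite(z)) || any(diff(z) <= 0))
    stop("'piezo_displacement' must be finite and strictly increasing")
  if (any(!is.finite(d))) stop("'deflection' must be finite")
  if (!is.finite(spring_constant) || spring_constant <= 0)
    stop("'spring_constant' must be positive")
  if (!is.finite(tip_radius) || tip_radius <= 0)
    stop("'tip_radius' must be positive")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("'poisson_ratio' must lie in [0, 0.5]")
  structure(list(z = z, deflection = d, spring_constant = spring_constant,
                 tip_radius = tip_radius, poisson_ratio = poisson_ratio,
                 meta = meta),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("AFM force curve: %d samples, k = %.3g N/m, R_tip = %.3g um, nu = %.2f\n",
              length(x$z), x$spring_constant, x$tip_radius * 1e6, x$poisson_ratio))
  invisible(x)
}

#' Reduce a force curve to indentation and force past a contact point
#'
#' Standard AFM reduction: force = deflection x spring constant; indentation
#' = (displacement - displacement at contact) - deflection, evaluated for
#' samples past the contact point. In the rigid-contact limit (deflection
#' tracking displacement one-to-one) the indentation is identically zero.
#'
#' @param curve A [force_curve()].
#' @param contact_z Piezo position of tip-sample contact, in metres.
#' @return Data frame with columns `indentation` (m) and `force` (N) for the
#'   post-contact samples with positive indentation.
#' @export
preprocess_force_curve <- function(curve, contact_z) {
  stopifnot(inherits(curve, "force_curve"))
  post <- curve$z > contact_z
  ind <- (curve$z[post] - contact_z) - curve$deflection[post]
  frc <- curve$deflection[post] * curve$spring_constant
  keep <- ind > 0
  data.frame(indentation = ind[keep], force = frc[keep])
}

.hertz_prefactor <- function(curve) {
  (4 / 3) * sqrt(curve$tip_radius) / (1 - curve$poisson_ratio^2)
}

#' Hertz-model force for a spherical indenter
#'
#' \deqn{F = \frac{4}{3}\,\frac{E}{1 - \nu^2}\,\sqrt{R_{tip}}\;\delta^{3/2}}
#'
#' @param delta Indentation in metres.
#' @param young_modulus Young's modulus in Pa.
#' @param tip_radius Tip radius in metres.
#' @param poisson_ratio Poisson ratio.
#' @return Force in newtons.
#' @export
hertz_force <- function(delta, young_modulus, tip_radius = 1e-6,
                        poisson_ratio = 0.5) {
  (4 / 3) * young_modulus / (1 - poisson_ratio^2) * sqrt(tip_radius) * delta^1.5
}

#' Fit the Hertz model to an AFM approach curve
#'
#' Jointly estimates the contact point and the Young's modulus. Every sample
#' position is a candidate contact point; for each candidate, the force is
#' modelled as zero before contact and Hertzian after, the modulus is the
#' closed-form least-squares solution (the Hertz force is linear in E), and
#' the candidate minimising the full-curve residual sum of squares wins.
#' The fitted indentation range is capped at `delta_max` (default the tip
#' radius) because the spherical Hertz form assumes indentation small
#' relative to the tip.
#'
#' @param curve A [force_curve()].
#' @param delta_max Maximum indentation included in the fit, metres
#'   (default `curve$tip_radius`).
#' @param min_post_contact Minimum number of post-contact samples required
#'   (default 20).
#' @return An object of class `"hertz_fit"` with `young_modulus` (Pa),
#'   `contact_point` (m), `r_squared`, `converged`, and fit data.
#' @examples
#' dl <- seq(0, 1e-6, length.out = 80)
#' f  <- hertz_force(dl, 1000)
#' d  <- f / 0.04
#' z  <- c(seq(-2e-6, 0, length.out = 40), (dl + d)[-1])
#' cv <- force_curve(z + 2e-6, c(rep(0, 40), d[-1]))
#' fit <- hertz_fit(cv)
#' coef(fit)  # ~1000 Pa
#' @export
hertz_fit <- function(curve, delta_max = curve$tip_radius,
                      min_post_contact = 20L) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z
  frc <- curve$deflection * curve$spring_constant
  pre <- .hertz_prefactor(curve)
  n <- length(z)
  if (n < min_post_contact + 2L)
    stop("too few samples for a Hertz fit")

  best <- list(rss = Inf, e = NA_real_, zc = NA_real_)
  ss_tot <- sum((frc - mean(frc))^2)
  for (i in seq_len(n - min_post_contact)) {
    zc <- z[i]
    post <- (i + 1L):n
    ind <- (z[post] - zc) - curve$deflection[post]
    ok <- ind > 0 & ind <= delta_max
    if (sum(ok) < min_post_contact) next
    x <- pre * ind[ok]^1.5
    y <- frc[post][ok]
    e <- sum(x * y) / sum(x * x)
    if (!is.finite(e) || e <= 0) next
    # residual over the whole curve: zero force before contact, Hertz after
    # (extended past the delta_max cap so no candidate can hide samples)
    fitted <- rep(0, n)
    fitted[post] <- e * pre * pmax(ind, 0)^1.5
    rss <- sum((frc - fitted)^2)
    if (rss < best$rss) best <- list(rss = rss, e = e, zc = zc)
  }
  r2 <- if (ss_tot > 0) 1 - best$rss / ss_tot else NA_real_
  converged <- is.finite(best$e) && !is.na(r2) && r2 > 0
  structure(list(young_modulus = best$e, contact_point = best$zc,
                 r_squared = r2, converged = converged,
                 curve = curve),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, digits = 4, ...) {
  cat("Hertz-model fit (spherical indenter)\n")
  cat(sprintf("  E (Young's modulus) : %s Pa\n", format(x$young_modulus, digits = digits)))
  cat(sprintf("  contact point       : %s um\n", format(x$contact_point * 1e6, digits = digits)))
  cat(sprintf("  R^2 (full curve)    : %s%s\n", format(x$r_squared, digits = digits),
              if (!x$converged) "  [NOT converged]" else ""))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(young_modulus = object$young_modulus, contact_point = object$contact_point)
}

#' Predict Hertz forces from a fitted curve
#'
#' @param object A `"hertz_fit"`.
#' @param z Piezo positions (default: those of the fitted curve).
#' @param ... Unused.
#' @return Predicted forces in newtons (zero before contact).
#' @export
predict.hertz_fit <- function(object, z = object$curve$z, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  d <- stats::approx(object$curve$z, object$curve$deflection, xout = z,
                     rule = 2)$y
  ind <- pmax((z - object$contact_point) - d, 0)
  hertz_force(ind, object$young_modulus, object$curve$tip_radius,
              object$curve$poisson_ratio)
}

#' Representative stiffness of one force map
#'
#' Reduces the 25 fits of a 5 x 5 force map to a single per-spheroid value:
#' the median of the converged Young's moduli (robust to the occasional bad
#' curve). Set `fun = mean` for the averaging convention.
#'
#' @param fits List of `"hertz_fit"` objects (typically 25).
#' @param fun Aggregation function applied to converged moduli (default
#'   [stats::median]).
#' @return Representative Young's modulus in Pa.
#' @export
map_representative <- function(fits, fun = stats::median) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no converged Hertz fits in this force map")
  fun(vapply(fits[conv], `[[`, numeric(1), "young_modulus"))
}
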
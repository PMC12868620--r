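# Shared oracles and fixture builders (all fixtures are generated in code).

# model trace: single exponential rising from t0, constant baseline before
make_model_trace <- function(a = 100, tau = 130, t0 = 10, baseline = 0,
                             times = seq(0, 180, by = 3), kind = "uptake") {
  vals <- baseline + ifelse(times >= t0, a * (1 - exp(-(times - t0) / tau)), 0)
  fluorescence_trace(times, vals, exposure_time = t0, kind = kind)
}

# Richardson-extrapolated central difference: error O(h^4)
num_deriv <- function(f, x, h) {
  (8 * (f(x + h / 2) - f(x - h / 2)) - (f(x + h) - f(x - h))) / (6 * h)
}

# independent field oracle: numerical gradient of the line-charge potential
field_by_gradient <- function(geom, x, y, h = 2e-6) {
  ex <- -num_deriv(function(xx) two_wire_potential(geom, xx, y), x, h)
  ey <- -num_deriv(function(yy) two_wire_potential(geom, x, yy), y, h)
  sqrt(ex^2 + ey^2)
}

# dense-grid least-squares oracle for the uptake model
grid_search_rss <- function(trace, n_grid = 2000) {
  trace <- subtract_baseline(trace)
  post <- trace$times >= trace$exposure_time
  dtt <- trace$times[post] - trace$exposure_time
  y <- trace$values[post]
  taus <- exp(seq(log(1), log(1e4), length.out = n_grid))
  min(vapply(taus, function(tau) {
    g <- 1 - exp(-dtt / tau)
    a <- max(sum(g * y) / sum(g * g), 0)
    sum((y - a * g)^2)
  }, numeric(1)))
}

rss_of_uptake_fit <- function(fit) sum(residuals(fit)^2)

# noiseless Hertzian approach curve through the generator-independent route
make_hertz_curve <- function(e = 1000, contact = 2e-6, k = 0.04,
                             r_tip = 1e-6, nu = 0.5, n_pre = 40, n_post = 80) {
  delta <- seq(0, r_tip, length.out = n_post)[-1]
  frc <- (4 / 3) * e / (1 - nu^2) * sqrt(r_tip) * delta^1.5
  defl <- frc / k
  z <- c(seq(0, contact, length.out = n_pre), contact + delta + defl)
  force_curve(z, c(rep(0, n_pre), defl), spring_constant = k,
              tip_radius = r_tip, poisson_ratio = nu)
}
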
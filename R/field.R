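# Analytic 2D field of two oppositely charged parallel wires.
#
# For infinite parallel cylinders of radius a at center spacing d carrying
# voltage U between them, the exterior field equals that of two line charges
# at x = +/- s, s = sqrt((d/2)^2 - a^2), with
#   lambda / (pi * eps) = U / acosh(d / (2a)).
# Each line charge contributes a radial field (lambda / 2 pi eps) / r; the
# package field is the vector superposition of the two contributions.

.line_charge_positions <- function(geom) {
  s <- sqrt((geom$center_spacing / 2)^2 - geom$wire_radius^2)
  k <- geom$applied_voltage / (2 * acosh(geom$center_spacing / (2 * geom$wire_radius)))
  list(s = s, k = k)  # k = lambda / (2 pi eps)
}

.inside_wire <- function(geom, x, y) {
  half <- geom$center_spacing / 2
  d1 <- sqrt((x - half)^2 + y^2)
  d2 <- sqrt((x + half)^2 + y^2)
  d1 < geom$wire_radius | d2 < geom$wire_radius
}

#' Electric field magnitude of a two-wire electrode pair
#'
#' Closed-form 2D field of two infinite parallel cylindrical electrodes,
#' evaluated in the specimen plane. The electrodes lie along the x-axis at
#' \eqn{x = \pm d/2}; the exterior solution is that of two opposite line
#' charges at \eqn{x = \pm s}, \eqn{s = \sqrt{(d/2)^2 - a^2}}, with the charge
#' density fixed so the inter-electrode voltage equals `applied_voltage`.
#' The magnitude is linear in the applied voltage and symmetric under
#' reflection through the perpendicular bisector of the electrode axis.
#'
#' This is an analytic idealisation of the experimental contact-electrode
#' geometry (the physical rods meet the coverslip at an angle, a 3D effect not
#' modelled here); it reproduces the monotone decay of the field with distance
#' from the gap and scales exactly as a unit-voltage solution.
#'
#' @param geom An [electrode_geometry()] object.
#' @param x,y Planar coordinates in metres (vectorised, recycled). Points must
#'   lie outside both wire cross-sections.
#' @return Field magnitude in V/m at each point.
#' @examples
#' g <- electrode_geometry()           # 0.5 mm rods, 1.5 mm apart, 1 V
#' two_wire_field_profile(g, 0, 0)     # ~802 V/m at the midpoint
#' @export
two_wire_field_profile <- function(geom, x, y) {
  stopifnot(inherits(geom, "electrode_geometry"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (any(.inside_wire(geom, x, y)))
    stop("evaluation point lies inside an electrode cross-section")
  lc <- .line_charge_positions(geom)
  # positive line at (+s, 0), negative at (-s, 0)
  r1sq <- (x - lc$s)^2 + y^2
  r2sq <- (x + lc$s)^2 + y^2
  ex <- lc$k * ((x - lc$s) / r1sq - (x + lc$s) / r2sq)
  ey <- lc$k * (y / r1sq - y / r2sq)
  sqrt(ex^2 + ey^2)
}

#' Electrostatic potential of the two-wire model
#'
#' The potential \eqn{\phi(x,y) = k \ln(r_2 / r_1)} whose negative gradient is
#' the field returned by [two_wire_field_profile()]. Exposed mainly for
#' verification and plotting.
#'
#' @inheritParams two_wire_field_profile
#' @return Potential in volts.
#' @export
two_wire_potential <- function(geom, x, y) {
  stopifnot(inherits(geom, "electrode_geometry"))
  lc <- .line_charge_positions(geom)
  r1 <- sqrt((x - lc$s)^2 + y^2)
  r2 <- sqrt((x + lc$s)^2 + y^2)
  lc$k * log(r2 / r1)
}

#' Mean, min and max field per imaging sub-region
#'
#' Places the rectangular ROI with its long edge on the electrode axis
#' (centred on the gap) extending away from the electrodes in the +y
#' direction, splits it into `n_subrois` equal bands along the depth, and
#' samples the two-wire field on a uniform Cartesian grid in each band.
#' Mean fields decrease with band distance from the electrode axis.
#'
#' @param geom An [electrode_geometry()] object.
#' @param roi An [roi_spec()] object.
#' @param grid_n Grid points per side within each subROI (default 21).
#' @param file Optional CSV output path.
#' @return Data frame with columns `subroi_index`, `e_mean`, `e_min`, `e_max`
#'   (V/m), ordered by increasing distance from the electrodes.
#' @export
assign_subroi_fields <- function(geom, roi, grid_n = 21, file = NULL) {
  stopifnot(inherits(geom, "electrode_geometry"), inherits(roi, "roi_spec"))
  grid_n <- as.integer(grid_n)
  if (is.na(grid_n) || grid_n < 2L) stop("'grid_n' must be >= 2")
  half_w <- roi$roi_width / 2
  band <- roi$roi_depth / roi$n_subrois
  xs <- seq(-half_w, half_w, length.out = grid_n)
  # reject ROI placements overlapping an electrode cross-section: closest
  # point of the rectangle to each wire center must lie outside the wire
  y_lo <- roi$offset_from_gap; y_hi <- roi$offset_from_gap + roi$roi_depth
  for (cx in c(-1, 1) * geom$center_spacing / 2) {
    px <- min(max(cx, -half_w), half_w)
    py <- min(max(0, y_lo), y_hi)
    if (sqrt((px - cx)^2 + py^2) <= geom$wire_radius)
      stop("ROI overlaps an electrode cross-section")
  }
  out <- lapply(seq_len(roi$n_subrois), function(i) {
    y0 <- roi$offset_from_gap + (i - 1) * band
    ys <- seq(y0, y0 + band, length.out = grid_n)
    g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
    e <- two_wire_field_profile(geom, g$x, g$y)
    data.frame(subroi_index = i, e_mean = mean(e), e_min = min(e), e_max = max(e))
  })
  out <- do.call(rbind, out)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
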
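#' Specify an illumination source
#'
#' Describes one LED emitter: a disk or rectangular emitting surface with a
#' collimated (surface-normal) emission direction, or an isotropic point
#' emitter used for physics validation. Positions and directions are in
#' world mm (RAS).
#'
#' @param kind `"disk"`, `"rect"` or `"point"` (isotropic; validation use).
#' @param center Emitting-surface center, world mm.
#' @param direction Unit emission direction, pointing into the head
#'   (normalized internally; must be within 1e-9 of unit length after
#'   normalization of a nonzero vector). Ignored for `"point"`.
#' @param wavelength Wavelength, nm.
#' @param power_density_mw_cm2 Emitted power density over the surface,
#'   mW/cm^2 (disk/rect).
#' @param radius_mm Disk radius, mm.
#' @param width_mm,height_mm Rectangle edge lengths, mm.
#' @param u_axis In-plane orientation of the rectangle width (projected
#'   perpendicular to `direction`); default picks any perpendicular axis.
#' @param power_mw Total power for `"point"` sources, mW (default 1).
#' @return An object of class `source_spec`. `source_power()` returns the
#'   total emitted power in mW (power density x emitting area).
#' @export
source_spec <- function(kind = c("disk", "rect", "point"), center, direction = NULL,
                        wavelength, power_density_mw_cm2 = 20,
                        radius_mm = NULL, width_mm = NULL, height_mm = NULL,
                        u_axis = NULL, power_mw = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 3, is.numeric(wavelength), wavelength > 0)
  if (kind != "point") {
    if (is.null(direction)) stop("direction is required for surface sources")
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stop("direction must be nonzero")
    direction <- direction / nrm
    if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
      stop("direction could not be normalized")
    if (power_density_mw_cm2 <= 0) stop("power density must be positive")
  }
  if (kind == "disk") {
    if (is.null(radius_mm) || radius_mm < 0) stop("disk needs radius_mm >= 0")
  }
  if (kind == "rect") {
    if (is.null(width_mm) || is.null(height_mm) || width_mm <= 0 || height_mm <= 0)
      stop("rect needs positive width_mm and height_mm")
  }
  if (kind != "point") {
    # orthonormal in-plane frame
    if (is.null(u_axis)) {
      u_axis <- if (abs(direction[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    }
    e1 <- u_axis - sum(u_axis * direction) * direction
    if (sqrt(sum(e1^2)) < 1e-9) stop("u_axis is parallel to direction")
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(direction[2] * e1[3] - direction[3] * e1[2],
            direction[3] * e1[1] - direction[1] * e1[3],
            direction[1] * e1[2] - direction[2] * e1[1])
  } else {
    direction <- c(0, 0, 1); e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
    if (is.null(power_mw)) power_mw <- 1
  }
  structure(list(kind = kind, center = as.numeric(center),
                 direction = as.numeric(direction), e1 = e1, e2 = e2,
                 wavelength = as.numeric(wavelength),
                 power_density_mw_cm2 = power_density_mw_cm2,
                 radius_mm = radius_mm, width_mm = width_mm,
                 height_mm = height_mm, power_mw = power_mw),
            class = "source_spec")
}

#' @rdname source_spec
#' @param src A `source_spec`.
#' @export
source_power <- function(src) {
  stopifnot(inherits(src, "source_spec"))
  area_cm2 <- switch(src$kind,
    disk = pi * (src$radius_mm / 10)^2,
    rect = (src$width_mm / 10) * (src$height_mm / 10),
    point = NA_real_)
  if (src$kind == "point") return(src$power_mw)
  src$power_density_mw_cm2 * area_cm2
}

#' @export
print.source_spec <- function(x, ...) {
  geom <- switch(x$kind,
    disk = sprintf("r=%g mm", x$radius_mm),
    rect = sprintf("%g x %g mm", x$width_mm, x$height_mm),
    point = "isotropic point")
  cat(sprintf("source_spec: %s (%s), %g nm, center (%g, %g, %g) mm, %.2f mW total\n",
              x$kind, geom, x$wavelength, x$center[1], x$center[2],
              x$center[3], source_power(x)))
  invisible(x)
}

#' Place a source on the scalp surface
#'
#' Casts a ray from the world origin in the direction given by the azimuth
#' `phi` (from +x, in the xy plane) and polar angle `theta` (from +z), finds
#' the outermost intersection with the head mask, pushes the point outward
#' by `standoff` mm and points the source back toward the origin.
#'
#' @param head_mask Logical head-mask array.
#' @param grid The `volume_grid` the mask lives on.
#' @param phi_deg Azimuth, degrees.
#' @param theta_deg Polar angle from +z, degrees.
#' @param standoff_mm Outward offset of the source center from the scalp
#'   surface, mm.
#' @return List with `center` (world mm) and `direction` (unit, pointing at
#'   the origin).
#' @export
place_source_on_scalp <- function(head_mask, grid, phi_deg, theta_deg,
                                  standoff_mm = 0) {
  stopifnot(is.logical(head_mask), inherits(grid, "volume_grid"))
  .check_volume(grid, head_mask, "head_mask")
  if (!any(head_mask)) stop("head mask is empty")
  phi <- phi_deg * pi / 180
  theta <- theta_deg * pi / 180
  d <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  tmax <- sqrt(sum((grid$shape * grid$voxel_size)^2))
  ts <- seq(0, tmax, by = min(grid$voxel_size) / 4)
  pts <- ts %o% d
  v <- round(world_to_voxel(grid, pts))
  ok <- v[, 1] >= 1 & v[, 1] <= grid$shape[1] &
        v[, 2] >= 1 & v[, 2] <= grid$shape[2] &
        v[, 3] >= 1 & v[, 3] <= grid$shape[3]
  hit <- ok
  hit[ok] <- head_mask[v[ok, , drop = FALSE]]
  if (!any(hit)) stop("ray misses head")
  # outermost masked voxel, its center projected onto the ray
  vox_out <- v[max(which(hit)), , drop = FALSE]
  t_surf <- sum(voxel_to_world(grid, vox_out) * d)
  list(center = (t_surf + standoff_mm) * d, direction = -d)
}
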
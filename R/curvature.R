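# Sagittal (axial) curvature, best-fit sphere and dioptric change maps of
# the anterior corneal surface.
#
# Sagittal power at a surface point is (n - 1) * 1000 / r_ax dioptres, with
# r_ax the distance from the point along the surface normal to the apex
# axis.  Flattening (radius increase) gives negative power change.

#' Extract an anterior (or posterior) surface profile
#'
#' Surface node coordinates, optionally displaced by a solution field,
#' ordered by radial position.
#'
#' @param mesh a `cornea_mesh`.
#' @param solution optional `solution_field`; when given, the deformed
#'   coordinates are returned.
#' @param surface `"anterior"` or `"posterior"`.
#' @return tibble with columns `x`, `y` (mm), class `surface_profile`.
#' @export
surface_profile <- function(mesh, solution = NULL,
                            surface = c("anterior", "posterior")) {
  surface <- match.arg(surface)
  ids <- mesh$node_sets[[paste0(surface, "_surface")]]
  xy <- mesh$nodes[ids, , drop = FALSE]
  if (!is.null(solution)) xy <- xy + solution$u[ids, , drop = FALSE]
  ord <- order(xy[, 1])
  out <- tibble::tibble(x = xy[ord, 1], y = xy[ord, 2])
  class(out) <- c("surface_profile", class(out))
  out
}

# fit a lightly smoothed spline to the surface; symmetric profiles (data on
# one side only) are mirrored first so odd/even symmetry is enforced
fit_surface_spline <- function(profile, lambda = 1e-7, mirror = NULL) {
  x <- profile$x; y <- profile$y
  if (is.null(mirror)) mirror <- min(x) > -1e-9
  if (mirror) {
    pos <- x > 1e-12
    zero <- abs(x) <= 1e-12
    x <- c(-rev(x[pos]), x[zero], x[pos])
    y <- c(rev(y[pos]), y[zero], y[pos])
  }
  stats::smooth.spline(x, y, lambda = lambda, all.knots = TRUE,
                       keep.data = FALSE)
}

#' Sagittal power profile of a surface
#'
#' Fits a smoothing spline to the surface, takes exact normals from the
#' spline and converts the axial radius (surface point to apex axis along
#' the normal) to dioptres with the keratometric index.  At the apex the
#' normal is parallel to the axis and the axial radius equals the local
#' radius of curvature, recovered from the second derivative.
#'
#' @param profile a [surface_profile()] (or any data frame with `x`, `y` in
#'   mm).
#' @param n_index keratometric index (default 1.3375).
#' @param grid radial evaluation grid, mm (default 25-um spacing across the
#'   central 10-mm zone).
#' @param lambda smoothing-spline penalty.  The fixed default 1e-7 filters
#'   oscillations below the scale of the mesh's surface-node spacing while
#'   keeping the analytic-circle recovery bias well below 0.01 D.
#' @param mirror mirror a half-profile about the apex axis before fitting
#'   (default: automatic, when no negative-x data are present).
#' @return tibble of class `curvature_profile` with columns `x` and `power`
#'   (dioptres).
#' @export
sagittal_power <- function(profile, n_index = 1.3375,
                           grid = seq(-5, 5, by = 0.025),
                           lambda = 1e-7, mirror = NULL) {
  fit <- fit_surface_spline(profile, lambda, mirror)
  xr <- range(fit$x)
  if (min(grid) < xr[1] - 1e-9 || max(grid) > xr[2] + 1e-9)
    stop("evaluation grid extends beyond the surface data")
  d1 <- stats::predict(fit, grid, deriv = 1)$y
  # r_ax = |x| * sqrt(1 + y'^2) / |y'|; power -> (n-1)*1000 * |y'| /
  # (|x| sqrt(1 + y'^2)), finite for flat surfaces
  power <- (n_index - 1) * 1000 * abs(d1) / (abs(grid) * sqrt(1 + d1^2))
  apex <- which(abs(grid) < 1e-9)
  if (length(apex)) {
    d2 <- stats::predict(fit, 0, deriv = 2)$y
    power[apex] <- (n_index - 1) * 1000 * abs(d2) / 1  # r_ax -> 1/|y''|
  }
  out <- tibble::tibble(x = grid, power = power)
  attr(out, "n_index") <- n_index
  class(out) <- c("curvature_profile", class(out))
  out
}

#' Interpolate the central zone of a curvature profile
#'
#' Replaces the values within `inner_radius` of the apex by a natural cubic
#' spline interpolation across the gap, supported by the flanking data.
#' Used in the plane-strain model, where the sagittal construction is
#' ill-conditioned near the apex.
#'
#' @param cp a `curvature_profile`.
#' @param inner_radius gap half-width, mm (default 1).
#' @param support flank width used for the fit, mm.
#' @return the profile with the central zone replaced; finite everywhere.
#' @export
central_interpolation <- function(cp, inner_radius = 1, support = 2.5) {
  inside <- abs(cp$x) < inner_radius
  flank <- !inside & abs(cp$x) <= inner_radius + support & is.finite(cp$power)
  if (sum(flank & cp$x < 0) < 4 || sum(flank & cp$x > 0) < 4)
    stop("gap wider than the available data support")
  fill <- stats::spline(cp$x[flank], cp$power[flank], method = "natural",
                        xout = cp$x[inside])$y
  cp$power[inside] <- fill
  cp
}

#' Least-squares best-fit sphere of a surface zone
#'
#' Fits a circle (the meridional section of a sphere) to the surface points
#' within the given zone by the algebraic least-squares (Kasa) method, which
#' recovers exact circles to machine precision, and converts the radius to
#' keratometric power.
#'
#' @param profile a [surface_profile()].
#' @param zone_diameter zone diameter, mm (default 10).
#' @param n_index keratometric index.
#' @return list with `radius` (mm), `power` (D), `center` (mm) and `rms`
#'   residual (mm).
#' @export
best_fit_sphere <- function(profile, zone_diameter = 10, n_index = 1.3375) {
  sel <- abs(profile$x) <= zone_diameter / 2
  x <- profile$x[sel]; y <- profile$y[sel]
  if (length(x) < 3) stop("too few points in the fitting zone")
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  if (qr(A)$rank < 3) stop("degenerate (collinear) points")
  sol <- qr.solve(A, rhs)
  cx <- sol[1]; cy <- sol[2]
  R <- sqrt(sol[3] + cx^2 + cy^2)
  r_i <- sqrt((x - cx)^2 + (y - cy)^2)
  list(radius = R, power = keratometric_power(R, n_index),
       center = c(cx, cy), rms = sqrt(mean((r_i - R)^2)))
}

#' Pointwise curvature change
#'
#' `post - pre` in dioptres on a common grid; flattening is negative.
#'
#' @param pre,post `curvature_profile`s on the same grid.
#' @return tibble of class `curvature_delta` with columns `x`, `delta`.
#' @export
curvature_change <- function(pre, post) {
  if (nrow(pre) != nrow(post) || max(abs(pre$x - post$x)) > 1e-12)
    stop("curvature profiles are on different grids")
  out <- tibble::tibble(x = pre$x, delta = post$power - pre$power)
  class(out) <- c("curvature_delta", class(out))
  out
}

#' Summaries of a curvature-change profile
#'
#' Central (apex) change, mean change over the central optical zone, and the
#' extremal (most negative, i.e. strongest flattening) change within the
#' ring zone.
#'
#' @param delta a [curvature_change()] result.
#' @param ring_zone length-2 numeric, mm: radial band containing the ring
#'   (e.g. the tunnel footprint widened by 1 mm).
#' @param central_zone_diameter central zone diameter, mm (default 4).
#' @param side `"both"` to search the ring zone on both sides of the apex,
#'   `"positive"` for the implanted side only (plane strain).
#' @return tibble with `central_delta`, `zone_mean_delta`,
#'   `peripheral_delta` (most negative value in the ring zone),
#'   `peripheral_x` and `steepening_max`.
#' @export
curvature_summary <- function(delta, ring_zone = c(1.6, 4.4),
                              central_zone_diameter = 4,
                              side = c("both", "positive")) {
  side <- match.arg(side)
  central <- delta$delta[which.min(abs(delta$x))]
  zone <- abs(delta$x) <= central_zone_diameter / 2
  in_ring <- if (side == "positive")
    delta$x >= ring_zone[1] & delta$x <= ring_zone[2]
  else abs(delta$x) >= ring_zone[1] & abs(delta$x) <= ring_zone[2]
  i_min <- which(in_ring)[which.min(delta$delta[in_ring])]
  tibble::tibble(
    central_delta = central,
    zone_mean_delta = mean(delta$delta[zone]),
    peripheral_delta = delta$delta[i_min],
    peripheral_x = delta$x[i_min],
    steepening_max = max(delta$delta[in_ring]))
}

#' Curvature maps of an implantation simulation
#'
#' Convenience wrapper: extracts pre- and post-operative anterior surfaces,
#' computes sagittal power (with central interpolation in plane strain), the
#' change profile and its summaries, and the best-fit-sphere change.
#'
#' @param sim an [simulate_implantation()] result.
#' @param n_index keratometric index.
#' @param bfs_zone best-fit-sphere zone diameter, mm.
#' @param central_zone_diameter central-zone diameter for the mean-change
#'   summary, mm.
#' @return list with `pre`, `post` (`curvature_profile`s), `delta`,
#'   `summary` (one-row tibble) and `bfs` (pre/post/delta powers).
#' @export
curvature_analysis <- function(sim, n_index = 1.3375, bfs_zone = 10,
                               central_zone_diameter = 4) {
  prof_pre <- surface_profile(sim$mesh, sim$preop)
  prof_post <- surface_profile(sim$mesh, sim$postop)
  mirror <- sim$mode == "axisymmetric"
  pre <- sagittal_power(prof_pre, n_index, mirror = mirror)
  post <- sagittal_power(prof_post, n_index, mirror = mirror)
  if (sim$mode == "plane_strain") {
    pre <- central_interpolation(pre)
    post <- central_interpolation(post)
  }
  delta <- curvature_change(pre, post)
  tz <- ring_zone_of(sim$tunnel)
  summ <- curvature_summary(
    delta, ring_zone = tz, central_zone_diameter = central_zone_diameter,
    side = if (sim$mode == "plane_strain") "positive" else "both")
  bfs_pre <- best_fit_sphere(prof_pre, bfs_zone, n_index)
  bfs_post <- best_fit_sphere(prof_post, bfs_zone, n_index)
  list(pre = pre, post = post, delta = delta, summary = summ,
       bfs = c(pre = bfs_pre$power, post = bfs_post$power,
               delta = bfs_post$power - bfs_pre$power))
}

# radial band containing the ring: tunnel footprint widened by 1 mm
ring_zone_of <- function(tunnel, widen = 1) {
  hw <- tunnel$width / UM_PER_MM / 2
  c(tunnel$center_radial_position - hw - widen,
    tunnel$center_radial_position + hw + widen)
}

#' Write a curvature profile or change map as CSV
#'
#' @param x a `curvature_profile` or `curvature_delta`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_curvature_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
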
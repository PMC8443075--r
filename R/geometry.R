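# Parametric meridional cross-section of the layered cornea.
#
# Coordinates: the apex axis is the y-axis; the anterior surface apex sits at
# the origin and the cornea bulges upward (+y anterior).  Both surfaces are
# circular arcs with centers on the apex axis: anterior center (0, -r_anterior),
# posterior center (0, -cct - r_posterior).  Through-thickness lines follow the
# anterior surface normal, so "depth" always means distance from the anterior
# surface along the local normal.

#' Construct a corneal cross-section geometry
#'
#' Builds the parametric meridional section of a three-layered cornea
#' (epithelium, anterior stroma, posterior stroma) bounded by two circular
#' arcs.  Defaults follow the Gullstrand-LeGrand schematic eye with a 550 um
#' central thickness; `cct = 450` gives the thin (keratoconus-representative)
#' variant.
#'
#' @param r_anterior anterior surface radius, mm.
#' @param r_posterior posterior surface radius, mm.
#' @param cct central corneal thickness, um.
#' @param t_epi epithelium thickness, um (anatomical default 50 um).
#' @param f_anterior_stroma anterior-stroma share of the stromal thickness,
#'   in (0, 1).
#' @param half_chord corneal half-width at the limbus, mm.
#' @return object of class `cornea_geometry`.
#' @examples
#' geo <- cornea_geometry()
#' thickness_at(geo, 0)   # 550 um
#' @export
cornea_geometry <- function(r_anterior = 7.8, r_posterior = 6.4,
                            cct = 550, t_epi = 50,
                            f_anterior_stroma = 0.4, half_chord = 5.8) {
  stopifnot(r_anterior > 0, r_posterior > 0, cct > 0, t_epi > 0,
            half_chord > 0)
  if (r_anterior <= r_posterior)
    stop("r_anterior must exceed r_posterior for a diverging corneal band")
  if (cct <= t_epi)
    stop("central thickness must exceed the epithelium thickness")
  if (f_anterior_stroma <= 0 || f_anterior_stroma >= 1)
    stop("f_anterior_stroma must lie strictly in (0, 1)")
  if (half_chord >= r_anterior)
    stop("half_chord must be smaller than the anterior radius")
  geo <- structure(
    list(r_anterior = r_anterior, r_posterior = r_posterior,
         cct = cct, t_epi = t_epi,
         f_anterior_stroma = f_anterior_stroma,
         half_chord = half_chord, apex_axis = "y"),
    class = "cornea_geometry")
  # arcs must not intersect (positive thickness) anywhere within the chord
  a <- seq(0, alpha_max(geo), length.out = 101)
  th <- vapply(a, function(ai) normal_depth_to_posterior(geo, ai), numeric(1))
  if (any(!is.finite(th)) || any(th <= 0))
    stop("anterior and posterior arcs intersect within the half-chord")
  geo
}

#' @export
print.cornea_geometry <- function(x, ...) {
  cat(sprintf(
    "<cornea_geometry> r_ant %.2f mm, r_post %.2f mm, cct %g um, epi %g um,\n",
    x$r_anterior, x$r_posterior, x$cct, x$t_epi))
  cat(sprintf("  anterior-stroma fraction %.2f, half-chord %.2f mm\n",
              x$f_anterior_stroma, x$half_chord))
  invisible(x)
}

# meridional angle (rad, from the apex axis at the anterior center) at which
# the anterior surface reaches the limbal chord
alpha_max <- function(geometry) asin(geometry$half_chord / geometry$r_anterior)

# anterior surface point at meridional angle alpha (vectorized), mm
anterior_point <- function(geometry, alpha) {
  Ra <- geometry$r_anterior
  cbind(x = Ra * sin(alpha), y = Ra * cos(alpha) - Ra)
}

# inward unit normal of the anterior surface at angle alpha
inward_normal <- function(alpha) cbind(x = -sin(alpha), y = -cos(alpha))

# distance (mm) from the anterior point at angle alpha to the posterior arc,
# measured along the inward anterior normal; closed-form circle-line
# intersection
normal_depth_to_posterior <- function(geometry, alpha) {
  Ra <- geometry$r_anterior
  Rp <- geometry$r_posterior
  cct_mm <- geometry$cct / UM_PER_MM
  A <- c(Ra * sin(alpha), Ra * cos(alpha) - Ra)
  d <- c(-sin(alpha), -cos(alpha))
  Cp <- c(0, -cct_mm - Rp)
  # |A + s d - Cp|^2 = Rp^2
  w <- A - Cp
  b <- sum(w * d)            # d is unit
  cc <- sum(w * w) - Rp^2
  disc <- b^2 - cc
  if (disc < 0) return(NA_real_)
  s <- -b - sqrt(disc)       # nearest intersection along the inward normal
  if (s <= 0) s <- -b + sqrt(disc)
  s
}

# point at meridional angle alpha and normal depth d (mm), vectorized over
# equal-length alpha / d
point_at_depth <- function(geometry, alpha, depth_mm) {
  Ra <- geometry$r_anterior
  cbind(x = (Ra - depth_mm) * sin(alpha),
        y = (Ra - depth_mm) * cos(alpha) - Ra)
}

#' Corneal thickness at a radial station
#'
#' Perpendicular (surface-normal) distance between the anterior and posterior
#' surfaces at radial distance `x` from the apex axis, measured from the
#' anterior surface point whose x-coordinate is `x`.
#'
#' @param geometry a [cornea_geometry()].
#' @param x radial distance from the apex axis, mm (vectorized);
#'   `abs(x) <= half_chord`.
#' @return thickness in um.
#' @export
thickness_at <- function(geometry, x) {
  if (any(abs(x) > geometry$half_chord + 1e-12))
    stop("radial station outside the corneal half-chord")
  alpha <- asin(abs(x) / geometry$r_anterior)
  vapply(alpha, function(a)
    normal_depth_to_posterior(geometry, a) * UM_PER_MM, numeric(1))
}

# layer interface depths (mm) at meridional angle alpha: returns c(0, epi,
# ant/post interface, total).  The epithelium has constant anatomical
# thickness; the stromal remainder is split by f_anterior_stroma.
layer_depths <- function(geometry, alpha) {
  tot <- normal_depth_to_posterior(geometry, alpha)
  epi <- geometry$t_epi / UM_PER_MM
  ant <- epi + geometry$f_anterior_stroma * (tot - epi)
  c(anterior = 0, epi = epi, stroma_split = ant, posterior = tot)
}

#' Specify the stromal tunnel footprint
#'
#' The tunnel is the rectangular area carved in the posterior stroma to
#' receive the ring segment: `width` along the surface-parallel direction,
#' `height` through thickness, with its anterior edge at `depth_fraction` of
#' the local corneal thickness (measured from the anterior surface along the
#' surface normal), centred `center_radial_position` mm from the apex axis.
#'
#' @param width tunnel footprint width, um.
#' @param height tunnel footprint height, um.
#' @param depth_fraction depth of the tunnel's anterior edge as a fraction of
#'   local thickness, in (0, 1).
#' @param center_radial_position distance of the tunnel center from the apex
#'   axis, mm.
#' @return object of class `tunnel_spec`.
#' @export
tunnel_spec <- function(width = 800, height = 30, depth_fraction = 0.70,
                        center_radial_position = 3.0) {
  stopifnot(width > 0, height > 0, center_radial_position > 0)
  if (depth_fraction <= 0 || depth_fraction >= 1)
    stop("depth_fraction must lie strictly in (0, 1)")
  structure(list(width = width, height = height,
                 depth_fraction = depth_fraction,
                 center_radial_position = center_radial_position),
            class = "tunnel_spec")
}

# meridional angle of the tunnel center: chosen so that the point at the
# tunnel's mid-depth lies center_radial_position mm from the apex axis
tunnel_center_alpha <- function(geometry, tunnel) {
  f <- function(a) {
    tot <- normal_depth_to_posterior(geometry, a)
    d <- tunnel$depth_fraction * tot + 0.5 * tunnel$height / UM_PER_MM
    (geometry$r_anterior - d) * sin(a) - tunnel$center_radial_position
  }
  stats::uniroot(f, c(1e-6, alpha_max(geometry)), tol = 1e-12)$root
}

# corner points (4 x 2, mm) of the tunnel rectangle in the curved band frame
tunnel_corners <- function(geometry, tunnel) {
  a_c <- tunnel_center_alpha(geometry, tunnel)
  tot <- normal_depth_to_posterior(geometry, a_c)
  d0 <- tunnel$depth_fraction * tot
  d1 <- d0 + tunnel$height / UM_PER_MM
  r_mid <- geometry$r_anterior - (d0 + d1) / 2
  da <- (tunnel$width / UM_PER_MM / 2) / r_mid
  al <- c(a_c - da, a_c + da)
  rbind(point_at_depth(geometry, al[1], d0),
        point_at_depth(geometry, al[2], d0),
        point_at_depth(geometry, al[2], d1),
        point_at_depth(geometry, al[1], d1))
}

#' Check that a tunnel fits inside the posterior stroma band
#'
#' @param geometry a [cornea_geometry()].
#' @param tunnel a [tunnel_spec()].
#' @return `TRUE` invisibly; errors if any tunnel corner leaves the posterior
#'   stroma.
#' @export
validate_tunnel <- function(geometry, tunnel) {
  a_c <- tunnel_center_alpha(geometry, tunnel)
  r_mid <- NULL
  tot <- normal_depth_to_posterior(geometry, a_c)
  d0 <- tunnel$depth_fraction * tot
  d1 <- d0 + tunnel$height / UM_PER_MM
  da <- (tunnel$width / UM_PER_MM / 2) /
    (geometry$r_anterior - (d0 + d1) / 2)
  for (a in c(a_c - da, a_c + da)) {
    ld <- layer_depths(geometry, a)
    dep0 <- tunnel$depth_fraction * ld[["posterior"]]
    dep1 <- dep0 + tunnel$height / UM_PER_MM
    if (dep0 <= ld[["stroma_split"]] || dep1 >= ld[["posterior"]])
      stop("tunnel does not lie strictly inside the posterior stroma band")
  }
  invisible(TRUE)
}

#' Sample the corneal outline as a polyline
#'
#' Returns the closed boundary of the meridional section (anterior arc, limbal
#' edge, posterior arc, apex-axis edge for the half-section) as a tibble,
#' suitable for CSV export or plotting.
#'
#' @param geometry a [cornea_geometry()].
#' @param n points per arc.
#' @param full if `TRUE`, return the full (mirrored) section.
#' @return tibble with columns `x`, `y` (mm) and `surface`.
#' @export
geometry_polyline <- function(geometry, n = 200, full = FALSE) {
  am <- alpha_max(geometry)
  a <- seq(if (full) -am else 0, am, length.out = n)
  ant <- anterior_point(geometry, a)
  post_d <- vapply(a, function(ai) normal_depth_to_posterior(geometry, ai),
                   numeric(1))
  post <- point_at_depth(geometry, a, post_d)
  tibble::tibble(
    x = c(ant[, 1], rev(post[, 1])),
    y = c(ant[, 2], rev(post[, 2])),
    surface = rep(c("anterior", "posterior"), each = n))
}
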
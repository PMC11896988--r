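# Phantom geometry: a PMMA "aquarium" filled with lung-equivalent foam,
# holding a PMMA tumour surrogate (proximal hemisphere + cylinder) whose
# spherical end sits at the isocenter. The whole phantom rides on a motion
# table and can be displaced along x.
#
# Frame: right-handed, z = beam direction, x = motion direction, origin at
# the isocenter; all lengths in mm.

#' Define a material
#'
#' @param name label.
#' @param density mass density in g/cm^3.
#' @param wer water-equivalent ratio (dimensionless); converts geometric path
#'   length to water-equivalent path length (WEPL).
#' @param x0 radiation length in mm, used by the Highland
#'   multiple-Coulomb-scattering estimate.
#' @return an object of class `ivi_material`.
#' @export
ivi_material <- function(name, density, wer, x0) {
  .check(density >= 0, "density must be >= 0")
  .check(wer >= 0, "wer must be >= 0")
  .check(x0 > 0, "x0 must be > 0")
  structure(list(name = name, density = density, wer = wer, x0 = x0),
            class = "ivi_material")
}

#' Default material set
#'
#' PMMA at the paper-grade density of 1.17 g/cm^3 (WER 1.16, X0 347 mm),
#' lung-equivalent foam of 0.23 g/cm^3 (WER and X0 scaled from PMMA by the
#' density ratio, i.e. PMMA-like composition), and air.
#'
#' @return named list of `ivi_material` objects with entries
#'   `pmma`, `foam`, `air`.
#' @export
default_materials <- function() {
  list(
    pmma = ivi_material("pmma", density = 1.17, wer = 1.16, x0 = 347),
    foam = ivi_material("foam", density = 0.23, wer = 0.23,
                        x0 = 347 * 1.17 / 0.23),
    air  = ivi_material("air", density = 0.0012, wer = 0.0012, x0 = 3.04e5)
  )
}

#' Construct the moving lung-tumour phantom
#'
#' The phantom is a PMMA cube (the "aquarium") filled with foam; a PMMA
#' insert — a hemisphere facing upstream joined to a cylinder extending
#' downstream along the beam axis — represents the tumour. At motion offset
#' zero the hemisphere center coincides with the isocenter.
#'
#' @param aquarium_outer outer cube edge in mm (default 260).
#' @param wall_x,wall_yz wall thickness in mm on the x faces and on the
#'   y/z faces. Defaults (10, 5) make the cavity match the 240 x 250 x 250 mm
#'   foam block.
#' @param cylinder_diameter insert diameter in mm (default 50; hemisphere
#'   radius is half of this).
#' @param cylinder_length length of the cylindrical body, from the hemisphere
#'   equator downstream, in mm (default 95, keeping the insert inside the
#'   foam).
#' @param materials named list with `pmma`, `foam`, `air` entries, see
#'   [default_materials()].
#' @return an object of class `ivi_phantom`.
#' @export
phantom_geometry <- function(aquarium_outer = 260,
                             wall_x = 10, wall_yz = 5,
                             cylinder_diameter = 50,
                             cylinder_length = 95,
                             materials = default_materials()) {
  h <- aquarium_outer / 2
  r <- cylinder_diameter / 2
  .check(h - wall_x > 0 && h - wall_yz > 0, "walls thicker than the aquarium")
  .check(r > 0 && cylinder_length >= 0, "insert dimensions must be positive")
  .check(cylinder_length <= h - wall_yz, "cylinder must stay inside the foam")
  ph <- list(
    half_outer = c(h, h, h),
    half_cavity = c(h - wall_x, h - wall_yz, h - wall_yz),
    r_insert = r,
    cyl_z = c(0, cylinder_length),
    materials = materials
  )
  class(ph) <- "ivi_phantom"
  ph
}

#' @export
print.ivi_phantom <- function(x, ...) {
  cat("ivi_phantom: aquarium", paste(2 * x$half_outer, collapse = " x "),
      "mm; foam cavity", paste(2 * x$half_cavity, collapse = " x "),
      "mm\n  PMMA insert: hemisphere r =", x$r_insert,
      "mm (upstream) + cylinder to z =", x$cyl_z[2], "mm\n")
  invisible(x)
}

#' Material lookup at a point
#'
#' Returns the material name at one or more points, for the phantom displaced
#' by `offset` mm along x. Points outside the aquarium are air.
#'
#' @param phantom an `ivi_phantom`.
#' @param points length-3 numeric vector or n x 3 matrix, mm.
#' @param offset motion offset in mm along +x.
#' @return character vector of material names (`"pmma"`, `"foam"`, `"air"`).
#' @export
material_at <- function(phantom, points, offset = 0) {
  p <- .as_points(points)
  .check(all(is.finite(p)), "points must be finite")
  x <- p[, 1] - offset; y <- p[, 2]; z <- p[, 3]
  ho <- phantom$half_outer; hc <- phantom$half_cavity
  in_outer <- abs(x) <= ho[1] & abs(y) <= ho[2] & abs(z) <= ho[3]
  in_cavity <- abs(x) < hc[1] & abs(y) < hc[2] & abs(z) < hc[3]
  r2 <- phantom$r_insert^2
  in_insert <- (x^2 + y^2 + z^2 <= r2 & z < 0) |
    (x^2 + y^2 <= r2 & z >= phantom$cyl_z[1] & z <= phantom$cyl_z[2])
  out <- rep("air", nrow(p))
  out[in_outer] <- "pmma"
  out[in_cavity] <- "foam"
  out[in_cavity & in_insert] <- "pmma"
  out
}

# ---- ray/interval primitives (vectorized over n rays) ----------------------
# Rays are p(t) = o + t * d with t >= 0 measured in mm when d is unit length.
# Each helper returns a 2-column matrix of [t_in, t_out] (empty -> t_in > t_out).

.iv_empty <- function(n) cbind(rep(1, n), rep(0, n))

# axis-aligned box |x - c| <= h (componentwise), vectorized slab method
.iv_box <- function(o, d, half, offset = 0) {
  n <- nrow(o)
  lo <- rep(0, n); hi <- rep(Inf, n)
  cen <- c(offset, 0, 0)
  for (k in 1:3) {
    ok <- o[, k] - cen[k]; dk <- d[, k]
    par <- abs(dk) < 1e-300
    t1 <- (-half[k] - ok) / dk
    t2 <- (half[k] - ok) / dk
    tmin <- pmin(t1, t2); tmax <- pmax(t1, t2)
    tmin[par] <- ifelse(abs(ok[par]) <= half[k], 0, Inf)
    tmax[par] <- ifelse(abs(ok[par]) <= half[k], Inf, -Inf)
    lo <- pmax(lo, tmin); hi <- pmin(hi, tmax)
  }
  cbind(lo, hi)
}

# sphere |p - c| <= r
.iv_sphere <- function(o, d, center, r) {
  oc <- sweep(o, 2, center)
  b <- rowSums(oc * d)
  cc <- rowSums(oc^2) - r^2
  disc <- b^2 - cc
  ok <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  lo <- ifelse(ok, -b - sq, 1)
  hi <- ifelse(ok, -b + sq, 0)
  cbind(pmax(lo, 0), hi)
}

# infinite cylinder x^2 + y^2 <= r^2 about the z axis through (cx, 0)
.iv_cyl <- function(o, d, cx, r) {
  ox <- o[, 1] - cx; oy <- o[, 2]
  dx <- d[, 1]; dy <- d[, 2]
  a <- dx^2 + dy^2
  b <- ox * dx + oy * dy
  cc <- ox^2 + oy^2 - r^2
  par <- a < 1e-300
  disc <- b^2 - a * cc
  ok <- disc >= 0 & !par
  sq <- sqrt(pmax(disc, 0))
  lo <- ifelse(ok, (-b - sq) / a, ifelse(par & cc <= 0, 0, 1))
  hi <- ifelse(ok, (-b + sq) / a, ifelse(par & cc <= 0, Inf, 0))
  cbind(pmax(lo, 0), hi)
}

# half space z (op) z0 along the ray -> t interval
.iv_z <- function(o, d, z0, below = TRUE) {
  oz <- o[, 3]; dz <- d[, 3]
  par <- abs(dz) < 1e-300
  tc <- (z0 - oz) / dz
  if (below) {
    lo <- ifelse(dz > 0, 0, tc)
    hi <- ifelse(dz > 0, tc, Inf)
  } else {
    lo <- ifelse(dz > 0, tc, 0)
    hi <- ifelse(dz > 0, Inf, tc)
  }
  inside0 <- if (below) oz <= z0 else oz >= z0
  lo[par] <- ifelse(inside0[par], 0, 1)
  hi[par] <- ifelse(inside0[par], Inf, 0)
  cbind(pmax(lo, 0), hi)
}

.iv_intersect <- function(a, b) cbind(pmax(a[, 1], b[, 1]), pmin(a[, 2], b[, 2]))
.iv_len <- function(a, tmax = Inf, tmin = 0) {
  pmax(pmin(a[, 2], tmax) - pmax(a[, 1], tmin), 0)
}

# Intervals of the PMMA insert (hemisphere z<0 plus cylinder [z1,z2]) along
# n rays; the two pieces are disjoint by construction, returned separately.
.iv_insert <- function(phantom, o, d, offset) {
  cen <- c(offset, 0, 0)
  hemi <- .iv_intersect(.iv_sphere(o, d, cen, phantom$r_insert),
                        .iv_z(o, d, 0, below = TRUE))
  cyl <- .iv_intersect(.iv_cyl(o, d, offset, phantom$r_insert),
                       .iv_intersect(.iv_z(o, d, phantom$cyl_z[1], below = FALSE),
                                     .iv_z(o, d, phantom$cyl_z[2], below = TRUE)))
  list(hemi = hemi, cyl = cyl)
}

# ---- path queries ----------------------------------------------------------

#' Ordered material segments along a ray
#'
#' Splits the chord of a ray inside the aquarium bounding box into ordered
#' material segments. Segment lengths sum to the in-box chord length; zero
#' length segments are dropped.
#'
#' @param phantom an `ivi_phantom`.
#' @param origin,direction length-3 numeric vectors, mm / arbitrary scale
#'   (the direction is normalised internally).
#' @param offset motion offset in mm.
#' @return a `data.table` with columns `material`, `t_in`, `t_out`,
#'   `length` (mm along the ray, starting at the origin).
#' @export
path_segments <- function(phantom, origin, direction, offset = 0) {
  .check(sum(direction^2) > 0, "direction must be non-zero")
  o <- matrix(as.numeric(origin), 1)
  d <- matrix(as.numeric(direction) / sqrt(sum(direction^2)), 1)
  box <- .iv_box(o, d, phantom$half_outer, offset)
  if (box[1] >= box[2]) {
    return(data.table::data.table(material = character(), t_in = numeric(),
                                  t_out = numeric(), length = numeric()))
  }
  cav <- .iv_box(o, d, phantom$half_cavity, offset)
  ins <- .iv_insert(phantom, o, d, offset)
  cuts <- sort(unique(pmin(pmax(
    c(box[1], box[2], cav[1, ], ins$hemi[1, ], ins$cyl[1, ]), box[1]), box[2])))
  cuts <- cuts[is.finite(cuts)]
  t_in <- cuts[-length(cuts)]
  t_out <- cuts[-1]
  keep <- (t_out - t_in) > 1e-9
  t_in <- t_in[keep]; t_out <- t_out[keep]
  mid <- (t_in + t_out) / 2
  pts <- sweep(outer(mid, d[1, ]), 2, o[1, ], `+`)
  mat <- material_at(phantom, pts, offset)
  dt <- data.table::data.table(material = mat, t_in = t_in, t_out = t_out,
                               length = t_out - t_in)
  # merge consecutive segments of identical material
  grp <- cumsum(c(TRUE, dt$material[-1] != dt$material[-nrow(dt)]))
  dt[, list(material = material[1], t_in = min(t_in), t_out = max(t_out),
            length = sum(length)), by = list(grp = grp)][, -"grp"]
}

#' Water-equivalent path length along a ray up to a stopping plane
#'
#' Sums segment length times water-equivalent ratio over the material
#' segments of the ray, truncated where the ray crosses `stop_z`.
#'
#' @inheritParams path_segments
#' @param stop_z z plane (mm) at which integration stops; `Inf` integrates
#'   the full in-box chord.
#' @return water-equivalent length in mm.
#' @export
wepl_to_depth <- function(phantom, origin, direction, stop_z = Inf, offset = 0) {
  segs <- path_segments(phantom, origin, direction, offset)
  if (nrow(segs) == 0L) return(0)
  dz <- direction[3] / sqrt(sum(direction^2))
  t_stop <- if (is.finite(stop_z) && abs(dz) > 1e-300) {
    (stop_z - origin[3]) / dz
  } else Inf
  wer <- vapply(phantom$materials, `[[`, numeric(1), "wer")
  lens <- pmax(pmin(segs$t_out, t_stop) - segs$t_in, 0)
  sum(lens * wer[segs$material])
}
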
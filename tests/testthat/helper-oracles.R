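# Independent oracles and small fixtures shared across the suite.
# Oracles deliberately avoid the code paths they check.

# brute-force ray marching: integrate material occupancy along a ray with a
# fixed small step; returns named lengths (mm) per material inside the
# aquarium box
oracle_ray_march <- function(phantom, origin, direction, offset = 0,
                             step = 0.01) {
  d <- direction / sqrt(sum(direction^2))
  # find the in-box parameter window by coarse scan + refinement
  t_grid <- seq(0, 1000, by = step)
  pts <- cbind(origin[1] + t_grid * d[1], origin[2] + t_grid * d[2],
               origin[3] + t_grid * d[3])
  ho <- phantom$half_outer
  inside <- abs(pts[, 1] - offset) <= ho[1] & abs(pts[, 2]) <= ho[2] &
    abs(pts[, 3]) <= ho[3]
  if (!any(inside)) return(c(pmma = 0, foam = 0, air = 0))
  mats <- material_at(phantom, pts[inside, , drop = FALSE], offset)
  out <- c(pmma = 0, foam = 0, air = 0)
  tab <- table(mats) * step
  out[names(tab)] <- tab
  out
}

# brute-force closest approach by numerical minimisation over (t1, t2)
oracle_closest_approach <- function(p1, d1, p2, d2) {
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  f <- function(t) sum((p1 + t[1] * d1 - p2 - t[2] * d2)^2)
  fit <- stats::optim(c(0, 0), f, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 1000))
  q1 <- p1 + fit$par[1] * d1
  q2 <- p2 + fit$par[2] * d2
  list(midpoint = (q1 + q2) / 2, dca = sqrt(fit$value))
}

# exhaustive cumulative scan for the z quantile convention
oracle_quantile_scan <- function(z, q) {
  zs <- sort(z)
  n <- length(zs)
  for (i in seq_len(n)) {
    if (i / n >= q - 1e-12) return(zs[i])
  }
  zs[n]
}

# numeric time-occupancy integration of the Lujan trace over one period
oracle_phase_fractions <- function(params, edges, n_grid = 1e6) {
  t <- seq(0, params$period, length.out = n_grid + 1)[-(n_grid + 1)]
  x <- params$amplitude *
    sin(pi * (t / params$period))^(2 * params$n)
  idx <- findInterval(pmin(pmax(x, edges[1]), max(edges)), edges,
                      rightmost.closed = TRUE)
  idx <- pmin(idx, length(edges) - 1L)
  tabulate(idx, nbins = length(edges) - 1L) / n_grid
}

# small fixtures -------------------------------------------------------------

tiny_world <- function() {
  list(phantom = phantom_geometry(), model = range_model(),
       scanner = scanner_geometry(), tracker = tracker_geometry(),
       fp = frag_params(), motion = lujan_params())
}

# a one-row plan-like spot
make_spot <- function(spot_index = 1L, energy = 160, x_v = 0, y_v = 0,
                      z_v = 0, n_planned = 1000) {
  data.table::data.table(spot_index = spot_index, layer = 1L,
                         energy = energy, x_v = x_v, y_v = y_v, z_v = z_v,
                         n_planned = n_planned)
}

# a spot-log record with MWPC centroids consistent with the planned line
make_record <- function(scanner, x_v = 0, y_v = 0, z_v = 0, sigma = 2.5,
                        energy = 160) {
  ax <- x_v / (z_v - scanner$z_xm)
  ay <- y_v / (z_v - scanner$z_ym)
  at_z <- function(z) c(x_v + ax * (z - z_v), y_v + ay * (z - z_v))
  e1 <- at_z(scanner$z_mwpc1); e2 <- at_z(scanner$z_mwpc2)
  data.table::data.table(
    spot_index = 1L, scanner_x = ax, scanner_y = ay,
    x_i1 = e1[1], y_i1 = e1[2], x_i2 = e2[1], y_i2 = e2[2],
    sigma_x_i = sigma, sigma_y_i = sigma, z_i = scanner$z_mwpc1,
    n_delivered = 1000, energy = energy, t_start = 0, t_end = 1e-3)
}

# computed-vertex table builder for monitor tests
make_cv <- function(spot_index, vz, n = 100) {
  data.table::data.table(spot_index = spot_index, n = n,
                         vx = 0, vy = 0, vz = vz, valid = n >= 50)
}
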
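# Simplified scanned-delivery planning: a power-law range-energy model,
# a uniform-fluence spherical target plan (layers x serpentine lateral grid),
# the delivery timeline, and the nozzle (spot) and FPGA timing logfiles.

#' Power-law range-energy model
#'
#' Fits \eqn{R = \alpha E^p} (R in mm water, E in MeV/u) through two anchor
#' points. The defaults anchor carbon-ion ranges in water at 200 and
#' 400 MeV/u.
#'
#' @param anchors 2 x 2 matrix-like: rows `(E, R)` used for the two-point fit.
#' @param domain calibrated energy domain in MeV/u.
#' @return object of class `range_model` with fields `alpha`, `p`, `domain`.
#' @export
range_model <- function(anchors = rbind(c(200, 86), c(400, 275)),
                        domain = c(80, 430)) {
  anchors <- as.matrix(anchors)
  .check(nrow(anchors) == 2 && ncol(anchors) == 2, "need two (E, R) anchors")
  p <- log(anchors[2, 2] / anchors[1, 2]) / log(anchors[2, 1] / anchors[1, 1])
  alpha <- anchors[1, 2] / anchors[1, 1]^p
  structure(list(alpha = alpha, p = p, domain = domain), class = "range_model")
}

#' @rdname range_model
#' @param model a `range_model`.
#' @param energy beam energy in MeV/u.
#' @return `energy_to_range()`: range in mm water.
#' @export
energy_to_range <- function(model, energy) {
  .check(all(energy >= model$domain[1] & energy <= model$domain[2]),
         "energy outside calibrated domain [%g, %g] MeV/u",
         model$domain[1], model$domain[2])
  model$alpha * energy^model$p
}

#' @rdname range_model
#' @param range_mm range in mm water.
#' @return `range_to_energy()`: energy in MeV/u.
#' @export
range_to_energy <- function(model, range_mm) {
  e <- (range_mm / model$alpha)^(1 / model$p)
  .check(all(e >= model$domain[1] & e <= model$domain[2]),
         "range maps outside calibrated domain [%g, %g] MeV/u",
         model$domain[1], model$domain[2])
  e
}

#' Scanner and nozzle geometry
#'
#' @param z_xm,z_ym z positions (mm, isocenter frame; upstream is negative)
#'   of the x and y scanning magnets. Defaults -7534 and -8234 mm.
#' @param z_mwpc1,z_mwpc2 z positions of the two nozzle MWPCs.
#' @return object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(z_xm = -7534, z_ym = -8234,
                             z_mwpc1 = -300, z_mwpc2 = -200) {
  .check(z_xm != z_ym, "scanner magnets cannot coincide")
  .check(z_mwpc1 > max(z_xm, z_ym) && z_mwpc1 < 0 &&
           z_mwpc2 > max(z_xm, z_ym) && z_mwpc2 < 0,
         "MWPCs must sit between the scanners and the phantom")
  structure(list(z_xm = z_xm, z_ym = z_ym,
                 z_mwpc1 = z_mwpc1, z_mwpc2 = z_mwpc2),
            class = "scanner_geometry")
}

#' Generate a uniform-fluence plan for the spherical target
#'
#' Builds iso-energy layers covering the margin-shrunk PMMA sphere: planned
#' voxel depths `z_v` are spaced by `layer_spacing_wepl` (converted to
#' geometric spacing through the PMMA water-equivalent ratio), each layer
#' carrying a square lateral grid of spots inside the sphere cross-section,
#' delivered in serpentine order. The layer energy stops the beam at the
#' layer depth on the central axis of the static phantom (offset 0). Spot
#' weights are uniform (`n_planned` ions per spot) — a surrogate for full
#' inverse dose optimisation.
#'
#' @param phantom an [phantom_geometry()] object.
#' @param model a [range_model()].
#' @param sphere_radius target sphere radius in mm (default: the insert
#'   radius).
#' @param inner_margin margin in mm by which the planning target is shrunk
#'   inside the PMMA surface (default 3).
#' @param spot_spacing lateral raster spacing in mm (default 2).
#' @param layer_spacing_wepl layer spacing in mm WEPL (default 3).
#' @param n_planned ions per spot (default 24000, the desk-scale equivalent
#'   of a 2 Gy prescription spread over thousands of spots).
#' @return a `data.table` (class `ivi_plan`) with columns `spot_index`,
#'   `layer`, `energy`, `x_v`, `y_v`, `z_v`, `n_planned`.
#' @export
generate_spherical_plan <- function(phantom, model,
                                    sphere_radius = phantom$r_insert,
                                    inner_margin = 3,
                                    spot_spacing = 2,
                                    layer_spacing_wepl = 3,
                                    n_planned = 24000) {
  .check(sphere_radius > inner_margin && inner_margin >= 0,
         "need sphere_radius > inner_margin >= 0")
  r_t <- sphere_radius - inner_margin
  .check(spot_spacing <= 2 * sphere_radius,
         "spot spacing larger than the target sphere")
  wer_pmma <- phantom$materials$pmma$wer
  dz <- layer_spacing_wepl / wer_pmma
  z_layers <- if (2 * r_t <= dz) 0 else seq(-r_t, r_t, by = dz)
  layers <- lapply(seq_along(z_layers), function(i) {
    zv <- z_layers[i]
    r_l <- sqrt(max(r_t^2 - zv^2, 0))
    g <- seq(-r_t, r_t, by = spot_spacing)
    g <- g[abs(g) <= r_l + 1e-9]
    if (length(g) == 0) g <- 0
    grid <- expand.grid(x_v = g, y_v = g)
    grid <- grid[grid$x_v^2 + grid$y_v^2 <= r_l^2 + 1e-9, , drop = FALSE]
    if (nrow(grid) == 0) grid <- data.frame(x_v = 0, y_v = 0)
    # serpentine: sort rows by y, alternate x direction per row
    grid <- grid[order(grid$y_v, grid$x_v), , drop = FALSE]
    rows <- rle(grid$y_v)$lengths
    flip <- rep(seq_along(rows) %% 2 == 0, rows)
    ord <- order(grid$y_v, ifelse(flip, -grid$x_v, grid$x_v))
    grid <- grid[ord, , drop = FALSE]
    wepl <- wepl_to_depth(phantom, c(0, 0, -phantom$half_outer[3] - 1),
                          c(0, 0, 1), stop_z = zv, offset = 0)
    data.table::data.table(layer = i, energy = range_to_energy(model, wepl),
                           x_v = grid$x_v, y_v = grid$y_v, z_v = zv,
                           n_planned = n_planned)
  })
  plan <- data.table::rbindlist(layers)
  plan[, spot_index := seq_len(.N)]
  data.table::setcolorder(plan, "spot_index")
  class(plan) <- c("ivi_plan", class(plan))
  plan[]
}

#' Delivery timeline for a plan
#'
#' Spots are delivered in plan order; each spot lasts
#' `n_planned / intensity` seconds, separated by `inter_spot_gap`, with an
#' extra `inter_layer_gap` pause at energy changes.
#'
#' @param plan an `ivi_plan`.
#' @param intensity beam intensity in ions/s (default 2e7, scaled with the
#'   desk-scale spot weights to preserve ~ms spot durations).
#' @param inter_spot_gap scanning gap between spots in s (default 2e-3).
#' @param inter_layer_gap energy-change gap in s (default 1).
#' @param t0 delivery start time in s (default 0).
#' @return `data.table` with `spot_index`, `t_start`, `t_end`, time-ordered.
#' @export
delivery_timeline <- function(plan, intensity = 2e7, inter_spot_gap = 2e-3,
                              inter_layer_gap = 1, t0 = 0) {
  .check(intensity > 0, "intensity must be > 0")
  p <- data.table::as.data.table(plan)[order(spot_index)]
  dur <- p$n_planned / intensity
  gap <- rep(inter_spot_gap, nrow(p))
  gap[1] <- 0
  if (nrow(p) > 1) {
    newlayer <- c(FALSE, diff(p$layer) != 0)
    gap[newlayer] <- gap[newlayer] + inter_layer_gap
  }
  t_end_cum <- t0 + cumsum(gap + dur)
  data.table::data.table(spot_index = p$spot_index,
                         t_start = t_end_cum - dur,
                         t_end = t_end_cum)
}

#' Simulate the nozzle spot logfile
#'
#' One record per delivered spot: scanner magnet settings, the MWPC beam
#' centroids/widths at the two nozzle planes (planned position extrapolated
#' to the MWPC plane plus Gaussian positioning noise), delivered particle
#' count, energy and timestamps.
#'
#' @param plan an `ivi_plan`.
#' @param timeline output of [delivery_timeline()].
#' @param scanner a [scanner_geometry()].
#' @param beam_sigma beam width sigma at the nozzle in mm (default 2.5).
#' @param position_noise MWPC centroid noise sigma in mm (default 0.1).
#' @param seed optional RNG seed.
#' @return `data.table` (class `spot_log`) ordered by `t_start`.
#' @export
simulate_spot_log <- function(plan, timeline, scanner,
                              beam_sigma = 2.5, position_noise = 0.1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- data.table::as.data.table(plan)
  tl <- data.table::as.data.table(timeline)
  .check(nrow(p) == nrow(tl), "plan and timeline sizes differ")
  m <- tl[p, on = "spot_index"]
  ax <- m$x_v / (m$z_v - scanner$z_xm)
  ay <- m$y_v / (m$z_v - scanner$z_ym)
  extrap <- function(z) {
    list(x = m$x_v + ax * (z - m$z_v), y = m$y_v + ay * (z - m$z_v))
  }
  e1 <- extrap(scanner$z_mwpc1)
  e2 <- extrap(scanner$z_mwpc2)
  n <- nrow(m)
  noise <- function() stats::rnorm(n, 0, position_noise)
  log <- data.table::data.table(
    spot_index = m$spot_index,
    scanner_x = ax, scanner_y = ay,
    x_i1 = e1$x + noise(), y_i1 = e1$y + noise(),
    x_i2 = e2$x + noise(), y_i2 = e2$y + noise(),
    sigma_x_i = rep(beam_sigma, n), sigma_y_i = rep(beam_sigma, n),
    z_i = rep(scanner$z_mwpc1, n),
    n_delivered = m$n_planned,
    energy = m$energy,
    t_start = m$t_start, t_end = m$t_end
  )[order(t_start)]
  class(log) <- c("spot_log", class(log))
  log
}

.spot_log_cols <- c("spot_index", "scanner_x", "scanner_y", "x_i1", "y_i1",
                    "x_i2", "y_i2", "sigma_x_i", "sigma_y_i", "z_i",
                    "n_delivered", "energy", "t_start", "t_end")

#' Spot logfile I/O
#'
#' CSV round trip for the nozzle spot log; values are written at full
#' precision.
#'
#' @param log a `spot_log` table.
#' @param file path.
#' @export
write_spot_log <- function(log, file) {
  data.table::fwrite(data.table::as.data.table(log)[, .spot_log_cols,
                                                    with = FALSE], file)
  invisible(file)
}

#' @rdname write_spot_log
#' @export
read_spot_log <- function(file) {
  log <- data.table::fread(file, showProgress = FALSE)
  missing <- setdiff(.spot_log_cols, names(log))
  .check(length(missing) == 0L, "spot log is missing column '%s'",
         if (length(missing)) missing[1] else "")
  class(log) <- c("spot_log", class(log))
  log
}

#' Build the FPGA timing log
#'
#' Timestamps (100 kHz clock ticks by default) for the two tracker frame
#' clocks, the next-spot signal (one event per delivered spot, at each spot
#' start) and the motion trigger.
#'
#' @param timeline output of [delivery_timeline()].
#' @param frame_dt tracker frame integration time in s (default 186.5e-6).
#' @param trigger_time motion trigger time in s (default 0).
#' @param clock_hz FPGA clock in Hz (default 1e5).
#' @return `data.table` with columns `tick`, `signal`, tick-ordered.
#' @export
fpga_log <- function(timeline, frame_dt = 186.5e-6, trigger_time = 0,
                     clock_hz = 1e5) {
  t_max <- max(timeline$t_end) + 10 * frame_dt
  frames <- seq(0, t_max, by = frame_dt)
  ev <- data.table::rbindlist(list(
    data.table::data.table(t = frames, signal = "frame_clock_sys1"),
    data.table::data.table(t = frames + frame_dt / 2,
                           signal = "frame_clock_sys2"),
    data.table::data.table(t = timeline$t_start, signal = "next_spot"),
    data.table::data.table(t = trigger_time, signal = "motion_trigger")
  ))
  ev[, tick := as.integer(floor(t * clock_hz))]
  out <- ev[order(tick, signal), list(tick, signal)]
  class(out) <- c("fpga_log", class(out))
  out
}

#' FPGA logfile I/O
#'
#' @param log an `fpga_log` table.
#' @param file path of the CSV (`tick,signal`).
#' @export
write_fpga_log <- function(log, file) {
  data.table::fwrite(data.table::as.data.table(log)[, list(tick, signal)], file)
  invisible(file)
}

#' @rdname write_fpga_log
#' @export
read_fpga_log <- function(file) {
  log <- data.table::fread(file, showProgress = FALSE)
  missing <- setdiff(c("tick", "signal"), names(log))
  .check(length(missing) == 0L, "FPGA log is missing column '%s'",
         if (length(missing)) missing[1] else "")
  class(log) <- c("fpga_log", class(log))
  log
}
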
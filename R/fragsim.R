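# Seeded forward simulation of nuclear fragmentation and tracker response.
#
# Each carbon ion of a spot is transported along z through the (possibly
# displaced) phantom; a fragmentation vertex is drawn by exponential thinning
# with a density-scaled mean free path; one light fragment (proton surrogate)
# is emitted forward-peaked, receives Highland multiple-scattering kicks at
# the layer boundaries it crosses, and is detected if its residual range
# carries it out of the phantom and its straight path crosses all three
# sensors of one tracker arm.

#' Tracker telescope geometry
#'
#' Four three-sensor CMOS arms in the x-z (bending) plane behind the target.
#'
#' @param angles_deg arm angles from the beam axis in degrees
#'   (default +-10.5, +-21).
#' @param radial_mm distance from the isocenter to the central sensor of each
#'   arm (default 248).
#' @param sensor_spacing spacing between the three sensor planes along the
#'   arm axis in mm (default 20).
#' @param half_u,half_v half extent of the active area in the in-plane
#'   coordinates, mm (defaults 9.6 and 9.936: 928 x 960 pixels of 20.7 um).
#' @param frame_dt frame integration time in s (default 186.5e-6).
#' @param cluster_sigma per-axis Gaussian cluster position resolution in mm
#'   (default 0.01).
#' @return object of class `tracker_geometry`. `$axes` holds per-arm unit
#'   axis `n`, in-plane directions `e_u`, `e_v`, and the three plane
#'   distances `d`.
#' @export
tracker_geometry <- function(angles_deg = c(-21, -10.5, 10.5, 21),
                             radial_mm = 248, sensor_spacing = 20,
                             half_u = 9.6, half_v = 9.936,
                             frame_dt = 186.5e-6, cluster_sigma = 0.01) {
  .check(sensor_spacing > 0, "sensor spacing must be > 0")
  a <- angles_deg * pi / 180
  axes <- lapply(seq_along(a), function(i) {
    n <- c(sin(a[i]), 0, cos(a[i]))
    list(arm = i, angle = a[i], n = n,
         e_u = c(cos(a[i]), 0, -sin(a[i])), e_v = c(0, 1, 0),
         d = radial_mm + sensor_spacing * (-1:1))
  })
  structure(list(angles_deg = angles_deg, radial_mm = radial_mm,
                 sensor_spacing = sensor_spacing, half_u = half_u,
                 half_v = half_v, frame_dt = frame_dt,
                 cluster_sigma = cluster_sigma, axes = axes),
            class = "tracker_geometry")
}

#' Fragmentation-model parameters
#'
#' @param lambda_w nuclear mean free path in water, mm (default 260); the
#'   local interaction rate scales with mass density.
#' @param range_mult fragment water range as a multiple of the residual
#'   primary range at the vertex (default 2.5).
#' @param sigma_theta Gaussian per-axis polar-angle sigma of fragment
#'   emission, rad (default 0.08).
#' @param n_frag light charged fragments emitted per interaction vertex
#'   (default 3, the typical light-charged-fragment multiplicity of carbon
#'   inelastic interactions at therapy energies; calibrated so the detected
#'   fragment fraction lands in the experimentally observed 0.2-1% band).
#' @param beam_sigma lateral Gaussian beam spread at the phantom, mm
#'   (default 2.5).
#' @param noise_rate uniform noise clusters per sensor per frame (default 0).
#' @return object of class `frag_params`.
#' @export
frag_params <- function(lambda_w = 260, range_mult = 2.5, sigma_theta = 0.08,
                        n_frag = 3L, beam_sigma = 2.5, noise_rate = 0) {
  .check(lambda_w > 0 && range_mult > 0, "lambda_w and range_mult must be > 0")
  .check(n_frag >= 1 && n_frag == round(n_frag),
         "n_frag must be a positive integer")
  structure(list(lambda_w = lambda_w, range_mult = range_mult,
                 sigma_theta = sigma_theta, n_frag = as.integer(n_frag),
                 beam_sigma = beam_sigma,
                 noise_rate = noise_rate), class = "frag_params")
}

#' Highland multiple-Coulomb-scattering angle
#'
#' \deqn{\theta_0 = \frac{13.6\,\mathrm{MeV}}{p\beta c}\, z\,
#'   \sqrt{x/X_0}\,[1 + 0.038 \ln(x/X_0)]}
#'
#' @param p_beta_c momentum times velocity, MeV.
#' @param z particle charge in units of e.
#' @param x_over_x0 material thickness over radiation length; 0 returns 0 by
#'   continuity.
#' @return RMS projected scattering angle in rad (never negative).
#' @export
highland_sigma <- function(p_beta_c, z = 1, x_over_x0) {
  .check(all(p_beta_c > 0), "p_beta_c must be > 0")
  .check(all(x_over_x0 >= 0), "x_over_x0 must be >= 0")
  out <- ifelse(x_over_x0 > 0,
                13.6 / p_beta_c * z * sqrt(x_over_x0) *
                  pmax(1 + 0.038 * log(x_over_x0), 0),
                0)
  pmax(out, 0)
}

# proton kinematics: pbc (MeV) from kinetic energy (MeV), and kinetic energy
# from water range via inverse Bragg-Kleeman (R_mm = 0.022 E^1.77)
.proton_pbc <- function(e_kin) {
  m <- 938.272
  e_kin * (e_kin + 2 * m) / (e_kin + m)
}
.proton_energy_from_range <- function(range_mm) {
  pmax(range_mm / 0.022, 1e-6)^(1 / 1.77)
}

#' True stopping depth of the central ray of a spot
#'
#' Depth z (mm) at which the accumulated water-equivalent path of an ion
#' entering at lateral position (x, y) parallel to the beam axis matches its
#' water range, for the phantom displaced by `offset`. This is the
#' ground-truth Bragg-peak position used to define "true range shifts".
#'
#' @param phantom an [phantom_geometry()].
#' @param model a [range_model()].
#' @param x,y lateral entry position(s), mm.
#' @param energy beam energy, MeV/u (recycled).
#' @param offset motion offset(s), mm.
#' @return stopping depth(s) z in mm (`Inf` when the ion punches through).
#' @export
true_stop_depth <- function(phantom, model, x, y, energy, offset = 0) {
  n <- max(length(x), length(y), length(offset), length(energy))
  x <- rep_len(x, n); y <- rep_len(y, n)
  offset <- rep_len(offset, n); energy <- rep_len(energy, n)
  breaks <- .axial_breaks(phantom, x, y, offset)
  .axial_invert(breaks, .axial_prop(phantom, "wer"),
                energy_to_range(model, energy))
}

# ---- per-spot axial transport ---------------------------------------------
# For ions travelling parallel to z at lateral (x, y), the material sequence
# is fixed: wall | foam | insert | foam | wall, with the insert segment
# possibly empty. Returns per-ion z breakpoints (n x 6) spanning the phantom.
.axial_breaks <- function(phantom, x, y, offset) {
  ho <- phantom$half_outer; hc <- phantom$half_cavity
  rho2 <- (x - offset)^2 + y^2
  r2 <- phantom$r_insert^2
  has_insert <- rho2 <= r2
  z_in <- ifelse(has_insert, -sqrt(pmax(r2 - rho2, 0)), phantom$cyl_z[2])
  z_out <- ifelse(has_insert, phantom$cyl_z[2], phantom$cyl_z[2])
  # ions outside the cavity cross section see wall the whole way; handled by
  # collapsing the cavity interval
  in_cav <- abs(x - offset) < hc[1] & abs(y) < hc[2]
  cav_lo <- ifelse(in_cav, -hc[3], 0)
  cav_hi <- ifelse(in_cav, hc[3], 0)
  z_in <- pmax(pmin(z_in, cav_hi), cav_lo)
  z_out <- pmax(pmin(z_out, cav_hi), cav_lo)
  cbind(-ho[3], cav_lo, z_in, z_out, cav_hi, ho[3])
}

# piecewise-constant property per segment (5 segments between 6 breakpoints)
.axial_prop <- function(phantom, what) {
  v <- vapply(phantom$materials, `[[`, numeric(1), what)
  c(v["pmma"], v["foam"], v["pmma"], v["foam"], v["pmma"])
}

# cumulative integral of `prop` at depth z (vectors), given breaks (n x 6)
.axial_cum <- function(breaks, prop, z) {
  n <- nrow(breaks)
  acc <- numeric(n)
  for (k in 1:5) {
    acc <- acc + prop[k] * pmax(pmin(z, breaks[, k + 1]) - breaks[, k], 0)
  }
  acc
}

# invert the cumulative integral: depth z at which it reaches `target`
# (Inf if never reached inside the phantom)
.axial_invert <- function(breaks, prop, target) {
  n <- nrow(breaks)
  z <- rep(Inf, n)
  acc <- numeric(n)
  done <- rep(FALSE, n)
  for (k in 1:5) {
    if (prop[k] > 0) {
      seg <- prop[k] * (breaks[, k + 1] - breaks[, k])
      hit <- which(!done & target <= acc + seg)
      if (length(hit)) {
        z[hit] <- breaks[hit, k] + (target[hit] - acc[hit]) / prop[k]
        done[hit] <- TRUE
      }
      acc <- acc + seg
    }
  }
  z
}

#' Sample fragmentation vertices for one beam spot
#'
#' Draws per-ion delivery times (uniform in the spot interval), lateral entry
#' positions (Gaussian beam spread around the planned spot position), ion
#' stopping depths (where the accumulated WEPL matches the beam range), and
#' fragmentation depths by exponential thinning with interaction rate
#' `density / lambda_w`. A vertex is recorded when the ion fragments before
#' it stops.
#'
#' @param phantom an [phantom_geometry()].
#' @param model a [range_model()].
#' @param spot one-row plan entry (needs `spot_index`, `energy`, `x_v`,
#'   `y_v`, `n_planned`).
#' @param t_start,t_end spot delivery interval, s.
#' @param offset_fun function(t) returning the motion offset in mm at time t
#'   (constant function for the static cases).
#' @param fp a [frag_params()].
#' @param seed optional RNG seed.
#' @return list with `vertices` (data.table: `spot_index`, `time`, `x`, `y`,
#'   `z`, `depth_wepl`, `residual_wepl`, `offset`) and `truth` (one-row
#'   data.table: per-spot motor offset at mid-time, mean/central stopping
#'   depth, ion and vertex counts).
#' @export
sample_fragmentation_vertices <- function(phantom, model, spot,
                                          t_start, t_end, offset_fun,
                                          fp = frag_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spot$n_planned
  t_ion <- stats::runif(n, t_start, t_end)
  off <- offset_fun(t_ion)
  x0 <- spot$x_v + stats::rnorm(n, 0, fp$beam_sigma)
  y0 <- spot$y_v + stats::rnorm(n, 0, fp$beam_sigma)
  breaks <- .axial_breaks(phantom, x0, y0, off)
  wer <- .axial_prop(phantom, "wer")
  dens <- .axial_prop(phantom, "density")
  range_w <- energy_to_range(model, spot$energy)
  z_stop <- .axial_invert(breaks, wer, rep(range_w, n))
  z_stop <- pmin(z_stop, phantom$half_outer[3])
  # fragmentation point: exponential in density-weighted path length
  xi <- stats::rexp(n) * fp$lambda_w
  z_int <- .axial_invert(breaks, dens, xi)
  frag <- z_int < z_stop & is.finite(z_int)
  depth_w <- .axial_cum(breaks[frag, , drop = FALSE], wer, z_int[frag])
  vert <- data.table::data.table(
    spot_index = spot$spot_index,
    time = t_ion[frag], x = x0[frag], y = y0[frag], z = z_int[frag],
    depth_wepl = depth_w,
    residual_wepl = pmax(range_w - depth_w, 0),
    offset = off[frag]
  )
  mid_off <- offset_fun((t_start + t_end) / 2)
  cen <- .axial_breaks(phantom, spot$x_v, spot$y_v, mid_off)
  truth <- data.table::data.table(
    spot_index = spot$spot_index,
    offset_mm = mid_off,
    motor_mm = abs(mid_off),
    stop_z_central = .axial_invert(cen, wer, range_w),
    stop_z_mean = mean(z_stop[is.finite(z_stop)]),
    n_ions = n, n_vertices = nrow(vert)
  )
  list(vertices = vert, truth = truth)
}

#' Emit light fragments from each vertex
#'
#' Each vertex emits `n_frag` fragments with independent forward-peaked
#' directions: Gaussian angular deviations of sigma `sigma_theta` in x and y
#' around the parent direction (+z). The fragment water range is
#' `range_mult` times the residual primary range at the vertex.
#'
#' @param vertices vertex table from [sample_fragmentation_vertices()].
#' @param fp a [frag_params()].
#' @param seed optional RNG seed.
#' @return one row per fragment: the vertex columns plus `vertex_id`, `dx`,
#'   `dy`, `dz` (unit direction) and `frag_range_w` (mm water).
#' @export
emit_fragments <- function(vertices, fp = frag_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(vertices)
  out <- data.table::as.data.table(vertices)[rep(seq_len(nv),
                                                 each = fp$n_frag)]
  out[, vertex_id := rep(seq_len(nv), each = fp$n_frag)]
  n <- nrow(out)
  tx <- stats::rnorm(n, 0, fp$sigma_theta)
  ty <- stats::rnorm(n, 0, fp$sigma_theta)
  nrm <- sqrt(tx^2 + ty^2 + 1)
  out[, `:=`(dx = tx / nrm, dy = ty / nrm, dz = 1 / nrm,
             frag_range_w = fp$range_mult * residual_wepl)]
  out[]
}

# WEPL (or any per-material property integral) from in-phantom points along
# arbitrary directions to the aquarium exit; also the per-layer geometric
# lengths and boundary distances needed for scattering kicks.
# o, d: n x 3 matrices (d unit). Returns list of vectors.
.exit_paths <- function(phantom, o, d, offset) {
  # translate into the phantom frame so per-ray offsets are supported
  o <- cbind(o[, 1] - offset, o[, 2], o[, 3])
  box <- .iv_box(o, d, phantom$half_outer, 0)
  cav <- .iv_box(o, d, phantom$half_cavity, 0)
  ins <- .iv_insert(phantom, o, d, 0)
  t_exit <- box[, 2]
  l_cav <- .iv_len(cav, t_exit)
  l_hemi <- .iv_len(ins$hemi, t_exit)
  l_cyl <- .iv_len(ins$cyl, t_exit)
  l_ins <- l_hemi + l_cyl
  l_wall <- pmax(t_exit - l_cav, 0)
  l_foam <- pmax(l_cav - l_ins, 0)
  mats <- phantom$materials
  wepl <- l_wall * mats$pmma$wer + l_foam * mats$foam$wer +
    l_ins * mats$pmma$wer
  # distance along the ray at which each layer is left (for thin-lens kicks):
  # insert exit, cavity exit, box exit
  t_ins_end <- pmax(ins$hemi[, 2] * (l_hemi > 0), ins$cyl[, 2] * (l_cyl > 0))
  list(t_exit = t_exit, t_cav_end = pmin(cav[, 2], t_exit),
       t_ins_end = pmin(ifelse(t_ins_end > 0, t_ins_end, 0), t_exit),
       l_wall = l_wall, l_foam = l_foam, l_ins = l_ins, wepl = wepl)
}

#' Propagate fragments to the tracker arms
#'
#' Applies Highland scattering kicks (thin lens, at the exit boundary of the
#' PMMA insert, the foam and the aquarium wall, with layer thicknesses taken
#' along the unperturbed direction), discards fragments whose water range is
#' shorter than the WEPL to the phantom exit, and intersects the emerging
#' straight line with the three sensor planes of each arm. A fragment is
#' detected when all three intersections of one arm fall inside the active
#' area; cluster positions are smeared by the cluster resolution.
#'
#' @param fragments output of [emit_fragments()].
#' @param phantom an [phantom_geometry()].
#' @param tracker a [tracker_geometry()].
#' @param offset motion offset per fragment (recycled), mm.
#' @param fp a [frag_params()].
#' @param t0 DAQ start time (frame 0 boundary), s.
#' @param seed optional RNG seed.
#' @param scattering logical; disable to propagate without Coulomb kicks.
#' @param smearing logical; disable for perfect cluster positions.
#' @return `data.table` of clusters: `arm`, `sensor`, `frame`, `u_mm`,
#'   `v_mm`, plus bookkeeping columns `spot_index`, `fragment_id` and the
#'   global impact coordinates `gx`, `gy`, `gz`.
#' @export
propagate_to_trackers <- function(fragments, phantom, tracker, offset = 0,
                                  fp = frag_params(), t0 = 0, seed = NULL,
                                  scattering = TRUE, smearing = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  fr <- data.table::as.data.table(fragments)
  n <- nrow(fr)
  if (n == 0L) return(.empty_clusters())
  o <- cbind(fr$x, fr$y, fr$z)
  d <- cbind(fr$dx, fr$dy, fr$dz)
  off <- rep_len(offset, n)
  # cheap angular pre-selection: a fragment can only be detected when its
  # direction points within ~0.12 rad (active area + scattering, doubled)
  # of the line from its vertex to some arm center
  slack <- 0.12
  near <- rep(FALSE, n)
  sx <- d[, 1] / d[, 3]; sy <- d[, 2] / d[, 3]
  for (ax in tracker$axes) {
    ctr <- tracker$radial_mm * ax$n
    vx <- (ctr[1] - o[, 1]) / (ctr[3] - o[, 3])
    vy <- (ctr[2] - o[, 2]) / (ctr[3] - o[, 3])
    near <- near | (abs(sx - vx) < slack & abs(sy - vy) < slack &
                      d[, 3] > 0 & ctr[3] > o[, 3])
  }
  if (!any(near)) return(.empty_clusters())
  pre <- which(near)
  fr <- fr[pre]; o <- o[pre, , drop = FALSE]; d <- d[pre, , drop = FALSE]
  off <- off[pre]
  n <- length(pre)
  paths <- .exit_paths(phantom, o, d, off)
  exits <- fr$frag_range_w > paths$wepl
  if (!any(exits)) return(.empty_clusters())
  idx <- which(exits)
  orig_id <- pre[idx] # row in the input fragment table, for truth matching
  o <- o[idx, , drop = FALSE]; d <- d[idx, , drop = FALSE]
  pt <- lapply(paths, `[`, idx)
  fr <- fr[idx]
  m <- length(idx)
  dir_out <- d
  pos_shift <- matrix(0, m, 3)
  if (scattering) {
    mats <- phantom$materials
    e_kin <- .proton_energy_from_range(pmax(fr$frag_range_w, 1))
    pbc <- .proton_pbc(e_kin)
    layers <- list(
      list(len = pt$l_ins, x0 = mats$pmma$x0, t_end = pt$t_ins_end),
      list(len = pt$l_foam, x0 = mats$foam$x0, t_end = pt$t_cav_end),
      list(len = pt$l_wall, x0 = mats$pmma$x0, t_end = pt$t_exit)
    )
    for (ly in layers) {
      th0 <- highland_sigma(pbc, 1, ly$len / ly$x0)
      kx <- stats::rnorm(m, 0, th0); ky <- stats::rnorm(m, 0, th0)
      lever <- pmax(pt$t_exit - ly$t_end, 0)
      pos_shift[, 1] <- pos_shift[, 1] + kx * lever
      pos_shift[, 2] <- pos_shift[, 2] + ky * lever
      dir_out[, 1] <- dir_out[, 1] + kx
      dir_out[, 2] <- dir_out[, 2] + ky
    }
    dir_out <- dir_out / sqrt(rowSums(dir_out^2))
  }
  exit_pos <- o + d * pt$t_exit + pos_shift
  # intersect with each arm's sensor planes
  cl <- vector("list", length(tracker$axes))
  for (ax in tracker$axes) {
    s <- exit_pos %*% ax$n
    ds <- dir_out %*% ax$n
    ok_dir <- ds > 1e-9
    uu <- matrix(NA_real_, m, 3); vv <- matrix(NA_real_, m, 3)
    inside <- ok_dir
    for (j in 1:3) {
      tt <- (ax$d[j] - s) / ds
      p <- exit_pos + dir_out * as.vector(tt)
      cu <- (p %*% ax$e_u) - 0   # arm axis passes through the isocenter
      cv <- p %*% ax$e_v
      uu[, j] <- cu; vv[, j] <- cv
      inside <- inside & tt > 0 & abs(cu) <= tracker$half_u &
        abs(cv) <= tracker$half_v
    }
    hit <- which(inside)
    if (length(hit) == 0L) next
    if (smearing) {
      uu[hit, ] <- uu[hit, ] + stats::rnorm(3 * length(hit), 0,
                                            tracker$cluster_sigma)
      vv[hit, ] <- vv[hit, ] + stats::rnorm(3 * length(hit), 0,
                                            tracker$cluster_sigma)
    }
    cl[[ax$arm]] <- data.table::data.table(
      spot_index = rep(fr$spot_index[hit], 3),
      fragment_id = rep(orig_id[hit], 3),
      arm = ax$arm,
      sensor = rep(1:3, each = length(hit)),
      frame = rep(as.integer(floor((fr$time[hit] - t0) / tracker$frame_dt)), 3),
      u_mm = c(uu[hit, 1], uu[hit, 2], uu[hit, 3]),
      v_mm = c(vv[hit, 1], vv[hit, 2], vv[hit, 3])
    )
  }
  out <- data.table::rbindlist(cl)
  if (nrow(out) > 0L) {
    # keep fragments detected by exactly one arm (first arm wins otherwise)
    first_arm <- out[, list(arm = arm[1]), by = "fragment_id"]
    out <- out[first_arm, on = c("fragment_id", "arm")]
  }
  if (fp$noise_rate > 0) {
    frames <- floor(range(fr$time - t0) / tracker$frame_dt)
    frames <- seq(frames[1], frames[2])
    n_noise <- stats::rpois(1, fp$noise_rate * length(frames) *
                              3 * length(tracker$axes))
    if (n_noise > 0) {
      noise <- data.table::data.table(
        spot_index = fr$spot_index[1], fragment_id = NA_integer_,
        arm = sample(length(tracker$axes), n_noise, replace = TRUE),
        sensor = sample(3L, n_noise, replace = TRUE),
        frame = as.integer(sample(frames, n_noise, replace = TRUE)),
        u_mm = stats::runif(n_noise, -tracker$half_u, tracker$half_u),
        v_mm = stats::runif(n_noise, -tracker$half_v, tracker$half_v))
      out <- data.table::rbindlist(list(out, noise))
    }
  }
  if (nrow(out) == 0L) return(.empty_clusters())
  gl <- .clusters_global(out, tracker)
  out[, `:=`(gx = gl$gx, gy = gl$gy, gz = gl$gz)]
  out[order(frame, arm, sensor)]
}

.empty_clusters <- function() {
  data.table::data.table(spot_index = integer(), fragment_id = integer(),
                         arm = integer(), sensor = integer(),
                         frame = integer(), u_mm = numeric(),
                         v_mm = numeric(), gx = numeric(), gy = numeric(),
                         gz = numeric())
}

# global coordinates of clusters from (arm, sensor, u, v)
.clusters_global <- function(cl, tracker) {
  gx <- numeric(nrow(cl)); gy <- numeric(nrow(cl)); gz <- numeric(nrow(cl))
  for (ax in tracker$axes) {
    for (j in 1:3) {
      sel <- cl$arm == ax$arm & cl$sensor == j
      if (!any(sel)) next
      p <- outer(rep(ax$d[j], sum(sel)), ax$n) +
        outer(cl$u_mm[sel], ax$e_u) + outer(cl$v_mm[sel], ax$e_v)
      gx[sel] <- p[, 1]; gy[sel] <- p[, 2]; gz[sel] <- p[, 3]
    }
  }
  list(gx = gx, gy = gy, gz = gz)
}

#' Cluster file I/O
#'
#' @param clusters cluster table.
#' @param file CSV path (`spot_index,fragment_id,arm,sensor,frame,u_mm,v_mm`).
#' @export
write_clusters <- function(clusters, file) {
  data.table::fwrite(data.table::as.data.table(clusters)[
    , list(spot_index, fragment_id, arm, sensor, frame, u_mm, v_mm)], file)
  invisible(file)
}

#' @rdname write_clusters
#' @param tracker a [tracker_geometry()] used to restore global coordinates.
#' @export
read_clusters <- function(file, tracker) {
  cl <- data.table::fread(file, showProgress = FALSE)
  need <- c("spot_index", "fragment_id", "arm", "sensor", "frame",
            "u_mm", "v_mm")
  missing <- setdiff(need, names(cl))
  .check(length(missing) == 0L, "cluster file is missing column '%s'",
         if (length(missing)) missing[1] else "")
  gl <- .clusters_global(cl, tracker)
  cl[, `:=`(gx = gl$gx, gy = gl$gy, gz = gl$gz)]
  cl[]
}

#' Simulate one delivery (all spots of a plan, one experimental case)
#'
#' Runs the full forward chain for the `static_in` (offset 0), `static_out`
#' (offset = motion amplitude) or `moving` (offset follows the Lujan trace at
#' each ion's delivery time) case and bundles spot log, FPGA log, motor log,
#' tracker clusters and per-spot ground truth.
#'
#' @param plan an `ivi_plan`.
#' @param case one of `"static_in"`, `"static_out"`, `"moving"`.
#' @param phantom,model,scanner,tracker,fp,motion geometry/model parameter
#'   objects ([phantom_geometry()], [range_model()], [scanner_geometry()],
#'   [tracker_geometry()], [frag_params()], [lujan_params()]).
#' @param intensity,inter_spot_gap,inter_layer_gap see [delivery_timeline()].
#' @param seed master seed for this run.
#' @param motion_sign sign relating the (positive) motor position to the
#'   phantom displacement in the beam frame (default -1: the table carries
#'   the phantom toward -x, so beam spots on the +x side of the target lose
#'   PMMA coverage and overshoot during motion — the high-gradient edge
#'   region selected for the edge study).
#' @param keep_fragments store the full per-fragment truth table (memory
#'   heavy; default `FALSE` keeps only the per-spot truth summary).
#' @return object of class `ivi_run`: list with `case`, `plan`, `timeline`,
#'   `spot_log`, `fpga_log`, `motor_log` (moving case), `clusters`, `truth`.
#' @export
simulate_delivery <- function(plan, case = c("static_in", "static_out",
                                             "moving"),
                              phantom = phantom_geometry(),
                              model = range_model(),
                              scanner = scanner_geometry(),
                              tracker = tracker_geometry(),
                              fp = frag_params(),
                              motion = lujan_params(),
                              intensity = 2e7, inter_spot_gap = 2e-3,
                              inter_layer_gap = 1, seed = 1L,
                              motion_sign = -1,
                              keep_fragments = FALSE) {
  case <- match.arg(case)
  tl <- delivery_timeline(plan, intensity, inter_spot_gap, inter_layer_gap)
  sl <- simulate_spot_log(plan, tl, scanner, fp$beam_sigma,
                          seed = seed_chain(seed, 1L))
  mlog <- NULL
  # motor positions are positive by convention; the beam-frame phantom
  # offset carries the mounting sign
  motor_fun <- switch(case,
    static_in = function(t) rep(0, length(t)),
    static_out = function(t) rep(motion$amplitude, length(t)),
    moving = function(t) lujan_position(t, motion))
  offset_fun <- function(t) motion_sign * motor_fun(t)
  if (case == "moving") {
    mlog <- motor_log(motion, duration = max(tl$t_end) + motion$period)
  }
  p <- data.table::as.data.table(plan)
  verts <- vector("list", nrow(p))
  clusters <- vector("list", nrow(p))
  truth <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    spot <- p[i]
    sv <- sample_fragmentation_vertices(
      phantom, model, spot, tl$t_start[i], tl$t_end[i], offset_fun, fp,
      seed = seed_chain(seed, 2L, spot$spot_index))
    fr <- emit_fragments(sv$vertices, fp,
                         seed = seed_chain(seed, 3L, spot$spot_index))
    cl <- propagate_to_trackers(fr, phantom, tracker,
                                offset = fr$offset, fp = fp, t0 = 0,
                                seed = seed_chain(seed, 4L, spot$spot_index))
    if (keep_fragments) verts[[i]] <- fr
    clusters[[i]] <- cl
    truth[[i]] <- sv$truth
  }
  run <- list(case = case, plan = p, timeline = tl, spot_log = sl,
              fpga_log = fpga_log(tl, tracker$frame_dt),
              motor_log = mlog,
              clusters = data.table::rbindlist(clusters),
              truth = data.table::rbindlist(truth),
              true_fragments = data.table::rbindlist(verts),
              seed = seed)
  class(run) <- "ivi_run"
  run
}

#' @export
print.ivi_run <- function(x, ...) {
  cat("ivi_run:", x$case, "-", nrow(x$plan), "spots,",
      sum(x$truth$n_vertices), "true vertices,",
      nrow(x$clusters), "clusters\n")
  invisible(x)
}
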
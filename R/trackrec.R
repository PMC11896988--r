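# Straight-track reconstruction from tracker clusters: telescope line fits
# in arm-local coordinates, greedy combinatorial cluster matching per
# (arm, frame), software alignment from a no-target run, and frame-to-spot
# association via the delivery timing.

# closed-form straight-line fit in arm-local coordinates for many candidate
# triples at once. u, v: n x 3 matrices of in-plane positions, dd: the 3
# plane distances. Returns intercepts/slopes (at d = 0, i.e. the isocenter
# plane of the arm) and the per-candidate residual rms.
.fit_lines_local <- function(u, v, dd) {
  db <- mean(dd)
  dc <- dd - db
  sxx <- sum(dc^2)
  bu <- (u %*% dc) / sxx
  bv <- (v %*% dc) / sxx
  au <- rowMeans(u) - bu * db
  av <- rowMeans(v) - bv * db
  ru <- u - (matrix(au, nrow(u), 3) + outer(as.vector(bu), dd))
  rv <- v - (matrix(av, nrow(v), 3) + outer(as.vector(bv), dd))
  rms <- sqrt((rowSums(ru^2) + rowSums(rv^2)) / 6)
  list(au = as.vector(au), bu = as.vector(bu),
       av = as.vector(av), bv = as.vector(bv), rms = as.vector(rms))
}

# convert arm-local line parameters to a global point + unit direction
.local_to_global <- function(fit, ax) {
  p <- outer(fit$au, ax$e_u) + outer(fit$av, ax$e_v)
  d <- outer(fit$bu, ax$e_u) + outer(fit$bv, ax$e_v) +
    matrix(ax$n, length(fit$au), 3, byrow = TRUE)
  d <- d / sqrt(rowSums(d^2))
  list(p = p, d = d)
}

#' Fit a straight track through one cluster per sensor plane
#'
#' Least-squares straight line (independent linear fits of the two in-plane
#' coordinates against the plane distance — the standard telescope fit).
#'
#' @param clusters table with one row per sensor (`sensor`, `u_mm`, `v_mm`)
#'   of a single arm and frame.
#' @param tracker a [tracker_geometry()].
#' @param arm arm index (taken from the clusters if present).
#' @return one-row `data.table`: `arm`, `px`, `py`, `pz` (point on the line
#'   at the arm's isocenter plane), `dx`, `dy`, `dz` (unit direction pointing
#'   away from the target), `residual_mm`.
#' @export
fit_track <- function(clusters, tracker, arm = clusters$arm[1]) {
  cl <- data.table::as.data.table(clusters)[order(sensor)]
  .check(nrow(cl) == 3L && all(cl$sensor == 1:3),
         "need exactly one cluster on each of the 3 sensor planes")
  ax <- tracker$axes[[arm]]
  fit <- .fit_lines_local(matrix(cl$u_mm, 1), matrix(cl$v_mm, 1), ax$d)
  g <- .local_to_global(fit, ax)
  data.table::data.table(arm = arm, px = g$p[1], py = g$p[2], pz = g$p[3],
                         dx = g$d[1], dy = g$d[2], dz = g$d[3],
                         residual_mm = fit$rms)
}

#' Build secondary tracks from all clusters of a run
#'
#' Within each (arm, frame) group, all combinations of one cluster per
#' sensor plane are fitted and accepted greedily in order of residual, each
#' cluster used at most once, until no combination below the residual cut
#' remains.
#'
#' @param clusters cluster table from [propagate_to_trackers()] (or
#'   [read_clusters()]).
#' @param tracker a [tracker_geometry()].
#' @param residual_cut maximum residual rms in mm (default 0.05).
#' @param max_clusters skip pathological groups with more clusters per
#'   sensor than this (default 100).
#' @return `data.table` of tracks: `arm`, `frame`, `px`, `py`, `pz`, `dx`,
#'   `dy`, `dz`, `residual_mm`, `n_cand` plus the contributing cluster rows'
#'   `fragment_id` (majority vote, for truth matching).
#' @export
build_tracks <- function(clusters, tracker, residual_cut = 0.05,
                         max_clusters = 100) {
  cl <- data.table::as.data.table(clusters)
  if (nrow(cl) == 0L) return(.empty_tracks())
  out <- cl[, .build_tracks_group(.SD, tracker$axes[[arm[1]]],
                                  residual_cut, max_clusters),
            by = list(arm, frame)]
  if (nrow(out) == 0L) return(.empty_tracks())
  out[]
}

.empty_tracks <- function() {
  data.table::data.table(arm = integer(), frame = integer(), px = numeric(),
                         py = numeric(), pz = numeric(), dx = numeric(),
                         dy = numeric(), dz = numeric(),
                         residual_mm = numeric(), n_cand = integer(),
                         fragment_id = integer(), spot_index = integer())
}

.build_tracks_group <- function(sd, ax, residual_cut, max_clusters) {
  i1 <- which(sd$sensor == 1L); i2 <- which(sd$sensor == 2L)
  i3 <- which(sd$sensor == 3L)
  if (!length(i1) || !length(i2) || !length(i3)) return(NULL)
  if (max(length(i1), length(i2), length(i3)) > max_clusters) return(NULL)
  combos <- as.matrix(expand.grid(a = i1, b = i2, c = i3))
  # drop combinations whose plane-to-plane slope is unphysically large
  # (tracks point back toward the target, |slope| << 0.3)
  if (nrow(combos) > 27L) {
    sp <- abs(ax$d[2] - ax$d[1]) * 0.3
    ok <- abs(sd$u_mm[combos[, 2]] - sd$u_mm[combos[, 1]]) < sp &
      abs(sd$u_mm[combos[, 3]] - sd$u_mm[combos[, 2]]) < sp &
      abs(sd$v_mm[combos[, 2]] - sd$v_mm[combos[, 1]]) < sp &
      abs(sd$v_mm[combos[, 3]] - sd$v_mm[combos[, 2]]) < sp
    if (any(ok)) combos <- combos[ok, , drop = FALSE] else return(NULL)
  }
  u <- cbind(sd$u_mm[combos[, 1]], sd$u_mm[combos[, 2]], sd$u_mm[combos[, 3]])
  v <- cbind(sd$v_mm[combos[, 1]], sd$v_mm[combos[, 2]], sd$v_mm[combos[, 3]])
  fit <- .fit_lines_local(u, v, ax$d)
  ord <- order(fit$rms)
  used <- rep(FALSE, nrow(sd))
  keep <- integer(0)
  for (k in ord) {
    if (fit$rms[k] > residual_cut) break
    cc <- combos[k, ]
    if (any(used[cc])) next
    used[cc] <- TRUE
    keep <- c(keep, k)
  }
  if (!length(keep)) return(NULL)
  g <- .local_to_global(lapply(fit, `[`, keep), ax)
  fid <- if ("fragment_id" %in% names(sd)) {
    apply(matrix(sd$fragment_id[combos[keep, , drop = FALSE]],
                 ncol = 3), 1, function(x) {
                   tx <- table(x) # drops NAs (noise clusters)
                   if (length(tx) == 0L) return(NA_integer_)
                   as.integer(names(tx)[which.max(tx)])
                 })
  } else rep(NA_integer_, length(keep))
  sp <- if ("spot_index" %in% names(sd)) {
    sd$spot_index[combos[keep, 1]]
  } else rep(NA_integer_, length(keep))
  data.table::data.table(px = g$p[, 1], py = g$p[, 2], pz = g$p[, 3],
                         dx = g$d[, 1], dy = g$d[, 2], dz = g$d[, 3],
                         residual_mm = fit$rms[keep],
                         n_cand = nrow(combos),
                         fragment_id = fid, spot_index = sp)
}

#' Simulate a no-target alignment run
#'
#' Generates straight reference tracks (no phantom in the beam) aimed at one
#' arm from points near the isocenter, records their clusters with optional
#' injected per-sensor rigid offsets, for use with [estimate_alignment()].
#'
#' @param tracker a [tracker_geometry()].
#' @param arm arm index.
#' @param n_tracks number of tracks (default 1e4).
#' @param offsets 3 x 2 matrix of injected per-sensor (du, dv) offsets in mm
#'   (default zero).
#' @param seed RNG seed.
#' @return cluster table (same shape as [propagate_to_trackers()] output).
#' @export
simulate_alignment_run <- function(tracker, arm, n_tracks = 1e4,
                                   offsets = matrix(0, 3, 2), seed = 1L) {
  set.seed(seed)
  ax <- tracker$axes[[arm]]
  # emission points spread near the isocenter, directions toward the arm
  au <- stats::runif(n_tracks, -tracker$half_u, tracker$half_u) * 0.5
  av <- stats::runif(n_tracks, -tracker$half_v, tracker$half_v) * 0.5
  bu <- stats::runif(n_tracks, -0.02, 0.02)
  bv <- stats::runif(n_tracks, -0.02, 0.02)
  cl <- lapply(1:3, function(j) {
    data.table::data.table(
      spot_index = NA_integer_, fragment_id = seq_len(n_tracks),
      arm = arm, sensor = j, frame = seq_len(n_tracks),
      u_mm = au + bu * ax$d[j] + offsets[j, 1] +
        stats::rnorm(n_tracks, 0, tracker$cluster_sigma),
      v_mm = av + bv * ax$d[j] + offsets[j, 2] +
        stats::rnorm(n_tracks, 0, tracker$cluster_sigma))
  })
  out <- data.table::rbindlist(cl)
  gl <- .clusters_global(out, tracker)
  out[, `:=`(gx = gl$gx, gy = gl$gy, gz = gl$gz)]
  out[]
}

#' Estimate per-sensor alignment offsets from a no-target run
#'
#' The two outer sensors define the reference frame (rigid offsets of the
#' full arm are unobservable from internal residuals); the middle sensor's
#' in-plane offset is estimated as the mean residual of its clusters against
#' the line through the outer-sensor clusters of the same track.
#'
#' @param clusters alignment-run cluster table (one cluster per sensor per
#'   frame; see [simulate_alignment_run()]).
#' @param tracker a [tracker_geometry()].
#' @param min_tracks minimum number of usable tracks (default 100).
#' @return `data.table` with `arm`, `sensor`, `du_mm`, `dv_mm` (estimated
#'   offsets; outer sensors fixed at 0 by construction).
#' @export
estimate_alignment <- function(clusters, tracker, min_tracks = 100) {
  cl <- data.table::as.data.table(clusters)
  est <- lapply(unique(cl$arm), function(a) {
    ax <- tracker$axes[[a]]
    w <- data.table::dcast(cl[arm == a], frame ~ sensor,
                           value.var = c("u_mm", "v_mm"))
    w <- w[stats::complete.cases(w)]
    .check(nrow(w) >= min_tracks,
           "insufficient alignment tracks on arm %d: %d", a, nrow(w))
    f <- (ax$d[2] - ax$d[1]) / (ax$d[3] - ax$d[1])
    du <- w$u_mm_2 - (w$u_mm_1 + f * (w$u_mm_3 - w$u_mm_1))
    dv <- w$v_mm_2 - (w$v_mm_1 + f * (w$v_mm_3 - w$v_mm_1))
    data.table::data.table(arm = a, sensor = 1:3,
                           du_mm = c(0, mean(du), 0),
                           dv_mm = c(0, mean(dv), 0))
  })
  data.table::rbindlist(est)
}

#' Apply an alignment set to clusters
#'
#' Subtracts estimated per-sensor offsets from the cluster coordinates.
#'
#' @param clusters cluster table.
#' @param alignment output of [estimate_alignment()].
#' @param tracker a [tracker_geometry()] used to refresh global coordinates.
#' @return corrected cluster table.
#' @export
apply_alignment <- function(clusters, alignment, tracker) {
  cl <- data.table::copy(data.table::as.data.table(clusters))
  al <- data.table::as.data.table(alignment)
  cl[al, on = c("arm", "sensor"),
     `:=`(u_mm = u_mm - i.du_mm, v_mm = v_mm - i.dv_mm)]
  gl <- .clusters_global(cl, tracker)
  cl[, `:=`(gx = gl$gx, gy = gl$gy, gz = gl$gz)]
  cl[]
}

#' Map readout frames to beam spots
#'
#' A frame is associated to the spot whose delivery interval contains the
#' frame midpoint; frames outside every spot interval map to no spot (NA).
#'
#' @param frames integer frame indices (frame k spans
#'   `[k, k+1) * frame_dt + t0`).
#' @param timeline delivery timeline ([delivery_timeline()]).
#' @param frame_dt frame integration time in s.
#' @param t0 time of the frame-0 boundary, s.
#' @return integer vector of spot indices (NA where unassigned).
#' @export
associate_frames_to_spots <- function(frames, timeline, frame_dt = 186.5e-6,
                                      t0 = 0) {
  tl <- data.table::as.data.table(timeline)[order(t_start)]
  .check(all(tl$t_start[-1] >= tl$t_end[-nrow(tl)] - 1e-12),
         "overlapping spot intervals")
  mid <- t0 + (frames + 0.5) * frame_dt
  pos <- findInterval(mid, tl$t_start)
  spot <- rep(NA_integer_, length(frames))
  ok <- pos >= 1
  inside <- ok & mid <= tl$t_end[pmax(pos, 1)]
  spot[inside] <- tl$spot_index[pos[inside]]
  spot
}

#' Track file I/O
#'
#' @param tracks track table from [build_tracks()].
#' @param file CSV path.
#' @export
write_tracks <- function(tracks, file) {
  data.table::fwrite(data.table::as.data.table(tracks), file)
  invisible(file)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(file) {
  data.table::fread(file, showProgress = FALSE)
}
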
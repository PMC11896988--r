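# Vertex reconstruction: per-spot primary pencil-beam lines (method a:
# deterministic MWPC/scanner extrapolation; method b: Gaussian-randomised
# origin plus Highland scattering randomisation of the slopes), closest
# approach between primary and secondary lines, vertex filtering, and the
# per-spot "computed vertex" summaries.

#' Primary track, method a
#'
#' Deterministic pencil-beam line: origin at the MWPC-averaged beam centroid
#' (mean of the two MWPC centre-of-mass readings, placed at the z of
#' MWPC 1), slopes from the scanner-magnet pivots through the planned voxel.
#'
#' @param record one-row spot-log entry (see [simulate_spot_log()]); needs
#'   `x_i1`, `y_i1`, `x_i2`, `y_i2`, `z_i`, `scanner_x`, `scanner_y`.
#' @param scanner a [scanner_geometry()].
#' @return one-row `data.table`: `px`, `py`, `pz` (origin), `ax`, `ay`
#'   (slopes dx/dz, dy/dz), `method`.
#' @export
primary_track_a <- function(record, scanner) {
  r <- data.table::as.data.table(record)
  need <- c("x_i1", "y_i1", "x_i2", "y_i2", "z_i", "scanner_x", "scanner_y")
  missing <- need[!need %in% names(r) | vapply(need, function(k)
    k %in% names(r) && anyNA(r[[k]]), logical(1))]
  .check(length(missing) == 0L, "spot record is missing MWPC field '%s'",
         if (length(missing)) missing[1] else "")
  data.table::data.table(px = (r$x_i1 + r$x_i2) / 2,
                         py = (r$y_i1 + r$y_i2) / 2,
                         pz = r$z_i,
                         ax = r$scanner_x, ay = r$scanner_y,
                         method = "a")
}

#' Primary track, method b
#'
#' Randomised variant: the origin is drawn from a Gaussian of mean
#' `(x_i, y_i)` and the MWPC-measured widths `(sigma_x_i, sigma_y_i)`; the
#' slopes receive a random multiple-Coulomb-scattering contribution with the
#' Highland angle accumulated in quadrature over the material layers the
#' primary traverses up to its planned voxel. With zero widths and
#' `scattering = FALSE` it degenerates exactly to method a.
#'
#' @inheritParams primary_track_a
#' @param phantom an [phantom_geometry()] (for the layer materials).
#' @param model a [range_model()] (for the primary momentum).
#' @param n number of randomised draws (default 1).
#' @param seed optional RNG seed.
#' @param scattering logical, add the Highland slope randomisation.
#' @param offset motion offset in mm for the layer query (default 0).
#' @return `data.table` of `n` rows, columns as [primary_track_a()].
#' @export
primary_track_b <- function(record, scanner, phantom, model, n = 1,
                            seed = NULL, scattering = TRUE, offset = 0) {
  if (!is.null(seed)) set.seed(seed)
  a <- primary_track_a(record, scanner)
  r <- data.table::as.data.table(record)
  sx <- r$sigma_x_i; sy <- r$sigma_y_i
  th <- 0
  if (scattering) {
    # carbon pbc: A = 12, Z = 6; pbc per nucleon times A over charge z
    e_kin <- r$energy
    m_u <- 931.494
    pbc_per_u <- e_kin * (e_kin + 2 * m_u) / (e_kin + m_u)
    pbc <- 12 * pbc_per_u
    segs <- path_segments(phantom, c(a$px, a$py, a$pz),
                          c(a$ax, a$ay, 1), offset = offset)
    x0 <- vapply(phantom$materials, `[[`, numeric(1), "x0")
    th2 <- sum(highland_sigma(pbc, 6, segs$length / x0[segs$material])^2)
    th <- sqrt(th2)
  }
  data.table::data.table(
    px = stats::rnorm(n, a$px, sx), py = stats::rnorm(n, a$py, sy),
    pz = a$pz,
    ax = a$ax + stats::rnorm(n, 0, th), ay = a$ay + stats::rnorm(n, 0, th),
    method = "b")
}

#' Closest approach of two 3D lines
#'
#' Returns the midpoint of the shortest segment joining the two lines and
#' its length (the distance of closest approach). For parallel lines the
#' midpoint is taken at the projection of the first line's origin onto the
#' second line.
#'
#' @param p1,d1 point and direction of line 1 (length-3 vectors).
#' @param p2,d2 point and direction of line 2.
#' @return list with `midpoint` (length-3) and `dca` (mm).
#' @export
closest_approach <- function(p1, d1, p2, d2) {
  .check(sum(d1^2) > 0 && sum(d2^2) > 0, "directions must be non-zero")
  out <- closest_approach_many(matrix(p1, 1), matrix(d1, 1),
                               matrix(p2, 1), matrix(d2, 1))
  list(midpoint = c(out$mx, out$my, out$mz), dca = out$dca)
}

#' Vectorised closest approach
#'
#' @param p1,d1,p2,d2 n x 3 matrices of points and directions.
#' @return `data.table` with `mx`, `my`, `mz`, `dca`.
#' @export
closest_approach_many <- function(p1, d1, p2, d2) {
  n1 <- sqrt(rowSums(d1^2)); n2 <- sqrt(rowSums(d2^2))
  d1 <- d1 / n1; d2 <- d2 / n2
  w <- p1 - p2
  b <- rowSums(d1 * d2)
  d_w1 <- rowSums(d1 * w)
  d_w2 <- rowSums(d2 * w)
  den <- 1 - b^2
  par <- den < 1e-12
  t1 <- ifelse(par, 0, (b * d_w2 - d_w1) / den)
  t2 <- ifelse(par, d_w2, (d_w2 - b * d_w1) / den)
  q1 <- p1 + d1 * t1
  q2 <- p2 + d2 * t2
  mid <- (q1 + q2) / 2
  data.table::data.table(mx = mid[, 1], my = mid[, 2], mz = mid[, 3],
                         dca = sqrt(rowSums((q1 - q2)^2)))
}

#' Reconstruct the vertex distribution of a run
#'
#' Pairs every secondary track with the (single, per-spot) primary track of
#' its associated beam spot, computes the closest-approach vertex, and keeps
#' vertices passing the distance-of-closest-approach cut and the aquarium z
#' filter.
#'
#' @param tracks secondary tracks ([build_tracks()] output) with a
#'   `spot_index` column (from truth bookkeeping or
#'   [associate_frames_to_spots()]).
#' @param spot_log the nozzle spot log of the run.
#' @param scanner a [scanner_geometry()].
#' @param method `"a"` or `"b"`.
#' @param phantom,model needed for method b.
#' @param dca_max DCA acceptance cut in mm (default 5).
#' @param z_range aquarium z extent, mm (default c(-130, 130)).
#' @param seed seed for the method-b randomisation.
#' @param scattering passed to [primary_track_b()].
#' @return `data.table` of vertices: `spot_index`, `arm`, `method`, `x_mm`,
#'   `y_mm`, `z_mm`, `dca_mm`, `fragment_id`.
#' @export
reconstruct_vertices <- function(tracks, spot_log, scanner, method = "a",
                                 phantom = NULL, model = NULL,
                                 dca_max = 5, z_range = c(-130, 130),
                                 seed = NULL, scattering = TRUE) {
  tr <- data.table::as.data.table(tracks)
  tr <- tr[!is.na(spot_index)]
  if (nrow(tr) == 0L) {
    return(data.table::data.table(spot_index = integer(), arm = integer(),
                                  method = character(), x_mm = numeric(),
                                  y_mm = numeric(), z_mm = numeric(),
                                  dca_mm = numeric(),
                                  fragment_id = integer()))
  }
  sl <- data.table::as.data.table(spot_log)
  if (method == "a") {
    prim <- sl[, primary_track_a(.SD, scanner), by = "spot_index"]
  } else {
    .check(!is.null(phantom) && !is.null(model),
           "method b needs phantom and model")
    if (!is.null(seed)) set.seed(seed)
    prim <- sl[, primary_track_b(.SD, scanner, phantom, model, n = 1,
                                 scattering = scattering),
               by = "spot_index"]
  }
  m <- prim[tr, on = "spot_index"]
  p1 <- cbind(m$px, m$py, m$pz)
  d1 <- cbind(m$ax, m$ay, rep(1, nrow(m)))
  p2 <- cbind(m$i.px, m$i.py, m$i.pz)
  d2 <- cbind(m$dx, m$dy, m$dz)
  ca <- closest_approach_many(p1, d1, p2, d2)
  out <- data.table::data.table(spot_index = m$spot_index, arm = m$arm,
                                method = method,
                                x_mm = ca$mx, y_mm = ca$my, z_mm = ca$mz,
                                dca_mm = ca$dca, fragment_id = m$fragment_id)
  out[dca_mm <= dca_max & z_mm >= z_range[1] & z_mm <= z_range[2]]
}

#' Computed vertex position in z (distribution quantile)
#'
#' The smallest sample z at which the empirical cumulative fraction of the
#' vertex distribution reaches `q` (sorted-sample convention, no
#' interpolation).
#'
#' @param z vertex z positions, mm.
#' @param q integral fraction in `[0.5, 1]`.
#' @return z position in mm (NA for an empty distribution).
#' @export
computed_vertex_z <- function(z, q) {
  .check(q >= 0.5 && q <= 1, "q must be in [0.5, 1]")
  n <- length(z)
  if (n == 0L) return(NA_real_)
  sort(z)[ceiling(q * n)]
}

#' Per-spot computed vertices of a run
#'
#' Means of x and y, the q-quantile of z, the vertex count and the validity
#' flag (at least `min_vertices` reconstructed vertices).
#'
#' @param vertices vertex table from [reconstruct_vertices()].
#' @param q integral fraction for the z summary.
#' @param min_vertices validity threshold (default 50).
#' @return `data.table`: `spot_index`, `n`, `vx`, `vy`, `vz`, `valid`.
#' @export
computed_vertex <- function(vertices, q, min_vertices = 50) {
  v <- data.table::as.data.table(vertices)
  out <- v[, list(n = .N, vx = mean(x_mm), vy = mean(y_mm),
                  vz = computed_vertex_z(z_mm, q)),
           by = "spot_index"]
  out[, valid := n >= min_vertices]
  out[order(spot_index)]
}

#' Select the z integral fraction maximising static contrast
#'
#' Scans `q` over a grid and returns the value maximising the mean absolute
#' per-spot difference of the computed vertex z between the static_in and
#' static_out reference runs (ties broken toward smaller q). Only spots
#' valid in both runs enter the mean.
#'
#' @param vertices_in,vertices_out vertex tables of the two static runs
#'   (lists of tables are pooled per spot across repeats).
#' @param q_grid candidate fractions (default 0.5 to 1 in steps of 0.05).
#' @param min_vertices validity threshold.
#' @return list with `q` (selected fraction) and `score` (`data.table` of
#'   the mean absolute difference per candidate).
#' @export
choose_q <- function(vertices_in, vertices_out,
                     q_grid = seq(0.5, 1, by = 0.05), min_vertices = 50) {
  pool <- function(v) {
    if (data.table::is.data.table(v) || is.data.frame(v)) {
      data.table::as.data.table(v)
    } else data.table::rbindlist(v)
  }
  vin <- pool(vertices_in); vout <- pool(vertices_out)
  score <- vapply(q_grid, function(q) {
    ci <- computed_vertex(vin, q, min_vertices)[valid == TRUE]
    co <- computed_vertex(vout, q, min_vertices)[valid == TRUE]
    m <- ci[co, on = "spot_index", nomatch = NULL]
    if (nrow(m) == 0L) return(NA_real_)
    mean(abs(m$vz - m$i.vz))
  }, numeric(1))
  .check(any(is.finite(score)), "no valid spots in either static case")
  best <- q_grid[which.max(replace(score, !is.finite(score), -Inf))]
  list(q = best,
       score = data.table::data.table(q = q_grid, mean_abs_diff = score))
}

#' Vertex file I/O
#'
#' @param vertices vertex table.
#' @param file CSV path (`spot,arm,method,x_mm,y_mm,z_mm,dca_mm`).
#' @export
write_vertices <- function(vertices, file) {
  data.table::fwrite(data.table::as.data.table(vertices), file)
  invisible(file)
}

#' @rdname write_vertices
#' @export
read_vertices <- function(file) {
  data.table::fread(file, showProgress = FALSE)
}
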
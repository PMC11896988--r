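# Respiratory motion of the phantom table: a Lujan-type 1D trace along x,
# the three-phase amplitude binning, and motor logfile generation / parsing.

#' Lujan motion parameters
#'
#' The table position follows \eqn{x(t) = A \sin^{2n}(\pi (t - t_0) / \tau)},
#' i.e. the classic Lujan breathing trace phased so that motion starts at the
#' in-position (0 mm) when the delivery trigger fires at `start_time`.
#'
#' @param amplitude peak-to-trough amplitude A in mm (default 20).
#' @param period breathing period tau in s (default 3).
#' @param n positive integer exponent; the trace is sin^(2n) (default 2,
#'   the cos^4-shaped cycle).
#' @param start_time trigger time t0 in s (default 0).
#' @return an object of class `lujan_params`.
#' @export
lujan_params <- function(amplitude = 20, period = 3, n = 2, start_time = 0) {
  .check(amplitude >= 0, "amplitude must be >= 0")
  .check(period > 0, "period must be > 0")
  .check(n >= 1 && n == round(n), "n must be a positive integer")
  structure(list(amplitude = amplitude, period = period, n = as.integer(n),
                 start_time = start_time),
            class = "lujan_params")
}

#' Table position at time t
#'
#' @param t time(s) in s; must be `>= start_time` (motion is not triggered
#'   before that).
#' @param params a [lujan_params()] object.
#' @return position(s) in mm, in `[0, amplitude]`.
#' @export
lujan_position <- function(t, params) {
  .check(all(t >= params$start_time - 1e-12),
         "motion not yet triggered: t < start_time")
  s <- sin(pi * (t - params$start_time) / params$period)
  params$amplitude * s^(2L * params$n)
}

#' Motion phase bins
#'
#' @param edges increasing numeric vector of 4 bin edges in mm; the default
#'   `c(0, 3, 17, 20)` defines Phase 1 = [0, 3), Phase 2 = [3, 17),
#'   Phase 3 = [17, 20].
#' @return numeric vector of edges (class `phase_bins`).
#' @export
phase_bins <- function(edges = c(0, 3, 17, 20)) {
  .check(length(edges) >= 2 && all(diff(edges) > 0),
         "edges must be strictly increasing")
  .check(edges[1] == 0, "first edge must be 0")
  structure(edges, class = "phase_bins")
}

#' Assign a motion phase to a position
#'
#' Half-open bins, top edge closed; positions outside `[0, max(edges)]` are
#' clamped.
#'
#' @param x position(s) in mm.
#' @param bins a [phase_bins()] vector.
#' @return integer phase index (1-based) per position.
#' @export
phase_of <- function(x, bins = phase_bins()) {
  e <- unclass(bins)
  x <- pmin(pmax(x, e[1]), e[length(e)])
  idx <- findInterval(x, e, rightmost.closed = TRUE)
  pmin(idx, length(e) - 1L)
}

#' Time-occupancy fractions of the motion phases
#'
#' Samples spot times uniformly over `n_periods` breathing cycles, evaluates
#' the Lujan position at each, and bins the positions into phases. This is
#' the fraction of beam spots expected to be delivered in each phase when
#' delivery timing is unsynchronised with breathing.
#'
#' @param params a [lujan_params()] object.
#' @param bins a [phase_bins()] vector.
#' @param n_samples number of sampled times (default 1e5).
#' @param seed optional RNG seed.
#' @param n_periods number of breathing periods spanned (default 100).
#' @return numeric vector of fractions, one per phase, summing to 1.
#' @export
phase_time_fractions <- function(params, bins = phase_bins(),
                                 n_samples = 1e5, seed = NULL,
                                 n_periods = 100) {
  if (!is.null(seed)) set.seed(seed)
  t <- params$start_time +
    stats::runif(n_samples, 0, n_periods * params$period)
  ph <- phase_of(lujan_position(t, params), bins)
  tabulate(ph, nbins = length(bins) - 1L) / n_samples
}

#' Generate a motor logfile
#'
#' Samples the Lujan trace at fixed `dt` from the trigger, optionally adding
#' a linear positioning drift reaching `drift` mm at the end of the run plus
#' uniform jitter of a tenth of the drift. Positions are quantised to 1e-6 mm
#' so that writing and re-reading the log is lossless.
#'
#' @param params a [lujan_params()] object.
#' @param duration run length in s.
#' @param dt sampling interval in s (default 1e-4, the ~100 us motor
#'   resolution).
#' @param drift total linear drift in mm reached at `duration` (default 0).
#' @param seed optional RNG seed (used only when `drift > 0`).
#' @return a `data.table` with columns `time_s`, `position_mm`
#'   (class `motor_log`).
#' @export
motor_log <- function(params, duration, dt = 1e-4, drift = 0, seed = NULL) {
  .check(duration > 0, "duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(params$start_time, params$start_time + duration, by = dt)
  pos <- lujan_position(t, params)
  if (drift != 0) {
    frac <- (t - t[1]) / duration
    pos <- pos + drift * frac +
      stats::runif(length(t), -abs(drift) / 10, abs(drift) / 10) * frac
  }
  log <- data.table::data.table(time_s = round(t, 6),
                                position_mm = round(pos, 6))
  class(log) <- c("motor_log", class(log))
  log
}

#' @rdname motor_log
#' @param log a `motor_log` table.
#' @param file path of the CSV logfile (`time_s,position_mm` header,
#'   6-decimal fixed format).
#' @export
write_motor_log <- function(log, file) {
  lines <- c("time_s,position_mm",
             sprintf("%.6f,%.6f", log$time_s, log$position_mm))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname motor_log
#' @export
read_motor_log <- function(file) {
  header <- readLines(file, n = 1L)
  .check(identical(header, "time_s,position_mm"),
         "malformed motor log header at line 1: '%s'", header)
  log <- data.table::fread(file, colClasses = list(character = 1:2),
                           showProgress = FALSE)
  log <- data.table::data.table(
    time_s = suppressWarnings(as.numeric(log[[1]])),
    position_mm = suppressWarnings(as.numeric(log[[2]])))
  bad <- which(!stats::complete.cases(log))
  .check(length(bad) == 0L, "malformed motor log row at line %d",
         if (length(bad)) bad[1] + 1L else 0L)
  .check(all(diff(log$time_s) > 0), "motor log times must strictly increase")
  class(log) <- c("motor_log", class(log))
  log
}

#' Interpolate motor position at arbitrary times
#'
#' @param log a `motor_log` table.
#' @param t time(s) in s within the log span.
#' @return position(s) in mm, linearly interpolated.
#' @export
motor_position_at <- function(log, t) {
  stats::approx(log$time_s, log$position_mm, xout = t, rule = 2)$y
}
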
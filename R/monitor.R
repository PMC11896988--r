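# 4D monitoring decision layer: repeat-based thresholds, per-spot
# differences of the computed vertex against the static references,
# delivered-as-planned classification with efficiency against the motor
# truth, edge-spot selection and motion-phase assignment.

#' Threshold from repeated static measurements
#'
#' For every spot, the per-repeat difference of the computed vertex z
#' between paired static_in and static_out runs is formed; `thr_diff` is
#' `mult` times the RMS of that difference about its per-spot mean (the
#' repeat variability). With `pooled = TRUE` (default) the RMS is pooled
#' over all spots; otherwise a per-spot threshold is returned.
#'
#' @param cv_in,cv_out lists (length = number of repeats) of per-spot
#'   computed-vertex tables ([computed_vertex()]); repeats are paired by
#'   position.
#' @param mult threshold multiplier (default 2, i.e. thr = 2 RMS).
#' @param pooled pool the repeat variability across spots (default TRUE).
#' @return `data.table` with `spot_index`, `thr_diff`, `rms_diff`,
#'   `uncertainty` (quadrature sum of the per-case repeat RMS of vz) and
#'   `mean_diff`; the pooled threshold is attached as attribute `"pooled"`
#'   and used for every spot when `pooled = TRUE`.
#' @export
thr_from_repeats <- function(cv_in, cv_out, mult = 2, pooled = TRUE) {
  .check(length(cv_in) >= 2 && length(cv_out) >= 2,
         "need at least 2 repeats per static case")
  .check(length(cv_in) == length(cv_out), "unpaired repeat lists")
  stack <- function(lst, tag) {
    data.table::rbindlist(lapply(seq_along(lst), function(r) {
      v <- data.table::as.data.table(lst[[r]])[valid == TRUE]
      v[, list(spot_index, rep = r, vz)]
    }))
  }
  si <- stack(cv_in); so <- stack(cv_out)
  m <- si[so, on = c("spot_index", "rep"), nomatch = NULL]
  d <- m[, list(diff = vz - i.vz), by = list(spot_index, rep)]
  per <- d[, list(mean_diff = mean(diff), rms_diff = .rms(diff),
                  n_rep = .N), by = "spot_index"]
  unc_in <- si[, list(rms_in = .rms(vz)), by = "spot_index"]
  unc_out <- so[, list(rms_out = .rms(vz)), by = "spot_index"]
  per <- unc_out[unc_in[per, on = "spot_index"], on = "spot_index"]
  per[, uncertainty := sqrt(rms_in^2 + rms_out^2)]
  dev <- d$diff - ave(d$diff, d$spot_index)
  pooled_rms <- sqrt(mean(dev^2))
  per[, thr_diff := if (pooled) mult * pooled_rms else mult * rms_diff]
  data.table::setattr(per, "pooled", mult * pooled_rms)
  per[order(spot_index)]
}

#' Delivered-as-planned classification
#'
#' A spot is "planned" when its `difference_in` does not exceed the
#' threshold (boundary equality counts as planned).
#'
#' @param difference_in absolute difference of the computed vertex z between
#'   the moving and static_in case, mm.
#' @param thr_diff threshold in mm (scalar or per spot).
#' @return factor with levels `planned`, `not_planned`.
#' @export
classify_delivery <- function(difference_in, thr_diff) {
  .check(all(is.finite(difference_in)) && all(is.finite(thr_diff)),
         "differences and threshold must be finite")
  factor(ifelse(abs(difference_in) <= thr_diff, "planned", "not_planned"),
         levels = c("planned", "not_planned"))
}

#' Select edge spots at the spherical target boundary
#'
#' Spots inside a shell of `slice` mm following the spherical end of the
#' target, restricted to `x_v > x_min` and `y_v < y_max` — the region where
#' lateral motion sweeps the PMMA/foam density edge through the beam.
#'
#' @param plan an `ivi_plan`.
#' @param sphere_radius PMMA sphere radius in mm (default 25).
#' @param slice shell thickness in mm (default 6).
#' @param x_min,y_max lateral selection cuts in mm (defaults 5 and 0).
#' @return integer vector of selected `spot_index`.
#' @export
select_edge_spots <- function(plan, sphere_radius = 25, slice = 6,
                              x_min = 5, y_max = 0) {
  p <- data.table::as.data.table(plan)
  r <- sqrt(p$x_v^2 + p$y_v^2 + p$z_v^2)
  sel <- p$x_v > x_min & p$y_v < y_max &
    r >= sphere_radius - slice & r <= sphere_radius
  p$spot_index[sel]
}

#' Ground-truth delivery category from the motor position
#'
#' @param motor_mm motor position at the spot time, mm.
#' @param pos_m motor-position interval parameter in mm (0.5 - 3.5): spots
#'   with `|motor| < pos_m` are truly "planned" (phantom close to the
#'   in-position), others truly "not_planned".
#' @return factor with levels `planned`, `not_planned`.
#' @export
delivery_truth <- function(motor_mm, pos_m) {
  .check(all(pos_m >= 0.5 & pos_m <= 3.5), "pos_m must lie in [0.5, 3.5] mm")
  factor(ifelse(abs(motor_mm) < pos_m, "planned", "not_planned"),
         levels = c("planned", "not_planned"))
}

#' Total classification efficiency
#'
#' Percentage of spots whose delivered-as-planned call matches the
#' motor-truth category.
#'
#' @param calls factor from [classify_delivery()].
#' @param truth factor from [delivery_truth()] (same length).
#' @return percentage in `[0, 100]` (NA when empty).
#' @export
total_efficiency <- function(calls, truth) {
  .check(length(calls) == length(truth), "calls and truth differ in length")
  ok <- !is.na(calls) & !is.na(truth)
  if (!any(ok)) return(NA_real_)
  100 * mean(calls[ok] == truth[ok])
}

#' Motion-phase assignment from the two static differences
#'
#' Four-case rule: `difference_in` below threshold and `difference_out`
#' above gives Phase 1 (similar to static_in); the opposite gives Phase 3;
#' both above gives Phase 2 (in-between state); both below is undefined.
#' Boundary equality counts as "below".
#'
#' @param difference_in,difference_out absolute computed-vertex differences
#'   of the moving case against the static_in / static_out references, mm.
#' @param thr_diff threshold in mm (scalar or per spot).
#' @return factor with levels `undefined`, `Phase1`, `Phase2`, `Phase3`.
#' @export
assign_phase <- function(difference_in, difference_out, thr_diff) {
  .check(all(is.finite(difference_in)) && all(is.finite(difference_out)) &&
           all(is.finite(thr_diff)), "inputs must be finite")
  below_in <- abs(difference_in) <= thr_diff
  below_out <- abs(difference_out) <= thr_diff
  out <- ifelse(below_in & !below_out, "Phase1",
         ifelse(!below_in & below_out, "Phase3",
         ifelse(!below_in & !below_out, "Phase2", "undefined")))
  factor(out, levels = c("undefined", "Phase1", "Phase2", "Phase3"))
}

#' Phase confusion matrix
#'
#' Rows are the true motion phases (from the motor position), columns the
#' assigned calls; each row is normalised to 100%. Planned-overshoot spots
#' (given via `exclude`) are removed before normalisation.
#'
#' @param calls factor from [assign_phase()].
#' @param truth_phase integer truth phases (1-3, from [phase_of()] of the
#'   motor position at the spot time).
#' @param exclude optional logical vector flagging spots to drop.
#' @return matrix of percentages, rows `Phase1..3`, columns `undefined`,
#'   `Phase1..3`.
#' @export
phase_confusion <- function(calls, truth_phase, exclude = NULL) {
  .check(length(calls) == length(truth_phase),
         "calls and truth differ in length")
  keep <- !is.na(calls) & !is.na(truth_phase)
  if (!is.null(exclude)) keep <- keep & !exclude
  calls <- calls[keep]
  truth <- factor(paste0("Phase", truth_phase[keep]),
                  levels = c("Phase1", "Phase2", "Phase3"))
  tab <- table(truth, calls)
  pct <- 100 * prop.table(tab, margin = 1)
  pct[is.nan(pct)] <- 0
  as.matrix(unclass(pct))
}
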
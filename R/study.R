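# End-to-end study orchestration: configuration, the simulate -> reconstruct
# -> analyze chain over the three experimental cases and N repeats, and
# reporting.

#' Study configuration
#'
#' Assembles all module parameter blocks with their defaults into one
#' validated configuration. Every random stage of the study derives its own
#' seed from the master seed, so a configuration plus seed fully determines
#' the outputs.
#'
#' @param phantom,model,scanner,tracker,fp,motion parameter objects; see
#'   [phantom_geometry()], [range_model()], [scanner_geometry()],
#'   [tracker_geometry()], [frag_params()], [lujan_params()].
#' @param plan_args list of arguments for [generate_spherical_plan()]
#'   (spacing, margins, spot weights).
#' @param intensity,inter_spot_gap,inter_layer_gap delivery timing, see
#'   [delivery_timeline()].
#' @param cases experimental cases to simulate.
#' @param repeats number of repeated deliveries per case (default 5).
#' @param method vertex reconstruction method, `"a"` or `"b"`.
#' @param dca_max,min_vertices,q_grid reconstruction/summary settings.
#' @param thr_mult threshold multiplier (default 2).
#' @param motion_sign table-mounting sign mapping motor positions to
#'   beam-frame offsets (see [simulate_delivery()]).
#' @param pos_m motor-position interval parameters scanned for the
#'   efficiency report, mm.
#' @param bins motion [phase_bins()].
#' @return validated list of class `ivi_config`.
#' @export
ivi_config <- function(phantom = phantom_geometry(),
                       model = range_model(),
                       scanner = scanner_geometry(),
                       tracker = tracker_geometry(),
                       fp = frag_params(),
                       motion = lujan_params(),
                       plan_args = list(spot_spacing = 5,
                                        layer_spacing_wepl = 4),
                       intensity = 2e7, inter_spot_gap = 2e-3,
                       inter_layer_gap = 1,
                       cases = c("static_in", "static_out", "moving"),
                       repeats = 5, method = "a",
                       dca_max = 5, min_vertices = 50,
                       q_grid = seq(0.5, 1, by = 0.05),
                       thr_mult = 2, motion_sign = -1,
                       pos_m = seq(0.5, 3.5, by = 0.5),
                       bins = phase_bins()) {
  .check(inherits(phantom, "ivi_phantom"), "invalid config field 'phantom'")
  .check(inherits(model, "range_model"), "invalid config field 'model'")
  .check(inherits(scanner, "scanner_geometry"),
         "invalid config field 'scanner'")
  .check(inherits(tracker, "tracker_geometry"),
         "invalid config field 'tracker'")
  .check(inherits(fp, "frag_params"), "invalid config field 'fp'")
  .check(inherits(motion, "lujan_params"), "invalid config field 'motion'")
  .check(repeats >= 1, "invalid config field 'repeats': need >= 1")
  .check(method %in% c("a", "b"), "invalid config field 'method'")
  .check(all(cases %in% c("static_in", "static_out", "moving")),
         "invalid config field 'cases'")
  structure(list(phantom = phantom, model = model, scanner = scanner,
                 tracker = tracker, fp = fp, motion = motion,
                 plan_args = plan_args, intensity = intensity,
                 inter_spot_gap = inter_spot_gap,
                 inter_layer_gap = inter_layer_gap, cases = cases,
                 repeats = repeats, method = method, dca_max = dca_max,
                 min_vertices = min_vertices, q_grid = q_grid,
                 thr_mult = thr_mult, motion_sign = motion_sign,
                 pos_m = pos_m, bins = bins),
            class = "ivi_config")
}

#' Reconstruct the vertex distribution of one simulated run
#'
#' Builds secondary tracks from the run's clusters, associates their frames
#' to beam spots through the delivery timeline (the FPGA timing surrogate),
#' and reconstructs the per-spot vertex distribution.
#'
#' @param run an `ivi_run` from [simulate_delivery()].
#' @param config an [ivi_config()].
#' @param seed seed for the method-b randomisation.
#' @return vertex table (see [reconstruct_vertices()]).
#' @export
reconstruct_run <- function(run, config, seed = 1L) {
  tracks <- build_tracks(run$clusters, config$tracker)
  if (nrow(tracks) == 0L) {
    return(reconstruct_vertices(tracks, run$spot_log, config$scanner))
  }
  tracks[, spot_index := associate_frames_to_spots(
    frame, run$timeline, config$tracker$frame_dt)]
  reconstruct_vertices(tracks, run$spot_log, config$scanner,
                       method = config$method, phantom = config$phantom,
                       model = config$model, dca_max = config$dca_max,
                       z_range = c(-config$phantom$half_outer[3],
                                   config$phantom$half_outer[3]),
                       seed = seed)
}

#' Run a complete monitoring study
#'
#' Simulates `repeats` deliveries of the plan for each experimental case,
#' reconstructs all vertex distributions, selects the z integral fraction on
#' the static references, derives the repeat-based threshold, classifies
#' every moving-case spot (delivered as planned / not) against the motor
#' truth for each `pos_m`, and assigns motion phases.
#'
#' @param config an [ivi_config()].
#' @param seed master seed.
#' @param out_dir optional directory; when given, logfiles, vertices and the
#'   JSON summary are written beneath it.
#' @param progress print per-run progress lines (default FALSE).
#' @param plan optional pre-built `ivi_plan` (e.g. a single iso-energy layer
#'   extracted from the 3D plan); defaults to generating the spherical plan
#'   from the config.
#' @param analyze run the decision-layer analysis (default TRUE; requires
#'   both static cases). With `FALSE` only simulation and vertex
#'   reconstruction are performed and the per-run vertex tables returned.
#' @return object of class `ivi_study`: list with `plan`, `config`, `q`,
#'   `thr`, `computed` (per case/repeat computed vertices), `diffs`
#'   (per-spot per-repeat differences and calls), `efficiency` (per pos_m),
#'   `confusion`, `confusion_edge`, `phase_occupancy`, `summary`.
#' @export
run_study <- function(config = ivi_config(), seed = 1L, out_dir = NULL,
                      progress = FALSE, plan = NULL, analyze = TRUE) {
  if (is.null(plan)) {
    plan <- do.call(generate_spherical_plan,
                    c(list(phantom = config$phantom, model = config$model),
                      config$plan_args))
  }
  runs <- list(); vdists <- list()
  for (case in config$cases) {
    for (r in seq_len(config$repeats)) {
      run_seed <- seed_chain(seed, match(case, c("static_in", "static_out",
                                                 "moving")), r)
      run <- simulate_delivery(
        plan, case, config$phantom, config$model, config$scanner,
        config$tracker, config$fp, config$motion, config$intensity,
        config$inter_spot_gap, config$inter_layer_gap, seed = run_seed,
        motion_sign = config$motion_sign)
      vd <- reconstruct_run(run, config, seed = seed_chain(run_seed, 99L))
      key <- paste(case, r, sep = ".")
      vdists[[key]] <- vd
      runs[[key]] <- run["truth"]
      if (progress) {
        message(sprintf("%s repeat %d: %d vertices over %d spots",
                        case, r, nrow(vd),
                        data.table::uniqueN(vd$spot_index)))
      }
      if (!is.null(out_dir)) .write_bundle(run, vd, out_dir, case, r)
    }
  }
  if (!analyze) {
    return(structure(list(plan = plan, config = config, vdists = vdists,
                          runs = runs, seed = seed),
                     class = "ivi_study_raw"))
  }
  st <- analyze_study(plan, vdists, runs, config)
  st$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(st$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  st
}

.write_bundle <- function(run, vd, out_dir, case, r) {
  d <- file.path(out_dir, sprintf("%s_rep%d", case, r))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_spot_log(run$spot_log, file.path(d, "spot_log.csv"))
  write_fpga_log(run$fpga_log, file.path(d, "fpga_log.csv"))
  if (!is.null(run$motor_log)) {
    write_motor_log(run$motor_log, file.path(d, "motor_log.csv"))
  }
  write_clusters(run$clusters, file.path(d, "clusters.csv"))
  data.table::fwrite(run$truth, file.path(d, "truth.csv"))
  write_vertices(vd, file.path(d, "vertices.csv"))
  invisible(d)
}

#' Analyse reconstructed vertex distributions of a study
#'
#' The analysis half of [run_study()], usable on pre-simulated bundles.
#'
#' @param plan the delivered `ivi_plan`.
#' @param vdists named list (`"case.repeat"`) of vertex tables.
#' @param runs named list of per-run truth (lists with a `truth` table).
#' @param config an [ivi_config()].
#' @return `ivi_study` object (see [run_study()]).
#' @export
analyze_study <- function(plan, vdists, runs, config) {
  keys <- names(vdists)
  kcase <- sub("\\.[0-9]+$", "", keys)
  vin <- vdists[kcase == "static_in"]
  vout <- vdists[kcase == "static_out"]
  vmov <- vdists[kcase == "moving"]
  .check(length(vin) >= 1 && length(vout) >= 1,
         "study needs both static cases")
  qsel <- choose_q(vin, vout, config$q_grid, config$min_vertices)
  cv <- lapply(vdists, computed_vertex, q = qsel$q,
               min_vertices = config$min_vertices)
  cv_in <- cv[kcase == "static_in"]; cv_out <- cv[kcase == "static_out"]
  cv_mov <- cv[kcase == "moving"]
  thr <- thr_from_repeats(cv_in, cv_out, mult = config$thr_mult)
  thr_pooled <- attr(thr, "pooled")
  ref <- function(lst) {
    data.table::rbindlist(lst)[valid == TRUE,
                               list(vz_ref = mean(vz), n_rep = .N),
                               by = "spot_index"]
  }
  ref_in <- ref(cv_in); ref_out <- ref(cv_out)
  # per-repeat moving differences and calls
  diffs <- data.table::rbindlist(lapply(seq_along(cv_mov), function(r) {
    v <- cv_mov[[r]][valid == TRUE]
    key <- names(vmov)[r]
    tru <- runs[[key]]$truth
    m <- ref_out[ref_in[v, on = "spot_index", nomatch = NULL],
                 on = "spot_index", nomatch = NULL]
    m <- tru[m, on = "spot_index", nomatch = NULL]
    m[, list(spot_index, rep = r, vz, motor_mm,
             difference_in = abs(vz - i.vz_ref),
             difference_out = abs(vz - vz_ref))]
  }))
  st <- list(plan = plan, config = config, q = qsel$q,
             q_score = qsel$score, thr = thr, thr_pooled = thr_pooled,
             computed = cv, diffs = diffs)
  if (nrow(diffs) > 0) {
    diffs[, call := classify_delivery(difference_in, thr_pooled)]
    diffs[, phase_call := assign_phase(difference_in, difference_out,
                                       thr_pooled)]
    diffs[, truth_phase := phase_of(motor_mm, config$bins)]
    eff <- data.table::rbindlist(lapply(config$pos_m, function(pm) {
      per_rep <- diffs[, list(eff = total_efficiency(
        call, delivery_truth(motor_mm, pm))), by = "rep"]
      data.table::data.table(pos_m = pm, mean_eff = mean(per_rep$eff),
                             rms_eff = .rms(per_rep$eff))
    }))
    edge <- select_edge_spots(plan, sphere_radius = config$phantom$r_insert)
    planned_overshoot <- planned_overshoot_spots(plan, config$phantom)
    excl <- diffs$spot_index %in% planned_overshoot
    st$efficiency <- eff
    st$edge_spots <- edge
    st$confusion <- phase_confusion(diffs$phase_call, diffs$truth_phase,
                                    exclude = excl)
    is_edge <- diffs$spot_index %in% edge
    st$confusion_edge <- if (any(is_edge & !excl)) {
      phase_confusion(diffs$phase_call[is_edge], diffs$truth_phase[is_edge],
                      exclude = excl[is_edge])
    } else NULL
    st$phase_occupancy <- as.vector(
      table(factor(diffs$truth_phase, levels = 1:3))) / nrow(diffs)
  }
  st$summary <- .study_summary(st)
  class(st) <- "ivi_study"
  st
}

.study_summary <- function(st) {
  s <- list(
    n_spots = nrow(st$plan),
    n_layers = length(unique(st$plan$layer)),
    energy_range = range(st$plan$energy),
    q_selected = st$q,
    thr_diff_mm = st$thr_pooled,
    repeats = st$config$repeats
  )
  if (!is.null(st$efficiency)) {
    s$efficiency <- st$efficiency
    s$phase_occupancy_pct <- round(100 * st$phase_occupancy, 1)
    s$confusion_pct <- round(st$confusion, 1)
    if (!is.null(st$confusion_edge)) {
      s$confusion_edge_pct <- round(st$confusion_edge, 1)
    }
  }
  s
}

#' Spots that miss the PMMA insert by plan
#'
#' "Planned overshoot": spots whose planned central ray does not intersect
#' the PMMA insert at zero motion offset; these never probe the density
#' edge and are excluded from phase scoring.
#'
#' @param plan an `ivi_plan`.
#' @param phantom an [phantom_geometry()].
#' @return integer vector of `spot_index`.
#' @export
planned_overshoot_spots <- function(plan, phantom) {
  p <- data.table::as.data.table(plan)
  rho2 <- p$x_v^2 + p$y_v^2
  p$spot_index[rho2 > phantom$r_insert^2]
}

#' @export
print.ivi_study <- function(x, ...) {
  cat("ivi_study:", nrow(x$plan), "spots,", x$config$repeats,
      "repeats; q* =", x$q, "; thr_diff =",
      round(x$thr_pooled, 2), "mm\n")
  if (!is.null(x$efficiency)) {
    cat("  total efficiency (pos_m sweep):",
        paste(sprintf("%.1f%%", x$efficiency$mean_eff), collapse = " "),
        "\n")
  }
  invisible(x)
}
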
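w <- tiny_world()

test_that("Highland angle hits its closed-form landmarks", {
  expect_equal(highland_sigma(13.6, 1, 1), 1)     # log term vanishes
  expect_equal(highland_sigma(100, 1, 0), 0)      # continuity at zero
  expect_lt(highland_sigma(100, 1, 1e-12), 1e-4)
  # 150 MeV proton through 1% of a radiation length: ~4.0 mrad
  e <- 150; m <- 938.272
  pbc <- e * (e + 2 * m) / (e + m) # independent kinematics
  expect_equal(highland_sigma(pbc, 1, 0.01), 0.0040, tolerance = 0.02)
})

test_that("scattering variance accumulates in quadrature over layers", {
  pbc <- 250
  x <- 0.04
  splits <- list(c(1), c(0.5, 0.5), c(0.1, 0.3, 0.6), rep(0.25, 4))
  # the simulator adds independent per-layer Gaussian kicks, so the total
  # variance must equal the quadrature sum regardless of the split
  v <- vapply(splits, function(s)
    sum(highland_sigma(pbc, 1, x * s)^2), numeric(1))
  v_pairwise <- vapply(splits, function(s) {
    tot <- 0
    for (xi in x * s) tot <- tot + highland_sigma(pbc, 1, xi)^2
    tot
  }, numeric(1))
  expect_equal(v, v_pairwise, tolerance = 1e-9)
  expect_true(all(v > 0))
})

test_that("no vertices in a zero-density phantom", {
  mats <- default_materials()
  mats$pmma$density <- 0; mats$foam$density <- 0
  ph0 <- phantom_geometry(materials = mats)
  sv <- sample_fragmentation_vertices(ph0, w$model, make_spot(n_planned = 5e3),
                                      0, 1e-3, function(t) rep(0, length(t)),
                                      frag_params(), seed = 2)
  expect_equal(nrow(sv$vertices), 0L)
  expect_equal(sv$truth$n_vertices, 0L)
})

test_that("vertex yield scales linearly with density (Poisson oracle)", {
  # homogeneous block: count vertices in a fixed window and compare with the
  # closed-form thinning expectation at two densities
  n <- 1e5
  fp <- frag_params()
  yield <- function(rho) {
    mats <- default_materials()
    mats$foam$density <- rho
    mats$foam$wer <- 0.01 # practically no stopping: pure thinning
    mats$pmma$wer <- 0.01
    ph <- phantom_geometry(cylinder_diameter = 1e-3, cylinder_length = 0,
                           materials = mats)
    sv <- sample_fragmentation_vertices(
      ph, w$model, make_spot(energy = 200, n_planned = n), 0, 1e-3,
      function(t) rep(0, length(t)), fp, seed = 31)
    sum(sv$vertices$z > -100 & sv$vertices$z < 0)
  }
  expect_window <- function(rho) {
    # P(vertex in foam window [-100, 0]) after 5 mm wall + 25 mm foam lead-in
    lam <- fp$lambda_w
    lead <- (5 * 1.17 + 25 * rho) / lam
    exp(-lead) * (1 - exp(-100 * rho / lam))
  }
  for (rho in c(0.2, 0.4)) {
    mu <- n * expect_window(rho)
    expect_lt(abs(yield(rho) - mu), 3 * sqrt(mu))
  }
})

test_that("no vertices beyond the stopping depth; deeper spots for misses", {
  fp <- frag_params()
  spot <- make_spot(energy = 160, n_planned = 2e4)
  sv0 <- sample_fragmentation_vertices(w$phantom, w$model, spot, 0, 1e-3,
                                       function(t) rep(0, length(t)), fp, 2)
  stop0 <- true_stop_depth(w$phantom, w$model, 0, 0, 160, 0)
  # central ions stop near stop0; allow for the lateral beam spread
  expect_lt(stats::quantile(sv0$vertices$z, 0.999), stop0 + 25)
  # spot whose ray lands in a foam-only corridor once the phantom moves out:
  # fragments (and the stopping point) reach much larger z
  spot_e <- make_spot(energy = 160, x_v = -10, n_planned = 2e4)
  svi <- sample_fragmentation_vertices(w$phantom, w$model, spot_e, 0, 1e-3,
                                       function(t) rep(0, length(t)), fp, 2)
  svo <- sample_fragmentation_vertices(w$phantom, w$model, spot_e, 0, 1e-3,
                                       function(t) rep(20, length(t)), fp, 2)
  expect_gt(stats::quantile(svo$vertices$z, 0.9),
            stats::quantile(svi$vertices$z, 0.9) + 10)
  expect_gt(svo$truth$stop_z_central, svi$truth$stop_z_central + 30)
})

test_that("fragment emission is forward-peaked with the configured spread", {
  sv <- sample_fragmentation_vertices(w$phantom, w$model,
                                      make_spot(n_planned = 2e4), 0, 1e-3,
                                      function(t) rep(0, length(t)),
                                      frag_params(), seed = 4)
  fr <- emit_fragments(sv$vertices, frag_params(), seed = 5)
  expect_equal(nrow(fr), 3L * nrow(sv$vertices)) # multiplicity
  # per-axis tangent is Gaussian with sigma_theta (KS test)
  tx <- fr$dx / fr$dz
  ks <- suppressWarnings(stats::ks.test(tx, "pnorm", 0, 0.08))
  expect_gt(ks$p.value, 1e-4)
  # mean polar angle well above any beam divergence (~3 mrad)
  polar <- atan2(sqrt(fr$dx^2 + fr$dy^2), fr$dz)
  expect_gt(mean(polar), 0.05)
  # degenerate spread: all fragments along the parent direction
  fr0 <- emit_fragments(sv$vertices, frag_params(sigma_theta = 0), seed = 5)
  expect_equal(unique(fr0$dz), 1)
  # fragments outrange the residual primary range
  expect_true(all(fr$frag_range_w >= fr$residual_wepl))
})

test_that("aimed fragment gives three collinear clusters; stopped gives none", {
  tg <- w$tracker
  aim <- function(arm, range_w) {
    ax <- tg$axes[[arm]]
    data.table::data.table(spot_index = 1L, time = 1e-4, x = 0, y = 0, z = 0,
                           depth_wepl = 10, residual_wepl = 40, offset = 0,
                           vertex_id = 1L, dx = ax$n[1], dy = ax$n[2],
                           dz = ax$n[3], frag_range_w = range_w)
  }
  cl <- propagate_to_trackers(aim(3, 1e4), w$phantom, tg,
                              scattering = FALSE, smearing = FALSE)
  expect_equal(nrow(cl), 3L)
  expect_equal(cl$arm, rep(3L, 3))
  expect_equal(cl$u_mm, rep(0, 3), tolerance = 1e-9) # on the arm axis
  expect_equal(cl$v_mm, rep(0, 3), tolerance = 1e-9)
  # range shorter than the exit path: absorbed
  cl2 <- propagate_to_trackers(aim(3, 5), w$phantom, tg,
                               scattering = FALSE, smearing = FALSE)
  expect_equal(nrow(cl2), 0L)
})

test_that("isotropic acceptance matches the solid-angle formula", {
  tg <- w$tracker
  set.seed(77)
  n <- 2e5
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  fr <- data.table::data.table(spot_index = 1L, time = 1e-4, x = 0, y = 0,
                               z = 0, depth_wepl = 0, residual_wepl = 100,
                               offset = 0, vertex_id = seq_len(n),
                               dx = s * cos(phi), dy = s * sin(phi), dz = u,
                               frag_range_w = 1e5)
  cl <- propagate_to_trackers(fr, w$phantom, tg,
                              scattering = FALSE, smearing = FALSE)
  n_det <- length(unique(cl$fragment_id))
  # per arm the 3-plane coincidence is limited by the farthest plane
  d_far <- tg$radial_mm + tg$sensor_spacing
  omega <- 4 * (2 * atan(tg$half_u / d_far)) * (2 * atan(tg$half_v / d_far))
  p_ref <- omega / (4 * pi)
  expect_lt(abs(n_det - n * p_ref), 3 * sqrt(n * p_ref) + 0.02 * n * p_ref)
})

test_that("deliveries are case-correct and bit-reproducible", {
  p <- generate_spherical_plan(w$phantom, w$model, sphere_radius = 6,
                               inner_margin = 0, spot_spacing = 6,
                               layer_spacing_wepl = 8, n_planned = 3000)
  expect_lte(nrow(p), 8)
  run_in <- simulate_delivery(p, "static_in", seed = 9)
  expect_true(all(run_in$truth$motor_mm == 0))
  run_out <- simulate_delivery(p, "static_out", seed = 9)
  expect_true(all(run_out$truth$motor_mm == 20))
  run_mv <- simulate_delivery(p, "moving", seed = 9)
  # per-spot offsets follow the motor log at spot mid-times
  tl <- run_mv$timeline
  ref <- motor_position_at(run_mv$motor_log, (tl$t_start + tl$t_end) / 2)
  expect_lt(max(abs(run_mv$truth$motor_mm - ref)), 1e-3)
  # determinism
  run_mv2 <- simulate_delivery(p, "moving", seed = 9)
  expect_equal(as.data.frame(run_mv$clusters), as.data.frame(run_mv2$clusters))
  expect_equal(as.data.frame(run_mv$truth), as.data.frame(run_mv2$truth))
  # different seed changes the observations
  run_mv3 <- simulate_delivery(p, "moving", seed = 10)
  expect_false(identical(run_mv$clusters, run_mv3$clusters))
})

test_that("cluster files round-trip", {
  p <- generate_spherical_plan(w$phantom, w$model, sphere_radius = 6,
                               inner_margin = 0, spot_spacing = 6,
                               layer_spacing_wepl = 8, n_planned = 4000)
  run <- simulate_delivery(p[1], "static_out", seed = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_clusters(run$clusters, f)
  back <- read_clusters(f, w$tracker)
  expect_equal(as.data.frame(back[, c("arm", "sensor", "frame")]),
               as.data.frame(run$clusters[, c("arm", "sensor", "frame")]))
  expect_equal(back$gx, run$clusters$gx, tolerance = 1e-9)
})

test_that("optional uniform noise clusters are injected and survive tracking", {
  w2 <- tiny_world()
  fpn <- frag_params(noise_rate = 0.5)
  sv <- sample_fragmentation_vertices(w2$phantom, w2$model,
                                      make_spot(energy = 185, x_v = 15,
                                                n_planned = 5000),
                                      0, 2.5e-4,
                                      function(t) rep(0, length(t)),
                                      fpn, seed = 61)
  fr <- emit_fragments(sv$vertices, fpn, seed = 62)
  cl <- propagate_to_trackers(fr, w2$phantom, w2$tracker, offset = 0,
                              fp = fpn, seed = 63)
  expect_gt(sum(is.na(cl$fragment_id)), 0) # noise present
  expect_gt(sum(!is.na(cl$fragment_id)), 0) # signal still present
  # tracking still runs; noise triples rarely align, signal dominates
  tr <- build_tracks(cl, w2$tracker)
  expect_gt(sum(!is.na(tr$fragment_id)), 0)
})

test_that("detected-fragment fraction rises with beam energy", {
  # higher-energy layers stop deeper, so fewer fragments are absorbed
  frac <- vapply(c(120, 160, 190), function(e) {
    sv <- sample_fragmentation_vertices(w$phantom, w$model,
                                        make_spot(energy = e,
                                                  n_planned = 2e4),
                                        0, 1e-3,
                                        function(t) rep(0, length(t)),
                                        frag_params(), seed = 71)
    fr <- emit_fragments(sv$vertices, frag_params(), seed = 72)
    cl <- propagate_to_trackers(fr, w$phantom, w$tracker, offset = 0,
                                fp = frag_params(), seed = 73)
    length(unique(cl$fragment_id)) / 2e4
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
  # and the detected fraction sits in the sub-percent regime
  expect_lt(max(frac), 0.02)
})
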
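test_that("threshold from repeats follows the 2-RMS definition", {
  # identical repeats: no repeat scatter, thr = 0
  cv_in <- list(make_cv(1:3, c(0, 1, 2)), make_cv(1:3, c(0, 1, 2)))
  cv_out <- list(make_cv(1:3, c(5, 6, 7)), make_cv(1:3, c(5, 6, 7)))
  thr0 <- thr_from_repeats(cv_in, cv_out)
  expect_equal(attr(thr0, "pooled"), 0)
  expect_equal(thr0$thr_diff, rep(0, 3))
  # differences deviating +-1 mm from their mean: RMS 1, thr 2
  cv_in2 <- list(make_cv(1, 10), make_cv(1, 12))
  cv_out2 <- list(make_cv(1, 5), make_cv(1, 5))
  thr2 <- thr_from_repeats(cv_in2, cv_out2)     # diffs 5 and 7, mean 6
  expect_equal(attr(thr2, "pooled"), 2)
  expect_equal(thr2$rms_diff, 1)
  expect_error(thr_from_repeats(cv_in2[1], cv_out2[1]), "2 repeats")
})

test_that("random repeats match the direct RMS formula oracle", {
  set.seed(51)
  n_rep <- 5; spots <- 1:20
  vz_in <- matrix(rnorm(100, -10, 2), n_rep)
  vz_out <- matrix(rnorm(100, 15, 2), n_rep)
  cv_in <- lapply(1:n_rep, function(r) make_cv(spots, vz_in[r, ]))
  cv_out <- lapply(1:n_rep, function(r) make_cv(spots, vz_out[r, ]))
  thr <- thr_from_repeats(cv_in, cv_out, mult = 2, pooled = FALSE)
  d <- vz_in - vz_out
  ref <- apply(d, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(thr[order(spot_index)]$rms_diff, ref, tolerance = 1e-12)
  expect_equal(thr$thr_diff, 2 * thr$rms_diff)
  # pooled value is the RMS of all per-spot deviations
  thr_p <- thr_from_repeats(cv_in, cv_out, mult = 2, pooled = TRUE)
  dev <- sweep(d, 2, colMeans(d))
  expect_equal(attr(thr_p, "pooled"), 2 * sqrt(mean(dev^2)),
               tolerance = 1e-12)
  # per-case repeat RMS combine quadratically into the uncertainty
  expect_equal(thr$uncertainty,
               sqrt(apply(vz_in, 2, function(x) sqrt(mean((x - mean(x))^2)))^2 +
                      apply(vz_out, 2, function(x)
                        sqrt(mean((x - mean(x))^2)))^2),
               tolerance = 1e-12)
})

test_that("delivery classification respects the boundary convention", {
  expect_equal(as.character(classify_delivery(1, 4)), "planned")
  expect_equal(as.character(classify_delivery(5, 4)), "not_planned")
  expect_equal(as.character(classify_delivery(4, 4)), "planned") # boundary
  expect_error(classify_delivery(NA, 4), "finite")
})

test_that("edge-spot selection matches brute-force enumeration", {
  # synthetic grid of spots on and around the sphere surface
  g <- expand.grid(x_v = seq(-24, 24, by = 2), y_v = seq(-24, 24, by = 2),
                   z_v = seq(-24, 0, by = 4))
  plan <- data.table::data.table(spot_index = seq_len(nrow(g)), g)
  sel <- select_edge_spots(plan)
  r <- sqrt(g$x_v^2 + g$y_v^2 + g$z_v^2)
  ref <- plan$spot_index[g$x_v > 5 & g$y_v < 0 & r >= 19 & r <= 25]
  expect_setequal(sel, ref)
  expect_gt(length(sel), 0)
  # the two landmark spots
  one <- data.table::data.table(spot_index = 1:2, x_v = c(10, 0),
                                y_v = c(-10, 0),
                                z_v = c(-sqrt(22^2 - 200), 0))
  expect_equal(select_edge_spots(one), 1L)
})

test_that("total efficiency counts correct categorisations", {
  calls <- classify_delivery(c(1, 1, 5, 5), 4)
  truth <- delivery_truth(c(0.2, 3, 0.2, 3), pos_m = 2)
  # truth: planned, not, planned, not; calls: planned, planned, not, not
  expect_equal(total_efficiency(calls, truth), 50)
  expect_equal(total_efficiency(calls, calls), 100)
  expect_equal(total_efficiency(calls[c(1, 2, 4)], truth[c(1, 2, 4)]),
               200 / 3, tolerance = 1e-9)
  # random confusion table vs hand count
  set.seed(52)
  c2 <- factor(sample(c("planned", "not_planned"), 200, TRUE),
               levels = c("planned", "not_planned"))
  t2 <- factor(sample(c("planned", "not_planned"), 200, TRUE),
               levels = c("planned", "not_planned"))
  expect_equal(total_efficiency(c2, t2), 100 * sum(c2 == t2) / 200)
  expect_error(delivery_truth(1, pos_m = 4), "pos_m")
})

test_that("phase assignment implements the four-case rule", {
  expect_equal(as.character(assign_phase(1, 10, 4)), "Phase1")
  expect_equal(as.character(assign_phase(10, 1, 4)), "Phase3")
  expect_equal(as.character(assign_phase(10, 10, 4)), "Phase2")
  expect_equal(as.character(assign_phase(1, 1, 4)), "undefined")
  # boundary equality counts as below
  expect_equal(as.character(assign_phase(4, 10, 4)), "Phase1")
  expect_equal(as.character(assign_phase(4, 4, 4)), "undefined")
  # vectorised and pure
  din <- c(1, 10, 10, 1); dout <- c(10, 1, 10, 1)
  expect_equal(as.character(assign_phase(din, dout, 4)),
               c("Phase1", "Phase3", "Phase2", "undefined"))
})

test_that("phase confusion normalises rows and honours exclusions", {
  truth <- c(1, 1, 2, 2, 3, 3)
  perfect <- factor(paste0("Phase", truth),
                    levels = c("undefined", "Phase1", "Phase2", "Phase3"))
  m <- phase_confusion(perfect, truth)
  expect_equal(unname(diag(m[, c("Phase1", "Phase2", "Phase3")])),
               rep(100, 3))
  expect_true(all(abs(rowSums(m) - 100) < 0.1))
  allund <- factor(rep("undefined", 6),
                   levels = c("undefined", "Phase1", "Phase2", "Phase3"))
  m2 <- phase_confusion(allund, truth)
  expect_equal(unname(m2[, "undefined"]), rep(100, 3))
  # mixed case vs hand-tabulated oracle with one excluded spot
  calls <- factor(c("Phase1", "Phase2", "Phase2", "undefined", "Phase3",
                    "Phase1"),
                  levels = c("undefined", "Phase1", "Phase2", "Phase3"))
  excl <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  m3 <- phase_confusion(calls, truth, exclude = excl)
  expect_equal(unname(m3["Phase1", c("Phase1", "Phase2")]), c(50, 50))
  expect_equal(unname(m3["Phase2", c("Phase2", "undefined")]), c(50, 50))
  expect_equal(unname(m3["Phase3", "Phase3"]), 100)
})
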
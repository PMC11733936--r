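top <- synthetic_complex()

test_that("superposition removes rigid motion exactly", {
  spec <- scripted_trajectory_spec(n_frames = 10,
                                   rotation_deg_per_frame = 9,
                                   translation_per_frame = c(0.5, -0.2, 0.1))
  traj <- make_scripted_trajectory(spec, top)
  fitted <- superpose_to_first_frame(traj)
  ref <- fitted$xyz[1, ]
  for (f in c(2, 5, 10)) {
    prot <- xyz_rmsd(ref, fitted$xyz[f, ], top$protein)
    expect_lt(prot, 1e-6)
  }
  # identical frames are left unchanged
  still <- make_scripted_trajectory(scripted_trajectory_spec(n_frames = 4),
                                    top)
  fitted_still <- superpose_to_first_frame(still)
  expect_equal(fitted_still$xyz, still$xyz, tolerance = 1e-9)
  expect_error(superpose_to_first_frame(traj, selection = c(1, 2)),
               "3 atoms")
})

test_that("collinear superposition selections are rejected", {
  atoms <- data.frame(
    serial = 1:5, name = c("CA", "CA", "CA", "C1", "C2"),
    element = "C", resname = c("ALA", "ALA", "ALA", "LIG", "LIG"),
    resno = c(1L, 2L, 3L, 9L, 9L), chain = c("A", "A", "A", "L", "L"),
    type = c("ATOM", "ATOM", "ATOM", "HETATM", "HETATM"),
    x = c(0, 1, 2, 5, 6), y = 0, z = 0
  )
  line_top <- structure_model(atoms, "LIG")
  xyz <- rbind(as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
               as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))))
  traj <- trajectory(xyz, c(10, 20), line_top)
  expect_error(superpose_to_first_frame(traj), "degenerate")
})

test_that("ligand RMSD reflects scripted displacement after superposition", {
  # pure rigid rotation, no noise: ligand RMSD stays 0 while bound
  spec <- scripted_trajectory_spec(n_frames = 20,
                                   rotation_deg_per_frame = 5,
                                   departure_frame = 11, displacement = 8)
  series <- ligand_rmsd_series(
    superpose_to_first_frame(make_scripted_trajectory(spec, top)))
  expect_equal(series$rmsd[1], 0, tolerance = 1e-6)
  expect_true(all(series$rmsd[1:10] < 1e-6))
  expect_equal(series$rmsd[11:20], rep(8, 10), tolerance = 1e-6)
})

test_that("a uniform (3,4,0) ligand shift gives RMSD 5 exactly", {
  ref <- as.matrix(top$atoms[, c("x", "y", "z")])
  shifted <- ref
  shifted[top$ligand, 1] <- shifted[top$ligand, 1] + 3
  shifted[top$ligand, 2] <- shifted[top$ligand, 2] + 4
  xyz <- rbind(as.vector(t(ref)), as.vector(t(shifted)))
  series <- ligand_rmsd_series(trajectory(xyz, c(10, 20), top))
  expect_equal(series$rmsd, c(0, 5), tolerance = 1e-9)
})

test_that("unbinding detection follows the cutoff-with-persistence rule", {
  mk_series <- function(rmsd, interval = 10) {
    structure(data.frame(time = seq_along(rmsd) * interval, rmsd = rmsd),
              class = c("rmsd_series", "data.frame"))
  }
  # all bound -> censored at the last frame time
  ev <- detect_unbinding(mk_series(rep(1, 50)), cutoff = 5, persistence = 1)
  expect_true(ev$censored)
  expect_equal(ev$t_max, 500)
  # sustained crossing at frame 100 of 120, persistence 1 -> 1000 ps
  r <- c(rep(1, 99), rep(8, 21))
  ev <- detect_unbinding(mk_series(r), cutoff = 5, persistence = 1)
  expect_equal(ev$unbind_time, 1000)
  # single-frame excursion at frame 50 ignored under persistence 5
  r2 <- r
  r2[50] <- 9
  ev2 <- detect_unbinding(mk_series(r2), cutoff = 5, persistence = 5)
  expect_equal(ev2$unbind_time, 1000)
  # but counted under the bare single-cutoff rule
  ev3 <- detect_unbinding(mk_series(r2), cutoff = 5, persistence = 1)
  expect_equal(ev3$unbind_time, 500)
  # an excursion truncated by the trajectory end does not qualify
  r4 <- c(rep(1, 118), 9, 9)
  expect_true(detect_unbinding(mk_series(r4), persistence = 5)$censored)
})

test_that("detection reports time, invariant to frame-interval refinement", {
  coarse <- scripted_trajectory_spec(n_frames = 120, frame_interval = 10,
                                     departure_frame = 100)
  fine <- scripted_trajectory_spec(n_frames = 240, frame_interval = 5,
                                   departure_frame = 200)
  t_coarse <- detect_unbinding(ligand_rmsd_series(
    superpose_to_first_frame(make_scripted_trajectory(coarse, top))),
    persistence = 1)$unbind_time
  t_fine <- detect_unbinding(ligand_rmsd_series(
    superpose_to_first_frame(make_scripted_trajectory(fine, top))),
    persistence = 1)$unbind_time
  expect_equal(t_coarse, 1000)
  expect_equal(t_fine, 1000)
})

test_that("median unbinding time handles censoring by order statistics", {
  expect_equal(median_unbinding_time(events_of(c(1, 2, 3), 5))$tau_median, 2)
  m <- median_unbinding_time(events_of(c(1, 2, 3, 4), 5))
  expect_equal(m$tau_median, 2.5)
  expect_equal(m$quality, "RELIABLE")
  # censored replica sits above the median at t_max
  m2 <- median_unbinding_time(events_of(c(1, 2, NA), 5))
  expect_equal(m2$tau_median, 2)
  expect_equal(m2$quality, "RELIABLE")
  # exactly half uncensored is only a lower bound
  m3 <- median_unbinding_time(events_of(c(1, 2, NA, NA), 5))
  expect_equal(m3$quality, "LOWER_BOUND")
  expect_equal(m3$tau_median, 3.5)
  expect_error(median_unbinding_time(events_of(c(NA, NA), 5),
                                     policy = "drop"), "censored")
})

test_that("censoring any event never decreases the median", {
  set.seed(17)
  for (k in 1:25) {
    n <- sample(3:12, 1)
    t_max <- 10
    times <- runif(n, 0, t_max)
    times[runif(n) < 0.3] <- NA
    base <- median_unbinding_time(events_of(times, t_max))$tau_median
    uncensored <- which(!is.na(times))
    if (!length(uncensored)) next
    times2 <- times
    times2[sample(uncensored, 1)] <- NA
    expect_gte(median_unbinding_time(events_of(times2, t_max))$tau_median,
               base)
  }
})

test_that("koff estimation composes median, rate and reweighting", {
  # lambda = 1, tau = ln 2 ns -> k = 1 ns^-1 -> log10 = 0
  res <- replica_set_result("L1", 300, events_of(rep(log(2), 3), 10))
  est <- estimate_koff(res, T_ref = 300, time_in = "ns")
  expect_equal(est$log10_koff_ref, 0)
  expect_equal(est$lambda, 1)
  expect_equal(est$quality, "RELIABLE")
  # faster unbinder keeps the larger reweighted rate
  resA <- replica_set_result("A", 900, events_of(c(1, 2, 3), 10))
  resB <- replica_set_result("B", 900, events_of(c(4, 5, 6), 10))
  expect_gt(estimate_koff(resA, time_in = "ns")$log10_koff_ref,
            estimate_koff(resB, time_in = "ns")$log10_koff_ref)
  # lower-bound medians are refused with actionable advice
  cens <- replica_set_result("C", 900, events_of(c(1, NA, NA), 5))
  expect_error(estimate_koff(cens, time_in = "ns"),
               "temperature|t_max")
  est_lb <- estimate_koff(cens, time_in = "ns", accept_lower_bound = TRUE)
  expect_equal(est_lb$quality, "LOWER_BOUND")
})

test_that("temperature scan picks the lowest fully-unbinding temperature", {
  mk <- function(lig, temp, times, t_max) {
    replica_set_result(lig, temp, events_of(times, t_max))
  }
  # at 800 K one ligand mostly censored; both unbind at 1000 K
  results <- list(
    mk("L1", 800, c(1000, 2000, NA), 4000),
    mk("L2", 800, c(NA, NA, 3000), 4000),
    mk("L1", 1000, c(500, 800, 900), 4000),
    mk("L2", 1000, c(1000, 1500, 2000), 4000)
  )
  scan <- temperature_scan(results, c(0.1, 4), time_in = "ps")
  expect_equal(scan$recommended, 1000)
  expect_false(scan$no_solution)
  # two qualifying temperatures -> the lower one
  results2 <- c(results[3:4],
                list(mk("L1", 900, c(600, 900, 1200), 4000),
                     mk("L2", 900, c(900, 1100, 1600), 4000)))
  expect_equal(temperature_scan(results2, c(0.1, 4))$recommended, 900)
  # nothing unbinds anywhere -> no-solution flag with full table
  dead <- list(mk("L1", 800, c(NA, NA, NA), 4000),
               mk("L1", 1000, c(NA, NA, NA), 4000))
  scan_dead <- temperature_scan(dead, c(0.1, 4))
  expect_true(scan_dead$no_solution)
  expect_true(is.na(scan_dead$recommended))
  expect_equal(nrow(scan_dead$table), 2)
})
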
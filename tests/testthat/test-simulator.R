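# Ground-truth generation, acquisition simulation, peak integration and the
# detectability filter.

test_that("ground truth is deterministic and respects its parameters", {
  lib <- tiny_library(20)
  params <- sim_params()
  r1 <- generate_ground_truth_run(lib, params, seed = 5)
  r2 <- generate_ground_truth_run(lib, params, seed = 5)
  expect_identical(r1$true_rt, r2$true_rt)
  expect_identical(r1$true_area, r2$true_area)
  r3 <- generate_ground_truth_run(lib, params, seed = 6)
  expect_false(identical(r1$true_rt, r3$true_rt))

  # zero jitter pins every peak to its expected retention time
  r0 <- generate_ground_truth_run(lib, sim_params(rt_sd_range = c(0, 0)), seed = 5)
  expect_equal(r0$true_rt, lib$expected_rt)

  # abundances span the configured decades
  big <- tiny_library(1000, rt_from = 0.1, rt_by = 0.02)
  s <- ground_truth_stats(big, sim_params(area_log10_range = c(2, 7)), seed = 9)
  obs_range <- range(log10(s$abundance))
  expect_lt(abs(obs_range[1] - 2), 0.25) # 5% of the 5-decade span
  expect_lt(abs(obs_range[2] - 7), 0.25)
})

test_that("noiseless acquisition recovers true areas on wide windows", {
  lib <- tiny_library(5, rt_from = 3, rt_by = 4)
  params <- sim_params(rt_sd_range = c(0, 0), baseline_cps = 0)
  stats <- ground_truth_stats(lib, params, seed = 2)
  run <- generate_ground_truth_run(lib, params, seed = 2, stats = stats)
  sched <- build_schedule(stats, "smrm", smrm_halfwidth = 1)
  trace <- simulate_acquisition(run, sched, seed = 3, noise = FALSE)
  meas <- integrate_peaks(trace, stats)
  expect_true(all(!meas$missing))
  rel_err <- abs(meas$area - run$true_area[match(meas$transition_id, run$transition_id)]) /
    run$true_area[match(meas$transition_id, run$transition_id)]
  expect_lt(max(rel_err), 0.01)
})

test_that("traces respect schedule windows and report cps signals", {
  lib <- tiny_library(3, rt_from = 4, rt_by = 6)
  params <- sim_params(rt_sd_range = c(0, 0))
  stats <- ground_truth_stats(lib, params, seed = 1)
  run <- generate_ground_truth_run(lib, params, seed = 1, stats = stats)
  sched <- build_schedule(stats, "variable")
  trace <- simulate_acquisition(run, sched, seed = 1)
  by_id <- split(trace, trace$transition_id)
  for (id in names(by_id)) {
    w <- sched[sched$transition_id == id, ]
    expect_true(all(by_id[[id]]$time >= w$window_start & by_id[[id]]$time < w$window_end))
    expect_false(is.unsorted(by_id[[id]]$time, strictly = TRUE))
  }
  expect_true(all(trace$signal_cps >= 0))
  # same seed reproduces the same trace
  expect_identical(trace, simulate_acquisition(run, sched, seed = 1))
})

test_that("peak integration handles degenerate traces", {
  short <- tibble::tibble(
    transition_id = "x", time = c(1, 1.01), dwell_ms = 10, signal_cps = c(5, 6)
  )
  m <- integrate_peaks(short)
  expect_true(m$missing)
  flat <- tibble::tibble(
    transition_id = "x", time = seq(1, 2, 0.01), dwell_ms = 10, signal_cps = 0
  )
  m2 <- integrate_peaks(flat)
  expect_false(m2$missing)
  expect_equal(m2$area, 0)
})

test_that("a dense noiseless Gaussian integrates to its analytic area", {
  # independent of the acquisition loop: construct the trace directly
  sigma_min <- 0.05
  area <- 1e5
  tt <- seq(9, 11, by = 0.005)
  y <- area / (sigma_min * 60 * sqrt(2 * pi)) * exp(-(tt - 10)^2 / (2 * sigma_min^2))
  trace <- tibble::tibble(transition_id = "g", time = tt, dwell_ms = 10, signal_cps = y)
  m <- integrate_peaks(trace)
  expect_equal(m$area, area, tolerance = 0.01)
})

test_that("doubling a transition's dwell improves S/N by about sqrt(2)", {
  lib <- tiny_library(3, rt_from = 10, rt_by = 0) # three co-eluting transitions
  params <- sim_params(rt_sd_range = c(0, 0), sigma_range = c(0.05, 0.05), baseline_cps = 2)
  stats <- ground_truth_stats(lib, params, seed = 4)
  stats$abundance <- c(2000, 1e5, 1e5) # first transition is shot-noise limited
  run <- generate_ground_truth_run(lib, params, seed = 4, stats = stats)
  sched_lo <- tibble::tibble(
    transition_id = lib$transition_id,
    window_start = 9.5, window_end = 10.5,
    dwell_weight = c(1, 1, 2)
  )
  # weights (2,1,1) exactly double the first transition's dwell share (1/4 -> 1/2)
  sched_hi <- dplyr::mutate(sched_lo, dwell_weight = c(2, 1, 1))
  areas <- function(sched, off) {
    vapply(1:200, function(r) {
      tr <- simulate_acquisition(run, sched, seed = 1000 * off + r)
      m <- integrate_peaks(tr[tr$transition_id == "t01", ], stats)
      m$area
    }, numeric(1))
  }
  a_lo <- areas(sched_lo, 1)
  a_hi <- areas(sched_hi, 2)
  cv_ratio <- (stats::sd(a_lo) / mean(a_lo)) / (stats::sd(a_hi) / mean(a_hi))
  expect_gt(cv_ratio, 1.15) # clearly better than unimproved
  expect_equal(cv_ratio, sqrt(2), tolerance = 0.2)
  # areas stay dwell-unbiased
  expect_equal(mean(a_hi), mean(a_lo), tolerance = 0.1)
})

test_that("the detectability filter applies the points and CV rules", {
  mk <- function(points, areas) {
    tibble::tibble(
      transition_id = "x", replicate = seq_along(points),
      area = areas, n_points = points, apex_rt = 5, snr = 10,
      missing = FALSE
    )
  }
  good <- mk(c(12, 11, 10, 13, 12), c(100, 108, 95, 103, 99)) # CV ~ 5%
  expect_true(detectability_filter(good, 5)$detected)
  few_points <- mk(c(12, 11, 9, 13, 12), c(100, 108, 95, 103, 99))
  expect_false(detectability_filter(few_points, 5)$detected)
  noisy <- mk(rep(12, 5), c(100, 160, 40, 150, 60)) # CV ~ 47%
  expect_false(detectability_filter(noisy, 5)$detected)
  absent <- dplyr::mutate(good, missing = replace(missing, 2, TRUE))
  expect_false(detectability_filter(absent, 5)$detected)
})

test_that("easy regimes are detected by all three modes", {
  lib <- tiny_library(10, rt_from = 2, rt_by = 2)
  params <- sim_params(
    area_log10_range = c(6, 7), # abundant
    sigma_range = c(0.05, 0.075), # wide peaks
    rt_sd_range = c(0, 0.005)
  )
  cmp <- compare_modes(lib, params, seed = 11, replicates = 3)
  expect_equal(cmp$detected$n_detected, rep(10, 3))
})

test_that("replicate area CV falls with true area under Poisson noise", {
  lib <- tiny_library(6, rt_from = 4, rt_by = 3)
  params <- sim_params(rt_sd_range = c(0, 0), sigma_range = c(0.05, 0.05), baseline_cps = 2)
  stats <- ground_truth_stats(lib, params, seed = 3)
  stats$abundance <- 10^seq(2, 7, by = 1)
  run <- generate_ground_truth_run(lib, params, seed = 3, stats = stats)
  sched <- build_schedule(stats, "smrm")
  meas <- purrr::map_dfr(1:40, function(r) {
    tr <- simulate_acquisition(run, sched, seed = 300 + r)
    dplyr::mutate(integrate_peaks(tr, stats), replicate = r)
  })
  cvs <- meas |>
    dplyr::filter(!missing) |>
    dplyr::group_by(transition_id) |>
    dplyr::summarise(cv = stats::sd(area) / mean(area), .groups = "drop")
  cvs <- cvs[match(lib$transition_id, cvs$transition_id), ]
  expect_true(all(diff(cvs$cv) < 0))
})
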
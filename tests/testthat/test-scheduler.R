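# Window assignment, dwell weighting, cycle allocation and concurrency.

test_that("window half-widths follow the clamp(3*sd + base) policy", {
  stats <- tibble::tibble(
    transition_id = c("a", "b", "c"),
    mean_rt = c(5, 10, 15),
    rt_sd = c(0, 0.10, 1.0),
    base_halfwidth = c(0.10, 0.20, 0.5)
  )
  w <- assign_rt_windows(stats)
  expect_equal(w$halfwidth, c(0.15, 0.50, 1.0)) # floor, linear, ceiling
  expect_equal(w$window_start, w$mean_rt - w$halfwidth)
  expect_equal(w$window_end, w$mean_rt + w$halfwidth)
  # clipping to the run
  w2 <- assign_rt_windows(dplyr::mutate(stats, mean_rt = c(0.05, 23.95, 12)))
  expect_true(all(w2$window_start >= 0 & w2$window_end <= 24))
})

test_that("dwell weights scale as sqrt of the abundance deficit, capped", {
  med <- 1e5
  stats <- tibble::tibble(
    transition_id = c("at-median", "at-median2", "low", "very-low", "high", "unknown"),
    # the median of the non-missing abundances is `med` by construction
    abundance = c(med, med, med / 4, med / 1e4, med * 100, NA)
  )
  expect_equal(stats::median(stats$abundance, na.rm = TRUE), med)
  w <- assign_dwell_weights(stats)
  expect_equal(w$dwell_weight[w$transition_id == "at-median"], 1)
  expect_equal(w$dwell_weight[w$transition_id == "low"], 2) # sqrt(4)
  expect_equal(w$dwell_weight[w$transition_id == "very-low"], 10) # capped
  expect_equal(w$dwell_weight[w$transition_id == "high"], 1) # floored
  expect_equal(w$dwell_weight[w$transition_id == "unknown"], 1) # default
})

test_that("dwell allocation matches the worked cycle examples", {
  b <- cycle_budget() # 0.5 s, 5 ms settling, 5.007 ms pause, 1 ms floor
  m <- tibble::tibble(transition_id = c("a", "b", "c"), dwell_weight = c(1, 1, 2))
  a <- allocate_dwell(m, b)
  # available = 500 - 3 * 10.007 = 469.979 ms, shares 1/4, 1/4, 1/2
  expect_equal(a$dwell_ms, c(117.49, 117.49, 234.99), tolerance = 1e-4)
  expect_equal(attr(a, "cycle_s"), 0.5)
  expect_false(attr(a, "over_budget"))

  single <- allocate_dwell(
    tibble::tibble(transition_id = "x", dwell_weight = 5), b
  )
  expect_equal(single$dwell_ms, 489.993, tolerance = 1e-3)

  crowd <- allocate_dwell(
    tibble::tibble(transition_id = as.character(1:60), dwell_weight = rep(1, 60)), b
  )
  expect_true(attr(crowd, "over_budget"))
  expect_equal(attr(crowd, "cycle_s") * 1000, 60 * 10.007 + 60 * 1)
  expect_error(allocate_dwell(m[0, ], b), "no transitions")
})

test_that("dwell conservation holds for random cycle compositions", {
  b <- cycle_budget()
  set.seed(71)
  for (i in 1:200) {
    n <- sample(1:80, 1)
    m <- tibble::tibble(
      transition_id = as.character(seq_len(n)),
      dwell_weight = round(stats::runif(n, 1, 10), 2)
    )
    a <- allocate_dwell(m, b)
    overhead <- n * (b$settling_ms + b$pause_ms)
    expect_equal(sum(a$dwell_ms) + overhead, attr(a, "cycle_s") * 1000,
      tolerance = 1e-9
    )
    expect_true(all(a$dwell_ms >= b$min_dwell_ms - 1e-12))
  }
})

test_that("allocation is monotone in weights and membership", {
  b <- cycle_budget()
  m <- tibble::tibble(transition_id = as.character(1:10), dwell_weight = rep(2, 10))
  base <- allocate_dwell(m, b)
  # increasing one member's weight never decreases its dwell
  up <- allocate_dwell(dplyr::mutate(m, dwell_weight = replace(dwell_weight, 3, 5)), b)
  expect_gte(up$dwell_ms[3], base$dwell_ms[3])
  # adding a member never increases anyone's dwell
  bigger <- allocate_dwell(
    dplyr::bind_rows(m, tibble::tibble(transition_id = "new", dwell_weight = 2)), b
  )
  expect_true(all(bigger$dwell_ms[1:10] <= base$dwell_ms + 1e-12))
})

test_that("equal weights reduce to the fixed-dwell scheduled allocation", {
  b <- cycle_budget()
  stats <- tibble::tibble(
    transition_id = as.character(1:5),
    mean_rt = rep(10, 5), rt_sd = 0, base_halfwidth = 0.5,
    abundance = rep(1000, 5)
  )
  sv <- build_schedule(stats, "variable")
  ss <- build_schedule(stats, "smrm")
  expect_equal(sv$dwell_weight, rep(1, 5)) # equal abundances give weight 1
  expect_equal(sv$window_start, ss$window_start)
  expect_equal(sv$window_end, ss$window_end)
  av <- allocate_dwell(sv[, c("transition_id", "dwell_weight")], b)
  as_ <- allocate_dwell(ss[, c("transition_id", "dwell_weight")], b)
  expect_equal(av$dwell_ms, as_$dwell_ms)
})

test_that("concurrency matches a brute-force interval-stabbing oracle", {
  set.seed(13)
  starts <- stats::runif(100, 0, 22)
  sched <- tibble::tibble(
    transition_id = as.character(1:100),
    window_start = starts,
    window_end = starts + stats::runif(100, 0.1, 3),
    dwell_weight = 1
  )
  grid <- c(sort(stats::runif(200, 0, 24)), sched$window_start[1:20], sched$window_end[1:20])
  prof <- concurrency_profile(sched, grid)
  brute <- vapply(
    grid,
    function(t) sum(sched$window_start <= t & t < sched$window_end),
    numeric(1)
  )
  expect_equal(prof$n_active, brute)

  # two disjoint windows never overlap; narrowing never raises concurrency
  two <- tibble::tibble(
    transition_id = c("a", "b"),
    window_start = c(1, 5), window_end = c(2, 6), dwell_weight = 1
  )
  expect_equal(max(concurrency_profile(two, seq(0, 10, 0.01))$n_active), 1)
  narrower <- dplyr::mutate(sched, window_end = window_start + (window_end - window_start) / 2)
  expect_true(all(
    concurrency_profile(narrower, grid)$n_active <= prof$n_active
  ))
})

test_that("expected points per peak equal base width over cycle time", {
  b <- cycle_budget()
  stats <- tibble::tibble(
    transition_id = c("wide", "narrow"),
    mean_rt = c(10, 14),
    # base widths 6 s and 4 s (half-widths in minutes)
    base_halfwidth = c(3, 2) / 60,
    rt_sd = 0,
    abundance = 1000
  )
  sched <- tibble::tibble(
    transition_id = c("wide", "narrow"),
    window_start = c(9, 13), window_end = c(11, 15), dwell_weight = 1
  )
  p <- predict_points_per_peak(sched, stats, b)
  expect_equal(p$expected_points[p$transition_id == "wide"], 12, tolerance = 1e-6)
  expect_equal(p$expected_points[p$transition_id == "narrow"], 8, tolerance = 1e-6)
  expect_error(
    predict_points_per_peak(sched[1, ], stats, b),
    "absent from schedule"
  )
})
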
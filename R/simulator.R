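# Synthetic LC-MRM ground truth and cycle-by-cycle acquisition simulation.
#
# The generator emulates plasma-like runs: class-clustered retention times
# (from the library's expected RTs), Gaussian elution peaks of 0.05-0.3 min
# base width, abundances spanning five orders of magnitude, and run-to-run
# retention-time jitter. Acquisition advances cycle by cycle; each active
# transition is sampled once per cycle with Poisson shot noise on the
# expected ion counts, and signals are reported normalised to counts per
# second so that peak areas are dwell-unbiased while noise scales as
# 1/sqrt(dwell).

# run a computation under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation fixture parameters
#'
#' Defaults emulate a plasma-like run: peak base widths 0.05-0.3 min
#' (sigma = width / 4), abundances log-uniform over five decades, run-to-run
#' retention-time jitter well below the 5 % retention-time CV bound, and a
#' small constant chemical baseline.
#'
#' @param area_log10_range Range of log10 true peak areas (counts * s).
#' @param sigma_range Range of Gaussian peak sigmas (min).
#' @param rt_sd_range Range of per-transition run-to-run RT jitter SDs (min).
#' @param baseline_cps Baseline rate (counts / s).
#' @param run_length Run length (min).
#' @param species_seed Optional fixed seed for the per-transition persistent
#'   properties (areas, widths, jitter SDs), so that replicate runs share
#'   them; defaults to the run seed.
#' @return A list of parameters.
#' @export
sim_params <- function(area_log10_range = c(2, 7),
                       sigma_range = c(0.0125, 0.075),
                       rt_sd_range = c(0.005, 0.04),
                       baseline_cps = 2,
                       run_length = 24,
                       species_seed = NULL) {
  list(
    area_log10_range = area_log10_range,
    sigma_range = sigma_range,
    rt_sd_range = rt_sd_range,
    baseline_cps = baseline_cps,
    run_length = run_length,
    species_seed = species_seed
  )
}

#' Persistent per-transition ground-truth properties
#'
#' Draws each transition's true peak area, width and run-to-run jitter SD.
#' These play the role of pilot-study peak statistics: the same tibble feeds
#' [build_schedule()] (as `stats`) and [generate_ground_truth_run()].
#'
#' @param library An `mrm_library` tibble.
#' @param params See [sim_params()].
#' @param seed Integer seed.
#' @return Tibble with columns `transition_id`, `mean_rt`, `rt_sd`,
#'   `peak_sigma`, `base_halfwidth` (2 sigma), `abundance` (true area) and
#'   `baseline_cps`.
#' @export
ground_truth_stats <- function(library, params = sim_params(), seed = 1) {
  stopifnot(nrow(library) > 0)
  n <- nrow(library)
  .with_seed(seed, {
    tibble::tibble(
      transition_id = library$transition_id,
      mean_rt = library$expected_rt,
      rt_sd = stats::runif(n, params$rt_sd_range[1], params$rt_sd_range[2]),
      peak_sigma = stats::runif(n, params$sigma_range[1], params$sigma_range[2]),
      abundance = 10^stats::runif(n, params$area_log10_range[1], params$area_log10_range[2]),
      baseline_cps = params$baseline_cps
    ) |>
      dplyr::mutate(base_halfwidth = 2 * .data$peak_sigma)
  })
}

#' Generate one synthetic run's ground truth
#'
#' Each transition elutes as a Gaussian centred at its expected retention
#' time plus run-specific jitter `Normal(0, rt_sd)`. Deterministic under a
#' fixed seed.
#'
#' @inheritParams ground_truth_stats
#' @param seed Integer seed for the run (jitter); persistent properties use
#'   `params$species_seed` (default: same seed).
#' @param stats Optional precomputed [ground_truth_stats()].
#' @return A `mrm_ground_truth` tibble: `transition_id`, `true_rt`,
#'   `peak_sigma`, `true_area`, `baseline_cps` plus the stats columns;
#'   attributes `run_length` and `seed`.
#' @export
generate_ground_truth_run <- function(library, params = sim_params(), seed = 1,
                                      stats = NULL) {
  if (is.null(stats)) {
    stats <- ground_truth_stats(library, params, params$species_seed %||% seed)
  }
  run <- .with_seed(seed, {
    dplyr::mutate(
      stats,
      true_rt = .data$mean_rt + stats::rnorm(dplyr::n(), 0, .data$rt_sd),
      true_area = .data$abundance
    )
  })
  attr(run, "run_length") <- params$run_length
  attr(run, "seed") <- seed
  class(run) <- c("mrm_ground_truth", class(run))
  run
}

#' Simulate MRM acquisition of one run under a schedule
#'
#' Time advances cycle by cycle. In each cycle every transition whose window
#' contains the current time is sampled once, with its dwell allocated by
#' [allocate_dwell()]. Expected counts are
#' `(intensity(t) + baseline) * dwell_s`; observed counts are Poisson draws
#' (or the expectation itself with `noise = FALSE`); reported signals are
#' counts per second.
#'
#' @param run A `mrm_ground_truth` tibble.
#' @param schedule An `mrm_schedule` covering the run's transitions.
#' @param budget A [cycle_budget()].
#' @param seed Integer seed for the shot noise.
#' @param noise Draw Poisson noise (default `TRUE`).
#' @return Trace tibble: `transition_id`, `time` (min), `dwell_ms`,
#'   `signal_cps`.
#' @export
simulate_acquisition <- function(run, schedule, budget = cycle_budget(),
                                 seed = 1, noise = TRUE) {
  ord <- match(run$transition_id, schedule$transition_id)
  if (anyNA(ord)) stop("schedule does not cover the run's transitions", call. = FALSE)
  ws <- schedule$window_start[ord]
  we <- schedule$window_end[ord]
  w <- schedule$dwell_weight[ord]
  rt <- run$true_rt
  sig <- run$peak_sigma
  amp_cps <- run$true_area / (sig * 60 * sqrt(2 * pi))
  base_cps <- run$baseline_cps
  run_length <- attr(run, "run_length") %||% 24
  target_ms <- budget$target_scan_time_s * 1000
  over_ms <- budget$settling_ms + budget$pause_ms
  min_d <- budget$min_dwell_ms

  .with_seed(seed, {
    t_now <- 0
    acc_id <- list()
    acc_t <- list()
    acc_dwell <- list()
    acc_sig <- list()
    i <- 0L
    while (t_now < run_length) {
      active <- which(ws <= t_now & t_now < we)
      n <- length(active)
      if (n == 0) {
        nxt <- suppressWarnings(min(ws[ws > t_now]))
        if (!is.finite(nxt) || nxt >= run_length) break
        t_now <- nxt
        next
      }
      overhead <- n * over_ms
      avail <- target_ms - overhead
      if (avail < n * min_d) {
        dwell <- rep(min_d, n)
        cycle_ms <- overhead + n * min_d
      } else {
        dwell <- .waterfill(w[active], avail, min_d)
        cycle_ms <- target_ms
      }
      dwell_s <- dwell / 1000
      mu <- (amp_cps[active] * exp(-((t_now - rt[active])^2) / (2 * sig[active]^2)) +
        base_cps[active]) * dwell_s
      counts <- if (noise) stats::rpois(n, mu) else mu
      i <- i + 1L
      acc_id[[i]] <- active
      acc_t[[i]] <- rep(t_now, n)
      acc_dwell[[i]] <- dwell
      acc_sig[[i]] <- counts / dwell_s
      t_now <- t_now + cycle_ms / 1000 / 60
    }
    tibble::tibble(
      transition_id = run$transition_id[unlist(acc_id)],
      time = unlist(acc_t),
      dwell_ms = unlist(acc_dwell),
      signal_cps = unlist(acc_sig)
    )
  })
}

# integrate one transition's trace
.integrate_one <- function(time, signal, base_halfwidth = NA, center = NA) {
  n <- length(time)
  if (n < 3) {
    return(tibble::tibble(
      area = NA_real_, n_points = 0L, apex_rt = NA_real_,
      snr = NA_real_, missing = TRUE
    ))
  }
  ord <- order(time)
  time <- time[ord]
  signal <- signal[ord]
  k <- max(1L, floor(n / 4))
  low <- sort(signal)[seq_len(k)]
  baseline <- stats::median(low)
  noise <- if (k >= 2) stats::sd(low) else 0
  threshold <- baseline + 3 * noise
  apex <- which.max(signal)
  above <- signal >= threshold
  # contiguous region around the apex
  lo <- apex
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- apex
  while (hi < n && above[hi + 1]) hi <- hi + 1
  idx <- lo:hi
  y <- pmax(signal[idx] - baseline, 0)
  tt <- time[idx] * 60 # minutes -> seconds
  area <- if (length(idx) >= 2) sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) else 0
  n_points <- if (!is.na(base_halfwidth)) {
    mid <- if (!is.na(center)) center else time[apex]
    sum(abs(time - mid) <= base_halfwidth)
  } else {
    length(idx)
  }
  tibble::tibble(
    area = area,
    n_points = as.integer(n_points),
    apex_rt = time[apex],
    snr = if (noise > 0) (signal[apex] - baseline) / noise else Inf,
    missing = FALSE
  )
}

#' Integrate peaks from chromatogram traces
#'
#' For each transition the baseline is the median of the lowest quartile of
#' samples, the peak region is the contiguous block of samples above
#' baseline + 3 * noise around the maximum, and the area is the trapezoidal
#' integral of the baseline-subtracted signal over that region (counts).
#' Traces with fewer than 3 samples are flagged missing. When peak-base
#' half-widths are supplied, `n_points` counts the samples falling across
#' the expected peak base (the scheduler's mean retention time when known,
#' otherwise the apex, +- the half-width) -- the quantity the >= 10
#' data-point detectability rule refers to; otherwise it counts the region
#' samples.
#'
#' @param traces Trace tibble from [simulate_acquisition()] (optionally with
#'   extra grouping columns such as `replicate`).
#' @param stats Optional tibble with `transition_id`, `base_halfwidth` and
#'   optionally `mean_rt`.
#' @return Tibble with one row per transition (and per value of any
#'   `replicate` column): `area`, `n_points`, `apex_rt`, `snr`, `missing`.
#' @export
integrate_peaks <- function(traces, stats = NULL) {
  bh <- ctr <- NULL
  if (!is.null(stats)) {
    bh <- stats::setNames(stats$base_halfwidth, stats$transition_id)
    if ("mean_rt" %in% names(stats)) {
      ctr <- stats::setNames(stats$mean_rt, stats$transition_id)
    }
  }
  group_cols <- intersect(c("transition_id", "replicate", "mode"), names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::reframe(
      .integrate_one(
        .data$time, .data$signal_cps,
        if (is.null(bh)) NA else unname(bh[.data$transition_id[1]]),
        if (is.null(ctr)) NA else unname(ctr[.data$transition_id[1]])
      )
    )
}

#' Detectability filter across technical replicates
#'
#' A transition is detected when it is present (non-missing) in every
#' replicate, every replicate has at least `min_points` data points across
#' the peak, and the replicate-to-replicate area CV is below `max_cv_pct`.
#'
#' @param measurements Tibble from [integrate_peaks()] with a `replicate`
#'   column.
#' @param n_replicates Expected number of replicates (default: number of
#'   distinct values present).
#' @param min_points Minimum data points per peak (default 10).
#' @param max_cv_pct Maximum area CV in percent (default 30).
#' @return Tibble per transition: `n_present`, `min_n_points`, `cv_pct`,
#'   `mean_area`, `detected`.
#' @export
detectability_filter <- function(measurements, n_replicates = NULL,
                                 min_points = 10, max_cv_pct = 30) {
  n_reps <- n_replicates %||% dplyr::n_distinct(measurements$replicate)
  stopifnot(n_reps >= 2)
  measurements |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("mode", "transition_id")))) |>
    dplyr::summarise(
      n_present = sum(!.data$missing & .data$area > 0),
      min_n_points = ifelse(
        any(!.data$missing),
        min(.data$n_points[!.data$missing]),
        NA_integer_
      ),
      cv_pct = ifelse(
        sum(!.data$missing) >= 2,
        stats::sd(.data$area[!.data$missing]) / mean(.data$area[!.data$missing]) * 100,
        NA_real_
      ),
      mean_area = ifelse(any(!.data$missing), mean(.data$area[!.data$missing]), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      detected = .data$n_present == n_reps &
        !is.na(.data$min_n_points) & .data$min_n_points >= min_points &
        !is.na(.data$cv_pct) & .data$cv_pct < max_cv_pct
    )
}

#' Compare unscheduled MRM, fixed-window sMRM and variable-window scheduling
#'
#' Runs the full simulation pipeline for each acquisition mode on a common
#' synthetic ground truth: schedule construction, `replicates` technical
#' replicate runs with shared per-transition properties but independent
#' retention-time jitter and shot noise, peak integration and the
#' detectability filter.
#'
#' @param library An `mrm_library` tibble.
#' @param params See [sim_params()].
#' @param budget A [cycle_budget()].
#' @param seed Integer seed.
#' @param replicates Technical replicates per mode.
#' @param modes Acquisition modes to compare.
#' @param min_points,max_cv_pct Detectability thresholds.
#' @return An `mrm_comparison` list: `detected` (per-mode counts),
#'   `by_transition` (per-mode detectability detail), `measurements`
#'   (per-replicate areas and points), `stats`, `schedules`.
#' @export
compare_modes <- function(library, params = sim_params(), budget = cycle_budget(),
                          seed = 1, replicates = 5,
                          modes = c("variable", "smrm", "mrm"),
                          min_points = 10, max_cv_pct = 30) {
  stats <- ground_truth_stats(library, params, params$species_seed %||% seed)
  schedules <- lapply(stats::setNames(modes, modes), function(m) {
    build_schedule(stats, mode = m, run_length = params$run_length)
  })
  runs <- lapply(seq_len(replicates), function(r) {
    generate_ground_truth_run(library, params, seed = seed + 131 * r, stats = stats)
  })
  measurements <- purrr::map_dfr(seq_along(modes), function(mi) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      trace <- simulate_acquisition(
        runs[[r]], schedules[[modes[mi]]], budget,
        seed = seed + 10007 * mi + 977 * r
      )
      meas <- integrate_peaks(trace, stats)
      # transitions with no samples at all are missing
      absent <- setdiff(library$transition_id, meas$transition_id)
      if (length(absent)) {
        meas <- dplyr::bind_rows(
          meas,
          tibble::tibble(
            transition_id = absent, area = NA_real_, n_points = 0L,
            apex_rt = NA_real_, snr = NA_real_, missing = TRUE
          )
        )
      }
      dplyr::mutate(meas, mode = modes[mi], replicate = r, .before = 1)
    })
  })
  by_transition <- detectability_filter(
    measurements,
    n_replicates = replicates, min_points = min_points, max_cv_pct = max_cv_pct
  )
  detected <- by_transition |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(n_detected = sum(.data$detected), .groups = "drop") |>
    dplyr::arrange(match(.data$mode, modes))
  out <- list(
    detected = detected,
    by_transition = by_transition,
    measurements = measurements,
    stats = stats,
    schedules = schedules
  )
  class(out) <- "mrm_comparison"
  out
}
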
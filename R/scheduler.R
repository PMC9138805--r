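# Retention-time window and dwell-time scheduling under a cycle-time budget.
#
# A schedule is a tibble (class "mrm_schedule") with one row per transition:
# monitoring window [window_start, window_end) in minutes and a relative
# dwell weight >= 1. The cycle budget models a triple quadrupole running a
# fixed target scan time with per-transition settling and inter-scan pause
# overheads.

#' Instrument cycle budget
#'
#' @param target_scan_time_s Target scan (cycle) time in seconds.
#' @param settling_ms,pause_ms Per-transition settling time and inter-scan
#'   pause in milliseconds, charged once per transition per cycle.
#' @param min_dwell_ms Minimum dwell time per transition (>= 1 ms).
#' @return A `cycle_budget` list.
#' @export
#' @examples
#' cycle_budget() # 0.5 s cycle, 5 ms settling, 5.007 ms pause
cycle_budget <- function(target_scan_time_s = 0.5, settling_ms = 5,
                         pause_ms = 5.007, min_dwell_ms = 1) {
  stopifnot(
    target_scan_time_s > 0, settling_ms > 0, pause_ms > 0,
    min_dwell_ms >= 1
  )
  structure(
    list(
      target_scan_time_s = target_scan_time_s,
      settling_ms = settling_ms,
      pause_ms = pause_ms,
      min_dwell_ms = min_dwell_ms
    ),
    class = "cycle_budget"
  )
}

#' Assign variable retention-time windows
#'
#' Wider windows go to transitions with larger run-to-run retention-time
#' variation or broader peaks: the window half-width is
#' `clamp(max(h_min, 3 * rt_sd + base_halfwidth), h_max)`, centred on the
#' mean retention time and clipped to the run.
#'
#' @param stats Tibble with columns `transition_id`, `mean_rt` (min),
#'   `rt_sd` (min), `base_halfwidth` (min; half the peak base width).
#' @param h_min,h_max Minimum/maximum half-width in minutes.
#' @param run_length Run length in minutes.
#' @return `stats` with `window_start`, `window_end` and `halfwidth` columns
#'   added.
#' @export
assign_rt_windows <- function(stats, h_min = 0.15, h_max = 1, run_length = 24) {
  stats |>
    dplyr::mutate(
      halfwidth = pmin(pmax(h_min, 3 * .data$rt_sd + .data$base_halfwidth), h_max),
      window_start = pmax(0, .data$mean_rt - .data$halfwidth),
      window_end = pmin(run_length, .data$mean_rt + .data$halfwidth)
    )
}

#' Assign relative dwell-time weights
#'
#' Low-abundance transitions receive a larger share of the cycle:
#' `weight = clamp(sqrt(median_abundance / abundance), 1, w_max)`, rounded to
#' two decimals; unknown abundance gives weight 1.
#'
#' @param stats Tibble with columns `transition_id` and `abundance` (peak
#'   area units; `NA` for unknown).
#' @param w_max Maximum weight.
#' @return `stats` with a `dwell_weight` column added.
#' @export
assign_dwell_weights <- function(stats, w_max = 10) {
  med <- stats::median(stats$abundance, na.rm = TRUE)
  stats |>
    dplyr::mutate(
      dwell_weight = ifelse(
        is.na(.data$abundance),
        1,
        round(pmin(pmax(sqrt(med / .data$abundance), 1), w_max), 2)
      )
    )
}

#' Allocate per-cycle dwell times to concurrent transitions
#'
#' Splits the cycle time left after per-transition overheads proportionally
#' to the dwell weights, with a minimum-dwell floor; when the floor binds,
#' the excess is redistributed proportionally among the unclamped members.
#' If the overhead plus minimum dwells already exceed the target scan time,
#' every member gets the minimum dwell and the cycle runs over budget.
#'
#' @param members Tibble with columns `transition_id` and `dwell_weight`
#'   (weights >= 0; at least one row).
#' @param budget A [cycle_budget()].
#' @return `members` with a `dwell_ms` column; attributes `cycle_s` (actual
#'   cycle time, seconds) and `over_budget` (logical).
#' @export
#' @examples
#' m <- tibble::tibble(transition_id = c("a", "b", "c"), dwell_weight = c(1, 1, 2))
#' allocate_dwell(m, cycle_budget()) # 117.49 / 117.49 / 234.99 ms
allocate_dwell <- function(members, budget = cycle_budget()) {
  n <- nrow(members)
  if (n == 0) stop("no transitions in the cycle", call. = FALSE)
  w <- members$dwell_weight
  stopifnot(all(w > 0))
  overhead_ms <- n * (budget$settling_ms + budget$pause_ms)
  target_ms <- budget$target_scan_time_s * 1000
  available_ms <- target_ms - overhead_ms
  min_d <- budget$min_dwell_ms

  if (available_ms < n * min_d) {
    dwell <- rep(min_d, n)
    cycle_ms <- overhead_ms + n * min_d
    over <- TRUE
  } else {
    dwell <- .waterfill(w, available_ms, min_d)
    cycle_ms <- target_ms
    over <- FALSE
  }
  out <- dplyr::mutate(members, dwell_ms = dwell)
  attr(out, "cycle_s") <- cycle_ms / 1000
  attr(out, "over_budget") <- over
  out
}

# proportional allocation with a floor; excess redistributed proportionally
# to the remaining weights (deterministic)
.waterfill <- function(w, total, floor_each) {
  n <- length(w)
  dwell <- numeric(n)
  free <- rep(TRUE, n)
  budget_left <- total
  repeat {
    share <- budget_left * w[free] / sum(w[free])
    clamped <- share < floor_each
    if (!any(clamped)) {
      dwell[free] <- share
      break
    }
    idx <- which(free)[clamped]
    dwell[idx] <- floor_each
    free[idx] <- FALSE
    budget_left <- budget_left - length(idx) * floor_each
    if (!any(free)) break
  }
  dwell
}

#' Build a schedule for a library
#'
#' @param stats Per-transition peak statistics: `transition_id`, `mean_rt`,
#'   `rt_sd`, `base_halfwidth`, `abundance`.
#' @param mode `"variable"` (variable windows + relative dwell weights),
#'   `"smrm"` (fixed windows, equal weights) or `"mrm"` (unscheduled:
#'   whole-run windows, equal weights).
#' @param smrm_halfwidth Fixed half-width (min) for `"smrm"`.
#' @param h_min,h_max,w_max,run_length Policy constants, see
#'   [assign_rt_windows()] and [assign_dwell_weights()].
#' @return An `mrm_schedule` tibble with columns `transition_id`,
#'   `window_start`, `window_end`, `dwell_weight`; the mode is kept as an
#'   attribute.
#' @export
build_schedule <- function(stats, mode = c("variable", "smrm", "mrm"),
                           smrm_halfwidth = 0.5, h_min = 0.15, h_max = 1,
                           w_max = 10, run_length = 24) {
  mode <- match.arg(mode)
  sched <- switch(mode,
    variable = {
      stats |>
        assign_rt_windows(h_min = h_min, h_max = h_max, run_length = run_length) |>
        assign_dwell_weights(w_max = w_max)
    },
    smrm = dplyr::mutate(
      stats,
      window_start = pmax(0, .data$mean_rt - smrm_halfwidth),
      window_end = pmin(run_length, .data$mean_rt + smrm_halfwidth),
      dwell_weight = 1
    ),
    mrm = dplyr::mutate(
      stats,
      window_start = 0,
      window_end = run_length,
      dwell_weight = 1
    )
  )
  out <- dplyr::select(
    sched, "transition_id", "window_start", "window_end", "dwell_weight"
  )
  attr(out, "mode") <- mode
  attr(out, "run_length") <- run_length
  class(out) <- c("mrm_schedule", class(out))
  out
}

#' Concurrent-transition count over time
#'
#' Counts, at each grid time, the transitions whose half-open window
#' `[window_start, window_end)` contains it.
#'
#' @param schedule An `mrm_schedule` tibble.
#' @param time_grid Numeric vector of times (minutes).
#' @return Tibble with columns `time` and `n_active`.
#' @export
concurrency_profile <- function(schedule, time_grid) {
  starts <- sort(schedule$window_start)
  ends <- sort(schedule$window_end)
  # half-open windows: active iff window_start <= t < window_end
  n_started <- findInterval(time_grid, starts)
  n_ended <- findInterval(time_grid, ends)
  tibble::tibble(time = time_grid, n_active = n_started - n_ended)
}

# actual cycle time (seconds) at each time point given the schedule
.cycle_time_at <- function(schedule, time_grid, budget) {
  n <- concurrency_profile(schedule, time_grid)$n_active
  overhead_ms <- n * (budget$settling_ms + budget$pause_ms)
  target_ms <- budget$target_scan_time_s * 1000
  cycle_ms <- ifelse(
    n == 0,
    target_ms,
    ifelse(
      target_ms - overhead_ms >= n * budget$min_dwell_ms,
      target_ms,
      overhead_ms + n * budget$min_dwell_ms
    )
  )
  cycle_ms / 1000
}

# deterministic dry run of the acquisition clock: cycle start times (min) and
# cycle durations (s) over the run. Depends only on the schedule and budget,
# not on any signal.
.cycle_clock <- function(schedule, budget, run_length = NULL) {
  run_length <- run_length %||% attr(schedule, "run_length") %||% 24
  ws <- schedule$window_start
  we <- schedule$window_end
  target_ms <- budget$target_scan_time_s * 1000
  over_ms <- budget$settling_ms + budget$pause_ms
  t_now <- 0
  starts <- numeric(0)
  cycles <- numeric(0)
  while (t_now < run_length) {
    n <- sum(ws <= t_now & t_now < we)
    if (n == 0) {
      nxt <- suppressWarnings(min(ws[ws > t_now]))
      if (!is.finite(nxt) || nxt >= run_length) break
      t_now <- nxt
      next
    }
    overhead <- n * over_ms
    cycle_ms <- if (target_ms - overhead >= n * budget$min_dwell_ms) {
      target_ms
    } else {
      overhead + n * budget$min_dwell_ms
    }
    starts <- c(starts, t_now)
    cycles <- c(cycles, cycle_ms / 1000)
    t_now <- t_now + cycle_ms / 1000 / 60
  }
  tibble::tibble(start = starts, cycle_s = cycles)
}

#' Expected chromatographic points per peak
#'
#' Expected number of acquisition cycles falling across each transition's
#' peak base: the base width (in seconds) divided by the harmonic-mean
#' actual cycle time over the peak's span. Actual cycle times come from a
#' deterministic dry run of the acquisition clock under the schedule and
#' budget (no signals involved), so the prediction can be cross-checked
#' against simulator-measured sample counts; it agrees with the realised
#' count within one sample for any span.
#'
#' @param schedule An `mrm_schedule` tibble.
#' @param stats Peak statistics with `transition_id`, `mean_rt`,
#'   `base_halfwidth`.
#' @param budget A [cycle_budget()].
#' @param run_length Run length in minutes (default: the schedule's).
#' @return `stats` with an `expected_points` column added (a real number).
#' @export
predict_points_per_peak <- function(schedule, stats, budget = cycle_budget(),
                                    run_length = NULL) {
  missing_ids <- setdiff(stats$transition_id, schedule$transition_id)
  if (length(missing_ids)) {
    stop("transitions absent from schedule: ",
      paste(utils::head(missing_ids, 5), collapse = ", "),
      call. = FALSE
    )
  }
  clock <- .cycle_clock(schedule, budget, run_length)
  cyc_end <- clock$start + clock$cycle_s / 60
  pts <- vapply(seq_len(nrow(stats)), function(i) {
    lo <- stats$mean_rt[i] - stats$base_halfwidth[i]
    hi <- stats$mean_rt[i] + stats$base_halfwidth[i]
    # fraction of each acquisition cycle overlapping the span; the sum is
    # the base width over the harmonic-mean actual cycle time, and is
    # within one sample of the realised count for any span
    overlap <- pmax(0, pmin(hi, cyc_end) - pmax(lo, clock$start))
    sum(overlap * 60 / clock$cycle_s)
  }, numeric(1))
  dplyr::mutate(stats, expected_points = pts)
}
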
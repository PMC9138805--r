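# Method validation: limits of blank/detection/quantitation from blank and
# serial-dilution measurements, linearity, spike recovery and coefficient of
# variation. Sample (n-1) standard deviations are used throughout.

#' Percent relative standard deviation
#'
#' `sd(x) / mean(x) * 100` with the sample (n-1) standard deviation.
#'
#' @param x Numeric vector (>= 2 values).
#' @return Percent RSD.
#' @export
#' @examples
#' rsd_pct(c(95, 100, 105)) # 5
rsd_pct <- function(x) {
  stats::sd(x) / mean(x) * 100
}

#' Method limits from blank replicates
#'
#' Limit of blank, detection and quantitation signal thresholds from
#' replicate blank (matrix-only) areas:
#' `LoB = mean + 1.645 SD`, `LoD = mean + 3 SD`, `LoQ = mean + 10 SD`.
#'
#' @param blank_areas Numeric vector of blank areas (>= 2 replicates).
#' @return Tibble with columns `lob`, `lod_threshold`, `loq_threshold`.
#' @export
#' @examples
#' limits_from_blank(c(90, 100, 110))
limits_from_blank <- function(blank_areas) {
  if (length(blank_areas) < 2) {
    stop("at least 2 blank replicates are required", call. = FALSE)
  }
  m <- mean(blank_areas)
  s <- stats::sd(blank_areas)
  tibble::tibble(
    lob = m + 1.645 * s,
    lod_threshold = m + 3 * s,
    loq_threshold = m + 10 * s
  )
}

#' Detection/quantitation concentrations from a dilution series
#'
#' The LoD (LoQ) concentration is the lowest calibrator whose mean signal
#' exceeds the LoD (LoQ) signal threshold. Linearity is the coefficient of
#' determination of an ordinary least-squares fit of signal against
#' concentration over the linear range from the LoQ concentration to the top
#' calibrator.
#'
#' @param series Tibble with columns `concentration` and `area` (replicate
#'   rows allowed).
#' @param lod_threshold,loq_threshold Signal thresholds from
#'   [limits_from_blank()].
#' @param use `"means"` (default) fits replicate means; `"points"` fits all
#'   replicate points.
#' @return Tibble with `lod_conc`, `loq_conc`, `r_squared` and `status`
#'   (`"ok"` or `"not_detected"` when no calibrator exceeds the threshold).
#' @export
limits_from_dilution <- function(series, lod_threshold, loq_threshold,
                                 use = c("means", "points")) {
  use <- match.arg(use)
  stopifnot(nrow(series) > 0)
  by_conc <- series |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(mean_area = mean(.data$area), .groups = "drop") |>
    dplyr::arrange(.data$concentration)

  lowest_above <- function(threshold) {
    ok <- by_conc$concentration[by_conc$mean_area > threshold]
    if (length(ok)) min(ok) else NA_real_
  }
  lod_conc <- lowest_above(lod_threshold)
  loq_conc <- lowest_above(loq_threshold)

  r2 <- NA_real_
  if (!is.na(loq_conc)) {
    if (use == "means") {
      fit_dat <- dplyr::filter(by_conc, .data$concentration >= loq_conc)
      fit <- stats::lm(mean_area ~ concentration, data = fit_dat)
    } else {
      fit_dat <- dplyr::filter(series, .data$concentration >= loq_conc)
      fit <- stats::lm(area ~ concentration, data = fit_dat)
    }
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  tibble::tibble(
    lod_conc = lod_conc,
    loq_conc = loq_conc,
    r_squared = r2,
    status = ifelse(is.na(lod_conc) | is.na(loq_conc), "not_detected", "ok")
  )
}

#' Validate a set of calibration series
#'
#' Convenience wrapper: computes blank-based thresholds and dilution-based
#' limits for every analyte in a long calibration table.
#'
#' @param calibration Tibble with columns `analyte`, `concentration`
#'   (`NA` or 0 for blank rows), `area` and optionally `is_blank`.
#' @param use Passed to [limits_from_dilution()].
#' @return A `lipid_validation` tibble, one row per analyte, with the
#'   threshold and limit columns of [limits_from_blank()] and
#'   [limits_from_dilution()].
#' @export
validate_calibration <- function(calibration, use = "means") {
  if (!"is_blank" %in% names(calibration)) {
    calibration$is_blank <- is.na(calibration$concentration) | calibration$concentration == 0
  }
  out <- calibration |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(function(df, key) {
      thr <- limits_from_blank(df$area[df$is_blank])
      lim <- limits_from_dilution(
        df[!df$is_blank, c("concentration", "area")],
        thr$lod_threshold, thr$loq_threshold,
        use = use
      )
      dplyr::bind_cols(thr, lim)
    }) |>
    dplyr::ungroup()
  class(out) <- c("lipid_validation", class(out))
  out
}

#' Spike recovery
#'
#' Relative recovery is the mean area of samples spiked before extraction
#' over the mean area of samples spiked after extraction, in percent. The
#' spread is reported as the percent RSD of the per-replicate pre/post
#' ratios.
#'
#' @param pre_spike,post_spike Numeric vectors of areas (>= 1 replicate
#'   each).
#' @return Tibble with `recovery_pct` and `rsd_pct`.
#' @export
#' @examples
#' recovery(c(80, 80), c(100, 100)) # 80 % recovery
recovery <- function(pre_spike, post_spike) {
  stopifnot(length(pre_spike) >= 1, length(post_spike) >= 1)
  if (mean(post_spike) == 0) stop("post-spike mean area is zero", call. = FALSE)
  ratio <- if (length(pre_spike) == length(post_spike)) {
    pre_spike / post_spike
  } else {
    pre_spike / mean(post_spike)
  }
  tibble::tibble(
    recovery_pct = mean(pre_spike) / mean(post_spike) * 100,
    rsd_pct = if (length(ratio) >= 2) rsd_pct(ratio) else 0
  )
}

#' Per-species CV after class-sum normalization
#'
#' Within each replicate, each species' area is divided by the total area of
#' its lipid class in that replicate; the percent CV
#' (`sd / mean * 100`) is then computed per species on the normalized
#' values, making the result invariant to per-replicate global scaling of a
#' class.
#'
#' @param areas Tibble with columns `replicate`, `species`, `lipid_class`,
#'   `area`.
#' @param min_replicates Minimum number of replicates required (default 2).
#' @return Tibble per species: `lipid_class`, `mean_norm`, `cv_pct`.
#' @export
cv_report <- function(areas, min_replicates = 2) {
  n_reps <- dplyr::n_distinct(areas$replicate)
  if (n_reps < min_replicates) stop("need >= ", min_replicates, " replicates", call. = FALSE)
  norm <- areas |>
    dplyr::group_by(.data$replicate, .data$lipid_class) |>
    dplyr::mutate(class_total = sum(.data$area)) |>
    dplyr::ungroup()
  if (any(norm$class_total == 0)) {
    stop("class total is zero in at least one replicate", call. = FALSE)
  }
  norm |>
    dplyr::mutate(norm_area = .data$area / .data$class_total) |>
    dplyr::group_by(.data$species, .data$lipid_class) |>
    dplyr::summarise(
      mean_norm = mean(.data$norm_area),
      cv_pct = rsd_pct(.data$norm_area),
      .groups = "drop"
    )
}
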
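# broom-style tidiers for the package's result objects.

#' Tidy an acquisition-mode comparison
#'
#' @param x An `mrm_comparison` from [compare_modes()].
#' @param ... Unused.
#' @return Per-transition detectability tibble (mode, transition, points,
#'   CV, detected).
#' @exportS3Method generics::tidy
tidy.mrm_comparison <- function(x, ...) {
  x$by_transition
}

#' @rdname tidy.mrm_comparison
#' @return `glance()`: one row per mode with the detected-transition count
#'   and median area CV among detected transitions.
#' @exportS3Method generics::glance
glance.mrm_comparison <- function(x, ...) {
  x$by_transition |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(
      n_detected = sum(.data$detected),
      median_cv_pct = stats::median(.data$cv_pct[.data$detected], na.rm = TRUE),
      .groups = "drop"
    )
}

#' Tidy a differential-screen result
#'
#' @param x A `lipid_de` tibble from [run_differential_pipeline()].
#' @param ... Unused.
#' @return The per-species result tibble (already tidy).
#' @exportS3Method generics::tidy
tidy.lipid_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.lipid_de
#' @return `glance()`: one row with species, candidate and confirmed counts.
#' @exportS3Method generics::glance
glance.lipid_de <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x),
    n_candidates = sum(x$candidate),
    n_confirmed = sum(x$decision == "confirmed"),
    n_rejected = sum(x$decision == "rejected")
  )
}

#' Tidy a calibration validation
#'
#' @param x A `lipid_validation` tibble from [validate_calibration()].
#' @param ... Unused.
#' @return The per-analyte tibble.
#' @exportS3Method generics::tidy
tidy.lipid_validation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.lipid_validation
#' @exportS3Method generics::glance
glance.lipid_validation <- function(x, ...) {
  tibble::tibble(
    n_analytes = nrow(x),
    n_detected = sum(x$status == "ok"),
    median_r_squared = stats::median(x$r_squared, na.rm = TRUE)
  )
}
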
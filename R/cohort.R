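# Synthetic two-group cohort generator for end-to-end testing of the
# differential pipeline. Emulates the structure of a case/control plasma
# study: log-normal species abundances, a handful of planted fold changes,
# batch location/scale effects, a sex covariate and sparse missingness.

#' Cohort design
#'
#' Defaults mirror a 47 vs 46 two-group plasma cohort measured on a 759
#' species panel whose per-class composition follows the default library
#' proportions, with 18 planted effects of at least 1.5-fold.
#'
#' @param n_deficient,n_normal Samples per group.
#' @param n_species Total species.
#' @param n_planted Number of planted differential species.
#' @param planted_fc_range Fold-change magnitudes are drawn uniformly from
#'   this range (>= 1); a third of the planted species are down-regulated.
#' @param planted_classes Classes the planted species are drawn from
#'   (abundant classes by default, so class-sum normalization is barely
#'   perturbed).
#' @param sdlog Log-normal within-group noise SD (natural log scale).
#' @param n_batches Number of measurement batches (round-robin assignment).
#' @param batch_location_sd SD of the per-batch log-location shifts.
#' @param batch_scale_range Per-batch multiplicative noise-scale range.
#' @param sex_effect_frac,sex_effect_log Fraction of species with a sex
#'   effect and its log magnitude (gives the batch model a real covariate to
#'   preserve).
#' @param missing_rate Probability that any measurement is missing.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_deficient = 47, n_normal = 46, n_species = 759,
                          n_planted = 18, planted_fc_range = c(1.5, 2.5),
                          planted_classes = c("TAG", "PC", "PE"),
                          sdlog = 0.4, n_batches = 3,
                          batch_location_sd = 0.3,
                          batch_scale_range = c(0.8, 1.25),
                          sex_effect_frac = 0.1, sex_effect_log = 0.2,
                          missing_rate = 0.005) {
  stopifnot(
    n_deficient >= 2, n_normal >= 2, n_species >= 2,
    n_planted >= 0, all(planted_fc_range >= 1), sdlog > 0,
    n_batches >= 1, missing_rate >= 0, missing_rate < 1
  )
  structure(
    list(
      n_deficient = n_deficient, n_normal = n_normal, n_species = n_species,
      n_planted = n_planted, planted_fc_range = planted_fc_range,
      planted_classes = planted_classes,
      sdlog = sdlog, n_batches = n_batches,
      batch_location_sd = batch_location_sd,
      batch_scale_range = batch_scale_range,
      sex_effect_frac = sex_effect_frac, sex_effect_log = sex_effect_log,
      missing_rate = missing_rate
    ),
    class = "cohort_design"
  )
}

# species panel with classes in the default library proportions
.cohort_species <- function(n_species) {
  counts <- .SPECIES_GRID$n_species
  classes <- .SPECIES_GRID$lipid_class
  scaled <- floor(n_species * counts / sum(counts))
  rem <- n_species - sum(scaled)
  if (rem > 0) {
    extra <- order(n_species * counts / sum(counts) - scaled, decreasing = TRUE)[seq_len(rem)]
    scaled[extra] <- scaled[extra] + 1
  }
  tibble::tibble(
    species = unlist(purrr::map2(classes, scaled, function(cl, k) {
      sprintf("%s_%03d", cl, seq_len(k))
    })),
    lipid_class = rep(classes, scaled)
  )
}

#' Generate a synthetic two-group cohort
#'
#' Log-normal areas per species; planted species are shifted by their fold
#' change in the deficient group; batch location/scale effects and sparse
#' missingness are applied. Deterministic under a fixed seed.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return A `lipid_cohort` list: `areas` (long tibble `sample`, `species`,
#'   `lipid_class`, `area` with `NA` for missing), `meta` (per-sample
#'   `group`, `batch`, `sex`, `age`) and `planted` (per planted species the
#'   true fold change).
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  .with_seed(seed, {
    panel <- .cohort_species(d$n_species)
    n <- d$n_deficient + d$n_normal
    meta <- tibble::tibble(
      sample = sprintf("S%03d", seq_len(n)),
      group = factor(
        rep(c("deficient", "normal"), c(d$n_deficient, d$n_normal)),
        levels = c("deficient", "normal")
      ),
      batch = factor(rep_len(paste0("B", seq_len(d$n_batches)), n)),
      sex = factor(sample(c("F", "M"), n, replace = TRUE, prob = c(0.58, 0.42))),
      age = sample(25:60, n, replace = TRUE)
    )

    pool <- which(panel$lipid_class %in% d$planted_classes)
    if (length(pool) < d$n_planted) pool <- seq_len(nrow(panel))
    planted_idx <- sort(sample(pool, d$n_planted))
    fc_mag <- stats::runif(d$n_planted, d$planted_fc_range[1], d$planted_fc_range[2])
    up <- rep(TRUE, d$n_planted)
    if (d$n_planted > 0) up[seq_len(floor(d$n_planted / 3))] <- FALSE
    up <- sample(up)
    planted <- tibble::tibble(
      species = panel$species[planted_idx],
      fold_change = ifelse(up, fc_mag, 1 / fc_mag)
    )

    base_log <- stats::runif(nrow(panel), log(1e3), log(1e7))
    sex_species <- stats::runif(nrow(panel)) < d$sex_effect_frac
    batch_loc <- stats::rnorm(d$n_batches, 0, d$batch_location_sd)
    batch_scale <- stats::runif(d$n_batches, d$batch_scale_range[1], d$batch_scale_range[2])

    grid <- tidyr::expand_grid(
      sample = meta$sample,
      species = panel$species
    ) |>
      dplyr::left_join(panel, by = "species") |>
      dplyr::left_join(meta, by = "sample")

    si <- match(grid$species, panel$species)
    bi <- as.integer(grid$batch)
    lfc <- stats::setNames(log(planted$fold_change), planted$species)
    eff <- lfc[grid$species]
    eff[is.na(eff)] <- 0
    eff <- eff * (grid$group == "deficient")
    sex_eff <- d$sex_effect_log * sex_species[si] * (grid$sex == "F")
    log_area <- base_log[si] + eff + sex_eff + batch_loc[bi] +
      batch_scale[bi] * stats::rnorm(nrow(grid), 0, d$sdlog)
    area <- exp(log_area)
    area[stats::runif(nrow(grid)) < d$missing_rate] <- NA

    out <- list(
      areas = tibble::tibble(
        sample = grid$sample,
        species = grid$species,
        lipid_class = grid$lipid_class,
        area = area
      ),
      meta = meta,
      planted = planted
    )
    class(out) <- "lipid_cohort"
    out
  })
}
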
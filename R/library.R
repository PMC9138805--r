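# Transition library assembly.
#
# A transition library is a tibble (class "mrm_library") with one row per MRM
# transition. The default configuration enumerates a plasma-style panel of
# 1218 species across the 17 classes (TAG entries at sn-isomer granularity)
# plus the 12 deuterated class standards, i.e. 1230 transitions in total,
# 611 positive and 619 negative.

.CHAIN_C_MIN <- 14L
.CHAIN_C_MAX <- 22L
.CHAIN_D_MAX <- 6L

# per-class enumeration grid for the default panel (totals are acyl sums;
# SM/Cer totals include the d18:1 backbone). `n_species` rows are taken from
# the grid in (carbons, double_bonds) order.
.SPECIES_GRID <- tibble::tribble(
  ~lipid_class, ~c_min, ~c_max, ~c_step, ~d_min, ~d_max, ~n_species,
  "SM",  32L, 40L, 2L, 1L, 3L, 12L,
  "CE",  14L, 22L, 1L, 0L, 2L, 21L,
  "Cer", 32L, 40L, 1L, 1L, 7L, 62L,
  "TAG", 43L, 54L, 1L, 0L, 7L, 96L,
  "DAG", 28L, 44L, 2L, 0L, 5L, 50L,
  "MAG", 14L, 22L, 1L, 0L, 1L, 17L,
  "LPC", 14L, 21L, 1L, 0L, 1L, 16L,
  "PC",  28L, 44L, 1L, 0L, 5L, 79L,
  "LPE", 14L, 21L, 1L, 0L, 1L, 16L,
  "PE",  28L, 44L, 1L, 0L, 8L, 142L,
  "LPI", 14L, 21L, 1L, 0L, 1L, 16L,
  "PI",  28L, 44L, 1L, 0L, 4L, 77L,
  "LPG", 14L, 21L, 1L, 0L, 1L, 16L,
  "PG",  28L, 44L, 1L, 0L, 4L, 78L,
  "LPS", 14L, 21L, 1L, 0L, 1L, 16L,
  "PS",  28L, 44L, 1L, 0L, 4L, 78L,
  "PA",  28L, 44L, 1L, 0L, 4L, 77L
)

#' Default fatty-acyl pool for isomer transitions
#'
#' The chains considered as sn-position neutral losses when expanding TAG
#' species into isomer transitions. The pool covers the abundant saturated,
#' mono- and polyunsaturated plasma fatty acids; it is configuration, not a
#' claim about any particular sample.
#'
#' @return Tibble with columns `carbons` and `double_bonds` (9 chains).
#' @export
default_fa_pool <- function() {
  tibble::tribble(
    ~carbons, ~double_bonds,
    14L, 0L,
    16L, 0L,
    18L, 1L,
    18L, 2L,
    18L, 3L,
    20L, 3L,
    20L, 4L,
    20L, 5L,
    22L, 5L
  )
}

#' Default per-class transition rules
#'
#' One rule row per lipid class: ion mode and adduct, the product-ion rule
#' (`headgroup`, `fa_neutral_loss`, `nl_nh3_h2o` or `fa_carboxylate`),
#' whether species are expanded into per-chain isomer transitions, the class
#' retention-time anchor (the class standard's retention time) with a linear
#' offset in carbons/double bonds and an elution range the prediction is
#' clipped to, and default voltages (declustering, entrance, collision and
#' cell-exit potential) taken from the class standards.
#'
#' @return Tibble with one row per class.
#' @export
default_class_rules <- function() {
  r <- tibble::tribble(
    ~lipid_class, ~product_rule, ~expand_isomers, ~anchor_rt, ~ref_carbons, ~ref_double_bonds, ~rt_min, ~rt_max, ~dp, ~ep, ~ce, ~cxp,
    "SM",  "headgroup",       FALSE, 11.89, 36L, 2L, 11.74, 12.38,  80,  10,  43,  15,
    "Cer", "headgroup",       FALSE,  2.58, 35L, 1L,    NA,    NA,  80,  10,  43,  15,
    "CE",  "headgroup",       FALSE,  2.50, 16L, 0L,    NA,    NA,  80,  10,  43,  15,
    "MAG", "nl_nh3_h2o",      FALSE,  2.46, 18L, 1L,    NA,    NA,  80,  10,  25,  15,
    "DAG", "fa_neutral_loss", FALSE,  2.46, 33L, 1L,    NA,    NA,  80,  10,  25,  15,
    "TAG", "fa_neutral_loss", TRUE,   2.39, 48L, 1L,    NA,    NA,  80,  10,  38,  15,
    "LPC", "fa_carboxylate",  FALSE, 12.63, 18L, 1L,    NA,    NA, -80, -10, -50, -15,
    "PC",  "fa_carboxylate",  FALSE,  9.73, 33L, 1L,  9.09, 11.59, -80, -10, -50, -15,
    "LPE", "fa_carboxylate",  FALSE, 13.09, 18L, 1L,    NA,    NA, -80, -10, -50, -15,
    "PE",  "fa_carboxylate",  FALSE, 10.61, 33L, 1L,    NA,    NA, -80, -10, -50, -15,
    "LPG", "fa_carboxylate",  FALSE,  9.30, 18L, 1L,    NA,    NA, -80, -10, -50, -15,
    "PG",  "fa_carboxylate",  FALSE,  6.59, 33L, 1L,    NA,    NA, -80, -10, -50, -15,
    "LPI", "fa_carboxylate",  FALSE, 15.50, 18L, 1L,    NA,    NA, -80, -10, -50, -15,
    "PI",  "fa_carboxylate",  FALSE, 13.09, 33L, 1L,    NA,    NA, -80, -10, -50, -15,
    "LPS", "fa_carboxylate",  FALSE, 12.50, 18L, 1L,    NA,    NA, -80, -10, -50, -15,
    "PS",  "fa_carboxylate",  FALSE,  9.78, 33L, 1L,    NA,    NA, -80, -10, -50, -15,
    "PA",  "fa_carboxylate",  FALSE, 11.85, 33L, 1L,    NA,    NA, -80, -10, -50, -15
  )
  r$adduct <- class_adduct(r$lipid_class)
  r$ion_mode <- .ADDUCTS$polarity[match(r$adduct, .ADDUCTS$adduct)]
  # class elution band when no printed range is known
  r$rt_min <- ifelse(is.na(r$rt_min), pmax(0.2, r$anchor_rt - 0.75), r$rt_min)
  r$rt_max <- ifelse(is.na(r$rt_max), pmin(23.8, r$anchor_rt + 0.75), r$rt_max)
  # linear retention-time offsets (min per carbon / per double bond)
  r$rt_per_carbon <- -0.05
  r$rt_per_db <- 0.08
  r
}

#' Default species panel
#'
#' Enumerates the default panel species from the per-class grids in
#' (carbons, double bonds) order, keeping for each class the configured
#' number of species. Totals always respect the per-chain bounds of the
#' library (14-22 carbons, 0-6 double bonds per chain).
#'
#' Species identical to an internal standard are skipped during enumeration
#' (the unlabeled ceramide 17:0 standard already occupies the Cer 35:1 slot;
#' the other standards are deuterated and cannot collide).
#'
#' @return Tibble with columns `lipid_class`, `total_carbons`,
#'   `total_double_bonds`, `label_d`, `chains` (NA: totals only) and
#'   `species` (display name); 1218 rows with the default configuration.
#' @export
default_species <- function() {
  purrr::pmap_dfr(.SPECIES_GRID, function(lipid_class, c_min, c_max, c_step,
                                          d_min, d_max, n_species) {
    grid <- tidyr::expand_grid(
      total_carbons = seq(c_min, c_max, by = c_step),
      total_double_bonds = seq(d_min, d_max)
    )
    grid <- grid[.species_feasible(lipid_class, grid$total_carbons, grid$total_double_bonds), ]
    if (lipid_class == "Cer") {
      grid <- grid[!(grid$total_carbons == 35 & grid$total_double_bonds == 1), ]
    }
    if (nrow(grid) < n_species) {
      stop("grid for ", lipid_class, " has fewer than ", n_species, " feasible species",
        call. = FALSE
      )
    }
    grid <- grid[seq_len(n_species), ]
    tibble::tibble(
      lipid_class = lipid_class,
      total_carbons = grid$total_carbons,
      total_double_bonds = grid$total_double_bonds,
      label_d = 0L,
      chains = NA_character_,
      species = format_species(lipid_class, grid$total_carbons, grid$total_double_bonds)
    )
  })
}

# how many acyl chains make up the totals of a class
.n_chains <- function(lipid_class) {
  dplyr::case_when(
    lipid_class %in% c("TAG") ~ 3L,
    lipid_class %in% c("DAG", .DIACYL_PL) ~ 2L,
    TRUE ~ 1L
  )
}

# can the stated totals be realised by chains within the library bounds?
.species_feasible <- function(lipid_class, total_carbons, total_double_bonds) {
  k <- .n_chains(lipid_class)
  c_ <- total_carbons
  d_ <- total_double_bonds
  sphingo <- lipid_class %in% c("SM", "Cer")
  # SM/Cer: fixed d18:1 backbone, one variable chain
  c_ <- ifelse(sphingo, c_ - 18L, c_)
  d_ <- ifelse(sphingo, d_ - 1L, d_)
  c_ >= k * .CHAIN_C_MIN & c_ <= k * .CHAIN_C_MAX &
    d_ >= 0L & d_ <= k * .CHAIN_D_MAX
}

# is `lost` a feasible sn-chain of a species with k chains in total?
.loss_feasible <- function(total_carbons, total_double_bonds, k,
                           fa_carbons, fa_double_bonds) {
  rem_c <- total_carbons - fa_carbons
  rem_d <- total_double_bonds - fa_double_bonds
  fa_carbons >= .CHAIN_C_MIN & fa_carbons <= .CHAIN_C_MAX &
    fa_double_bonds >= 0L & fa_double_bonds <= .CHAIN_D_MAX &
    rem_c >= (k - 1) * .CHAIN_C_MIN & rem_c <= (k - 1) * .CHAIN_C_MAX &
    rem_d >= 0L & rem_d <= (k - 1) * .CHAIN_D_MAX
}

# canonical two-chain split of diacyl totals: chain 1 as close to 16:0 as the
# bounds allow, remaining unsaturation on chain 2 first
.canonical_split <- function(total_carbons, total_double_bonds) {
  c1 <- pmin(pmax(16L, total_carbons - .CHAIN_C_MAX), total_carbons - .CHAIN_C_MIN)
  c2 <- total_carbons - c1
  d2 <- pmin(total_double_bonds, .CHAIN_D_MAX)
  d1 <- total_double_bonds - d2
  tibble::tibble(c1 = c1, d1 = d1, c2 = c2, d2 = d2)
}

#' The twelve internal standards
#'
#' Deuterated one-per-class standards (the Splash mix plus ceramide d18:1/17:0)
#' with their chains, label and per-standard acquisition settings.
#'
#' @return Tibble, one row per standard.
#' @export
internal_standards <- function() {
  tibble::tribble(
    ~lipid_class, ~chains, ~expected_rt, ~dp, ~ep, ~ce, ~cxp,
    "SM",  "d18:1/18:1(d9)",      11.89,  80,  10,  43,  15,
    "Cer", "d18:1/17:0",           2.58,  80,  10,  43,  15,
    "TAG", "15:0/18:1(d7)/15:0",   2.39,  80,  10,  38,  15,
    "DAG", "15:0/18:1(d7)",        2.46,  80,  10,  25,  15,
    "LPC", "18:1(d7)",            12.63, -80, -10, -50, -15,
    "PC",  "15:0/18:1(d7)",        9.73, -80, -10, -50, -15,
    "LPE", "18:1(d7)",            13.09, -80, -10, -50, -15,
    "PE",  "15:0/18:1(d7)",       10.61, -80, -10, -50, -15,
    "PG",  "15:0/18:1(d7)",        6.59, -80, -10, -50, -15,
    "PI",  "15:0/18:1(d7)",       13.09, -80, -10, -50, -15,
    "PS",  "15:0/18:1(d7)",        9.78, -80, -10, -50, -15,
    "PA",  "15:0/18:1(d7)",       11.85, -80, -10, -50, -15
  )
}

# product ion of one species row under a class rule; returns a tibble of one
# or more (q3, product) rows
.product_ions <- function(rule, lipid_class, total_carbons, total_double_bonds,
                          chains, q1, fa_pool) {
  if (rule == "headgroup") {
    return(tibble::tibble(q3 = headgroup_product_mz(lipid_class), product = "headgroup"))
  }
  if (rule == "nl_nh3_h2o") {
    return(tibble::tibble(
      q3 = q1 - .NH3_MASS - monoisotopic_mass("H2O"),
      product = "NL NH3+H2O"
    ))
  }
  has_chains <- !is.na(chains)
  ch <- if (has_chains) parse_chains(chains) else NULL
  if (!is.null(ch) && any(ch$sphingoid)) ch <- ch[!ch$sphingoid, , drop = FALSE]
  k <- .n_chains(lipid_class)

  if (rule == "fa_neutral_loss") {
    if (has_chains) {
      # lose each distinct unlabeled-notation chain once (standards lose the
      # first chain by convention: all Table-1 style standards put the
      # labelled chain in the retained fragment)
      lost <- ch[!duplicated(ch[c("carbons", "double_bonds", "label_d")]), , drop = FALSE]
      lost <- lost[lost$label_d == 0, , drop = FALSE][1, , drop = FALSE]
      return(tibble::tibble(
        q3 = neutral_loss_product_mz(q1, lost$carbons, lost$double_bonds, lost$label_d),
        product = sprintf("FA%d:%d", lost$carbons, lost$double_bonds)
      ))
    }
    feas <- .loss_feasible(
      total_carbons, total_double_bonds, k,
      fa_pool$carbons, fa_pool$double_bonds
    )
    pool <- fa_pool[feas, , drop = FALSE]
    if (nrow(pool) == 0) {
      return(tibble::tibble(q3 = numeric(0), product = character(0)))
    }
    return(tibble::tibble(
      q3 = neutral_loss_product_mz(q1, pool$carbons, pool$double_bonds),
      product = sprintf("FA%d:%d", pool$carbons, pool$double_bonds)
    ))
  }
  if (rule == "fa_carboxylate") {
    if (has_chains) {
      # one product per distinct chain; the labelled chain keeps its label
      ions <- ch[!duplicated(ch[c("carbons", "double_bonds", "label_d")]), , drop = FALSE]
      if (nrow(ions) > 1 && any(ions$label_d > 0)) {
        # standards monitor the labelled chain only
        ions <- ions[ions$label_d > 0, , drop = FALSE]
      }
      return(tibble::tibble(
        q3 = fa_carboxylate_mz(ions$carbons, ions$double_bonds, ions$label_d),
        product = sprintf(
          "FA%d:%d%s", ions$carbons, ions$double_bonds,
          ifelse(ions$label_d > 0, sprintf("(d%d)", ions$label_d), "")
        )
      ))
    }
    if (k == 1) {
      return(tibble::tibble(
        q3 = fa_carboxylate_mz(total_carbons, total_double_bonds),
        product = sprintf("FA%d:%d", total_carbons, total_double_bonds)
      ))
    }
    sp <- .canonical_split(total_carbons, total_double_bonds)
    return(tibble::tibble(
      q3 = fa_carboxylate_mz(sp$c2, sp$d2),
      product = sprintf("FA%d:%d", sp$c2, sp$d2)
    ))
  }
  stop("unknown product rule: ", rule, call. = FALSE)
}

#' Build the transitions of one lipid class
#'
#' Applies a class rule to a set of species: headgroup-fragment rules give
#' one transition per species; fatty-acyl neutral-loss rules with isomer
#' expansion give one transition per feasible lost chain from the pool
#' (shared Q1, distinct Q3); carboxylate rules give one transition per chain
#' of a stated composition (or a canonical representative chain when only
#' totals are known). Feasibility means the remaining carbons/double bonds
#' are attainable by the other chains within the pool bounds.
#'
#' @param species Tibble with columns `lipid_class`, `total_carbons`,
#'   `total_double_bonds` and optionally `label_d`, `chains`, `species`,
#'   `expected_rt`.
#' @param rules A single-class row of [default_class_rules()] (or an edited
#'   copy).
#' @param fa_pool Fatty-acyl pool tibble, see [default_fa_pool()].
#' @param expand_isomers Override the rule's isomer-expansion flag (e.g. to
#'   expand a single species into all its isomer transitions).
#' @return Tibble of transitions (columns as in [assemble_library()]).
#' @export
#' @examples
#' tag <- tibble::tibble(lipid_class = "TAG", total_carbons = 52, total_double_bonds = 6)
#' rules <- dplyr::filter(default_class_rules(), lipid_class == "TAG")
#' build_class_transitions(tag, rules) # 9 isomer transitions, one Q1
build_class_transitions <- function(species, rules, fa_pool = default_fa_pool(),
                                    expand_isomers = NULL) {
  stopifnot(nrow(rules) == 1)
  if (!all(species$lipid_class == rules$lipid_class)) {
    stop("species do not all belong to class ", rules$lipid_class, call. = FALSE)
  }
  species <- dplyr::mutate(
    species,
    label_d = if ("label_d" %in% names(species)) .data$label_d else 0L,
    chains = if ("chains" %in% names(species)) .data$chains else NA_character_
  )
  expand <- expand_isomers %||% rules$expand_isomers

  rows <- purrr::pmap_dfr(
    list(
      species$lipid_class, species$total_carbons, species$total_double_bonds,
      species$label_d, species$chains, seq_len(nrow(species))
    ),
    function(cls, c_, d_, lab, chains, i) {
      q1 <- precursor_mz(cls, c_, d_, lab, chains = if (is.na(chains)) NULL else chains)
      ions <- .product_ions(rules$product_rule, cls, c_, d_, chains, q1, fa_pool)
      if (rules$product_rule == "fa_neutral_loss" && !expand) {
        if (nrow(ions) > 1) {
          # species-level library entry: keep the representative (first pool) loss
          ions <- ions[1, , drop = FALSE]
        } else if (nrow(ions) == 0 && is.na(chains) && .n_chains(cls) == 2) {
          # totals outside the pool: fall back to the canonical-split chain
          sp_ <- .canonical_split(c_, d_)
          ions <- tibble::tibble(
            q3 = neutral_loss_product_mz(q1, sp_$c1, sp_$d1),
            product = sprintf("FA%d:%d", sp_$c1, sp_$d1)
          )
        }
      }
      if (nrow(ions) == 0) {
        return(tibble::tibble())
      }
      name <- if ("species" %in% names(species) && !is.na(species$species[i])) {
        species$species[i]
      } else {
        format_species(cls, c_, d_, lab, chains = if (is.na(chains)) NULL else chains)
      }
      rt <- if ("expected_rt" %in% names(species) && !is.na(species$expected_rt[i])) {
        species$expected_rt[i]
      } else {
        .predict_rt(rules, c_, d_)
      }
      tibble::tibble(
        species = name,
        lipid_class = cls,
        total_carbons = c_,
        total_double_bonds = d_,
        label_d = lab,
        chains = chains,
        ion_mode = rules$ion_mode,
        adduct = rules$adduct,
        q1 = q1,
        q3 = ions$q3,
        product = ions$product,
        expected_rt = rt,
        dp = rules$dp, ep = rules$ep, ce = rules$ce, cxp = rules$cxp
      )
    }
  )
  rows
}

.predict_rt <- function(rules, total_carbons, total_double_bonds) {
  rt <- rules$anchor_rt +
    rules$rt_per_carbon * (total_carbons - rules$ref_carbons) +
    rules$rt_per_db * (total_double_bonds - rules$ref_double_bonds)
  pmin(pmax(rt, rules$rt_min), rules$rt_max)
}

#' Assemble an MRM transition library
#'
#' Builds the per-class transitions for all configured species, appends the
#' internal standards and checks that `(q1, q3, ion_mode)` is unique at
#' 4-decimal m/z resolution. With the default configuration the result has
#' 1218 species entries plus 12 standards (1230 transitions), split 611
#' positive / 619 negative.
#'
#' @param species Species tibble, see [default_species()].
#' @param standards Standards tibble, see [internal_standards()]; `NULL` for
#'   none.
#' @param rules Class rules, see [default_class_rules()].
#' @param fa_pool Isomer fatty-acyl pool, see [default_fa_pool()].
#' @return An `mrm_library` tibble with one row per transition, including a
#'   unique `transition_id` and an `is_internal_standard` flag.
#' @export
#' @examples
#' \donttest{
#' lib <- assemble_library()
#' library_summary(lib)
#' }
assemble_library <- function(species = default_species(),
                             standards = internal_standards(),
                             rules = default_class_rules(),
                             fa_pool = default_fa_pool()) {
  lib <- purrr::map_dfr(unique(species$lipid_class), function(cls) {
    build_class_transitions(
      dplyr::filter(species, .data$lipid_class == cls),
      dplyr::filter(rules, .data$lipid_class == cls),
      fa_pool
    )
  })
  lib$is_internal_standard <- rep(FALSE, nrow(lib))

  if (!is.null(standards) && nrow(standards)) {
    std <- purrr::map_dfr(seq_len(nrow(standards)), function(i) {
      s <- standards[i, ]
      r <- dplyr::filter(rules, .data$lipid_class == s$lipid_class)
      ch <- parse_chains(s$chains)
      sp <- tibble::tibble(
        lipid_class = s$lipid_class,
        total_carbons = sum(ch$carbons),
        total_double_bonds = sum(ch$double_bonds),
        label_d = 0L,
        chains = s$chains,
        expected_rt = s$expected_rt
      )
      out <- build_class_transitions(sp, r, fa_pool)
      out$dp <- s$dp
      out$ep <- s$ep
      out$ce <- s$ce
      out$cxp <- s$cxp
      out
    })
    std$is_internal_standard <- rep(TRUE, nrow(std))
    lib <- dplyr::bind_rows(lib, std)
  }

  if (nrow(lib) == 0) {
    lib <- tibble::tibble(
      transition_id = character(0), species = character(0),
      lipid_class = character(0), total_carbons = integer(0),
      total_double_bonds = integer(0), label_d = integer(0),
      chains = character(0), ion_mode = character(0), adduct = character(0),
      q1 = numeric(0), q3 = numeric(0), product = character(0),
      expected_rt = numeric(0), dp = numeric(0), ep = numeric(0),
      ce = numeric(0), cxp = numeric(0), is_internal_standard = logical(0)
    )
    class(lib) <- c("mrm_library", class(lib))
    return(lib)
  }
  lib <- dplyr::mutate(
    lib,
    transition_id = paste0(.data$species, "/", .data$product),
    .before = 1
  )
  key <- paste(round(lib$q1, 4), round(lib$q3, 4), lib$ion_mode)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    clash <- lib$transition_id[dup]
    stop(
      "duplicate (q1, q3, ion_mode) transitions: ",
      paste(utils::head(clash, 10), collapse = "; "),
      call. = FALSE
    )
  }
  if (anyDuplicated(lib$transition_id)) {
    stop("duplicate transition ids", call. = FALSE)
  }
  class(lib) <- c("mrm_library", class(lib))
  lib
}

#' Per-class and per-mode library accounting
#'
#' @param lib An `mrm_library` tibble.
#' @return A list with `per_class` (class, ion mode, transitions, distinct
#'   species, standards), `per_mode` (positive/negative transition counts)
#'   and `totals` (species entries excluding standards, standards,
#'   transitions).
#' @export
library_summary <- function(lib) {
  per_class <- lib |>
    dplyr::group_by(.data$lipid_class, .data$ion_mode) |>
    dplyr::summarise(
      n_transitions = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species[!.data$is_internal_standard]),
      n_standards = sum(.data$is_internal_standard),
      .groups = "drop"
    )
  per_mode <- lib |>
    dplyr::count(.data$ion_mode, name = "n_transitions")
  totals <- tibble::tibble(
    n_species_entries = sum(!lib$is_internal_standard),
    n_standards = sum(lib$is_internal_standard),
    n_transitions = nrow(lib)
  )
  list(per_class = per_class, per_mode = per_mode, totals = totals)
}

#' Write / read a transition list CSV
#'
#' Vendor-flavoured flat export with Q1/Q3 at 4-decimal resolution. The
#' reader restores an `mrm_library` tibble; writing then reading is lossless
#' at that resolution. If a schedule is given, its retention-time windows and
#' dwell weights are included.
#'
#' @param lib An `mrm_library` tibble.
#' @param path File path.
#' @param schedule Optional `mrm_schedule` to merge (adds `rt_window` and
#'   `dwell_weight`).
#' @return `write_transition_list()` returns `path` invisibly;
#'   `read_transition_list()` returns an `mrm_library` tibble.
#' @export
write_transition_list <- function(lib, path, schedule = NULL) {
  out <- tibble::tibble(
    id = lib$transition_id,
    Q1 = round(lib$q1, 4),
    Q3 = round(lib$q3, 4),
    RT = round(lib$expected_rt, 4),
    ion_mode = lib$ion_mode,
    lipid_class = lib$lipid_class,
    species = lib$species,
    product = lib$product,
    DP = lib$dp, EP = lib$ep, CE = lib$ce, CXP = lib$cxp,
    is_internal_standard = lib$is_internal_standard
  )
  if (!is.null(schedule)) {
    sch <- tibble::tibble(
      id = schedule$transition_id,
      rt_window = schedule$window_end - schedule$window_start,
      dwell_weight = schedule$dwell_weight
    )
    out <- dplyr::left_join(out, sch, by = "id")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_transition_list
#' @export
read_transition_list <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  lib <- tibble::tibble(
    transition_id = x$id,
    species = x$species,
    lipid_class = x$lipid_class,
    ion_mode = x$ion_mode,
    q1 = x$Q1,
    q3 = x$Q3,
    product = x$product,
    expected_rt = x$RT,
    dp = x$DP, ep = x$EP, ce = x$CE, cxp = x$CXP,
    is_internal_standard = x$is_internal_standard
  )
  class(lib) <- c("mrm_library", class(lib))
  lib
}
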
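# Lipid species identity and molecular-formula construction.
#
# Seventeen lipid classes are supported. Species are described by their class
# and total acyl carbons : total double bonds, optionally with the individual
# chains and a deuterium label. The sphingoid backbone of SM and Cer is fixed
# at d18:1.

.LIPID_CLASSES <- c(
  "SM", "Cer", "CE", "MAG", "DAG", "TAG", "PA", "LPC", "PC",
  "LPE", "PE", "LPI", "PI", "LPG", "PG", "LPS", "PS"
)

.GLYCEROLIPID_CHAINS <- c(MAG = 1L, DAG = 2L, TAG = 3L)

.DIACYL_PL <- c("PA", "PC", "PE", "PG", "PI", "PS")
.LYSO_PL <- c("LPA" = NA, "LPC" = NA)[0] # placeholder, see .LYSO_PARENT
.LYSO_PARENT <- c(LPC = "PC", LPE = "PE", LPI = "PI", LPG = "PG", LPS = "PS")

# headgroup addition relative to the phosphatidic-acid backbone
# (glycerophosphoric acid C3H9O6P)
.PL_HEAD_ADD <- list(
  PA = c(C = 0, H = 0, N = 0, O = 0),
  PC = c(C = 5, H = 11, N = 1, O = 0),
  PE = c(C = 2, H = 5, N = 1, O = 0),
  PG = c(C = 3, H = 6, N = 0, O = 2),
  PI = c(C = 6, H = 10, N = 0, O = 5),
  PS = c(C = 3, H = 5, N = 1, O = 2)
)

#' Supported lipid classes
#'
#' @return Character vector of the seventeen supported lipid class codes.
#' @export
lipid_classes <- function() .LIPID_CLASSES

# ---- chain helpers ---------------------------------------------------------

#' Parse fatty-acyl chain notation
#'
#' Parses chain strings such as `"16:0"`, `"18:1(d7)"` or the sphingoid
#' backbone `"d18:1"`.
#'
#' @param x Character vector of chain descriptors.
#' @return A tibble with columns `carbons`, `double_bonds`, `label_d`
#'   (deuterium count) and `sphingoid` (logical).
#' @export
#' @examples
#' parse_chain(c("16:0", "18:1(d7)", "d18:1"))
parse_chain <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^(d?)([0-9]+):([0-9]+)(?:\\(d([0-9]+)\\))?$", x))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) stop("cannot parse chain(s): ", paste(x[bad], collapse = ", "), call. = FALSE)
  tibble::tibble(
    carbons = vapply(m, function(g) as.integer(g[3]), integer(1)),
    double_bonds = vapply(m, function(g) as.integer(g[4]), integer(1)),
    label_d = vapply(m, function(g) if (nzchar(g[5])) as.integer(g[5]) else 0L, integer(1)),
    sphingoid = vapply(m, function(g) nzchar(g[2]), logical(1))
  )
}

#' Split a chains string into its chains
#'
#' @param chains A chains string such as `"15:0/18:1(d7)/15:0"`.
#' @return Tibble as for [parse_chain()], one row per chain.
#' @export
parse_chains <- function(chains) {
  parse_chain(strsplit(chains, "/", fixed = TRUE)[[1]])
}

.chain_check <- function(carbons, double_bonds) {
  if (any(double_bonds < 0) || any(carbons < 2)) {
    stop("invalid chain composition", call. = FALSE)
  }
  if (any(double_bonds > (carbons - 2) / 2)) {
    stop("double bonds exceed the chemically possible maximum for the chain length",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# free fatty acid CnH(2n-2d)O2, optionally deuterated
.fa_formula <- function(carbons, double_bonds, label_d = 0L) {
  .chain_check(carbons, double_bonds)
  h <- 2 * carbons - 2 * double_bonds
  .ef(C = carbons, H = h - label_d, D = label_d, O = 2)
}

# ---- species formula -------------------------------------------------------

.species_formula_one <- function(lipid_class, total_carbons, total_double_bonds,
                                 label_d = 0L) {
  cls <- lipid_class
  c_ <- total_carbons
  d_ <- total_double_bonds
  if (!cls %in% .LIPID_CLASSES) {
    stop("unsupported lipid class: ", cls, call. = FALSE)
  }
  glycerol <- .ef(C = 3, H = 8, O = 3)
  h2o <- .ef(H = 2, O = 1)
  pa_backbone <- .ef(C = 3, H = 9, O = 6, P = 1)

  f <- if (cls %in% names(.GLYCEROLIPID_CHAINS)) {
    k <- .GLYCEROLIPID_CHAINS[[cls]]
    # glycerol + n acyls (as free acids, summed over totals) - n H2O
    acids <- .ef(C = c_, H = 2 * c_ - 2 * d_, O = 2 * k)
    .ef_add(.ef_add(glycerol, acids), h2o, -k)
  } else if (cls %in% .DIACYL_PL) {
    head <- .PL_HEAD_ADD[[cls]]
    base <- .ef_add(pa_backbone, .ef(C = head["C"], H = head["H"], N = head["N"], O = head["O"]))
    acids <- .ef(C = c_, H = 2 * c_ - 2 * d_, O = 4)
    .ef_add(.ef_add(base, acids), h2o, -2L)
  } else if (cls %in% names(.LYSO_PARENT)) {
    head <- .PL_HEAD_ADD[[.LYSO_PARENT[[cls]]]]
    base <- .ef_add(pa_backbone, .ef(C = head["C"], H = head["H"], N = head["N"], O = head["O"]))
    acids <- .ef(C = c_, H = 2 * c_ - 2 * d_, O = 2)
    .ef_add(.ef_add(base, acids), h2o, -1L)
  } else if (cls == "SM") {
    # d18:1 sphingoid backbone; totals include the backbone 18:1
    if (c_ <= 18 || d_ < 1) stop("SM totals must include the d18:1 backbone", call. = FALSE)
    .ef(C = 5 + c_, H = 2 * c_ - 2 * d_ + 13, N = 2, O = 6, P = 1)
  } else if (cls == "Cer") {
    if (c_ <= 18 || d_ < 1) stop("Cer totals must include the d18:1 backbone", call. = FALSE)
    .ef(C = c_, H = 2 * c_ - 2 * d_ + 1, N = 1, O = 3)
  } else if (cls == "CE") {
    # totals are the esterified fatty-acyl chain
    .ef(C = 27 + c_, H = 44 + 2 * c_ - 2 * d_, O = 2)
  } else {
    stop("unsupported lipid class: ", cls, call. = FALSE)
  }
  if (label_d > 0) {
    if (f[["H"]] < label_d) stop("not enough hydrogens to place the deuterium label", call. = FALSE)
    f[["H"]] <- f[["H"]] - label_d
    f[["D"]] <- f[["D"]] + label_d
  }
  f
}

#' Neutral molecular formula of lipid species
#'
#' Assembles the neutral molecular formula from the class backbone and the
#' total acyl composition: glycerolipids are glycerol plus n acyls minus n
#' H2O; diacyl phospholipids add the headgroup to the glycerophosphate
#' backbone; lyso species carry a single acyl (equivalently, the diacyl
#' formula minus one acyl ketene); SM and Cer use a fixed d18:1 sphingoid
#' backbone; CE esterifies cholesterol with one chain. A deuterium label
#' replaces that many hydrogens.
#'
#' @param lipid_class Character vector of class codes (see [lipid_classes()]).
#' @param total_carbons,total_double_bonds Integer vectors of total acyl
#'   carbons and double bonds (for SM/Cer the totals include the d18:1
#'   backbone; for CE the esterified chain).
#' @param label_d Integer vector, number of deuteriums (default 0).
#' @param chains Optional character vector of chain strings
#'   (e.g. `"15:0/18:1(d7)"`). When given, totals and label are derived from
#'   the chains and checked against `total_carbons`/`total_double_bonds` if
#'   those are supplied.
#' @return Character vector of molecular formulas.
#' @export
#' @examples
#' species_formula("PC", 38, 4)                       # "C46H84NO8P"
#' species_formula("TAG", 52, 6)                      # "C55H94O6"
#' species_formula("SM", chains = "d18:1/18:1", label_d = 9)
species_formula <- function(lipid_class, total_carbons = NA, total_double_bonds = NA,
                            label_d = 0L, chains = NULL) {
  n <- max(length(lipid_class), length(total_carbons), length(chains %||% character(0)))
  lipid_class <- rep_len(lipid_class, n)
  total_carbons <- rep_len(total_carbons, n)
  total_double_bonds <- rep_len(total_double_bonds, n)
  label_d <- rep_len(label_d, n)
  chains <- if (is.null(chains)) rep_len(NA_character_, n) else rep_len(chains, n)

  vapply(seq_len(n), function(i) {
    c_ <- total_carbons[i]
    d_ <- total_double_bonds[i]
    lab <- label_d[i]
    if (!is.na(chains[i])) {
      ch <- parse_chains(chains[i])
      c_sum <- sum(ch$carbons)
      d_sum <- sum(ch$double_bonds) # the d18:1 backbone counts its own double bond
      lab <- lab + sum(ch$label_d)
      if (!is.na(c_) && (c_sum != c_ || d_sum != d_)) {
        stop("chains are inconsistent with the stated totals for ",
          lipid_class[i], " ", c_, ":", d_,
          call. = FALSE
        )
      }
      c_ <- c_sum
      d_ <- d_sum
    }
    if (is.na(c_) || is.na(d_)) {
      stop("either totals or chains must be given", call. = FALSE)
    }
    format_formula(.species_formula_one(lipid_class[i], c_, d_, lab))
  }, character(1))
}

#' Format a species display name
#'
#' @param lipid_class,total_carbons,total_double_bonds,label_d,chains As for
#'   [species_formula()].
#' @return Character vector like `"PC 38:4"` or `"TAG(15:0/18:1(d7)/15:0)"`.
#' @export
format_species <- function(lipid_class, total_carbons = NA, total_double_bonds = NA,
                           label_d = 0L, chains = NULL) {
  n <- max(length(lipid_class), length(total_carbons), length(chains %||% character(0)))
  lipid_class <- rep_len(lipid_class, n)
  total_carbons <- rep_len(total_carbons, n)
  total_double_bonds <- rep_len(total_double_bonds, n)
  label_d <- rep_len(label_d, n)
  chains <- if (is.null(chains)) rep_len(NA_character_, n) else rep_len(chains, n)
  ifelse(
    !is.na(chains),
    paste0(lipid_class, "(", chains, ")"),
    paste0(
      lipid_class, " ", total_carbons, ":", total_double_bonds,
      ifelse(label_d > 0, paste0("(d", label_d, ")"), "")
    )
  )
}
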
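# Precursor and product ion m/z computation.

.ADDUCTS <- tibble::tibble(
  adduct = c("M+H", "M+NH4", "M-H", "M+CH3COO"),
  polarity = c("positive", "positive", "negative", "negative"),
  # proton-mass convention (+-1.00728); electron mass neglected
  delta = c(1.00728, 18.03383, -1.00728, 59.01331)
)

# default adduct per class: positive-mode SM/Cer as M+H, neutral lipids as
# ammonium adducts; negative-mode phospholipids as M-H except (L)PC which is
# measured as the acetate adduct
.CLASS_ADDUCT <- c(
  SM = "M+H", Cer = "M+H",
  CE = "M+NH4", MAG = "M+NH4", DAG = "M+NH4", TAG = "M+NH4",
  PC = "M+CH3COO", LPC = "M+CH3COO",
  PA = "M-H", PE = "M-H", LPE = "M-H", PG = "M-H", LPG = "M-H",
  PI = "M-H", LPI = "M-H", PS = "M-H", LPS = "M-H"
)

.NH3_MASS <- 17.02655

#' Supported adducts
#'
#' @return Tibble with columns `adduct`, `polarity` and `delta` (Da mass
#'   shift, proton-mass convention).
#' @export
adducts <- function() .ADDUCTS

#' Default adduct for each lipid class
#'
#' @param lipid_class Character vector of class codes.
#' @return Character vector of adduct names.
#' @export
class_adduct <- function(lipid_class) {
  out <- .CLASS_ADDUCT[lipid_class]
  if (anyNA(out)) {
    stop("unsupported lipid class: ",
      paste(unique(lipid_class[is.na(out)]), collapse = ", "),
      call. = FALSE
    )
  }
  unname(out)
}

.adduct_delta <- function(adduct) {
  i <- match(adduct, .ADDUCTS$adduct)
  if (anyNA(i)) {
    stop("unknown adduct: ", paste(unique(adduct[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .ADDUCTS$delta[i]
}

#' Precursor (Q1) m/z of a lipid species
#'
#' Monoisotopic mass of the neutral species plus the adduct mass shift
#' (singly charged). The adduct must be the one permitted for the class
#' unless `check = FALSE`.
#'
#' @inheritParams species_formula
#' @param adduct Adduct name (default: the class rule, see [class_adduct()]).
#' @param check Validate the class/adduct pairing (default `TRUE`).
#' @return Numeric vector of m/z values.
#' @export
#' @examples
#' precursor_mz("TAG", 52, 6)        # [M+NH4]+ 868.74
#' precursor_mz("PC", 38, 4)         # [M+CH3COO]- 868.607
precursor_mz <- function(lipid_class, total_carbons = NA, total_double_bonds = NA,
                         label_d = 0L, chains = NULL, adduct = NULL, check = TRUE) {
  f <- species_formula(lipid_class, total_carbons, total_double_bonds, label_d, chains)
  n <- length(f)
  lipid_class <- rep_len(lipid_class, n)
  adduct <- if (is.null(adduct)) class_adduct(lipid_class) else rep_len(adduct, n)
  if (check && any(adduct != class_adduct(lipid_class))) {
    bad <- which(adduct != class_adduct(lipid_class))
    stop(
      "adduct ", paste(unique(adduct[bad]), collapse = ", "),
      " is not the one used for class ",
      paste(unique(lipid_class[bad]), collapse = ", "),
      " (pass check = FALSE to override)",
      call. = FALSE
    )
  }
  monoisotopic_mass(f) + .adduct_delta(adduct)
}

#' Monoisotopic mass of a free fatty acid
#'
#' @param carbons,double_bonds,label_d Chain composition (deuteriums via
#'   `label_d`).
#' @return Numeric vector of neutral monoisotopic masses (CnH(2n-2d)O2).
#' @export
fatty_acid_mass <- function(carbons, double_bonds, label_d = 0L) {
  n <- max(length(carbons), length(double_bonds))
  carbons <- rep_len(carbons, n)
  double_bonds <- rep_len(double_bonds, n)
  label_d <- rep_len(label_d, n)
  vapply(
    seq_len(n),
    function(i) monoisotopic_mass(.fa_formula(carbons[i], double_bonds[i], label_d[i])),
    numeric(1)
  )
}

#' Product ion from neutral loss of a fatty acyl chain plus NH3
#'
#' Product (Q3) m/z of the sn-position isomer transitions of ammoniated
#' glycerolipids: the [M+NH4]+ precursor loses one fatty acyl chain as the
#' free acid (RCOOH) together with NH3.
#'
#' @param precursor Precursor m/z values ([M+NH4]+).
#' @param fa_carbons,fa_double_bonds,fa_label_d Composition of the lost chain.
#' @return Numeric vector of product m/z values.
#' @export
#' @examples
#' neutral_loss_product_mz(precursor_mz("TAG", 52, 6), 16, 0) # 595.47
neutral_loss_product_mz <- function(precursor, fa_carbons, fa_double_bonds,
                                    fa_label_d = 0L) {
  precursor - fatty_acid_mass(fa_carbons, fa_double_bonds, fa_label_d) - .NH3_MASS
}

#' Fatty-acid carboxylate anion m/z
#'
#' Product ion used for negative-mode phospholipid transitions: the
#' deprotonated free fatty acid.
#'
#' @inheritParams fatty_acid_mass
#' @return Numeric vector of m/z values.
#' @export
#' @examples
#' fa_carboxylate_mz(18, 1, label_d = 7) # 288.29 (shared by the Splash standards)
fa_carboxylate_mz <- function(carbons, double_bonds, label_d = 0L) {
  fatty_acid_mass(carbons, double_bonds, label_d) - .PROTON_MASS
}

# class-specific fragment cations: protonated phosphocholine for SM (and
# positive-mode PC), the dehydrated sphingosine cation for Cer, and the
# cholestadienyl cation for CE
.HEADGROUP_FRAGMENT <- c(
  SM = "C5H14NO4P", PC = "C5H14NO4P",
  Cer = "C18H33N",
  CE = "C27H44"
)

#' Class-specific headgroup/backbone product ion m/z
#'
#' @param lipid_class Character vector (`SM`, `PC`, `Cer` or `CE`).
#' @return Numeric vector of fragment cation m/z values: phosphocholine
#'   184.073 for SM/PC, the sphingoid fragment 264.269 for Cer and the
#'   cholestadienyl cation 369.352 for CE.
#' @export
headgroup_product_mz <- function(lipid_class) {
  f <- .HEADGROUP_FRAGMENT[lipid_class]
  if (anyNA(f)) {
    stop("no headgroup fragment defined for class: ",
      paste(unique(lipid_class[is.na(f)]), collapse = ", "),
      call. = FALSE
    )
  }
  unname(monoisotopic_mass(f) + .PROTON_MASS)
}
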
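# Element bookkeeping for lipid molecular formulas.
#
# Formulas are represented externally as Hill-style strings ("C46H84NO8P",
# deuterium written as D: "C41H72D9N2O6P") and internally as named integer
# vectors over the supported elements.

.ELEMENT_ORDER <- c("C", "H", "D", "N", "O", "P")

# proton-mass convention for charged species; electron mass neglected
.PROTON_MASS <- 1.00728

.element_mass_env <- new.env(parent = emptyenv())

#' Monoisotopic element masses
#'
#' Returns the monoisotopic atomic mass table used for all m/z arithmetic.
#' The table is shipped as a plain-text data file with the package.
#'
#' @return A tibble with columns `element` and `monoisotopic_mass` (Da).
#' @export
#' @examples
#' element_masses()
element_masses <- function() {
  if (is.null(.element_mass_env$tbl)) {
    path <- system.file("extdata", "element_masses.csv", package = "lipidmrm")
    tbl <- readr::read_csv(path, show_col_types = FALSE)
    .element_mass_env$tbl <- tbl
    .element_mass_env$vec <- stats::setNames(tbl$monoisotopic_mass, tbl$element)
  }
  .element_mass_env$tbl
}

.element_mass_vec <- function() {
  element_masses()
  .element_mass_env$vec
}

.empty_formula <- function() {
  stats::setNames(integer(length(.ELEMENT_ORDER)), .ELEMENT_ORDER)
}

# build a formula vector from element counts
.ef <- function(C = 0, H = 0, D = 0, N = 0, O = 0, P = 0) {
  f <- c(C = C, H = H, D = D, N = N, O = O, P = P)
  if (any(f < 0)) {
    stop("element counts must be non-negative", call. = FALSE)
  }
  f
}

.ef_add <- function(a, b, k = 1L) {
  out <- a + k * b
  if (any(out < 0)) {
    stop("formula subtraction produced a negative element count", call. = FALSE)
  }
  out
}

.parse_formula_one <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(stats::setNames(rep(NA_integer_, length(.ELEMENT_ORDER)), .ELEMENT_ORDER))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!identical(paste(parts, collapse = ""), x)) {
    stop("cannot parse formula: ", x, call. = FALSE)
  }
  f <- .empty_formula()
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .ELEMENT_ORDER) {
      stop("unknown element '", el, "' in formula ", x, call. = FALSE)
    }
    f[el] <- f[el] + n
  }
  f
}

#' Parse molecular formulas
#'
#' @param x Character vector of Hill-style formulas, e.g. `"C46H84NO8P"`.
#'   Deuterium is written `D`.
#' @return A list of named integer vectors (one per formula) with counts for
#'   C, H, D, N, O and P.
#' @export
#' @examples
#' parse_formula("C46H84NO8P")
parse_formula <- function(x) {
  lapply(x, .parse_formula_one)
}

#' Format a formula count vector as a string
#'
#' @param counts Named numeric vector of element counts (C, H, D, N, O, P).
#' @return A single formula string with elements in C, H, D, N, O, P order and
#'   zero counts omitted.
#' @export
format_formula <- function(counts) {
  counts <- counts[.ELEMENT_ORDER]
  counts[is.na(counts)] <- 0
  keep <- counts > 0
  paste0(
    vapply(
      which(keep),
      function(i) {
        n <- counts[i]
        paste0(names(counts)[i], if (n > 1) n else "")
      },
      character(1)
    ),
    collapse = ""
  )
}

#' Monoisotopic mass of molecular formulas
#'
#' @param x Character vector of formulas, or a single named count vector as
#'   produced by [parse_formula()].
#' @return Numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C46H84NO8P")
monoisotopic_mass <- function(x) {
  masses <- .element_mass_vec()
  if (is.numeric(x) && !is.null(names(x))) {
    bad <- setdiff(names(x), names(masses))
    if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
    return(sum(x * masses[names(x)]))
  }
  vapply(
    parse_formula(x),
    function(f) sum(f * masses[names(f)]),
    numeric(1)
  )
}
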
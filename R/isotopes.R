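# Natural isotope abundances (IUPAC 2021 representative values, dimensionless
# mole fractions). Only the elements common in small-molecule ESI analytes are
# covered; `lightest` is the abundance of the lowest-mass stable isotope.
.isotope_lightest <- c(
  C  = 0.9893,
  H  = 0.999885,
  N  = 0.99636,
  O  = 0.99757,
  S  = 0.9499,
  P  = 1.0,
  F  = 1.0,
  Cl = 0.7576,
  Br = 0.5069,
  I  = 1.0
)

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as `"C10H14N2"` into a named integer
#' vector of element counts. Two-letter element symbols (Cl, Br) are
#' supported; a missing count means 1.
#'
#' @param formula Character scalar, e.g. `"C6H5ClO"`, or an already-named
#'   numeric vector of element counts (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C10H14N2")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula)))) {
      stop("numeric formula must be a named element -> count vector")
    }
    if (any(formula < 0)) stop("element counts must be >= 0")
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse molecular formula: ", formula)
  }
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(cnt, els, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic fraction of a molecular formula
#'
#' Probability that a molecule consists exclusively of the lightest stable
#' isotope of each of its elements, i.e. the fraction of the total ion
#' population carried by the monoisotopic peak. Peak areas integrated on the
#' monoisotopic peak only are divided by this fraction to recover the
#' full-isotopologue signal.
#'
#' @param formula Molecular formula (string or named element count vector);
#'   see [parse_formula()]. Supported elements: C, H, N, O, S, P, F, Cl, Br, I.
#' @return Fraction in (0, 1]; 1 for the empty formula.
#' @examples
#' monoisotopic_fraction("C10H14N2") # about 0.890, dominated by 0.9893^10
#' @export
monoisotopic_fraction <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(1.0)
  unknown <- setdiff(names(counts), names(.isotope_lightest))
  if (length(unknown) > 0L) {
    stop("element(s) not in the isotope abundance table: ",
         paste(unknown, collapse = ", "))
  }
  prod(.isotope_lightest[names(counts)]^counts)
}

#' Isotope-correct a peak area
#'
#' Divides a monoisotopic peak area by the monoisotopic fraction so that the
#' corrected area represents all isotopologues of the analyte.
#'
#' @param area Non-negative peak area (arbitrary counts units).
#' @param fraction Monoisotopic fraction in (0, 1], from
#'   [monoisotopic_fraction()].
#' @return Corrected area, `area / fraction`.
#' @export
correct_area <- function(area, fraction) {
  if (any(fraction <= 0) || any(fraction > 1)) {
    stop("fraction must be in (0, 1]")
  }
  if (any(area < 0)) stop("area must be >= 0")
  area / fraction
}
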
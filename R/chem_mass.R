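# Exact-mass utilities for small pathway intermediates (e.g. the
# indole-isonitrile, C11H8N2).

# Monoisotopic masses of the most abundant isotope (CODATA/AME values) and
# the corresponding integer mass numbers used for nominal m/z.
.element_masses <- data.frame(
  element = c("C", "H", "N", "O", "S", "P", "Cl"),
  monoisotopic = c(12.0000000, 1.00782503, 14.00307401, 15.99491462,
                   31.97207117, 30.97376200, 34.96885268),
  nominal = c(12L, 1L, 14L, 16L, 32L, 31L, 35L),
  stringsAsFactors = FALSE
)

#' Parse a Hill-notation molecular formula
#'
#' @param text Formula string such as `"C11H8N2"` or `"H2O"`. Element symbols
#'   must be in the embedded mass table (C, H, N, O, S, P, Cl); an omitted
#'   count means 1.
#' @return Named integer vector of element counts, class `"formula_counts"`.
#' @examples
#' parse_formula("C11H8N2")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (text == "") {
    return(structure(integer(0), class = "formula_counts"))
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  matched <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE))[[1]]
  if (sum(nchar(matched)) != nchar(text)) {
    stop("malformed formula: ", text)
  }
  elements <- sub("[0-9]*$", "", matched)
  counts <- as.integer(ifelse(grepl("[0-9]+$", matched),
                              sub("^[A-Za-z]+", "", matched), "1"))
  unknown <- setdiff(elements, .element_masses$element)
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  counts <- tapply(counts, elements, sum)
  out <- setNames(as.integer(counts), names(counts))
  structure(out, class = "formula_counts")
}

.as_formula <- function(f) {
  if (inherits(f, "formula_counts")) return(f)
  parse_formula(f)
}

#' Monoisotopic (neutral) mass of a molecular formula
#'
#' Sums most-abundant-isotope masses; no electron-mass correction is applied,
#' so the value is the neutral monoisotopic mass, reported to 4 decimals.
#'
#' @param f Formula string or result of [parse_formula()].
#' @return Mass in Da, rounded to 4 decimal places.
#' @examples
#' monoisotopic_mass("C11H8N2")  # 168.0687
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (length(f) == 0) return(0.0)
  idx <- match(names(f), .element_masses$element)
  round(sum(as.numeric(f) * .element_masses$monoisotopic[idx]), 4)
}

#' Nominal (integer) m/z of an adduct ion
#'
#' @param f Formula string or parsed formula.
#' @param adduct One of `"M"`, `"M-H"`, `"M+H"`.
#' @return Integer nominal mass of the adjusted composition.
#' @examples
#' nominal_ion_mz("C11H8N2", "M-H")  # 167
#' @export
nominal_ion_mz <- function(f, adduct = c("M", "M-H", "M+H")) {
  f <- .as_formula(f)
  adduct <- match.arg(adduct)
  counts <- setNames(as.integer(f), names(f))
  if (adduct == "M-H") {
    if (is.na(counts["H"]) || counts["H"] < 1L) {
      stop("cannot form [M-H]: formula has no hydrogen")
    }
    counts["H"] <- counts["H"] - 1L
  } else if (adduct == "M+H") {
    counts["H"] <- if (is.na(counts["H"])) 1L else counts["H"] + 1L
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(0L)
  idx <- match(names(counts), .element_masses$element)
  as.integer(sum(counts * .element_masses$nominal[idx]))
}

#' Parts-per-million difference between observed and expected masses
#'
#' @param observed,expected Masses in Da; `expected` must be positive.
#' @return `1e6 * |observed - expected| / expected`.
#' @export
ppm_difference <- function(observed, expected) {
  stopifnot(expected > 0)
  1e6 * abs(observed - expected) / expected
}
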
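# Monoisotopic mass arithmetic shared by the generator and the annotator.

# Monoisotopic masses of the most abundant isotope (Da), CODATA/IUPAC values.
.ATOMIC_MONO <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376199,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885268
)

#' Mass constants used in adduct and isotope arithmetic
#'
#' Named vector of the mass differences (Da) the package uses when turning
#' neutral monoisotopic masses into ionization products: the proton mass
#' (charge carrier), the sodium-for-proton and potassium-for-proton exchange
#' deltas, the 13C-12C shift used for isotopologue satellites, and the SO3
#' neutral loss observed for sulfate conjugates.
#'
#' @return Named numeric vector of mass deltas in Da.
#' @export
#' @examples
#' mass_constants()["proton"]
mass_constants <- function() {
  c(
    proton    = 1.007276,
    na_minus_h = 21.981944,
    k_minus_h  = 37.955881,
    c13_shift  = 1.003355,
    so3_loss   = 79.956815
  )
}

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula such as `"C8H10N4O2"` into element
#' counts.  Only single-token formulas are supported (no parentheses, no
#' isotope labels); elements must be drawn from C, H, N, O, S, P, Na, K, Cl.
#'
#' @param formula Character scalar, e.g. `"C4H6O6"`.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C8H10N4O2")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'")
  }
  elem <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(tokens, "")))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(elem, names(.ATOMIC_MONO))
  if (length(unknown)) {
    stop("unknown element(s) in formula '", formula, "': ",
         paste(unknown, collapse = ", "))
  }
  counts <- tapply(cnt, factor(elem, levels = unique(elem)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula Character scalar elemental formula.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C8H10N4O2")  # caffeine, 194.08038
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.ATOMIC_MONO[names(counts)] * counts)
}

#' Carbon count of a formula
#'
#' Used to scale the M+1 (13C) isotopologue satellite, whose abundance is
#' approximately 1.1% per carbon atom.
#'
#' @param formula Character scalar elemental formula.
#' @return Integer number of carbon atoms (0 if none).
#' @export
carbon_count <- function(formula) {
  counts <- parse_formula(formula)
  if ("C" %in% names(counts)) unname(counts[["C"]]) else 0L
}
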
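# Elemental formula strings ("C6H12O6", "CH1.624O0.456N0.216", pseudo-elements
# such as "Fd" for carrier moieties). Counts may be real-valued: biomass and
# lumped precursors use fractional stoichiometry.

#' Parse an elemental formula string
#'
#' @param x a single formula string such as `"C3H8O3"`. Counts may be
#'   fractional (`"CH1.624O0.456"`). An element is one capital letter followed
#'   by optional lower-case letters, so pseudo-elements (e.g. `"Fd"` for a
#'   ferredoxin moiety) are accepted.
#' @return a named numeric vector of atom counts, empty for `NA` input.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(x) {
  if (length(x) != 1L) stop("parse_formula() expects a single string")
  if (is.na(x) || !nzchar(x)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)", x)[[1]]
  pieces <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("malformed formula: '", x, "'")
  }
  el <- sub("^([A-Z][a-z]*).*$", "\\1", pieces)
  ct <- sub("^[A-Z][a-z]*", "", pieces)
  ct <- ifelse(ct == "", 1, as.numeric(ct))
  if (anyNA(ct) || any(ct < 0)) stop("malformed formula: '", x, "'")
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Format an atom-count vector as a formula string
#'
#' Elements are printed in Hill order (C, H, then alphabetical); unit counts
#' are omitted and counts are rounded to `digits`.
#'
#' @param atoms named numeric vector of atom counts.
#' @param digits number of digits kept for fractional counts.
#' @return a single formula string.
#' @export
format_formula <- function(atoms, digits = 4) {
  atoms <- atoms[atoms != 0]
  if (length(atoms) == 0L) return("")
  els <- names(atoms)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  atoms <- atoms[ord]
  ct <- round(unname(atoms), digits)
  paste0(names(atoms), ifelse(ct == 1, "", sub("\\.?0+$", "", formatC(ct, format = "f", digits = digits))),
         collapse = "")
}

# standard atomic weights for the elements that occur in fermentation models;
# pseudo-elements (anything else) get weight 0 so they never enter a mass.
.atomic_weights <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974, S = 32.06,
  Fe = 55.845, Mg = 24.305, K = 39.098, Na = 22.99, Ca = 40.078, Cl = 35.45,
  Zn = 65.38, Mn = 54.938, Co = 58.933, Se = 78.971
)

# molar mass (g/mol) of a formula string; pseudo-elements weigh nothing
formula_weight <- function(x) {
  atoms <- parse_formula(x)
  w <- .atomic_weights[names(atoms)]
  w[is.na(w)] <- 0
  sum(atoms * w)
}
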
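# Reaction formula grammar: "coef id + coef id ... <=> coef id + ...".
# Coefficients are positive decimals; an omitted coefficient means 1.
# Left-hand side compounds get negative signed coefficients (substrates),
# right-hand side positive (products). The forward direction of the formula
# is, by convention, the direction of the net pathway flux, and coefficients
# are the actual molecularities at the enzyme (not rescaled).

#' Parse a reaction formula string
#'
#' @param text A formula such as `"2 A + B <=> C"`. Compound ids may contain
#'   letters, digits, `_`, `-`, `.`, `(`, `)`, `+` (trailing charge marks),
#'   but must start with a letter.
#' @return Named numeric vector of signed stoichiometric coefficients,
#'   substrates negative, products positive, in order of appearance.
#' @examples
#' parse_reaction_formula("2 A + B <=> C")
#' parse_reaction_formula("glc <=> 2 pyr")
#' @export
parse_reaction_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  sides <- strsplit(text, "<=>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("formula must contain exactly one '<=>': ", sQuote(text), call. = FALSE)
  }
  parse_side <- function(side, sign, label) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    if (!length(terms) || any(terms == "")) {
      stop("empty term on ", label, " side of ", sQuote(text), call. = FALSE)
    }
    out <- numeric(0)
    for (k in seq_along(terms)) {
      tok <- strsplit(terms[k], "[[:space:]]+")[[1]]
      if (length(tok) == 1L) {
        coef <- 1; id <- tok
      } else if (length(tok) == 2L) {
        coef <- suppressWarnings(as.numeric(tok[1]))
        id <- tok[2]
        if (is.na(coef)) {
          stop("bad coefficient ", sQuote(tok[1]), " in term ", k, " (",
               label, " side) of ", sQuote(text), call. = FALSE)
        }
      } else {
        stop("malformed term ", sQuote(terms[k]), " (term ", k, ", ",
             label, " side) of ", sQuote(text), call. = FALSE)
      }
      if (!grepl("^[A-Za-z][A-Za-z0-9_().+-]*$", id)) {
        stop("malformed compound id ", sQuote(id), " in term ", k, " (",
             label, " side) of ", sQuote(text), call. = FALSE)
      }
      if (!is.finite(coef) || coef <= 0) {
        stop("coefficient must be a positive number in term ", k, " (",
             label, " side) of ", sQuote(text), call. = FALSE)
      }
      if (id %in% names(out)) {
        stop("duplicate compound ", sQuote(id), " on ", label, " side of ",
             sQuote(text), call. = FALSE)
      }
      out[id] <- sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1, "left")
  rhs <- parse_side(sides[2], +1, "right")
  both <- intersect(names(lhs), names(rhs))
  if (length(both)) {
    stop("compound(s) on both sides of ", sQuote(text), ": ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  c(lhs, rhs)
}

#' Format a stoichiometry map back to a formula string
#'
#' Inverse of [parse_reaction_formula()]: `parse -> format -> parse` is the
#' identity on canonical formulas.
#'
#' @param stoichiometry Named numeric vector, substrates negative, products
#'   positive.
#' @return A formula string with unit coefficients omitted.
#' @export
format_reaction_formula <- function(stoichiometry) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)),
            all(stoichiometry != 0))
  fmt <- function(ids, coefs) {
    paste(ifelse(coefs == 1, ids,
                 paste(format(coefs, trim = TRUE, scientific = FALSE), ids)),
          collapse = " + ")
  }
  lhs <- stoichiometry < 0
  if (!any(lhs) || all(lhs)) {
    stop("stoichiometry needs at least one substrate and one product",
         call. = FALSE)
  }
  paste(fmt(names(stoichiometry)[lhs], -stoichiometry[lhs]),
        "<=>",
        fmt(names(stoichiometry)[!lhs], stoichiometry[!lhs]))
}
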
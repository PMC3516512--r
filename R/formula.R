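#' Parse a reaction formula string
#'
#' Formulas follow the usual flat-file convention:
#' `"A[c] + 2 B[c] -> C[c]"`. The arrow `->` marks an irreversible
#' reaction (default bounds `[0, 1000]`), `<=>` a reversible one
#' (`[-1000, 1000]`); 1000 is the conventional finite stand-in for an
#' unconstrained bound. Coefficients default to 1. Either side may be
#' empty, as in exchange (`"A[e] <=>"`) or demand (`"B[n] ->"`) reactions.
#'
#' @param formula A single formula string.
#' @return A list with `stoich` (named numeric vector, negative for
#'   substrates) and `reversible` (logical).
#' @examples
#' parse_reaction_formula("A[c] + 2 B[c] -> C[c]")
#' @export
parse_reaction_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, !is.na(formula))
  arrow <- if (grepl("<=>", formula, fixed = TRUE)) "<=>"
           else if (grepl("->", formula, fixed = TRUE)) "->"
           else stop("formula has no '->' or '<=>' arrow: \"", formula, "\"",
                     call. = FALSE)
  sides <- strsplit(formula, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2) {
    stop("formula has more than one arrow: \"", formula, "\"", call. = FALSE)
  }
  lhs <- parse_formula_side(if (length(sides) >= 1) sides[1] else "")
  rhs <- parse_formula_side(if (length(sides) == 2) sides[2] else "")
  st <- c(-lhs, rhs)
  # merge duplicates (compound on both sides) and drop net-zero entries
  if (anyDuplicated(names(st))) {
    st <- tapply(st, names(st), sum)
    st <- st[st != 0]
    st <- stats::setNames(as.numeric(st), names(st))
  }
  if (length(st) == 0) {
    stop("formula has no participants: \"", formula, "\"", call. = FALSE)
  }
  list(stoich = st, reversible = arrow == "<=>")
}

parse_formula_side <- function(side) {
  side <- trimws(side)
  if (side == "") return(stats::setNames(numeric(), character()))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  terms <- terms[terms != ""]
  coefs <- numeric(length(terms))
  ids <- character(length(terms))
  for (i in seq_along(terms)) {
    parts <- strsplit(terms[i], "[[:space:]]+")[[1]]
    if (length(parts) == 2 && grepl("^[0-9.]+$", parts[1])) {
      coefs[i] <- as.numeric(parts[1])
      ids[i] <- parts[2]
    } else if (length(parts) == 1) {
      coefs[i] <- 1
      ids[i] <- parts[1]
    } else {
      stop("malformed formula term: \"", terms[i], "\"", call. = FALSE)
    }
  }
  stats::setNames(coefs, ids)
}

#' Render a stoichiometry as a formula string
#'
#' Inverse of [parse_reaction_formula()] up to term order (substrates and
#' products are emitted in compound-id order).
#'
#' @param stoich Named numeric vector of signed coefficients.
#' @param reversible Use the `<=>` arrow instead of `->`.
#' @return A formula string.
#' @export
render_reaction_formula <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    if (length(v) == 0) return("")
    v <- v[order(names(v))]
    paste(ifelse(v == 1, names(v), paste(format(v, trim = TRUE), names(v))),
          collapse = " + ")
  }
  lhs <- -stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  trimws(paste(fmt(lhs), if (reversible) "<=>" else "->", fmt(rhs)))
}
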
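# Atomic mass tables and elemental-composition arithmetic.
#
# Compositions are named integer vectors over the element symbols in
# `.elements`; all mass bookkeeping in the package funnels through
# `formula_mass()` so that a single constant table governs every prediction.

.elements <- c("C", "H", "N", "O", "S")

# IUPAC/CODATA monoisotopic atomic masses (u)
.monoisotopic <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# IUPAC 2021 standard atomic weights
.average <- c(
  C = 12.011,
  H = 1.008,
  N = 14.007,
  O = 15.999,
  S = 32.06
)

# mass removed on deprotonation: H atom minus the electron left behind
.proton_mass <- 1.00727646688

# Boltzmann constant, kcal mol^-1 K^-1
.kB_kcal <- 0.0019872

#' Create an elemental composition
#'
#' @param ... element counts, e.g. `comp(C = 6, H = 10, O = 7)`.
#' @return named integer vector over C, H, N, O, S.
#' @examples
#' comp(C = 6, H = 10, O = 7)
#' @export
comp <- function(...) {
  x <- c(...)
  if (length(x) == 0) x <- stats::setNames(numeric(0), character(0))
  bad <- setdiff(names(x), .elements)
  if (length(bad) > 0) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  out <- stats::setNames(numeric(length(.elements)), .elements)
  out[names(x)] <- x
  out
}

comp_add <- function(a, b) {
  out <- comp()
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

comp_scale <- function(a, k) {
  a * k
}

comp_validate <- function(x, what = "composition") {
  if (any(x < 0)) {
    stop(what, " has negative element count: ",
         paste(names(x)[x < 0], collapse = ", "))
  }
  invisible(x)
}

#' Parse a molecular formula string
#'
#' Understands simple Hill-style formulas over C, H, N, O, S such as
#' `"C13H10N2O"`; used for user-supplied aglycone compositions.
#'
#' @param text formula string.
#' @return elemental composition vector.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  if (!grepl("^([CHNOS][0-9]*)+$", s)) {
    stop("cannot parse formula: '", text, "'")
  }
  m <- gregexpr("[CHNOS][0-9]*", s)[[1]]
  parts <- regmatches(s, gregexpr("[CHNOS][0-9]*", s))[[1]]
  out <- comp()
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- if (nchar(p) > 1) as.numeric(substr(p, 2, nchar(p))) else 1
    out[el] <- out[el] + n
  }
  out
}

#' Format a composition as a molecular formula
#'
#' @param x elemental composition.
#' @return character scalar, Hill order (C, H, then alphabetical).
#' @export
format_formula <- function(x) {
  ord <- c("C", "H", "N", "O", "S")
  keep <- ord[x[ord] > 0]
  paste0(vapply(keep, function(el) {
    n <- x[[el]]
    if (n == 1) el else paste0(el, format(n, scientific = FALSE))
  }, character(1)), collapse = "")
}

#' Mass of an elemental composition
#'
#' @param x elemental composition (named vector over C,H,N,O,S).
#' @param mass_type `"monoisotopic"` (default) or `"average"`.
#' @return mass in Da.
#' @export
formula_mass <- function(x, mass_type = c("monoisotopic", "average")) {
  mass_type <- match.arg(mass_type)
  tab <- if (mass_type == "monoisotopic") .monoisotopic else .average
  sum(tab[.elements] * x[.elements])
}
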
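# Built-in residue and aglycone tables.
#
# A residue composition is the glycosyl residue, i.e. the monosaccharide
# minus one water; a free chain of n residues therefore sums the residue
# compositions and adds back a single H2O for the two termini.

.residue_table <- list(
  GlcA   = list(composition = c(C = 6, H = 8, O = 6),
                class = "uronic"),
  GlcNAc = list(composition = c(C = 8, H = 13, N = 1, O = 5),
                class = "hexosamine"),
  # 4-deoxy-L-threo-hex-4-enopyranosyluronic acid: lyase beta-elimination
  # product, GlcA minus H2O with a 4,5 double bond
  dUA    = list(composition = c(C = 6, H = 6, O = 5),
                class = "uronic"),
  # glucosamine (free amine; GlcNAc minus the acetyl group)
  GlcN   = list(composition = c(C = 6, H = 11, N = 1, O = 4),
                class = "hexosamine"),
  # N-sulfo-glucosamine
  GlcNS  = list(composition = c(C = 6, H = 11, N = 1, O = 7, S = 1),
                class = "hexosamine")
)

.mod_tokens <- c("4-thio", "N-sulfo", "2-O-sulfo", "6-O-sulfo",
                 "4,5-unsaturated", "N-acetyl")

# short grammar codes for modifications (used by parse_chain/format_chain)
.mod_codes <- c(`4S` = "4-thio", NS = "N-sulfo", `2S` = "2-O-sulfo",
                `6S` = "6-O-sulfo", dU = "4,5-unsaturated",
                NAc = "N-acetyl")

# Aglycones are stored as the full substituent group R that replaces the
# hydrogen of the anomeric hydroxyl at the reducing end.  The fluorescein
# entry is a synthetic stand-in (thiourea adduct of fluorescein
# isothiocyanate with the ethylamine linker); it is editable via
# `aglycone(name, formula)`.
.aglycone_table <- list(
  "C2H4-amido-benzaldehyde"    = c(C = 10, H = 10, N = 1, O = 2),
  "C2H4-NH2"                   = c(C = 2, H = 6, N = 1),
  "C2H4-thioamido-fluorescein" = c(C = 23, H = 17, N = 2, O = 5, S = 1)
)

#' Known residue names
#' @return character vector of built-in residue tokens.
#' @export
residue_names <- function() names(.residue_table)

residue_class <- function(name) {
  if (!name %in% names(.residue_table)) {
    stop("unknown residue token: '", name, "'")
  }
  .residue_table[[name]]$class
}

#' Elemental composition of one glycosyl residue
#'
#' Applies the requested modifications to the base residue composition:
#' `4-thio` swaps exactly one ring-substituent O for S, each O-sulfation
#' adds SO3, `N-sulfo` on GlcNAc removes the acetyl (C2H2O) and adds SO3,
#' and `4,5-unsaturated` removes H2O (the lyase elimination product).
#'
#' @param name residue token (see [residue_names()]); `"4SH-GlcNAc"` is
#'   accepted as an alias for GlcNAc with the 4-thio modification.
#' @param mods character vector of modification tokens.
#' @return elemental composition vector.
#' @export
residue_composition <- function(name, mods = character(0)) {
  if (identical(name, "4SH-GlcNAc")) {
    name <- "GlcNAc"
    mods <- union(mods, "4-thio")
  }
  if (!name %in% names(.residue_table)) {
    stop("unknown residue token: '", name, "'")
  }
  bad <- setdiff(mods, .mod_tokens)
  if (length(bad) > 0) {
    stop("unknown modification token(s): ", paste(bad, collapse = ", "))
  }
  x <- comp_add(comp(), .residue_table[[name]]$composition)
  for (m in mods) {
    x <- switch(m,
      "4-thio" = {
        if (x[["O"]] < 1) stop("no oxygen available for 4-thio substitution")
        x + comp(O = -1, S = 1)
      },
      "N-sulfo" = {
        if (residue_class(name) != "hexosamine") {
          stop("N-sulfo applies to hexosamine residues only")
        }
        if (identical(name, "GlcNAc")) {
          # replace the acetyl: GlcNAc -> GlcNS
          x + comp(C = -2, H = -2, O = -1) + comp(S = 1, O = 3)
        } else {
          x + comp(S = 1, O = 3)
        }
      },
      "2-O-sulfo" = x + comp(S = 1, O = 3),
      "6-O-sulfo" = x + comp(S = 1, O = 3),
      "4,5-unsaturated" = x + comp(H = -2, O = -1),
      "N-acetyl" = x
    )
  }
  comp_validate(x, paste0("residue ", name))
  x
}

#' Look up or construct an aglycone
#'
#' @param name aglycone name. Built-ins: `"C2H4-amido-benzaldehyde"`,
#'   `"C2H4-NH2"`, `"C2H4-thioamido-fluorescein"` (the last is a synthetic
#'   stand-in composition and can be overridden via `formula`).
#' @param formula optional molecular formula string overriding the table.
#' @return list with `name` and `composition` (the R group replacing the
#'   anomeric hydroxyl hydrogen).
#' @export
aglycone <- function(name, formula = NULL) {
  if (!is.null(formula)) {
    cmp <- parse_formula(formula)
  } else {
    if (!name %in% names(.aglycone_table)) {
      stop("unknown aglycone '", name, "'; supply `formula` to define it")
    }
    cmp <- comp_add(comp(), .aglycone_table[[name]])
  }
  structure(list(name = name, composition = cmp), class = "gag_aglycone")
}
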
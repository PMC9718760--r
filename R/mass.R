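# Ion mass prediction for glycan chains.
#
# Convention: negative reflector-mode MALDI, singly deprotonated [M-H]-.
# Predicted masses are monoisotopic by default; deprotonation subtracts one
# proton mass (H atom minus the retained electron).

.amac_comp <- c(C = 13, H = 10, N = 2, O = 1)  # 2-aminoacridone

#' Ion species descriptor
#'
#' @param polarity only `"negative"` is supported.
#' @param adduct only the deprotonated molecular ion `"[M-H]-"`.
#' @param mass_type `"monoisotopic"` (default) or `"average"`.
#' @return list of class `ion_species`.
#' @export
ion_species <- function(polarity = "negative", adduct = "[M-H]-",
                        mass_type = c("monoisotopic", "average")) {
  if (!identical(polarity, "negative")) {
    stop("unsupported polarity: ", polarity)
  }
  if (!identical(adduct, "[M-H]-")) {
    stop("unsupported adduct: ", adduct)
  }
  structure(list(polarity = polarity, adduct = adduct,
                 mass_type = match.arg(mass_type)),
            class = "ion_species")
}

#' Predicted ion mass of a chain
#'
#' @param chain a [glycan_chain()] or chain grammar string.
#' @param ion an [ion_species()]; defaults to monoisotopic [M-H]-.
#' @return mass in Da.
#' @examples
#' predicted_mz(addition_product(0))            # 950.29
#' predicted_mz(addition_product(0, thio = TRUE))  # 966.27
#' @export
predicted_mz <- function(chain, ion = ion_species()) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(ion, "ion_species"))
  m <- formula_mass(elemental_composition(chain), ion$mass_type)
  m - .proton_mass
}

#' Mass difference between two chains
#'
#' `predicted_mz(chain_a) - predicted_mz(chain_b)`.  One O->S substitution
#' shifts the mass by +15.9772 Da.
#'
#' @param chain_a,chain_b chains (or grammar strings).
#' @param ion an [ion_species()].
#' @return difference in Da.
#' @export
mass_shift <- function(chain_a, chain_b, ion = ion_species()) {
  predicted_mz(chain_a, ion) - predicted_mz(chain_b, ion)
}

#' AMAC reductive-amination labelled mass of a fragment
#'
#' 2-aminoacridone condenses with the free reducing-end aldehyde and the
#' Schiff base is reduced: labelled M = fragment M + AMAC (C13H10N2O)
#' - H2O + H2, an increment of +194.0844 Da.
#'
#' @param fragment a [glycan_chain()] with a free reducing end.
#' @return list with `exact` (monoisotopic [M-H]- mass) and `nominal`
#'   (nearest integer m/z, half away from zero).
#' @examples
#' amac_label_mz(parse_chain("dUA-S-GlcNAc"))$nominal  # 588
#' @export
amac_label_mz <- function(fragment) {
  if (is.character(fragment)) fragment <- parse_chain(fragment)
  if (!is.null(fragment$aglycone)) {
    stop("reducing end is aglycone-capped; no free aldehyde to label")
  }
  cmp <- elemental_composition(fragment)
  cmp <- comp_add(cmp, .amac_comp) + comp(H = 2) + comp(H = -2, O = -1)
  exact <- formula_mass(cmp) - .proton_mass
  list(exact = exact, nominal = floor(exact + 0.5))
}

#' Mass increment of the AMAC label
#' @return monoisotopic increment in Da (C13H10N2O + H2 - H2O).
#' @export
amac_increment <- function() {
  formula_mass(comp_add(comp(H = 2), .amac_comp) + comp(H = -2, O = -1))
}
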
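# Enzymatic cleavage-site rules.
#
# A bond is cleavable iff its donor/acceptor residue classes match the rule
# AND the linkage heteroatom is oxygen: thio-glycosidic bonds are never cut.
# Heparanase (human endo-beta-glucuronidase) hydrolyses GlcA-O-GlcNAc bonds;
# bacterial heparin lyases cut hexosamine-O-uronate bonds by
# beta-elimination, converting the uronate gaining the new non-reducing end
# into the 4,5-unsaturated dUA (a net -H2O relative to hydrolysis, so the
# fragment mass multiset conserves the parent mass).

#' Enzyme cleavage rule
#'
#' @param name `"heparanase"` or `"heparin-lyase"` (alias `"lyase"`).
#' @return list of class `enzyme_rule` with donor/acceptor residue targets,
#'   required linkage heteroatom (always `"O"`) and mechanism tag.
#' @export
enzyme_rule <- function(name = c("heparanase", "heparin-lyase", "lyase")) {
  name <- match.arg(name)
  if (name == "lyase") name <- "heparin-lyase"
  if (name == "heparanase") {
    structure(list(name = name,
                   donor = "GlcA", acceptor_class = "hexosamine",
                   heteroatom = "O", mechanism = "hydrolysis"),
              class = "enzyme_rule")
  } else {
    structure(list(name = name,
                   donor_class = "hexosamine", acceptor = "GlcA",
                   heteroatom = "O", mechanism = "beta-elimination"),
              class = "enzyme_rule")
  }
}

bond_matches <- function(chain, i, rule) {
  don <- chain$residues[i]
  acc <- chain$residues[i + 1]
  if (chain$linkages[i] != rule$heteroatom) return(FALSE)
  if (rule$name == "heparanase") {
    identical(don, rule$donor) && residue_class(acc) == rule$acceptor_class
  } else {
    residue_class(don) == rule$donor_class && identical(acc, rule$acceptor)
  }
}

#' Simulate an enzymatic digest
#'
#' Cuts every bond matching the rule (exhaustive digestion).  For the lyase
#' the residue at the new non-reducing end of each downstream fragment is
#' converted to dUA (4,5-unsaturated, -H2O).  The chain must alternate
#' uronic acid / hexosamine residues.
#'
#' @param chain a [glycan_chain()] or grammar string.
#' @param rule an [enzyme_rule()] or enzyme name.
#' @return list with `fragments` (list of [glycan_chain()], non-reducing to
#'   reducing order) and `sites` (1-based bond indices cut, bond `i` joining
#'   residues `i` and `i + 1`).
#' @examples
#' cleave(heparosan(5, slinked = TRUE), "heparanase")$sites  # integer(0)
#' @export
cleave <- function(chain, rule) {
  if (is.character(chain)) chain <- parse_chain(chain)
  if (is.character(rule)) rule <- enzyme_rule(rule)
  stopifnot(inherits(chain, "glycan_chain"), inherits(rule, "enzyme_rule"))
  cls <- vapply(chain$residues, residue_class, character(1))
  n <- length(chain$residues)
  if (n > 1 && any(cls[-1] == cls[-n])) {
    stop("chain does not alternate uronic acid / hexosamine residues")
  }
  sites <- if (n > 1) {
    which(vapply(seq_len(n - 1), bond_matches, logical(1),
                 chain = chain, rule = rule))
  } else integer(0)

  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  fragments <- vector("list", length(starts))
  for (f in seq_along(starts)) {
    idx <- starts[f]:ends[f]
    res <- chain$residues[idx]
    mods <- chain$mods[idx]
    if (rule$mechanism == "beta-elimination" && starts[f] > 1) {
      # new non-reducing terminus gains the 4,5-unsaturation
      res[1] <- "dUA"
    }
    links <- if (length(idx) > 1) chain$linkages[idx[-length(idx)]] else character(0)
    agl <- if (ends[f] == n) chain$aglycone else NULL
    fragments[[f]] <- glycan_chain(res, links, mods, agl)
  }
  list(fragments = fragments, sites = sites)
}
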
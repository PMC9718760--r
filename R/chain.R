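# GlycanChain: ordered residues (non-reducing -> reducing end), one glycosidic
# linkage heteroatom (O or S) per inter-residue bond, and an optional
# reducing-end aglycone.

#' Construct a glycan chain
#'
#' Residues are listed from the non-reducing end to the reducing end, the
#' reading order used throughout reports (1-based indexing from the
#' non-reducing terminus).  Linkage `i` is the glycosidic bond between the
#' anomeric carbon (C1) of residue `i` and the 4-position heteroatom of
#' residue `i + 1`; an `"S"` token denotes a thio-glycosidic bond, which
#' implies that the downstream residue carries sulfur at its 4-position.
#'
#' @param residues character vector of residue tokens (see
#'   [residue_names()]); `"4SH-GlcNAc"` is normalised to GlcNAc + 4-thio.
#' @param linkages character vector of `"O"`/`"S"`, length
#'   `length(residues) - 1`.
#' @param mods list of character vectors of modification tokens, one per
#'   residue (recycled from empty).
#' @param aglycone optional [aglycone()] object (or name string) capping the
#'   reducing end through a glycosidic bond.
#' @return object of class `glycan_chain`.
#' @examples
#' heparosan(5, slinked = TRUE)
#' glycan_chain(c("GlcA", "GlcNAc"), "S")
#' @export
glycan_chain <- function(residues, linkages = NULL, mods = NULL,
                         aglycone = NULL) {
  stopifnot(is.character(residues), length(residues) >= 1)
  if (is.null(mods)) mods <- rep(list(character(0)), length(residues))
  stopifnot(length(mods) == length(residues))
  # normalise the 4SH alias
  for (i in seq_along(residues)) {
    if (identical(residues[i], "4SH-GlcNAc")) {
      residues[i] <- "GlcNAc"
      mods[[i]] <- union(mods[[i]], "4-thio")
    }
    residue_class(residues[i])  # validates token
  }
  if (is.null(linkages)) linkages <- rep("O", length(residues) - 1L)
  if (length(linkages) != length(residues) - 1L) {
    stop("need exactly length(residues) - 1 linkages")
  }
  if (length(linkages) > 0 && !all(linkages %in% c("O", "S"))) {
    stop("linkage heteroatoms must be 'O' or 'S'")
  }
  if (is.character(aglycone)) aglycone <- aglycone(aglycone)
  if (!is.null(aglycone) && !inherits(aglycone, "gag_aglycone")) {
    stop("aglycone must be NULL, a name, or an aglycone() object")
  }
  structure(list(residues = residues, linkages = linkages, mods = mods,
                 aglycone = aglycone),
            class = "glycan_chain")
}

#' @export
print.glycan_chain <- function(x, ...) {
  cat("<glycan_chain> ", length(x$residues), " residues\n  ",
      format_chain(x), "\n", sep = "")
  invisible(x)
}

#' @export
length.glycan_chain <- function(x) length(x$residues)

#' Number of O->S substitutions carried by a chain
#'
#' Counts residues whose 4-position heteroatom is sulfur, either through an
#' explicit 4-thio modification (free thiol at a terminus) or by being the
#' downstream partner of an S-linkage (the same atom, so never
#' double-counted).
#'
#' @param chain a [glycan_chain()].
#' @return integer count.
#' @export
n_thio_substitutions <- function(chain) {
  n <- length(chain$residues)
  thio <- vapply(chain$mods, function(m) "4-thio" %in% m, logical(1))
  if (n > 1) {
    down <- which(chain$linkages == "S") + 1L
    thio[down] <- TRUE
  }
  sum(thio)
}

#' Elemental composition of a glycan chain
#'
#' Sums the residue compositions, adds H2O for the chain termini, applies
#' one O->S substitution per thio 4-position (see
#' [n_thio_substitutions()]), and, when an aglycone is present, adds its
#' composition minus one hydrogen (the glycosidic substitution of the
#' anomeric hydroxyl).
#'
#' @param chain a [glycan_chain()].
#' @return elemental composition vector.
#' @export
elemental_composition <- function(chain) {
  stopifnot(inherits(chain, "glycan_chain"))
  total <- comp(H = 2, O = 1)
  for (i in seq_along(chain$residues)) {
    mods_i <- setdiff(chain$mods[[i]], "4-thio")  # handled globally below
    total <- comp_add(total, residue_composition(chain$residues[i], mods_i))
  }
  k <- n_thio_substitutions(chain)
  total <- total + comp(O = -k, S = k)
  if (!is.null(chain$aglycone)) {
    total <- comp_add(total, chain$aglycone$composition) + comp(H = -1)
  }
  comp_validate(total, "chain")
  total
}

# ---- chain grammar -------------------------------------------------------

#' Parse the chain grammar
#'
#' Residue tokens joined by `-O-` / `-S-`, each token optionally carrying a
#' `@mods` suffix with comma-separated modification codes
#' (`4S`, `NS`, `2S`, `6S`, `dU`, `NAc`), e.g.
#' `"GlcA-S-GlcNAc@4S-O-GlcA"`.  A final element `R(<aglycone name>)`
#' attaches an aglycone through the preceding linkage token.
#'
#' @param text chain description string.
#' @return a [glycan_chain()].
#' @export
parse_chain <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  parts <- strsplit(s, "-([OS])-")[[1]]
  links <- regmatches(s, gregexpr("-([OS])-", s))[[1]]
  links <- gsub("-", "", links)
  agl <- NULL
  if (grepl("^R\\(.+\\)$", parts[length(parts)])) {
    agl <- aglycone(sub("^R\\((.+)\\)$", "\\1", parts[length(parts)]))
    parts <- parts[-length(parts)]
  }
  if (length(parts) < 1) stop("empty chain description")
  expected <- length(parts) - 1L + as.integer(!is.null(agl))
  if (length(links) != expected) {
    stop("malformed chain description: '", text, "'")
  }
  agl_link <- NULL
  if (!is.null(agl)) {
    agl_link <- links[length(links)]
    if (agl_link != "O") stop("aglycone must be O-linked")
    links <- links[-length(links)]
  }
  residues <- character(length(parts))
  mods <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    tok <- strsplit(parts[i], "@", fixed = TRUE)[[1]]
    residues[i] <- tok[1]
    mods[[i]] <- character(0)
    if (length(tok) > 1) {
      codes <- strsplit(tok[2], ",", fixed = TRUE)[[1]]
      bad <- setdiff(codes, names(.mod_codes))
      if (length(bad) > 0) {
        stop("unknown modification code(s): ", paste(bad, collapse = ", "))
      }
      mods[[i]] <- unname(.mod_codes[codes])
    }
  }
  glycan_chain(residues, links, mods, agl)
}

#' Serialise a chain to the grammar
#'
#' Inverse of [parse_chain()]; `parse_chain(format_chain(x))` round-trips.
#'
#' @param chain a [glycan_chain()].
#' @return character scalar.
#' @export
format_chain <- function(chain) {
  code_of <- stats::setNames(names(.mod_codes), .mod_codes)
  toks <- vapply(seq_along(chain$residues), function(i) {
    t <- chain$residues[i]
    m <- chain$mods[[i]]
    if (length(m) > 0) t <- paste0(t, "@", paste(code_of[m], collapse = ","))
    t
  }, character(1))
  out <- toks[1]
  for (i in seq_along(chain$linkages)) {
    out <- paste0(out, "-", chain$linkages[i], "-", toks[i + 1])
  }
  if (!is.null(chain$aglycone)) {
    out <- paste0(out, "-O-R(", chain$aglycone$name, ")")
  }
  out
}

# ---- convenience constructors -------------------------------------------

#' Heparosan and hemi-A S-linked heparosan chains
#'
#' Builds `[GlcA-GlcNAc]_n` read from the non-reducing end.  With
#' `slinked = TRUE` the chain is the hemi-A analog: every GlcA->GlcNAc bond
#' is thio-glycosidic while every GlcNAc->GlcA bond stays O-linked.
#'
#' @param n_disacch number of GlcA-GlcNAc disaccharide repeats.
#' @param slinked logical; hemi-A thio linkage pattern.
#' @param aglycone optional aglycone (name or [aglycone()]).
#' @param n_residues optionally override the residue count (e.g. odd
#'   lengths); alternation still starts at GlcA.
#' @return a [glycan_chain()].
#' @export
heparosan <- function(n_disacch = 5, slinked = FALSE, aglycone = NULL,
                      n_residues = NULL) {
  n <- if (is.null(n_residues)) 2L * n_disacch else as.integer(n_residues)
  stopifnot(n >= 1)
  residues <- rep(c("GlcA", "GlcNAc"), length.out = n)
  links <- character(0)
  if (n > 1) {
    # bond i joins residue i (donor C1) to residue i+1; GlcA donors sit at
    # odd i, and carry the S in the hemi-A pattern
    links <- ifelse(seq_len(n - 1) %% 2 == 1 & slinked, "S", "O")
  }
  glycan_chain(residues, links, aglycone = aglycone)
}

#' Single-addition and co-polymerisation products on the trisaccharide
#' acceptor
#'
#' Product chains `(GlcNAc-GlcA)_k-GlcNAc-R'` where
#' `R' = GlcA-GlcNAc-GlcA-C2H4-amido-benzaldehyde` is the aldehyde-glycoside
#' acceptor.  With `thio = TRUE` every hexosamine added enzymatically (the
#' `k + 1` newest GlcNAc residues) is the 4-thio analog, so the chain
#' carries `k + 1` sulfur atoms: one free terminal thiol plus `k`
#' thio-glycosidic bonds.
#'
#' @param k number of complete disaccharide repeats added beyond the single
#'   sugar addition (0, 1 or 2 for the reported products).
#' @param thio logical; use the 4-SH-GlcNAc donor.
#' @return a [glycan_chain()].
#' @export
addition_product <- function(k = 0, thio = FALSE) {
  stopifnot(k >= 0)
  residues <- c(rep(c("GlcNAc", "GlcA"), k), "GlcNAc",
                "GlcA", "GlcNAc", "GlcA")
  n <- length(residues)
  mods <- rep(list(character(0)), n)
  links <- rep("O", n - 1)
  if (thio) {
    mods[[1]] <- "4-thio"  # non-reducing terminal free thiol
    if (k > 0) {
      # GlcA donors at even positions 2, 4, ... link onto thio acceptors
      s_bonds <- 2L * seq_len(k)
      links[s_bonds] <- "S"
    }
  }
  glycan_chain(residues, links, mods,
               aglycone = aglycone("C2H4-amido-benzaldehyde"))
}
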
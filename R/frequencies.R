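# Conformer frequency tables over ensembles.

#' Residue indices of the most internal disaccharide
#'
#' For an n-residue chain returns residues floor(n/2) and floor(n/2) + 1,
#' the innermost uronate/hexosamine pair of an even-length chain; used to
#' limit chain-end effects when reporting pucker statistics.
#'
#' @param n number of residues (>= 2).
#' @return integer vector of two residue indices.
#' @export
internal_disaccharide <- function(n) {
  stopifnot(n >= 2)
  k <- floor(n / 2)
  c(k, k + 1L)
}

#' Conformer and class frequencies per residue over an ensemble
#'
#' Runs the Cremer-Pople transform and nearest-reference classification on
#' the selected residue rings in every frame and tabulates normalised
#' frequencies (summing to 1 per residue).  The interconvertible skew/boat
#' group (1S5, 1S3, 1,4B, B2,5) is flagged in the output so its pooled
#' frequency can be read off directly.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param residues `"internal"` (default: the most internal disaccharide),
#'   `"all"`, or an integer vector of residue indices (1-based from the
#'   non-reducing end).
#' @return data.frame with columns `residue_index`, `residue_name`,
#'   `label`, `class`, `skew_boat_group`, `count`, `frequency`.
#' @export
pucker_frequencies <- function(ensemble, residues = "internal") {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  n <- max(ensemble$atoms$residue_index)
  if (identical(residues, "internal")) {
    residues <- internal_disaccharide(n)
  } else if (identical(residues, "all")) {
    residues <- seq_len(n)
  }
  stopifnot(is.numeric(residues), all(residues >= 1), all(residues <= n))
  nf <- length(ensemble$frames)
  out <- list()
  for (ri in residues) {
    labs <- character(nf)
    cls <- character(nf)
    for (f in seq_len(nf)) {
      ring <- tryCatch(
        extract_ring(ensemble$atoms, ensemble$frames[[f]], ri),
        error = function(e) {
          stop("frame ", f, ", residue ", ri, ": ", conditionMessage(e))
        })
      st <- cremer_pople(ring)
      cc <- classify_conformer(st)
      labs[f] <- cc$name
      cls[f] <- cc$class
    }
    tab <- table(labs)
    cls_of <- stats::setNames(conformer_table()$class, conformer_table()$name)
    out[[length(out) + 1]] <- data.frame(
      residue_index = ri,
      residue_name = ensemble$chain$residues[ri],
      label = names(tab),
      class = unname(cls_of[names(tab)]),
      skew_boat_group = names(tab) %in% .skew_boat_group,
      count = as.integer(tab),
      frequency = as.integer(tab) / nf,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
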
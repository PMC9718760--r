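# Trajectory geometry: end-to-end lengths, glycosidic bond geometry,
# histograms, and trajectory bookkeeping.

atom_index <- function(atoms, residue_index, name) {
  k <- which(atoms$residue_index == residue_index & atoms$atom == name)
  if (length(k) != 1) {
    stop("atom ", name, " of residue ", residue_index,
         if (length(k) == 0) " not found" else " not unique")
  }
  k
}

#' Chain topology of an ensemble
#'
#' Identifies the two terminal atoms used for end-to-end measurement and
#' the glycosidic bond triplets C1-X-C4 (X = O or S).  The non-reducing
#' terminus is "O4 of the non-reducing sugar", generalised to the
#' position-4 exocyclic heteroatom (S4 for a 4-thio terminal residue)
#' unless `strict_o4` is set.
#'
#' @param ensemble a `conformer_ensemble` (see [build_ensemble()] or
#'   [read_frames()] plus [as_ensemble()]).
#' @param strict_o4 if TRUE, require the literal O4 terminal atom and fail
#'   on a thio terminus.
#' @return list with `nonreducing` / `reducing` atom row indices and a
#'   data.frame `linkages` (`index`, `heteroatom`, atom row indices `c1`,
#'   `x`, `c4`).
#' @export
chain_topology <- function(ensemble, strict_o4 = FALSE) {
  atoms <- ensemble$atoms
  n <- max(atoms$residue_index)
  term <- atoms$atom[atoms$residue_index == 1 & atoms$atom %in% c("O4", "S4")]
  if (length(term) != 1) stop("non-reducing terminal 4-heteroatom not found")
  if (strict_o4 && term != "O4") {
    stop("strict O4 mode: non-reducing terminus carries ", term)
  }
  red <- atom_index(atoms, n, "O1")
  nonred <- atom_index(atoms, 1, term)
  links <- NULL
  if (n > 1) {
    het <- ensemble$chain$linkages
    links <- data.frame(
      index = seq_len(n - 1),
      heteroatom = het,
      c1 = vapply(seq_len(n - 1), function(i) atom_index(atoms, i, "C1"), 1L),
      x = vapply(seq_len(n - 1), function(i)
        atom_index(atoms, i + 1, paste0(het[i], "4")), 1L),
      c4 = vapply(seq_len(n - 1), function(i) atom_index(atoms, i + 1, "C4"), 1L),
      stringsAsFactors = FALSE
    )
  }
  list(nonreducing = nonred, reducing = red, linkages = links)
}

#' Per-frame end-to-end distance
#'
#' Euclidean distance from O1 of the reducing sugar to the position-4
#' heteroatom (O4, or S4 for thio termini) of the non-reducing terminus.
#'
#' @inheritParams chain_topology
#' @param topology optional precomputed [chain_topology()].
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
end_to_end <- function(ensemble, topology = NULL, strict_o4 = FALSE) {
  if (is.null(topology)) topology <- chain_topology(ensemble, strict_o4)
  vapply(ensemble$frames, function(xyz) {
    sqrt(sum((xyz[topology$reducing, ] - xyz[topology$nonreducing, ])^2))
  }, numeric(1))
}

vec_angle_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu < 1e-9 || cv < 1e-9) stop("coincident atoms in angle computation")
  acos(pmin(1, pmax(-1, sum(u * v) / (cu * cv)))) * 180 / pi
}

#' Per-frame, per-linkage glycosidic geometry
#'
#' @inheritParams end_to_end
#' @return data.frame with columns `frame`, `linkage`, `heteroatom`,
#'   `r_c1x` and `r_xc4` (bond lengths, Angstrom), `angle` (interior
#'   C1-X-C4 angle, degrees).
#' @export
glycosidic_geometry <- function(ensemble, topology = NULL) {
  if (is.null(topology)) topology <- chain_topology(ensemble)
  lk <- topology$linkages
  if (is.null(lk)) stop("chain has no glycosidic linkages")
  out <- vector("list", length(ensemble$frames))
  for (f in seq_along(ensemble$frames)) {
    xyz <- ensemble$frames[[f]]
    r1 <- sqrt(rowSums((xyz[lk$c1, , drop = FALSE] - xyz[lk$x, , drop = FALSE])^2))
    r2 <- sqrt(rowSums((xyz[lk$c4, , drop = FALSE] - xyz[lk$x, , drop = FALSE])^2))
    ang <- vapply(seq_len(nrow(lk)), function(i) {
      vec_angle_deg(xyz[lk$c1[i], ] - xyz[lk$x[i], ],
                    xyz[lk$c4[i], ] - xyz[lk$x[i], ])
    }, numeric(1))
    out[[f]] <- data.frame(frame = f, linkage = lk$index,
                           heteroatom = lk$heteroatom,
                           r_c1x = r1, r_xc4 = r2, angle = ang,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-frame contour length bound
#'
#' Length of the covalent path from the non-reducing terminal heteroatom
#' through each ring (C4 to C1) and glycosidic bond down to the reducing
#' O1.  By the triangle inequality the end-to-end distance never exceeds
#' this value.
#'
#' @inheritParams end_to_end
#' @return numeric vector, one length (Angstrom) per frame.
#' @export
contour_length <- function(ensemble, topology = NULL) {
  if (is.null(topology)) topology <- chain_topology(ensemble)
  atoms <- ensemble$atoms
  n <- max(atoms$residue_index)
  c4 <- vapply(seq_len(n), function(i) atom_index(atoms, i, "C4"), 1L)
  c1 <- vapply(seq_len(n), function(i) atom_index(atoms, i, "C1"), 1L)
  path <- c(topology$nonreducing)
  for (i in seq_len(n)) {
    path <- c(path, c4[i], c1[i])
    if (i < n) path <- c(path, topology$linkages$x[i])
  }
  path <- c(path, topology$reducing)
  vapply(ensemble$frames, function(xyz) {
    seg <- diff(xyz[path, , drop = FALSE])
    sum(sqrt(rowSums(seg^2)))
  }, numeric(1))
}

#' Histogram of a length series
#'
#' Fixed-width bins anchored at `lower` (default 0); the upper limit is the
#' smallest bin edge covering the data (or `upper` if given).  Counts sum
#' to the number of observations.
#'
#' @param x numeric vector (e.g. end-to-end distances, Angstrom).
#' @param bin_width bin width (default 0.5 Angstrom).
#' @param lower,upper range policy; `upper = NULL` extends to cover the
#'   data.
#' @return data.frame with `lower`, `upper`, `count`.
#' @export
length_histogram <- function(x, bin_width = 0.5, lower = 0, upper = NULL) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive")
  }
  stopifnot(length(x) >= 1, all(is.finite(x)))
  if (any(x < lower)) stop("data below histogram lower bound")
  if (is.null(upper)) {
    upper <- lower + bin_width * max(1, ceiling((max(x) - lower) / bin_width))
    if (upper <= max(x)) upper <- upper + bin_width  # right-open top edge
  } else if (any(x > upper)) {
    stop("data above histogram upper bound")
  }
  edges <- seq(lower, upper, by = bin_width)
  if (edges[length(edges)] < upper) edges <- c(edges, upper)
  idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE),
              length(edges) - 1)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             count = counts)
}

#' Trajectory bookkeeping
#'
#' `frame_count()` is the number of snapshots saved at a fixed interval
#' over a production run: `floor(duration / interval)` (e.g. 5e6 ps at
#' 10 ps -> 500,000).  `retained_duration()` is the production time left
#' after discarding an initial equilibration segment.
#'
#' @param duration production duration (any time unit).
#' @param interval save interval (same unit); must not exceed `duration`.
#' @return integer frame count.
#' @export
frame_count <- function(duration, interval) {
  stopifnot(duration > 0, interval > 0)
  if (interval > duration) stop("save interval exceeds duration")
  as.integer(floor(duration / interval))
}

#' @rdname frame_count
#' @param total total simulated duration.
#' @param discard initial duration discarded.
#' @export
retained_duration <- function(total, discard) {
  stopifnot(total > 0, discard >= 0, discard <= total)
  total - discard
}
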
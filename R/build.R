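# Desk-scale conformational ensemble generator.
#
# Each frame draws a canonical ring conformer per residue (multinomial over
# configured mixture weights), joins consecutive rings through glycosidic
# internal coordinates Boltzmann-sampled from the harmonic linkage
# parameters, with independent von Mises glycosidic torsions, and rejects
# frames with hard-sphere steric overlap (bounded torsion resampling).
# This is a stand-in for microsecond explicit-solvent MD: ring conformer
# frequencies and linkage geometry are inputs, not predictions.

.ring_names <- c("O5", "C1", "C2", "C3", "C4", "C5")

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# tetrahedral substituent direction at atom `at` with ring neighbours nb1,
# nb2; `side` picks the face (+/-1)
subst_dir <- function(at, nb1, nb2, side = 1) {
  u1 <- unit3(nb1 - at)
  u2 <- unit3(nb2 - at)
  b <- -unit3(u1 + u2)
  p <- unit3(cross3(u1, u2))
  unit3(0.5773503 * b + side * 0.8164966 * p)
}

# natural extension reference frame: place D bonded to C with bond length
# r, angle(B,C,D) = theta, dihedral(A,B,C,D) = tau (degrees)
place_atom <- function(A, B, C, r, theta, tau) {
  theta <- theta * pi / 180
  tau <- tau * pi / 180
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(tau), r * sin(theta) * sin(tau))
  C + cbind(bc, m, n) %*% d
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Rodrigues rotation matrix about unit axis by angle (degrees)
rot_axis <- function(axis, angle_deg) {
  a <- unit3(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotation aligning unit vector a onto unit vector b
rot_align <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  v <- cross3(a, b)
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any perpendicular axis
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rot_axis(cross3(a, ref), 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

# ---- atom roster ---------------------------------------------------------

# Atom roster per residue: the six ring atoms, the position-4 exocyclic
# heteroatom (O4/S4; for residue i >= 2 this IS the glycosidic atom of bond
# i-1), one pseudo-atom for the main exocyclic group (N2 = N-acetyl of a
# hexosamine, C6 = carboxylate carbon of a uronate), and O1 on the reducing
# residue.
ensemble_atoms <- function(chain) {
  n <- length(chain$residues)
  rows <- list()
  for (i in seq_len(n)) {
    res <- chain$residues[i]
    thio4 <- "4-thio" %in% chain$mods[[i]] ||
      (i > 1 && chain$linkages[i - 1] == "S")
    het4 <- if (thio4) "S4" else "O4"
    pseudo <- if (residue_class(res) == "hexosamine") "N2" else "C6"
    nm <- c(.ring_names, het4, pseudo)
    if (i == n) nm <- c(nm, "O1")
    rows[[i]] <- data.frame(atom = nm, residue_index = i,
                            residue_name = res,
                            element = substr(nm, 1, 1),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# ---- ensemble spec -------------------------------------------------------

#' Specification of a synthetic conformational ensemble
#'
#' @param chain a [glycan_chain()] or grammar string (no aglycone).
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed; mandatory, every frame derives its own RNG
#'   substream from it by a counter offset.
#' @param temperature temperature (K) for the Boltzmann sampling of
#'   linkage geometry.
#' @param mixtures named list of per-residue-name conformer mixtures, e.g.
#'   `list(GlcNAc = c("1C4" = 0.6, "4C1" = 0.4))`; weights must sum to 1.
#'   Residues without an entry stay in 4C1.
#' @param params named list of [linkage_params()] keyed by heteroatom
#'   (defaults for `"O"` and `"S"` supplied automatically).
#' @param torsion named list per heteroatom with von Mises glycosidic
#'   torsion settings `phi_mean`, `phi_kappa`, `psi_mean`, `psi_kappa`
#'   (degrees / concentration; kappa = 0 is uniform).  The default gives
#'   the S-link a lower concentration than the O-link - the "floppier"
#'   thio chain.
#' @param Q ring puckering amplitude used for the canonical rigid rings.
#' @param clash_radius hard-sphere overlap threshold between heavy atoms
#'   of non-adjacent residues (Angstrom).
#' @param max_retries torsion resampling attempts per frame before
#'   failing.
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(chain, n_frames, seed, temperature = 298,
                          mixtures = list(),
                          params = list(),
                          torsion = list(),
                          Q = 0.57, clash_radius = 1.8, max_retries = 50) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(chain, "glycan_chain"))
  if (!is.null(chain$aglycone)) {
    stop("ensemble generation supports plain chains (no aglycone)")
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_frames >= 1, temperature > 0)
  tab <- conformer_table()
  for (nm in names(mixtures)) {
    w <- mixtures[[nm]]
    if (is.null(names(w)) || !all(names(w) %in% tab$name)) {
      stop("mixture for ", nm, " has unknown conformer labels")
    }
    if (abs(sum(w) - 1) > 1e-8) {
      stop("mixture weights for ", nm, " must sum to 1")
    }
  }
  defaults <- list(O = linkage_params("O"), S = linkage_params("S"))
  for (h in names(params)) defaults[[h]] <- params[[h]]
  tor_def <- list(
    O = list(phi_mean = 180, phi_kappa = 10, psi_mean = 180, psi_kappa = 10),
    S = list(phi_mean = 180, phi_kappa = 3, psi_mean = 180, psi_kappa = 3)
  )
  for (h in names(torsion)) tor_def[[h]] <- utils::modifyList(tor_def[[h]], torsion[[h]])
  structure(list(chain = chain, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), temperature = temperature,
                 mixtures = mixtures, params = defaults, torsion = tor_def,
                 Q = Q, clash_radius = clash_radius,
                 max_retries = as.integer(max_retries)),
            class = "ensemble_spec")
}

frame_seed <- function(seed, frame) {
  (as.double(seed) + 1000003 * as.double(frame)) %% 2147483647
}

# ---- frame assembly ------------------------------------------------------

build_frame <- function(spec, labels, atoms, clash_pairs) {
  chain <- spec$chain
  n <- length(chain$residues)
  het <- chain$linkages
  # linkage internal coordinates
  r1 <- r2 <- angle <- phi_t <- psi_t <- numeric(max(n - 1, 0))
  for (i in seq_len(n - 1)) {
    p <- spec$params[[het[i]]]
    s <- sample_harmonic(p, spec$temperature, 1)
    r2b <- sample_harmonic(p, spec$temperature, 1)
    r1[i] <- s$length
    r2[i] <- r2b$length
    angle[i] <- s$angle
    tor <- spec$torsion[[het[i]]]
    phi_t[i] <- rvonmises_deg(1, tor$phi_mean, tor$phi_kappa)
    psi_t[i] <- rvonmises_deg(1, tor$psi_mean, tor$psi_kappa)
  }

  assemble <- function(phi_t, psi_t) {
    rings <- vector("list", n)
    xatoms <- matrix(NA_real_, max(n - 1, 0), 3)
    rings[[1]] <- canonical_ring(labels[1], spec$Q)
    for (i in seq_len(n - 1)) {
      rg <- rings[[i]]
      d1 <- subst_dir(rg["C1", ], rg["O5", ], rg["C2", ], side = -1)
      X <- rg["C1", ] + r1[i] * d1
      c4p <- as.vector(place_atom(rg["O5", ], rg["C1", ], X,
                                  r2[i], angle[i], phi_t[i]))
      nxt <- canonical_ring(labels[i + 1], spec$Q)
      d4c <- subst_dir(nxt["C4", ], nxt["C3", ], nxt["C5", ], side = 1)
      u <- unit3(X - c4p)
      R <- rot_align(d4c, u)
      nxt <- sweep(nxt, 2, nxt["C4", ]) %*% t(R)
      nxt <- sweep(nxt, 2, c4p, `+`)
      colnames(nxt) <- c("x", "y", "z")
      # spin about the X-C4 bond to the sampled psi torsion
      d0 <- dihedral_deg(rg["C1", ], X, nxt["C4", ], nxt["C5", ])
      spin <- function(m, a) {
        Rs <- rot_axis(u, a)
        sweep(sweep(m, 2, c4p) %*% t(Rs), 2, c4p, `+`)
      }
      cand <- spin(nxt, psi_t[i] - d0)
      d1n <- dihedral_deg(rg["C1", ], X, cand["C4", ], cand["C5", ])
      err <- abs(((d1n - psi_t[i] + 180) %% 360) - 180)
      if (err > 1e-6) cand <- spin(nxt, -(psi_t[i] - d0))
      rownames(cand) <- .ring_names
      rings[[i + 1]] <- cand
      xatoms[i, ] <- X
    }
    list(rings = rings, xatoms = xatoms)
  }

  coords_of <- function(parts) {
    rings <- parts$rings
    xyz <- matrix(NA_real_, nrow(atoms), 3)
    row <- 1L
    for (i in seq_len(n)) {
      rg <- rings[[i]]
      xyz[row:(row + 5), ] <- rg
      row <- row + 6L
      # position-4 heteroatom
      if (i == 1) {
        thio <- atoms$atom[atoms$residue_index == 1 &
                             atoms$atom %in% c("O4", "S4")] == "S4"
        r0 <- spec$params[[if (thio) "S" else "O"]]$r0
        xyz[row, ] <- rg["C4", ] +
          r0 * subst_dir(rg["C4", ], rg["C3", ], rg["C5", ], side = 1)
      } else {
        xyz[row, ] <- parts$xatoms[i - 1, ]
      }
      row <- row + 1L
      # pseudo exocyclic group
      if (residue_class(chain$residues[i]) == "hexosamine") {
        xyz[row, ] <- rg["C2", ] +
          1.45 * subst_dir(rg["C2", ], rg["C1", ], rg["C3", ], side = -1)
      } else {
        xyz[row, ] <- rg["C5", ] +
          1.52 * subst_dir(rg["C5", ], rg["C4", ], rg["O5", ], side = 1)
      }
      row <- row + 1L
      if (i == n) {
        xyz[row, ] <- rg["C1", ] +
          1.43 * subst_dir(rg["C1", ], rg["O5", ], rg["C2", ], side = -1)
        row <- row + 1L
      }
    }
    xyz
  }

  has_clash <- function(xyz) {
    if (nrow(clash_pairs) == 0) return(FALSE)
    d2 <- rowSums((xyz[clash_pairs[, 1], , drop = FALSE] -
                     xyz[clash_pairs[, 2], , drop = FALSE])^2)
    any(d2 < spec$clash_radius^2)
  }

  for (try in seq_len(spec$max_retries + 1L)) {
    xyz <- coords_of(assemble(phi_t, psi_t))
    if (!has_clash(xyz)) return(xyz)
    for (i in seq_len(n - 1)) {
      tor <- spec$torsion[[het[i]]]
      phi_t[i] <- rvonmises_deg(1, tor$phi_mean, tor$phi_kappa)
      psi_t[i] <- rvonmises_deg(1, tor$psi_mean, tor$psi_kappa)
    }
  }
  stop("frame generation failed: steric clash persisted after ",
       spec$max_retries, " torsion resamples")
}

#' Build a synthetic conformational ensemble
#'
#' Deterministic given the spec seed: frame `f` uses an RNG substream
#' seeded at `(seed + 1000003 f) mod (2^31 - 1)`, so identical specs give
#' bit-identical ensembles.
#'
#' @param spec an [ensemble_spec()].
#' @return object of class `conformer_ensemble`: list with `chain`,
#'   `atoms` (atom roster data.frame), `frames` (list of n_atoms x 3
#'   coordinate matrices, Angstrom), `labels` (n_frames x n_residues
#'   matrix of drawn conformer labels) and `provenance`.
#' @export
build_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  chain <- spec$chain
  n <- length(chain$residues)
  atoms <- ensemble_atoms(chain)
  # clash pairs: heavy-atom pairs from residues at least 2 apart
  ridx <- atoms$residue_index
  pairs <- which(outer(ridx, ridx, function(a, b) b - a >= 2), arr.ind = TRUE)
  clash_pairs <- pairs[, c(2, 1), drop = FALSE]  # (row < col) ordering
  colnames(clash_pairs) <- c("i", "j")

  tab <- conformer_table()
  frames <- vector("list", spec$n_frames)
  labels <- matrix(NA_character_, spec$n_frames, n)
  for (f in seq_len(spec$n_frames)) {
    set.seed(frame_seed(spec$seed, f))
    lab <- character(n)
    for (i in seq_len(n)) {
      w <- spec$mixtures[[chain$residues[i]]]
      if (is.null(w)) {
        lab[i] <- "4C1"
      } else {
        lab[i] <- sample(names(w), 1, prob = w)
      }
    }
    labels[f, ] <- lab
    frames[[f]] <- build_frame(spec, lab, atoms, clash_pairs)
  }
  structure(list(chain = chain, atoms = atoms, frames = frames,
                 labels = labels,
                 provenance = list(seed = spec$seed,
                                   n_frames = spec$n_frames,
                                   temperature = spec$temperature,
                                   chain = format_chain(chain))),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", length(x$frames), " frames, ",
      nrow(x$atoms), " atoms, chain ", format_chain(x$chain), "\n", sep = "")
  invisible(x)
}

#' Assemble an ensemble object from raw frames
#'
#' Used after [read_frames()] to re-attach chain topology to a coordinate
#' set produced elsewhere.
#'
#' @param chain the [glycan_chain()] the frames describe.
#' @param atoms atom roster data.frame (`atom`, `residue_index`,
#'   `residue_name`, `element`).
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @return a `conformer_ensemble`.
#' @export
as_ensemble <- function(chain, atoms, frames) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(chain, "glycan_chain"), is.list(frames),
            length(frames) >= 1)
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != nrow(atoms) || ncol(f) != 3) {
      stop("each frame must be an n_atoms x 3 matrix matching the roster")
    }
  }
  structure(list(chain = chain, atoms = atoms, frames = frames,
                 labels = NULL,
                 provenance = list(source = "external")),
            class = "conformer_ensemble")
}
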
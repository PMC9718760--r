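# Frame I/O: multi-MODEL PDB (canonical interchange, fixed width, 3-decimal
# Angstrom) and multi-frame XYZ (frictionless synthetic data; the atom
# label column carries "name:residue_name:residue_index" so the load is
# lossless).

.pdb_resname <- c(GlcA = "GCA", GlcNAc = "NAG", dUA = "UAP",
                  GlcN = "GCS", GlcNS = "SGN")
.pdb_resname_rev <- stats::setNames(names(.pdb_resname), .pdb_resname)

#' Write ensemble frames
#'
#' @param ensemble a `conformer_ensemble`.
#' @param path output file.
#' @param format `"pdb"` (multi-MODEL, default) or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(ensemble, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  atoms <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    resn <- .pdb_resname[atoms$residue_name]
    resn[is.na(resn)] <- "UNK"
    for (f in seq_along(ensemble$frames)) {
      xyz <- ensemble$frames[[f]]
      writeLines(sprintf("MODEL     %4d", f), con)
      lines <- vapply(seq_len(nrow(atoms)), function(i) {
        nm <- atoms$atom[i]
        nm4 <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
        sprintf("ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                i, nm4, resn[i], atoms$residue_index[i],
                xyz[i, 1], xyz[i, 2], xyz[i, 3], atoms$element[i])
      }, character(1))
      writeLines(lines, con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    lab <- paste(atoms$atom, atoms$residue_name, atoms$residue_index,
                 sep = ":")
    for (f in seq_along(ensemble$frames)) {
      xyz <- ensemble$frames[[f]]
      writeLines(as.character(nrow(atoms)), con)
      writeLines(sprintf("frame %d", f), con)
      writeLines(sprintf("%-24s %14.6f %14.6f %14.6f",
                         lab, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

#' Read multi-frame coordinates
#'
#' PDB frames are delimited by MODEL/ENDMDL records; XYZ frames by the
#' per-frame atom-count header.  The atom roster must be identical across
#' frames.
#'
#' @param path input file.
#' @param format `"pdb"` or `"xyz"`; default guesses from the extension.
#' @return list of class `frame_set` with `atoms` (roster data.frame) and
#'   `frames` (list of n x 3 coordinate matrices).
#' @export
read_frames <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  format <- match.arg(format, c("pdb", "xyz"))
  lines <- readLines(path)
  if (format == "pdb") read_pdb_lines(lines) else read_xyz_lines(lines)
}

read_pdb_lines <- function(lines) {
  frames <- list()
  roster <- NULL
  cur <- NULL
  in_model <- FALSE
  has_model <- any(startsWith(lines, "MODEL"))
  if (!has_model) in_model <- TRUE
  for (k in seq_along(lines)) {
    ln <- lines[k]
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      in_model <- TRUE
      cur <- list()
    } else if (startsWith(rec, "ENDMDL")) {
      frames[[length(frames) + 1]] <- cur
      cur <- NULL
      in_model <- FALSE
    } else if (in_model && (rec == "ATOM  " || rec == "HETATM")) {
      if (nchar(ln) < 54) stop("malformed ATOM record at line ", k)
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (any(is.na(c(x, y, z)))) stop("malformed coordinates at line ", k)
      if (is.null(cur)) cur <- list()
      cur[[length(cur) + 1]] <- list(
        atom = trimws(substr(ln, 13, 16)),
        resname = trimws(substr(ln, 18, 20)),
        resid = suppressWarnings(as.integer(substr(ln, 23, 26))),
        xyz = c(x, y, z))
    }
  }
  if (!has_model && !is.null(cur)) frames[[1]] <- cur
  if (length(frames) == 0) stop("no coordinate frames found")
  to_roster <- function(fr) {
    data.frame(
      atom = vapply(fr, `[[`, character(1), "atom"),
      residue_index = vapply(fr, `[[`, integer(1), "resid"),
      residue_name = {
        rn <- vapply(fr, `[[`, character(1), "resname")
        mapped <- .pdb_resname_rev[rn]
        ifelse(is.na(mapped), rn, mapped)
      },
      stringsAsFactors = FALSE)
  }
  roster <- to_roster(frames[[1]])
  roster$element <- substr(roster$atom, 1, 1)
  mats <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    r <- to_roster(frames[[f]])
    if (nrow(r) != nrow(roster) ||
        !identical(r$atom, roster$atom) ||
        !identical(r$residue_index, roster$residue_index)) {
      stop("inconsistent atom roster in frame ", f)
    }
    mats[[f]] <- do.call(rbind, lapply(frames[[f]], `[[`, "xyz"))
  }
  structure(list(atoms = roster, frames = mats, format = "pdb"),
            class = "frame_set")
}

read_xyz_lines <- function(lines) {
  frames <- list()
  roster <- NULL
  k <- 1L
  while (k <= length(lines)) {
    if (!nzchar(trimws(lines[k]))) { k <- k + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[k])))
    if (is.na(nat)) stop("malformed XYZ atom-count header at line ", k)
    if (k + 1L + nat > length(lines)) stop("truncated XYZ frame at line ", k)
    body <- lines[(k + 2L):(k + 1L + nat)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) != 4)
    if (length(bad) > 0) stop("malformed XYZ record at line ", k + 1L + bad[1])
    lab <- vapply(parts, `[`, character(1), 1)
    xyz <- matrix(suppressWarnings(as.numeric(unlist(lapply(parts, `[`, 2:4)))),
                  ncol = 3, byrow = TRUE)
    if (any(is.na(xyz))) stop("malformed XYZ coordinates near line ", k + 2L)
    sub <- strsplit(lab, ":", fixed = TRUE)
    r <- data.frame(
      atom = vapply(sub, `[`, character(1), 1),
      residue_index = vapply(sub, function(s)
        if (length(s) >= 3) as.integer(s[3]) else NA_integer_, 1L),
      residue_name = vapply(sub, function(s)
        if (length(s) >= 2) s[2] else NA_character_, ""),
      stringsAsFactors = FALSE)
    if (is.null(roster)) {
      roster <- r
      roster$element <- substr(roster$atom, 1, 1)
    } else if (!identical(r$atom, roster$atom)) {
      stop("inconsistent atom roster in XYZ frame ", length(frames) + 1)
    }
    frames[[length(frames) + 1]] <- xyz
    k <- k + 2L + nat
  }
  if (length(frames) == 0) stop("no coordinate frames found")
  structure(list(atoms = roster, frames = frames, format = "xyz"),
            class = "frame_set")
}

#' Extract ordered ring coordinates for one residue
#'
#' @param atoms atom roster data.frame (from an ensemble or `frame_set`).
#' @param xyz one frame's n x 3 coordinate matrix.
#' @param residue_index residue to extract.
#' @param naming named character vector mapping the canonical ring names
#'   O5, C1..C5 to the names used in the file (e.g. `c(O5 = "O5'")`).
#' @return 6 x 3 matrix in ring order O5, C1, C2, C3, C4, C5.
#' @export
extract_ring <- function(atoms, xyz, residue_index,
                         naming = NULL) {
  want <- .ring_names
  if (!is.null(naming)) {
    stopifnot(!is.null(names(naming)))
    want[match(names(naming), want)] <- naming
  }
  sel <- atoms$residue_index == residue_index
  rows <- match(want, ifelse(sel, atoms$atom, NA))
  if (any(is.na(rows))) {
    miss <- .ring_names[is.na(rows)]
    stop("residue ", residue_index, " is missing ring atom(s): ",
         paste(miss, collapse = ", "))
  }
  m <- xyz[rows, , drop = FALSE]
  dimnames(m) <- list(.ring_names, c("x", "y", "z"))
  m
}
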
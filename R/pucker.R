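# Cremer-Pople puckering of six-membered rings.
#
# Ring atoms are taken in the fixed order O5, C1, C2, C3, C4, C5 (index
# j = 0..5 in the formulas).  The calibration of this implementation is:
# an ideal 4C1 chair (O5 displaced up, alternating signs around the ring)
# gives theta = 0, and the canonical O,3B boat gives theta = 90, phi = 0.
# That calibration is what fixes the traversal handedness used by
# `canonical_ring()` and is asserted by `selftest()`.

.planarity_Q <- 1e-4  # Angstrom; below this the angles are undefined

.tg_cache <- new.env(parent = emptyenv())

.cp_j <- 0:5

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Out-of-plane displacements are measured against the mean plane through
#' the geometric centre, with the plane normal defined by the standard
#' R' x R'' construction so that sum(z_j) = 0 by construction.
#'
#' @param ring 6 x 3 numeric matrix of coordinates (Angstrom), rows in ring
#'   order O5, C1, C2, C3, C4, C5.
#' @return object of class `pucker_state`: list with total amplitude `Q`
#'   (Angstrom), azimuthal `theta` (degrees, 0-180), meridional `phi`
#'   (degrees, [0, 360)), the components `q2`, `q3`, and `planar` flag.
#'   For a planar ring `Q` is ~0 and the angles are `NA` with
#'   `planar = TRUE`.
#' @examples
#' cremer_pople(canonical_ring("4C1"))$theta  # 0
#' @export
cremer_pople <- function(ring) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || !all(dim(ring) == c(6, 3)) || !all(is.finite(ring))) {
    stop("ring must be a finite 6 x 3 numeric coordinate matrix")
  }
  centre <- colMeans(ring)
  r <- sweep(ring, 2, centre)
  ang <- 2 * pi * .cp_j / 6
  R1 <- colSums(r * sin(ang))
  R2 <- colSums(r * cos(ang))
  nrm <- c(R1[2] * R2[3] - R1[3] * R2[2],
           R1[3] * R2[1] - R1[1] * R2[3],
           R1[1] * R2[2] - R1[2] * R2[1])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) stop("degenerate ring geometry (zero-area ring)")
  nrm <- nrm / nn
  z <- as.vector(r %*% nrm)

  qc <- sqrt(1 / 3) * sum(z * cos(2 * ang))   # q2 cos(phi2)
  qs <- -sqrt(1 / 3) * sum(z * sin(2 * ang))  # q2 sin(phi2)
  q2 <- sqrt(qc^2 + qs^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^.cp_j)
  Q <- sqrt(q2^2 + q3^2)

  if (Q < .planarity_Q) {
    return(structure(list(Q = Q, theta = NA_real_, phi = NA_real_,
                          q2 = q2, q3 = q3, planar = TRUE),
                     class = "pucker_state"))
  }
  theta <- atan2(q2, q3) * 180 / pi
  phi <- atan2(qs, qc) * 180 / pi
  phi <- phi %% 360
  # numerical wrap of the periodic coordinate: values within round-off of
  # 360 belong at 0
  if (360 - phi < 1e-7) phi <- 0
  structure(list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3,
                 planar = FALSE),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  if (x$planar) {
    cat(sprintf("<pucker_state> Q = %.4f A (planar; angles undefined)\n", x$Q))
  } else {
    cat(sprintf("<pucker_state> Q = %.4f A, theta = %.2f deg, phi = %.2f deg\n",
                x$Q, x$theta, x$phi))
  }
  invisible(x)
}

# ---- canonical conformer reference table --------------------------------

.band_theta <- atan(sqrt(2)) * 180 / pi  # 54.7356... tetrahedral band

#' Reference table of the 38 canonical pyranose conformers
#'
#' 2 chairs (poles), 6 boats and 6 skews (equator, alternating at 30 deg
#' spacing), and 12 envelopes plus 12 half-chairs interleaved on the
#' tetrahedral bands theta = 54.74 and 125.26 deg.  The placements follow
#' the standard puckering sphere under this package's calibration
#' (theta(4C1) = 0, phi(O,3B) = 0); row order is the canonical tie-break
#' order for classification.
#'
#' @return data.frame with columns `name`, `class`, `theta_ref`, `phi_ref`.
#' @export
conformer_table <- function() {
  if (!is.null(.tg_cache$conformer_table)) return(.tg_cache$conformer_table)
  tb <- .band_theta
  rows <- list(
    # chairs
    c("4C1", "chair", 0, 0), c("1C4", "chair", 180, 0),
    # boats (equator, phi = 0, 60, ..., 300)
    c("O,3B", "boat", 90, 0), c("B1,4", "boat", 90, 60),
    c("2,5B", "boat", 90, 120), c("B3,O", "boat", 90, 180),
    c("1,4B", "boat", 90, 240), c("B2,5", "boat", 90, 300),
    # skews (equator, phi = 30, 90, ..., 330)
    c("3S1", "skew", 90, 30), c("5S1", "skew", 90, 90),
    c("2SO", "skew", 90, 150), c("1S3", "skew", 90, 210),
    c("1S5", "skew", 90, 270), c("OS2", "skew", 90, 330),
    # envelopes, northern then southern band
    c("OE", "envelope", tb, 0), c("E1", "envelope", tb, 60),
    c("2E", "envelope", tb, 120), c("E3", "envelope", tb, 180),
    c("4E", "envelope", tb, 240), c("E5", "envelope", tb, 300),
    c("3E", "envelope", 180 - tb, 0), c("E4", "envelope", 180 - tb, 60),
    c("5E", "envelope", 180 - tb, 120), c("EO", "envelope", 180 - tb, 180),
    c("1E", "envelope", 180 - tb, 240), c("E2", "envelope", 180 - tb, 300),
    # half-chairs, northern then southern band
    c("OH1", "half-chair", tb, 30), c("2H1", "half-chair", tb, 90),
    c("2H3", "half-chair", tb, 150), c("4H3", "half-chair", tb, 210),
    c("4H5", "half-chair", tb, 270), c("OH5", "half-chair", tb, 330),
    c("3H4", "half-chair", 180 - tb, 30), c("5H4", "half-chair", 180 - tb, 90),
    c("5HO", "half-chair", 180 - tb, 150), c("1HO", "half-chair", 180 - tb, 210),
    c("1H2", "half-chair", 180 - tb, 270), c("3H2", "half-chair", 180 - tb, 330)
  )
  out <- data.frame(
    name = vapply(rows, `[`, character(1), 1),
    class = vapply(rows, `[`, character(1), 2),
    theta_ref = as.numeric(vapply(rows, `[`, character(1), 3)),
    phi_ref = as.numeric(vapply(rows, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
  .tg_cache$conformer_table <- out
  out
}

# the interconvertible skew/boat class implicated in glycosidase
# transition-state mimicry
.skew_boat_group <- c("1S5", "1S3", "1,4B", "B2,5")

#' Idealised ring coordinates for a canonical conformer
#'
#' Inverse puckering construction: a regular hexagon (traversed with the
#' handedness fixed by the package calibration) is displaced along its
#' normal by `z_j = sqrt(1/3) q2 cos(phi_ref + 120 j) + sqrt(1/6) q3 (-1)^j`
#' with `q2 = Q sin(theta_ref)`, `q3 = Q cos(theta_ref)`.  The round trip
#' through [cremer_pople()] recovers `(Q, theta_ref, phi_ref)` to machine
#' precision.
#'
#' @param label conformer name from [conformer_table()].
#' @param Q total puckering amplitude (Angstrom), > 0; 0.57 is a typical
#'   pyranose chair amplitude.
#' @param radius circumradius of the base hexagon (Angstrom).
#' @return 6 x 3 coordinate matrix, rows O5, C1, ..., C5.
#' @export
canonical_ring <- function(label, Q = 0.57, radius = 1.46) {
  tab <- conformer_table()
  k <- match(label, tab$name)
  if (is.na(k)) stop("unknown conformer label: '", label, "'")
  if (!is.numeric(Q) || Q <= 0) stop("Q must be > 0")
  ring_from_pucker(tab$theta_ref[k], tab$phi_ref[k], Q, radius)
}

# build a ring at arbitrary (theta, phi, Q); clockwise hexagon so the
# Cremer-Pople normal points along +z
ring_from_pucker <- function(theta, phi, Q, radius = 1.46) {
  q2 <- Q * sin(theta * pi / 180)
  q3 <- Q * cos(theta * pi / 180)
  ang <- 2 * pi * .cp_j / 6
  x <- radius * cos(ang)
  y <- -radius * sin(ang)
  z <- sqrt(1 / 3) * q2 * cos(phi * pi / 180 + 2 * ang) +
    sqrt(1 / 6) * q3 * (-1)^.cp_j
  m <- cbind(x, y, z)
  dimnames(m) <- list(c("O5", "C1", "C2", "C3", "C4", "C5"),
                      c("x", "y", "z"))
  m
}

# ---- classification ------------------------------------------------------

great_circle_deg <- function(t1, p1, t2, p2) {
  t1 <- t1 * pi / 180; p1 <- p1 * pi / 180
  t2 <- t2 * pi / 180; p2 <- p2 * pi / 180
  cd <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(p1 - p2)
  acos(pmin(1, pmax(-1, cd))) * 180 / pi
}

#' Classify a pucker state among the 38 canonical conformers
#'
#' Returns the conformer whose reference point minimises the great-circle
#' distance on the (theta, phi) sphere; the amplitude Q is ignored.  Ties
#' are broken by the canonical row order of [conformer_table()].
#'
#' @param state a `pucker_state` from [cremer_pople()], or a numeric
#'   `theta` when `phi` is given separately.
#' @param phi meridional angle (degrees) when `state` is numeric.
#' @return list with `name`, `class`, `theta_ref`, `phi_ref`, `distance`
#'   (great-circle distance to the reference, degrees).
#' @export
classify_conformer <- function(state, phi = NULL) {
  if (inherits(state, "pucker_state")) {
    if (isTRUE(state$planar)) {
      stop("ring is planar (Q below threshold); conformer undefined")
    }
    theta <- state$theta
    phi <- state$phi
  } else {
    theta <- state
    if (is.null(phi)) stop("phi required when state is numeric")
  }
  if (is.na(theta) || is.na(phi)) stop("pucker angles undefined")
  tab <- conformer_table()
  d <- great_circle_deg(theta, phi, tab$theta_ref, tab$phi_ref)
  k <- which.min(d)  # which.min returns the first minimum: canonical order
  list(name = tab$name[k], class = tab$class[k],
       theta_ref = tab$theta_ref[k], phi_ref = tab$phi_ref[k],
       distance = d[k])
}

#' Sinusoidal (equal-area) projection of pucker angles
#'
#' Latitude `psi = theta - 90` (the 4C1 pole at theta = 0 maps to the south
#' pole, y = -90), longitude `lambda = phi` wrapped to (-180, 180] with the
#' +180 edge kept; `x = lambda cos(psi)`, `y = psi`.  The Jacobian is
#' cos(psi), so uniform-on-sphere samples are uniform per unit plot area.
#'
#' @param state a `pucker_state`, or numeric `theta`.
#' @param phi meridional angle when `state` is numeric (both may be
#'   vectors).
#' @return data.frame with columns `x`, `y` (degrees).
#' @export
sinusoidal_projection <- function(state, phi = NULL) {
  if (inherits(state, "pucker_state")) {
    if (isTRUE(state$planar)) stop("pucker angles undefined for planar ring")
    theta <- state$theta
    phi <- state$phi
  } else {
    theta <- state
    if (is.null(phi)) stop("phi required when state is numeric")
  }
  if (any(is.na(theta) | is.na(phi))) stop("pucker angles undefined")
  psi <- theta - 90
  lambda <- ((phi + 180) %% 360) - 180
  lambda[lambda == -180] <- 180  # wrap edge assigned to +180
  data.frame(x = lambda * cos(psi * pi / 180), y = psi)
}
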
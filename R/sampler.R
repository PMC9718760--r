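# Boltzmann sampling of harmonic linkage geometry, partial-charge checks,
# and the small random-variate machinery used by the ensemble builder.

#' Harmonic glycosidic linkage parameters
#'
#' Energy convention is AMBER-style `E = K (x - x0)^2` (no 1/2), so the
#' Boltzmann marginal at temperature T is Gaussian with mean `x0` and
#' variance `kB T / (2 K)`.
#'
#' S-link defaults are the quantum-derived thio-linkage values
#' (r0 = 1.8392 A, k_bond = 215.9 kcal/mol/A^2, theta0 = 99.24 deg,
#' k_angle = 60.2 kcal/mol/rad^2).  O-link defaults use the approximate
#' natural ether geometry (r0 = 1.43 A, theta0 = 116 deg) with the force
#' constants mirrored from the S-link values; all fields are overridable.
#'
#' @param heteroatom `"O"` or `"S"`.
#' @param r0 equilibrium C-X bond length (Angstrom).
#' @param k_bond bond force constant (kcal mol^-1 A^-2).
#' @param theta0 equilibrium C-X-C angle (degrees).
#' @param k_angle angle force constant (kcal mol^-1 rad^-2).
#' @return list of class `linkage_params`.
#' @export
linkage_params <- function(heteroatom = c("S", "O"), r0 = NULL,
                           k_bond = NULL, theta0 = NULL, k_angle = NULL) {
  heteroatom <- match.arg(heteroatom)
  def <- if (heteroatom == "S") {
    list(r0 = 1.8392, k_bond = 215.9, theta0 = 99.24, k_angle = 60.2)
  } else {
    list(r0 = 1.43, k_bond = 215.9, theta0 = 116, k_angle = 60.2)
  }
  p <- list(heteroatom = heteroatom,
            r0 = if (is.null(r0)) def$r0 else r0,
            k_bond = if (is.null(k_bond)) def$k_bond else k_bond,
            theta0 = if (is.null(theta0)) def$theta0 else theta0,
            k_angle = if (is.null(k_angle)) def$k_angle else k_angle)
  if (any(unlist(p[c("r0", "k_bond", "theta0", "k_angle")]) <= 0)) {
    stop("all linkage parameters must be positive")
  }
  structure(p, class = "linkage_params")
}

#' Sample bond lengths and angles from the harmonic Boltzmann distribution
#'
#' Draws from the Gaussian marginals implied by `E = K (x - x0)^2` at
#' temperature T: sd = sqrt(kB T / (2 K)) with kB = 0.0019872
#' kcal mol^-1 K^-1 (angle K is per rad^2; the returned angles are in
#' degrees).
#'
#' @param params a [linkage_params()].
#' @param temperature temperature in K (default 298).
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#' @return list with numeric vectors `length` (Angstrom) and `angle`
#'   (degrees).
#' @export
sample_harmonic <- function(params, temperature = 298, n, seed = NULL) {
  stopifnot(inherits(params, "linkage_params"), n >= 1, temperature > 0)
  if (!is.null(seed)) set.seed(seed)
  kT <- .kB_kcal * temperature
  sd_bond <- sqrt(kT / (2 * params$k_bond))
  sd_angle <- sqrt(kT / (2 * params$k_angle)) * 180 / pi
  list(length = stats::rnorm(n, params$r0, sd_bond),
       angle = stats::rnorm(n, params$theta0, sd_angle))
}

#' Closed-form Boltzmann standard deviations of a harmonic linkage
#'
#' @inheritParams sample_harmonic
#' @return list with `sd_bond` (Angstrom) and `sd_angle` (degrees).
#' @export
harmonic_sd <- function(params, temperature = 298) {
  kT <- .kB_kcal * temperature
  list(sd_bond = sqrt(kT / (2 * params$k_bond)),
       sd_angle = sqrt(kT / (2 * params$k_angle)) * 180 / pi)
}

# ---- partial charges -----------------------------------------------------

#' Thio-linkage partial charge set
#'
#' The refit partial charges around the thio-glycosidic linkage (units of
#' e): S4 -0.46, C1 0.49, O5 -0.56, C2 0.31, C4 0.20, C3 0.32, C5 0.21.
#' These are a partial set: the remaining atoms of the residue keep their
#' stock force-field charges, so these seven alone do not sum to an
#' integer.
#'
#' @param declared_total declared total integer charge of the full residue
#'   set (default 0).
#' @return list of class `charge_set` with `charges` (named numeric) and
#'   `declared_total`.
#' @export
charge_set <- function(declared_total = 0) {
  structure(list(
    charges = c(S4 = -0.46, C1 = 0.49, O5 = -0.56, C2 = 0.31,
                C4 = 0.20, C3 = 0.32, C5 = 0.21),
    declared_total = declared_total
  ), class = "charge_set")
}

#' Integer total-charge check
#'
#' Passes iff the summed partial charges agree with the nearest integer to
#' the declared total within `tolerance`.
#'
#' @param charges a `charge_set`, or a named numeric vector of charges
#'   (then `declared_total` applies).
#' @param tolerance absolute tolerance (e).
#' @param declared_total declared integer total when `charges` is a bare
#'   vector.
#' @return list with `pass` (logical), `total`, `residual`.
#' @export
integer_charge_check <- function(charges, tolerance = 1e-4,
                                 declared_total = 0) {
  if (inherits(charges, "charge_set")) {
    declared_total <- charges$declared_total
    charges <- charges$charges
  }
  if (length(charges) == 0) stop("empty charge map")
  total <- sum(charges)
  residual <- abs(total - round(declared_total))
  list(pass = residual <= tolerance, total = total, residual = residual)
}

# ---- random variates -----------------------------------------------------

# von Mises sampler (Best & Fisher 1979 rejection method); kappa = 0 is the
# circular uniform.  mu in degrees, returns degrees in (-180, 180].
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -180, 180))
  mu_r <- mu * pi / 180
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      theta <- mu_r + sign(u3 - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  deg <- out * 180 / pi
  deg <- ((deg + 180) %% 360) - 180
  deg[deg == -180] <- 180
  deg
}
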
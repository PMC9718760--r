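# Independent oracles used to freeze expected values.  These deliberately
# do not share code paths with the package: masses come from a separately
# transcribed atomic-mass table and explicit per-atom bookkeeping, and the
# conformer oracle uses chord distance between unit vectors instead of the
# package's great-circle formula.

oracle_amu <- c(C = 12.0, H = 1.007825032, N = 14.003074,
                O = 15.994915, S = 31.972071)
oracle_proton <- 1.007276467

# mass from an explicit atom multiset, e.g. oracle_mass(C = 6, H = 10, O = 7)
oracle_mass <- function(...) {
  x <- c(...)
  sum(oracle_amu[names(x)] * x)
}

# brute-force nearest canonical conformer by chord distance on the unit
# sphere
oracle_classify <- function(theta, phi) {
  tab <- conformer_table()
  to_xyz <- function(t, p) {
    t <- t * pi / 180; p <- p * pi / 180
    c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  }
  v <- to_xyz(theta, phi)
  d <- vapply(seq_len(nrow(tab)), function(k) {
    sqrt(sum((v - to_xyz(tab$theta_ref[k], tab$phi_ref[k]))^2))
  }, numeric(1))
  tab$name[which.min(d)]
}

# random rigid transform (proper rotation + translation)
random_rigid <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, tr) {
  sweep(xyz %*% t(tr$R), 2, tr$t, `+`)
}

# dihedral for test-side geometry checks
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# small ensembles reused across tests (built once per test run)
tg_test_ensemble <- local({
  cache <- new.env()
  function(slinked = TRUE, n_frames = 40, seed = 11, mixtures = list()) {
    key <- paste(slinked, n_frames, seed,
                 paste(names(mixtures), collapse = ","), sep = "_")
    if (is.null(cache[[key]])) {
      spec <- ensemble_spec(heparosan(5, slinked = slinked),
                            n_frames = n_frames, seed = seed,
                            mixtures = mixtures)
      cache[[key]] <- build_ensemble(spec)
    }
    cache[[key]]
  }
})
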
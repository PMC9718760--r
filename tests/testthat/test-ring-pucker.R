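# Cremer-Pople transform, conformer classification, projections.

test_that("the calibration conventions hold", {
  # ideal 4C1: alternating +/- z on a regular hexagon, O5 displaced up
  ring <- canonical_ring("4C1", 0.57)
  st <- cremer_pople(ring)
  expect_equal(st$theta, 0, tolerance = 1e-8)
  expect_equal(st$Q, 0.57, tolerance = 1e-8)

  # all z negated -> the antipodal chair
  inv <- ring
  inv[, 3] <- -inv[, 3]
  expect_equal(cremer_pople(inv)$theta, 180, tolerance = 1e-8)

  boat <- cremer_pople(canonical_ring("O,3B", 0.76))
  expect_equal(boat$theta, 90, tolerance = 1e-8)
  expect_equal(min(boat$phi, 360 - boat$phi), 0, tolerance = 1e-8)

  # in the O,3B construction O5 (j = 0) and C3 (j = 3) sit above the plane
  b <- canonical_ring("O,3B", 0.76)
  expect_true(all(b[c("O5", "C3"), 3] > 0))
  expect_true(all(b[c("C1", "C2", "C4", "C5"), 3] < 0))

  # planar hexagon: amplitude ~ 0, angles undefined
  flat <- canonical_ring("4C1", 0.57)
  flat[, 3] <- 0
  st_flat <- cremer_pople(flat)
  expect_true(st_flat$planar)
  expect_lt(st_flat$Q, 1e-4)
  expect_true(is.na(st_flat$theta))
  expect_error(classify_conformer(st_flat), "planar")
})

test_that("the conformer table has the canonical 38-label structure", {
  tab <- conformer_table()
  expect_equal(nrow(tab), 38)
  expect_equal(anyDuplicated(tab$name), 0)
  expect_equal(as.vector(table(tab$class)[c("chair", "boat", "skew",
                                            "envelope", "half-chair")]),
               c(2L, 6L, 6L, 12L, 12L))
  # reference points are unique on the sphere
  key <- paste(round(tab$theta_ref, 6), round(tab$phi_ref, 6))
  expect_equal(anyDuplicated(key), 0)
})

test_that("construct -> transform -> classify is the identity for all 38", {
  tab <- conformer_table()
  for (Q in c(0.35, 0.57, 0.76)) {
    for (k in seq_len(nrow(tab))) {
      st <- cremer_pople(canonical_ring(tab$name[k], Q))
      expect_equal(st$Q, Q, tolerance = 1e-9)
      # angles land on the reference within 1e-6 degrees
      d <- thiogag:::great_circle_deg(st$theta, st$phi,
                                      tab$theta_ref[k], tab$phi_ref[k])
      expect_lt(d, 1e-6)
      expect_identical(classify_conformer(st)$name, tab$name[k])
    }
  }
  expect_error(canonical_ring("7C3"), "unknown conformer")
  expect_error(canonical_ring("4C1", Q = 0), "Q must be")
})

test_that("cremer_pople is invariant under rigid motions", {
  set.seed(402)
  tab <- conformer_table()
  for (rep in 1:25) {
    lab <- sample(tab$name, 1)
    ring <- canonical_ring(lab, runif(1, 0.3, 0.8))
    st0 <- cremer_pople(ring)
    st1 <- cremer_pople(apply_rigid(ring, random_rigid()))
    expect_equal(st1$Q, st0$Q, tolerance = 1e-9)
    expect_lt(abs(st1$theta - st0$theta), 1e-6)
    dphi <- abs(((st1$phi - st0$phi + 180) %% 360) - 180)
    expect_lt(dphi * sin(st0$theta * pi / 180), 1e-6)
  }
})

test_that("mean-plane displacements satisfy the closed-form identities", {
  set.seed(87)
  for (rep in 1:10) {
    ring <- canonical_ring(sample(conformer_table()$name, 1), 0.57)
    ring <- apply_rigid(ring, random_rigid())
    centre <- colMeans(ring)
    r <- sweep(ring, 2, centre)
    ang <- 2 * pi * (0:5) / 6
    R1 <- colSums(r * sin(ang)); R2 <- colSums(r * cos(ang))
    nrm <- c(R1[2] * R2[3] - R1[3] * R2[2],
             R1[3] * R2[1] - R1[1] * R2[3],
             R1[1] * R2[2] - R1[2] * R2[1])
    z <- as.vector(r %*% (nrm / sqrt(sum(nrm^2))))
    expect_equal(sum(z), 0, tolerance = 1e-9)
    st <- cremer_pople(ring)
    expect_equal(sqrt(1 / 6) * sum(z * (-1)^(0:5)), st$q3, tolerance = 1e-9)
    expect_equal(st$Q, sqrt(sum(z^2)), tolerance = 1e-9)
  }
})

test_that("classification agrees with the brute-force chord oracle", {
  set.seed(2211)
  for (rep in 1:200) {
    theta <- runif(1, 1, 179)
    phi <- runif(1, 0, 360)
    expect_identical(classify_conformer(theta, phi),
                     classify_conformer(theta, phi))  # deterministic
    expect_identical(classify_conformer(theta, phi)$name,
                     oracle_classify(theta, phi))
  }
  # spot values
  expect_identical(classify_conformer(2, 137)$name, "4C1")
  expect_identical(classify_conformer(90, 0)$name, "O,3B")
  expect_identical(classify_conformer(88, 32)$name, oracle_classify(88, 32))
})

test_that("sinusoidal projection is oriented, wrapped and area-preserving", {
  # 4C1 pole at the bottom of the plot
  expect_equal(unlist(sinusoidal_projection(0, 0)), c(x = 0, y = -90))
  expect_equal(sinusoidal_projection(180, 123)$y, 90)
  # equator maps isometrically; the +/-180 boundary keeps the right edge
  expect_equal(sinusoidal_projection(90, 180)$x, 180)
  expect_equal(sinusoidal_projection(90, 179.9)$x, 179.9, tolerance = 1e-9)
  expect_equal(sinusoidal_projection(90, 180.1)$x, -179.9, tolerance = 1e-9)
  # Monte-Carlo area preservation: uniform-on-sphere points are uniform in
  # (x, y) area, so the occupied-cell counts are near-uniform
  set.seed(9)
  n <- 20000
  theta <- acos(runif(n, -1, 1)) * 180 / pi
  phi <- runif(n, 0, 360)
  pr <- sinusoidal_projection(theta, phi)
  # compare the fraction of points inside the central latitude band with
  # its analytic area fraction (sin(30 deg) = 0.5)
  frac <- mean(abs(pr$y) < 30)
  expect_equal(frac, 0.5, tolerance = 0.02)
  # chi-square uniformity over equal-area latitude slabs
  slabs <- cut(sin(pr$y * pi / 180), seq(-1, 1, length.out = 11))
  counts <- as.numeric(table(slabs))
  chi2 <- sum((counts - n / 10)^2 / (n / 10))
  expect_lt(chi2, qchisq(0.999, df = 9))
})
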
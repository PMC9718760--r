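# Boltzmann sampling, charge checks, and the ensemble generator.

test_that("harmonic samples match the closed-form Gaussian", {
  p <- linkage_params("S")
  expect_equal(p$r0, 1.8392)
  expect_equal(p$theta0, 99.24)
  expect_equal(p$k_bond, 215.9)
  expect_equal(p$k_angle, 60.2)

  n <- 1e5
  s <- sample_harmonic(p, temperature = 298, n = n, seed = 71)
  sds <- harmonic_sd(p, 298)
  # kB T / (2K) closed forms
  expect_equal(sds$sd_bond, sqrt(0.0019872 * 298 / (2 * 215.9)),
               tolerance = 1e-12)
  expect_equal(sds$sd_angle,
               sqrt(0.0019872 * 298 / (2 * 60.2)) * 180 / pi,
               tolerance = 1e-12)
  # means within 3 SE
  expect_lt(abs(mean(s$length) - p$r0), 3 * sds$sd_bond / sqrt(n))
  expect_lt(abs(mean(s$angle) - p$theta0), 3 * sds$sd_angle / sqrt(n))
  # variances within the chi-square interval (3-sigma-ish via log bounds)
  rat <- stats::var(s$length) / sds$sd_bond^2
  expect_gt(rat, qchisq(0.0005, n - 1) / (n - 1))
  expect_lt(rat, qchisq(0.9995, n - 1) / (n - 1))
  # goodness of fit against the closed-form Gaussian at significance 0.001
  ks <- suppressWarnings(
    stats::ks.test(s$angle, "pnorm", p$theta0, sds$sd_angle))
  expect_gt(ks$p.value, 0.001)
  # determinism
  s2 <- sample_harmonic(p, 298, n, seed = 71)
  expect_identical(s, s2)
  expect_error(linkage_params("S", k_bond = -1), "positive")
})

test_that("von Mises torsion sampler is calibrated", {
  set.seed(5)
  x <- thiogag:::rvonmises_deg(20000, mu = 60, kappa = 4)
  expect_true(all(x > -180 & x <= 180))
  # circular mean near mu
  cm <- atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi
  expect_equal(cm, 60, tolerance = 2)
  # mean resultant length ~ besselI ratio A(kappa)
  R <- sqrt(mean(sin(x * pi / 180))^2 + mean(cos(x * pi / 180))^2)
  expect_equal(R, besselI(4, 1) / besselI(4, 0), tolerance = 0.02)
  # kappa = 0 is circular uniform
  set.seed(6)
  u <- thiogag:::rvonmises_deg(20000, 0, 0)
  expect_lt(sqrt(mean(sin(u * pi / 180))^2 + mean(cos(u * pi / 180))^2), 0.02)
})

test_that("integer charge checks flag the partial thio charge set", {
  cs <- charge_set()
  # the seven refit linkage charges alone sum to +0.51: a partial set
  chk <- integer_charge_check(cs)
  expect_false(chk$pass)
  expect_equal(chk$residual, 0.51, tolerance = 1e-9)
  # a completed set passes
  full <- c(cs$charges, rest = -0.51)
  expect_true(integer_charge_check(full, declared_total = 0)$pass)
  expect_true(integer_charge_check(c(a = -0.99995), tolerance = 1e-4,
                                   declared_total = -1)$pass)
  expect_false(integer_charge_check(c(a = -0.999), tolerance = 1e-4,
                                    declared_total = -1)$pass)
  expect_error(integer_charge_check(numeric(0)), "empty")
})

test_that("ensembles are seed-deterministic and validate their spec", {
  spec <- ensemble_spec(heparosan(2, slinked = TRUE), n_frames = 6, seed = 42)
  e1 <- build_ensemble(spec)
  e2 <- build_ensemble(spec)
  expect_identical(e1$frames, e2$frames)
  expect_identical(e1$labels, e2$labels)
  e3 <- build_ensemble(ensemble_spec(heparosan(2, slinked = TRUE),
                                     n_frames = 6, seed = 43))
  expect_false(identical(e1$frames, e3$frames))

  expect_error(ensemble_spec(heparosan(2), n_frames = 5), "seed")
  expect_error(ensemble_spec(heparosan(2), 5, 1,
                             mixtures = list(GlcA = c(`4C1` = 0.5))),
               "sum to 1")
  expect_error(ensemble_spec(heparosan(2), 5, 1,
                             mixtures = list(GlcA = c(foo = 1))),
               "unknown conformer")
  expect_error(ensemble_spec(addition_product(0), 5, 1), "aglycone")
})

test_that("rings are emitted at their reference pucker before assembly", {
  mix <- list(GlcA = c("1S3" = 1), GlcNAc = c("1C4" = 1))
  ens <- build_ensemble(ensemble_spec(heparosan(2, slinked = TRUE),
                                      n_frames = 4, seed = 9,
                                      mixtures = mix))
  tab <- conformer_table()
  for (f in seq_along(ens$frames)) {
    for (ri in 1:4) {
      st <- cremer_pople(extract_ring(ens$atoms, ens$frames[[f]], ri))
      want <- if (ens$chain$residues[ri] == "GlcA") "1S3" else "1C4"
      k <- match(want, tab$name)
      d <- thiogag:::great_circle_deg(st$theta, st$phi,
                                      tab$theta_ref[k], tab$phi_ref[k])
      expect_lt(d, 1e-6)
    }
  }
})

test_that("configured conformer mixtures are recovered from frequencies", {
  w <- 0.6
  nf <- 1000
  ens <- tg_test_ensemble(slinked = TRUE, n_frames = nf, seed = 11,
                          mixtures = list(GlcNAc = c("1C4" = w, "4C1" = 1 - w)))
  fq <- pucker_frequencies(ens, residues = "internal")
  expect_equal(sum(fq$frequency[fq$residue_index == 5]), 1, tolerance = 1e-9)
  expect_equal(sum(fq$frequency[fq$residue_index == 6]), 1, tolerance = 1e-9)
  # internal disaccharide of the decasaccharide is residues 5 (GlcA) and 6
  # (GlcNAc); GlcA stays all-4C1, GlcNAc recovers the 60/40 mixture
  expect_equal(fq$frequency[fq$residue_index == 5 & fq$label == "4C1"], 1)
  got <- fq$frequency[fq$residue_index == 6 & fq$label == "1C4"]
  se <- sqrt(w * (1 - w) / nf)
  expect_lt(abs(got - w), 3 * se)
})

test_that("O- vs S-link specs reproduce their configured equilibria", {
  go <- glycosidic_geometry(tg_test_ensemble(slinked = FALSE,
                                             n_frames = 150, seed = 29))
  gs <- glycosidic_geometry(tg_test_ensemble(slinked = TRUE,
                                             n_frames = 150, seed = 29))
  expect_equal(mean(go$angle), 116, tolerance = 0.01)
  expect_equal(mean(gs$angle[gs$heteroatom == "S"]), 99.24, tolerance = 0.01)
  expect_equal(mean(go$r_c1x), 1.43, tolerance = 0.005)
  expect_equal(mean(gs$r_c1x[gs$heteroatom == "S"]), 1.8392,
               tolerance = 0.005)
})

test_that("steric filter rejects impossible clash thresholds", {
  spec <- ensemble_spec(heparosan(3), n_frames = 1, seed = 1,
                        clash_radius = 50, max_retries = 3)
  expect_error(build_ensemble(spec), "steric clash")
})
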
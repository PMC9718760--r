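# Chain representation, elemental composition and ion-mass prediction.

test_that("residue and chain compositions match per-atom bookkeeping", {
  # free GlcA monosaccharide = residue + H2O
  free_glca <- elemental_composition(glycan_chain("GlcA"))
  expect_equal(format_formula(free_glca), "C6H10O7")
  expect_equal(formula_mass(free_glca),
               oracle_mass(C = 6, H = 10, O = 7), tolerance = 1e-7)

  # O-linked disaccharide GlcNAc-GlcA
  di <- elemental_composition(glycan_chain(c("GlcNAc", "GlcA"), "O"))
  expect_equal(format_formula(di), "C14H23NO12")

  # hemi-A S-linked disaccharide: same formula with one O -> S
  di_s <- elemental_composition(glycan_chain(c("GlcA", "GlcNAc"), "S"))
  expect_equal(unname(di_s["S"]), 1)
  expect_equal(unname(di_s["O"]), unname(di["O"]) - 1)
  expect_equal(di_s[c("C", "H", "N")], di[c("C", "H", "N")])

  # explicit 4-thio on the S-linked acceptor must not double count
  di_s2 <- elemental_composition(
    glycan_chain(c("GlcA", "GlcNAc"), "S", mods = list(character(0), "4-thio")))
  expect_identical(di_s2, di_s)

  expect_error(residue_composition("Xyl"), "unknown residue")
  expect_error(glycan_chain(c("GlcA", "GlcNAc"), c("O", "O")), "linkages")
})

test_that("modification arithmetic follows the substitution rules", {
  base <- residue_composition("GlcNAc")
  thio <- residue_composition("GlcNAc", "4-thio")
  expect_equal(unname(thio["S"] - base["S"]), 1)
  expect_equal(unname(base["O"] - thio["O"]), 1)
  expect_identical(residue_composition("4SH-GlcNAc"), thio)

  # N-sulfo on GlcNAc removes the acetyl, giving GlcNS
  expect_identical(residue_composition("GlcNAc", "N-sulfo"),
                   residue_composition("GlcNS"))
  # O-sulfation adds SO3 and nothing else
  s6 <- residue_composition("GlcNAc", "6-O-sulfo")
  expect_equal(unname(s6 - base), c(0, 0, 0, 3, 1),
               ignore_attr = TRUE)
  # lyase product: GlcA - H2O
  expect_identical(residue_composition("GlcA", "4,5-unsaturated"),
                   residue_composition("dUA"))
})

test_that("chain grammar parses, serialises and round-trips", {
  txt <- "GlcA-S-GlcNAc@6S-O-GlcA-O-GlcNAc"
  ch <- parse_chain(txt)
  expect_equal(ch$residues, c("GlcA", "GlcNAc", "GlcA", "GlcNAc"))
  expect_equal(ch$linkages, c("S", "O", "O"))
  expect_equal(ch$mods[[2]], "6-O-sulfo")
  expect_equal(format_chain(ch), txt)

  withagl <- parse_chain("GlcNAc-O-GlcA-O-R(C2H4-amido-benzaldehyde)")
  expect_equal(withagl$aglycone$name, "C2H4-amido-benzaldehyde")
  expect_equal(format_chain(parse_chain(format_chain(withagl))),
               format_chain(withagl))

  expect_error(parse_chain("GlcA-X-GlcNAc"), "unknown")
  expect_error(parse_chain("GlcA@9Z"), "modification code")
})

test_that("predicted [M-H]- masses reproduce the six reference products", {
  # frozen from the independent per-atom oracle (helper table)
  expected <- data.frame(
    k = c(0, 0, 1, 1, 2, 2),
    thio = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    mz = c(950.2895, 966.2667, 1329.4010, 1361.3553, 1708.5125, 1756.4439))
  for (r in seq_len(nrow(expected))) {
    got <- predicted_mz(addition_product(expected$k[r], expected$thio[r]))
    expect_equal(got, expected$mz[r], tolerance = 2e-4)
  }
})

test_that("mass additivity holds against the per-atom oracle", {
  # decasaccharide assembled atom-by-atom in the oracle:
  # 5 x GlcNAc + 5 x GlcA + H2O, n_S sulfurs swapped for oxygens
  for (nS in c(0L, 5L)) {
    m_oracle <- oracle_mass(C = 5 * 8 + 5 * 6, H = 5 * 13 + 5 * 8 + 2,
                            N = 5, O = 5 * 5 + 5 * 6 + 1 - nS, S = nS) -
      oracle_proton
    ch <- heparosan(5, slinked = nS > 0)
    expect_equal(predicted_mz(ch), m_oracle, tolerance = 1e-6)
  }
})

test_that("mass_shift is linear in the number of O->S substitutions", {
  shift1 <- oracle_amu[["S"]] - oracle_amu[["O"]]  # 15.9772
  expect_equal(mass_shift(heparosan(1, slinked = TRUE), heparosan(1)),
               shift1, tolerance = 1e-6)
  expect_equal(mass_shift(heparosan(3), heparosan(3)), 0)
  for (n in c(2, 5, 9)) {
    s <- heparosan(n, slinked = TRUE)
    o <- heparosan(n)
    expect_equal(mass_shift(s, o), n_thio_substitutions(s) * shift1,
                 tolerance = 1e-6)
  }
  # three substitutions: the triple-addition product
  expect_equal(mass_shift(addition_product(2, TRUE), addition_product(2)),
               3 * shift1, tolerance = 1e-6)
})

test_that("ion species validation rejects unsupported conventions", {
  expect_error(ion_species(polarity = "positive"), "polarity")
  expect_error(ion_species(adduct = "[M+Na]+"), "adduct")
  # average masses supported but distinct
  expect_gt(predicted_mz(heparosan(5), ion_species(mass_type = "average")),
            predicted_mz(heparosan(5)))
})
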
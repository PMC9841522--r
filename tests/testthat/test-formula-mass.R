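# Formula parsing and mass computation against independently tabulated
# atomic masses (frozen expected values recomputed by hand from NIST
# monoisotopic masses and IUPAC standard weights).

test_that("parse_formula handles counts, implicit ones and charges", {
  f <- parse_formula("C16H15N4OS+")
  expect_equal(f$counts, c(C = 16L, H = 15L, N = 4L, O = 1L, S = 1L))
  expect_equal(f$charge, 1L)

  f2 <- parse_formula("C13H11ClN3O2S2+")
  expect_equal(f2$counts,
               c(C = 13L, H = 11L, Cl = 1L, N = 3L, O = 2L, S = 2L))
  expect_equal(f2$charge, 1L)

  expect_equal(parse_formula("H")$counts, c(H = 1L))
  expect_equal(parse_formula("H")$charge, 0L)

  # multi-charge suffixes and the typographic minus; digits before a
  # trailing sign are subscripts (PO4- is one charge, four oxygens)
  expect_equal(parse_formula("Ca+2")$charge, 2L)
  expect_equal(parse_formula("Ca++")$charge, 2L)
  f3 <- parse_formula("PO4-")
  expect_equal(f3$charge, -1L)
  expect_equal(f3$counts[["O"]], 4L)
  expect_equal(parse_formula("Cl−")$charge, -1L)
})

test_that("parse_formula rejects malformed input with informative errors", {
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("C6Xx6"), "unknown element symbol 'Xx'")
  expect_error(parse_formula("c6h6"), "malformed")
  expect_error(parse_formula("C0H4"), "non-positive")
})

test_that("render_formula round-trips through parse_formula", {
  for (txt in c("C16H15N4OS+", "C13H11ClN3O2S2+", "H2O", "CH4", "Ca+2",
                "C14H10F3N3O2S2", "NaCl", "C6H5BrNO2-")) {
    f <- parse_formula(txt)
    g <- parse_formula(render_formula(f))
    expect_equal(g$counts[sort(names(g$counts))],
                 f$counts[sort(names(f$counts))], info = txt)
    expect_equal(g$charge, f$charge, info = txt)
  }
})

test_that("monoisotopic masses match hand-tabulated sums", {
  # H2O: 2 x 1.00782503207 + 15.9949146196 = 18.0105646838
  expect_equal(monoisotopic_mass("H2O"), 18.0106)
  # C is exactly 12 by definition
  expect_equal(monoisotopic_mass("C"), 12.0000)
  # {C14,H14,N3,O2,S2}+ = 320.05268...
  expect_equal(monoisotopic_mass("C14H14N3O2S2+"), 320.0527)
  expect_equal(monoisotopic_mass("C16H15N4OS+", digits = NA),
               16 * 12 + 15 * 1.00782503207 + 4 * 14.0030740048 +
                 15.9949146196 + 31.9720711744,
               tolerance = 1e-10)
})

test_that("average masses use standard atomic weights", {
  expect_equal(average_mass("C"), 12.0, tolerance = 1e-9)
  expect_equal(average_mass("C", digits = 3), 12.011)
  # CH4: 12.011 + 4 x 1.008 = 16.043
  expect_equal(average_mass("CH4", digits = 3), 16.043)
  expect_equal(average_mass("C13H12N3O2S2+"), 306.4)
})

test_that("electron-mass correction subtracts charge electron masses", {
  m0 <- monoisotopic_mass("C16H15N4OS+", digits = NA)
  m1 <- monoisotopic_mass("C16H15N4OS+", digits = NA,
                          electron_correct = TRUE)
  expect_equal(m0 - m1, 0.000548579909, tolerance = 1e-9)
  # neutral species unaffected
  expect_equal(monoisotopic_mass("H2O", digits = NA),
               monoisotopic_mass("H2O", digits = NA,
                                 electron_correct = TRUE))
})

test_that("mass is additive over formula merge (both modes)", {
  set.seed(42)
  els <- c("C", "H", "N", "O", "S", "Cl", "F", "P")
  for (rep in 1:20) {
    c1 <- sample(1:30, 4)
    c2 <- sample(1:30, 4)
    f1 <- structure(list(counts = stats::setNames(as.integer(c1),
                                                  sample(els, 4)),
                         charge = 0L), class = "mol_formula")
    f2 <- structure(list(counts = stats::setNames(as.integer(c2),
                                                  sample(els, 4)),
                         charge = 0L), class = "mol_formula")
    fm <- formula_add(f1, f2)
    expect_equal(monoisotopic_mass(fm, digits = NA),
                 monoisotopic_mass(f1, digits = NA) +
                   monoisotopic_mass(f2, digits = NA),
                 tolerance = 1e-9)
    expect_equal(average_mass(fm, digits = NA),
                 average_mass(f1, digits = NA) +
                   average_mass(f2, digits = NA),
                 tolerance = 1e-9)
  }
})

test_that("rounding is half-up at the reported precision", {
  expect_equal(round_half_up(0.5, 0), 1)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_equal(round_half_up(0.12345, 4), 0.1235)
  expect_equal(round_half_up(1.005, 2), 1.01)
})

test_that("batch mode computes a whole formula column", {
  out <- mass_table_batch(c("H2O", "CH4", "C16H15N4OS+"), mode = "mono")
  expect_equal(nrow(out), 3)
  expect_equal(out$mass, c(18.0106, 16.0313, 311.0967))
  expect_equal(out$charge, c(0L, 0L, 1L))
})
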
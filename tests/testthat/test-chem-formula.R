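test_that("formula parsing covers plain, charged, and repeated-element strings", {
  f <- parse_formula("C15H24N3O")
  expect_equal(unclass(f)[c("C", "H", "N", "O")],
               c(C = 15L, H = 24L, N = 3L, O = 1L))
  expect_identical(formula_charge(f), 0L)

  w <- parse_formula("H2O")
  expect_equal(unclass(w)[c("H", "O")], c(H = 2L, O = 1L))

  cation <- parse_formula("C16H13N2O+")
  expect_identical(formula_charge(cation), 1L)
  expect_equal(cation[["N"]], 2L)

  # repeated element tokens accumulate
  expect_equal(parse_formula("CH3CH3")[["C"]], 2L)
  expect_equal(parse_formula("CH3CH3")[["H"]], 6L)
})

test_that("formula parsing rejects unknown elements and zero multipliers", {
  expect_error(parse_formula("C2Na"), "Na")
  expect_error(parse_formula("C0H4"), "zero")
  expect_error(parse_formula(""), "empty")
})

test_that("parse/format round trip is the identity on canonical Hill strings", {
  for (s in c("C15H10O5", "H2O", "C16H13N2O+", "CHCl3", "C6H5Br", "N2", "C2H3O2-")) {
    expect_identical(format_formula(parse_formula(s)), s)
  }
})

test_that("monoisotopic m/z is electron-corrected for cations", {
  # printed theoretical values for the two unknown-component peaks
  expect_equal(round(monoisotopic_mz(parse_formula("C15H24N3O+")), 3), 262.191)
  expect_equal(round(monoisotopic_mz(parse_formula("C16H13N2O+")), 3), 249.102)
  # neutral water from summed pinned NIST masses
  expect_equal(monoisotopic_mz(parse_formula("H2O")), 18.010565, tolerance = 1e-6)
  # electron correction direction: cation lighter than neutral
  n <- monoisotopic_mz(parse_formula("C16H13N2O"))
  c1 <- monoisotopic_mz(parse_formula("C16H13N2O+"))
  expect_lt(c1, n)
  expect_equal(n - c1, 0.000548579909, tolerance = 1e-6)
  expect_error(monoisotopic_mz(mol_formula(integer(0))), "empty")
})

test_that("subtract_formula yields the loss and add_formula inverts it", {
  loss <- subtract_formula(parse_formula("C15H11O5+"), parse_formula("C15H11O4+"))
  expect_identical(format_formula(loss), "O")
  # methyl-radical loss 269 -> 254
  loss2 <- subtract_formula(parse_formula("C16H13O4+"), parse_formula("C15H10O4+"))
  expect_identical(format_formula(loss2), "CH3")
  x <- parse_formula("C6H12O6")
  expect_identical(length(subtract_formula(x, x)), 0L)
  expect_error(subtract_formula(parse_formula("H2O"), parse_formula("CH4")),
               "sub-formula")
})

test_that("mass additivity holds for random parent/child splits", {
  set.seed(11)
  for (i in 1:50) {
    parent <- mol_formula(c(C = sample(1:20, 1), H = sample(1:30, 1),
                            O = sample(0:6, 1), N = sample(0:4, 1)))
    keep <- vapply(names(parent), function(e) sample(0:parent[[e]], 1), integer(1))
    child <- mol_formula(keep[keep > 0])
    if (length(child) == 0L || length(child) == length(parent) &&
        all(as.integer(child) == as.integer(parent))) next
    loss <- subtract_formula(parent, child)
    if (length(loss) == 0L) next
    expect_equal(monoisotopic_mz(child) + monoisotopic_mz(loss),
                 monoisotopic_mz(parent), tolerance = 1e-9)
  }
})

test_that("match_level distinguishes all-atom, heavy-atom and mismatch tiers", {
  a <- parse_formula("C16H13N2O")
  expect_identical(match_level(a, parse_formula("C16H13N2O")), "all_atoms")
  expect_identical(match_level(a, parse_formula("C16H15N2O")), "heavy_atoms")
  expect_identical(match_level(parse_formula("C2H4"), parse_formula("C2H4O")),
                   "mismatch")
  # symmetric, and identity maps to all_atoms, over random formulas
  set.seed(4)
  for (i in 1:25) {
    x <- mol_formula(c(C = sample(1:10, 1), H = sample(0:20, 1),
                       O = sample(0:4, 1))[c(TRUE, sample(c(TRUE, FALSE), 2, TRUE))])
    y <- mol_formula(c(C = sample(1:10, 1), H = sample(0:20, 1)))
    expect_identical(match_level(x, y), match_level(y, x))
    expect_identical(match_level(x, x), "all_atoms")
  }
  # protonated vs neutral: charge compared only when both declared
  expect_identical(match_level(parse_formula("C15H11O5+"),
                               parse_formula("C15H11O5")), "all_atoms")
})

test_that("rdbe follows the default valence convention", {
  expect_equal(rdbe(parse_formula("C6H6")), 4)
  expect_equal(rdbe(parse_formula("CH4")), 0)
  expect_equal(rdbe(parse_formula("C15H10O5")), 11)
  expect_equal(rdbe(parse_formula("CH5N2")), 0.5)
  expect_equal(rdbe(parse_formula("CH6O")), -1)
  expect_equal(rdbe(parse_formula("CHCl3")), 0)
})
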
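test_that("fixture panel parses and has correct literature compositions", {
  fm <- fixture_molecules()
  expect_gte(nrow(fm), 20L)
  expect_setequal(unique(fm$class), c("flavonoid", "stilbene", "other"))
  # spot-check hand-verifiable compositions
  expect_identical(fm$formula[fm$name == "galangin"], "C15H10O5")
  expect_identical(fm$formula[fm$name == "formononetin"], "C16H12O4")
  expect_identical(fm$formula[fm$name == "resveratrol"], "C14H12O3")
  expect_identical(fm$formula[fm$name == "rotundine"], "C21H25NO4")
  # every SMILES parses and matches its stored formula via OpenBabel's
  # independent formula computation
  ob <- vapply(fm$smiles, function(s) {
    ChemmineR::propOB(ChemmineR::smiles2sdf(s))$formula
  }, character(1), USE.NAMES = FALSE)
  expect_identical(fm$formula, ob)
})

test_that("in-silico spectra contain the worked-example parent ions", {
  fm <- fixture_molecules()
  gal <- in_silico_spectrum(fm$smiles[fm$name == "galangin"])
  expect_true(271 %in% gal$peaks$mz)
  expect_identical(gal$precursor_mz, 271)
  fo <- in_silico_spectrum(fm$smiles[fm$name == "formononetin"])
  expect_true(269 %in% fo$peaks$mz)
  # highest intensity is the precursor; fragments decay with depth
  expect_identical(gal$peaks$mz[which.max(gal$peaks$intensity)], 271)
})

test_that("spectrum generation is deterministic under a seed", {
  fm <- fixture_molecules()
  a <- in_silico_spectrum(fm$smiles[1], noise_peaks = 5L, seed = 42L)
  b <- in_silico_spectrum(fm$smiles[1], noise_peaks = 5L, seed = 42L)
  expect_identical(a$peaks, b$peaks)
  c2 <- in_silico_spectrum(fm$smiles[1], noise_peaks = 5L, seed = 43L)
  expect_false(identical(a$peaks, c2$peaks))
})

test_that("in-silico fragment peaks are explainable by the fragment tree", {
  # closing the loop: on noiseless spectra, FT annotation under the true
  # precursor formula must cover >= 80% of selected peaks
  fm <- fixture_molecules()
  for (nm in c("galangin", "formononetin", "resveratrol")) {
    row <- fm[fm$name == nm, ]
    s <- select_top_peaks(in_silico_spectrum(row$smiles, mode = "exact"), 6L)
    prec <- mol_formula(unclass(add_formula(parse_formula(row$formula),
                                            parse_formula("H"))), 1L)
    ft <- fragment_tree(s, precursor_formula = prec)
    n_peaks <- nrow(s$peaks)
    expect_gte(nrow(ft$nodes) / n_peaks, 0.8)
  }
})

test_that("decoys are valid, distinct, and score below the parent", {
  fm <- fixture_molecules()
  parent <- fm$smiles[fm$name == "formononetin"]
  d <- make_decoys(parent, 5L, seed = 11L)
  expect_length(d, 5L)
  expect_length(unique(d), 5L)
  expect_true(all(vapply(d, is_valid_smiles, logical(1))))
  expect_false(canonical_smiles(parent) %in% d)
  # reproducible
  expect_identical(d, make_decoys(parent, 5L, seed = 11L))

  # self-consistency: parent outranks every decoy against its own FT
  s <- select_top_peaks(in_silico_spectrum(parent, mode = "exact"), 6L)
  ft <- fragment_tree(s, precursor_formula = "C16H13O4+")
  r <- rank_candidates(c(parent, d), ft)
  expect_identical(r$smiles[1], canonical_smiles(parent))
})

test_that("training sets are paired, padded, capped and shuffled by seed", {
  fm <- fixture_molecules()[1:8, ]
  ts <- make_training_set(fm, seed = 5L)
  expect_length(ts, 8L)
  for (p in ts) {
    expect_lte(length(p$spectrum), 100L)
    expect_identical(length(p$target), 100L)
    expect_identical(sum(p$target == 1L), 1L)  # exactly one <SOS>
    expect_identical(sum(p$target == 2L), 1L)  # exactly one <EOS>
  }
  ts2 <- make_training_set(fm, seed = 5L)
  expect_identical(lapply(ts, `[[`, "smiles"), lapply(ts2, `[[`, "smiles"))
})
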
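test_that("pair scores reproduce the three-tier table exactly", {
  expect_identical(pair_score("parent", "all_atoms"), 6)
  expect_identical(pair_score("parent", "heavy_atoms"), 3)
  expect_identical(pair_score("parent", "mismatch"), 0)
  expect_identical(pair_score("fragment", "all_atoms"), 5)
  expect_identical(pair_score("fragment", "heavy_atoms"), 2)
  expect_identical(pair_score("fragment", "mismatch"), 0)
  expect_identical(pair_score("loss", "all_atoms"), 4)
  expect_identical(pair_score("loss", "heavy_atoms"), 1.5)
  expect_identical(pair_score("loss", "mismatch"), 0)
  # score_table enforces all >= heavy >= mismatch and loss <= fragment
  expect_error(score_table(loss = c(all_atoms = 6, heavy_atoms = 2, mismatch = 0)))
})

test_that("a tree aligned with its exact counterpart normalizes to 1", {
  fmls <- c("C16H13O4+", "C15H10O4+", "C15H9O3+", "C13H9O3+")
  ft <- manual_tree(fmls, c(NA, 1L, 1L, 1L), as = "fragment")
  st <- manual_tree(fmls, c(NA, 1L, 1L, 1L), as = "smiles")
  al <- align_and_score(st, ft)
  expect_equal(al$normalized, 1.0)
  expect_equal(al$raw, 6 + 3 * 5 + 3 * 4)
})

test_that("trees sharing no formulas score zero", {
  ft <- manual_tree(c("C10H10O2+", "C8H8O+"), c(NA, 1L), as = "fragment")
  st <- manual_tree(c("C5H5N5+", "C4H4N4+"), c(NA, 1L), as = "smiles")
  expect_equal(align_and_score(st, ft)$normalized, 0)
})

test_that("the mixed-tier example sums to 18.5/24", {
  # FT: root + two fragments; one matches all-atom with all-atom loss,
  # the other matches heavy-atom with heavy-atom loss
  ft <- manual_tree(c("C10H10O2+", "C8H8O+", "C7H6O+"), c(NA, 1L, 1L),
                    as = "fragment")
  st <- manual_tree(c("C10H10O2+", "C8H8O+", "C7H8O+"), c(NA, 1L, 1L),
                    as = "smiles")
  al <- align_and_score(st, ft)
  expect_equal(al$raw, 6 + 5 + 4 + 2 + 1.5)
  expect_equal(al$denominator, 24)
  expect_equal(al$normalized, 18.5 / 24)
})

test_that("losses compose along skipped SMILES-tree generations", {
  # FT observes one CH4O loss; the SMILES tree explains it as CH3 then HO
  ft <- manual_tree(c("C10H10O2+", "C9H6O+"), c(NA, 1L), as = "fragment")
  st <- manual_tree(c("C10H10O2+", "C9H7O2+", "C9H6O+"), c(NA, 1L, 2L),
                    as = "smiles")
  al <- align_and_score(st, ft)
  expect_equal(al$raw, 6 + 5 + 4)  # loss CH4O matched via composition
  expect_identical(unname(al$mapping[["2"]]), 3L)
})

test_that("alignment equals the exhaustive mapping oracle on random tree pairs", {
  set.seed(77)
  n_trials <- 150
  for (i in seq_len(n_trials)) {
    ft <- random_align_tree(sample(2:5, 1), as = "fragment")
    st <- random_align_tree(sample(2:6, 1), as = "smiles")
    mine <- align_and_score(st, ft)$raw
    oracle <- oracle_align_score(st, ft)
    expect_equal(mine, oracle, tolerance = 1e-12, info = paste("trial", i))
  }
})

test_that("degrading a matched object never increases the score", {
  base_st <- c("C10H10O2+", "C8H8O+", "C7H6O+")
  ft <- manual_tree(c("C10H10O2+", "C8H8O+", "C7H6O+"), c(NA, 1L, 1L),
                    as = "fragment")
  score_with <- function(st_fmls) {
    align_and_score(manual_tree(st_fmls, c(NA, 1L, 1L), as = "smiles"), ft)$raw
  }
  all_atom <- score_with(base_st)
  heavy <- score_with(c("C10H10O2+", "C8H8O+", "C7H8O+"))   # H differs
  miss <- score_with(c("C10H10O2+", "C8H8O+", "C6H6O+"))    # heavy differs
  expect_gte(all_atom, heavy)
  expect_gte(heavy, miss)
})

test_that("candidate ranking prefers the true molecule over a pruned decoy", {
  s <- ms_spectrum(c(213.055, 237.055, 254.058), c(20, 30, 40),
                   precursor_mz = 269.081)
  ft <- fragment_tree(s, precursor_formula = "C16H13O4+")
  true_mol <- "COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1"   # formononetin
  decoy <- "Oc1ccc(-c2coc3cc(O)ccc3c2=O)cc1"       # demethylated: no CH3 loss
  r <- rank_candidates(c(true_mol, decoy), ft)
  expect_identical(canonical_smiles(r$smiles[1]), canonical_smiles(true_mol))
  expect_gt(r$score[1], r$score[2])
  # single candidate ranks first; duplicates collapse with summed frequency
  r1 <- rank_candidates(true_mol, ft)
  expect_identical(nrow(r1), 1L)
  r2 <- rank_candidates(c(true_mol, true_mol, decoy), ft)
  expect_identical(r2$frequency[r2$smiles == canonical_smiles(true_mol)], 2L)
  # invalid SMILES are dropped and counted
  r3 <- rank_candidates(c(true_mol, "zz9"), ft)
  expect_identical(attr(r3, "n_invalid"), 1L)
  expect_error(rank_candidates(c("zz9", "qq8"), ft), "no valid")
})

test_that("peak annotation reports fragments for matched peaks only", {
  s <- ms_spectrum(c(213.055, 237.055, 254.058), c(20, 30, 40),
                   precursor_mz = 269.081)
  ft <- fragment_tree(s, precursor_formula = "C16H13O4+")
  r <- rank_candidates("COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1", ft)
  ann <- annotate_peaks(r, ft)
  expect_identical(nrow(ann), 4L)
  good <- ann$match %in% c("all_atoms", "heavy_atoms")
  expect_gte(sum(good), 3L)  # three complete annotations, one open peak
  # annotated fragments sit at the right mass
  for (i in which(good)) {
    frag_mz <- monoisotopic_mz(parse_formula(ann$formula[i]))
    expect_lt(abs(frag_mz - ann$peak_mz[i]), 0.5)
  }
})

test_that("fingerprint similarity behaves like a similarity", {
  fo <- "COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1"
  for (kind in c("maccs", "morgan")) {
    expect_equal(fingerprint_similarity(fo, fo, kind), 1.0)
    ab <- fingerprint_similarity(fo, "CCO", kind)
    ba <- fingerprint_similarity("CCO", fo, kind)
    expect_equal(ab, ba)
    expect_lt(ab, 0.5)
    expect_gte(ab, 0)
  }
  d <- fingerprint_similarity("CCO", "CCN", "maccs", "dice")
  t <- fingerprint_similarity("CCO", "CCN", "maccs", "tanimoto")
  expect_gte(d, t)  # Dice >= Tanimoto always
  expect_error(fingerprint_similarity("zz9", "CCO"), "unparseable")
})
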
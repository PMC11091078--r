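# Flavonoid/stilbene structures used throughout: compositions are
# literature-standard and re-derivable from the SMILES by hand.
test_that("SMILES parsing recovers correct compositions incl. aromatics", {
  cases <- list(
    list(smi = "CCO", formula = "C2H6O"),
    list(smi = "c1ccccc1", formula = "C6H6"),
    list(smi = "O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12", formula = "C15H10O5"),  # galangin
    list(smi = "COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1", formula = "C16H12O4"),      # formononetin
    list(smi = "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1", formula = "C14H12O3"),        # resveratrol
    list(smi = "C", formula = "CH4"),
    list(smi = "[NH4+]", formula = "H4N+"),
    list(smi = "CC(=O)[O-]", formula = "C2H3O2-"),
    list(smi = "ClC(Cl)Cl", formula = "CHCl3")
  )
  for (cs in cases) {
    g <- parse_smiles(cs$smi)
    expect_identical(format_formula(graph_formula(g)), cs$formula, info = cs$smi)
  }
})

test_that("parsing rejects invalid SMILES and unsupported elements", {
  expect_error(parse_smiles("xx(("), "cannot parse")
  expect_false(is_valid_smiles("zz9"))
  expect_true(is_valid_smiles("c1ccccc1O"))
})

test_that("worked-example protonated parents have the expected nominal m/z", {
  protonated <- function(smi) {
    f <- add_formula(graph_formula(parse_smiles(smi)), parse_formula("H"))
    nominal_mz(mol_formula(unclass(f), 1L))
  }
  expect_identical(protonated("O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12"), 271L)
  expect_identical(protonated("COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1"), 269L)
})

test_that("ring perception marks ring bonds and finds six-membered rings", {
  g <- parse_smiles("O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12")
  expect_identical(length(.rings_of_size(g, 6)), 3L)  # A, B, C rings
  # biphenyl bridge bond is acyclic, ring bonds are cyclic
  bp <- parse_smiles("c1ccc(-c2ccccc2)cc1")
  expect_identical(sum(!bp$bonds$ring), 1L)
  expect_identical(sum(bp$bonds$ring), 12L)
  # ethanol has no rings
  expect_false(any(parse_smiles("CCO")$bonds$ring))
})

test_that("graph round trip through OpenBabel preserves constitution", {
  # bond/double-bond stereo is intentionally not carried by the graph:
  # fragment formulas and m/z are stereo-independent, so compare
  # stereo-stripped canonical forms
  strip_stereo <- function(s) canonical_smiles(gsub("[/\\\\]", "", s))
  for (smi in c("CCO", "c1ccccc1", "CC(=O)OC", "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1")) {
    g <- parse_smiles(smi)
    out <- graph_to_smiles(g)
    expect_identical(strip_stereo(out), strip_stereo(smi), info = smi)
  }
})

test_that("subgraph extraction and components behave on a cut bond", {
  g <- parse_smiles("CCOc1ccccc1")  # ethoxybenzene
  expect_identical(length(.graph_components(g)), 1L)
  # cut the (acyclic) O-ring bond: two components
  acyc <- which(!g$bonds$ring)
  co <- acyc[vapply(acyc, function(i) {
    els <- g$atoms$element[c(g$bonds$a1[i], g$bonds$a2[i])]
    setequal(els, c("C", "O")) && all(g$atoms$ring[c(g$bonds$a1[i], g$bonds$a2[i])] == c(FALSE, FALSE)) ||
      setequal(els, c("C", "O"))
  }, logical(1))]
  g2 <- .cut_bonds(g, co[length(co)])
  comps <- .graph_components(g2)
  expect_identical(length(comps), 2L)
  subs <- lapply(comps, function(ix) .subgraph(g2, ix))
  fs <- sort(vapply(subs, function(s) format_formula(graph_formula(s)), character(1)))
  # ethoxy side + phenyl side, both valence-filled after the cut
  expect_identical(length(fs), 2L)
  total_heavy <- sum(vapply(subs, function(s) nrow(s$atoms), integer(1)))
  expect_identical(total_heavy, nrow(g$atoms))
})

test_that("charged fragments keep their charge through molblock round trip", {
  g <- parse_smiles("CC")
  g$atoms$charge[2] <- 1L
  g <- .assign_implicit_h(g)
  expect_identical(graph_to_smiles(g), canonical_smiles("C[CH2+]"))
  expect_identical(format_formula(graph_formula(g)), "C2H5+")
})
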
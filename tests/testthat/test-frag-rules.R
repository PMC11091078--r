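# The registry's behaviour is pinned by small hand-checkable molecules;
# wider invariants (conservation, dedup, caps) are property-checked on the
# flavonoid fixtures.

test_that("default registry covers the documented mechanism families", {
  rules <- load_rules("default")
  expect_gte(length(rules), 8L)
  fams <- unique(vapply(rules, `[[`, character(1), "family"))
  expect_gte(length(fams), 6L)
  expect_true(all(c("C-C", "C-O", "C-N", "neutral_loss", "mclafferty",
                    "rda", "stilbene") %in% fams))
  classes <- vapply(rules, `[[`, character(1), "class")
  expect_setequal(unique(classes),
                  c("cleavage", "rearrangement", "domain_specific"))
})

test_that("rule files extend or replace the registry; bad SMARTS is named", {
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "  - id: my_rule",
               "    smarts: '[#6]-!@[#16]'",
               "    class: cleavage",
               "    cut: [[1, 2]]"), cfgfile)
  rules <- load_rules(cfgfile)
  expect_true("my_rule" %in% names(rules))
  expect_true(all(names(default_rules()) %in% names(rules)))
  expect_error(frag_rule("bad", "C(>>", cut = list(c(1L, 2L))), "bad")
})

test_that("C-O cleavage of protonated ethanol yields the ethyl cation channel", {
  out <- apply_rule("CCO", default_rules()$cleave_co)
  labels <- vapply(out, function(x) format_formula(x$formula), character(1))
  losses <- vapply(out, function(x) format_formula(x$loss), character(1))
  # even-electron channel: ethyl cation + water; radical channel: + hydroxyl
  expect_true(any(labels == "C2H5+" & losses == "H2O"))
  expect_true(any(labels == "C2H6+" & losses == "HO"))
  # formula conservation on every product pair
  parent <- parse_formula("C2H7O+")
  for (x in out) {
    total <- add_formula(x$formula, x$loss)
    expect_identical(format_formula(mol_formula(unclass(total), 1L)),
                     format_formula(parent))
  }
})

test_that("water loss transfers one hydrogen to the neutral loss", {
  out <- apply_rule("CCO", default_rules()$loss_water)
  losses <- vapply(out, function(x) format_formula(x$loss), character(1))
  expect_true("H2O" %in% losses)
  frag <- out[[which(losses == "H2O")[1]]]
  expect_identical(format_formula(frag$formula), "C2H5+")
})

test_that("methane matches no C-C rule", {
  expect_length(apply_rule("C", default_rules()$cleave_cc), 0L)
})

test_that("simulated fragmentation of galangin reproduces the RDA channel", {
  st <- simulate_fragmentation("O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12",
                               frag_config(max_depth = 2))
  nominal <- round(st$nodes$mz)
  expect_identical(nominal[1], 271)          # protonated parent
  expect_true(153 %in% nominal)              # 1,3A+ retro-Diels-Alder fragment
  rda_children <- st$edges$child[st$edges$rule %in% c("rda_flavone",
                                                      "rda_flavanol")]
  expect_true(153 %in% round(st$nodes$mz[st$nodes$id %in% rda_children]))
  # the canonical A-ring fragment formula
  expect_true("C7H5O4+" %in% st$nodes$formula)
})

test_that("every SmilesTree edge conserves formulas exactly", {
  for (smi in c("O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12",
                "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1",
                "CCCCC(C)=O")) {
    st <- simulate_fragmentation(smi, frag_config(max_depth = 2))
    for (e in seq_len(nrow(st$edges))) {
      p <- parse_formula(st$nodes$formula[st$edges$parent[e]])
      ch <- parse_formula(st$nodes$formula[st$edges$child[e]])
      loss <- parse_formula(st$edges$loss[e])
      expect_identical(
        format_formula(subtract_formula(mol_formula(unclass(p), 0L),
                                        mol_formula(unclass(ch), 0L))),
        format_formula(loss),
        info = paste(smi, "edge", e))
    }
    # tree shape: every non-root node has exactly one parent
    expect_identical(sort(st$edges$child), 2:nrow(st$nodes))
    # dedup: no two nodes share (canonical SMILES, formula)
    expect_false(any(duplicated(paste(st$nodes$smiles, st$nodes$formula))))
  }
})

test_that("node cap truncates deterministically and monotonically", {
  smi <- "COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1"
  st40 <- simulate_fragmentation(smi, frag_config(max_nodes = 40, max_depth = 3))
  st80 <- simulate_fragmentation(smi, frag_config(max_nodes = 80, max_depth = 3))
  expect_lte(nrow(st40$nodes), 40L)
  # BFS order is deterministic: the smaller tree is a prefix of the larger
  expect_identical(st40$nodes$smiles,
                   st80$nodes$smiles[seq_len(nrow(st40$nodes))])
  rerun <- simulate_fragmentation(smi, frag_config(max_nodes = 40, max_depth = 3))
  expect_identical(st40$nodes, rerun$nodes)
})

test_that("molecules matching no rule give a single-node tree", {
  st <- simulate_fragmentation("C", frag_config())
  expect_identical(nrow(st$nodes), 1L)
  expect_identical(nrow(st$edges), 0L)
})

test_that("McLafferty rearrangement of 2-hexanone loses propene", {
  st <- simulate_fragmentation("CCCCC(C)=O", frag_config(max_depth = 1))
  mcl <- st$edges[st$edges$rule == "mclafferty", ]
  expect_gte(nrow(mcl), 1L)
  expect_true("C3H6" %in% mcl$loss)
})

test_that("stilbene vinyl-bridge cleavage fires on resveratrol", {
  st <- simulate_fragmentation("Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1",
                               frag_config(max_depth = 1))
  expect_true("stilbene_vinyl" %in% st$edges$rule)
})

test_that("trees serialize to JSON and DOT", {
  st <- simulate_fragmentation("CCO", frag_config(max_depth = 1))
  j <- withr::local_tempfile(fileext = ".json")
  d <- withr::local_tempfile(fileext = ".dot")
  write_tree(st, j)
  parsed <- jsonlite::fromJSON(j)
  expect_identical(nrow(parsed$nodes), nrow(st$nodes))
  write_tree(st, d)
  expect_true(any(grepl("digraph", readLines(d))))
})
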
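test_that("token dictionary has exactly 44 stable entries with specials", {
  d <- build_token_dictionary()
  expect_length(d, 44L)
  expect_true(all(c("<SOS>", "<EOS>", "<PAD>") %in% names(d)))
  expect_identical(unname(d[["<PAD>"]]), 0L)
  expect_identical(sort(unname(d)), 0:43)
  expect_identical(d, build_token_dictionary())  # stable across calls
  expect_true("Cl" %in% names(d))
})

test_that("tokenizer uses longest match and round-trips", {
  expect_identical(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_identical(tokenize_smiles("c1ccccc1"),
                   c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_identical(tokenize_smiles("CCl"), c("C", "Cl"))
  expect_identical(tokenize_smiles("C[C@@H](N)O"),
                   c("C", "[", "C", "@@", "H", "]", "(", "N", ")", "O"))
  expect_error(tokenize_smiles("C?O"), "\\?")
  # round trip over the whole fixture panel and their decoys
  fm <- fixture_molecules()
  pool <- c(fm$smiles, vapply(fm$smiles, canonical_smiles, character(1)))
  for (s in pool) {
    expect_identical(detokenize_smiles(tokenize_smiles(s)), s, info = s)
  }
})

test_that("target encoding is length 100 with one SOS and one EOS", {
  d <- build_token_dictionary()
  v <- encode_target(c("C", "C", "O"))
  expect_length(v, 100L)
  expect_identical(v[1:5], c(d[["<SOS>"]], d[["C"]], d[["C"]], d[["O"]],
                             d[["<EOS>"]]), ignore_attr = TRUE)
  expect_true(all(v[6:100] == d[["<PAD>"]]))
  v0 <- encode_target(character(0))
  expect_identical(v0[1:2], c(d[["<SOS>"]], d[["<EOS>"]]), ignore_attr = TRUE)
  expect_error(encode_target(rep("C", 99)), "too long")
  # random round trips through decode
  set.seed(9)
  fm <- fixture_molecules()
  for (s in sample(fm$smiles, 5)) {
    cs <- canonical_smiles(s)
    expect_identical(decode_target(encode_target(tokenize_smiles(cs))), cs)
  }
})

test_that("training is seeded-deterministic and reduces the loss", {
  cfg <- model_config("toy", enc_layers = 1L, dec_layers = 1L, d_model = 16L,
                      n_heads = 2L, d_ff = 32L, mz_vocab = 1000L,
                      batch_size = 2L)
  ds <- list(
    list(spectrum = c(100L, 300L, 700L),
         target = encode_target(tokenize_smiles("CCO"))),
    list(spectrum = c(50L, 400L, 900L),
         target = encode_target(tokenize_smiles("CCN"))))
  m1 <- train_seq_model(ds, cfg, epochs = 30L, seed = 3L)
  m2 <- train_seq_model(ds, cfg, epochs = 30L, seed = 3L)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params$Wout, m2$params$Wout)
  expect_lt(utils::tail(m1$loss_trace, 1), m1$loss_trace[1])
  m3 <- train_seq_model(ds, cfg, epochs = 30L, seed = 4L)
  expect_false(identical(m1$loss_trace, m3$loss_trace))
  expect_error(train_seq_model(list(), cfg), "length")
})

test_that("a one-example model overfits towards zero loss", {
  cfg <- model_config("toy", enc_layers = 1L, dec_layers = 1L, d_model = 32L,
                      n_heads = 2L, d_ff = 64L, mz_vocab = 1000L,
                      batch_size = 1L)
  ds <- list(list(spectrum = c(120L, 340L),
                  target = encode_target(tokenize_smiles("CCO"))))
  m <- train_seq_model(ds, cfg, epochs = 150L, seed = 2L)
  expect_lt(utils::tail(m$loss_trace, 1), 0.05)
  g <- generate_candidates(m, c(120L, 340L), n_runs = 3L, mode = "greedy")
  expect_identical(g$smiles[1], "CCO")
})

test_that("greedy decoding is deterministic; sampling respects run counts", {
  cfg <- model_config("toy", enc_layers = 1L, dec_layers = 1L, d_model = 32L,
                      n_heads = 2L, d_ff = 64L, mz_vocab = 1000L,
                      batch_size = 1L)
  ds <- list(list(spectrum = c(120L, 340L),
                  target = encode_target(tokenize_smiles("CCO"))))
  m <- train_seq_model(ds, cfg, epochs = 150L, seed = 2L)
  g <- generate_candidates(m, c(120L, 340L), n_runs = 10L, mode = "greedy")
  expect_identical(nrow(g), 1L)             # one distinct candidate
  expect_identical(g$frequency[1], 10L)     # credited with all runs
  s <- generate_candidates(m, c(120L, 340L), n_runs = 20L, mode = "sample",
                           temperature = 2, seed = 8L)
  expect_lte(sum(s$frequency) + attr(s, "n_invalid"), 20L)
  s2 <- generate_candidates(m, c(120L, 340L), n_runs = 20L, mode = "sample",
                            temperature = 2, seed = 8L)
  expect_identical(s, s2)  # seeded sampling reproduces
})

test_that("fragment-seeded re-prediction preserves the prefix verbatim", {
  cfg <- model_config("toy", enc_layers = 1L, dec_layers = 1L, d_model = 32L,
                      n_heads = 2L, d_ff = 64L, mz_vocab = 1000L,
                      batch_size = 1L)
  ds <- list(list(spectrum = c(120L, 340L),
                  target = encode_target(tokenize_smiles("CCOC"))))
  m <- train_seq_model(ds, cfg, epochs = 150L, seed = 2L)
  out <- reseed_generate(m, c(120L, 340L), "CC")
  expect_true(startsWith(out, "CC"))
  # full training sequence as prefix reproduces itself
  out2 <- reseed_generate(m, c(120L, 340L), "CCOC")
  expect_true(startsWith(out2, "CCOC"))
  # empty prefix equals plain greedy generation
  g <- generate_candidates(m, c(120L, 340L), n_runs = 1L, mode = "greedy")
  expect_identical(reseed_generate(m, c(120L, 340L), ""), g$smiles[1])
  expect_error(reseed_generate(m, c(120L, 340L), strrep("C", 99)), "too long")
})

test_that("parameter counting scales with the configuration", {
  cfg_small <- model_config("toy", enc_layers = 1L, dec_layers = 1L,
                            d_model = 16L, n_heads = 2L, d_ff = 32L,
                            mz_vocab = 100L)
  set.seed(1)
  p_small <- fragtree:::.tf_init_params(cfg_small, 44L)
  n_small <- count_parameters(p_small)
  # closed-form expectation for this configuration
  d <- 16L; dff <- 32L
  attn <- 4L * d * d
  ln <- 2L * d
  enc_layer <- attn + 2L * ln + (d * dff + dff + dff * d + d)
  dec_layer <- 2L * attn + 3L * ln + (d * dff + dff + dff * d + d)
  expected <- 100L * d + 44L * d + enc_layer + dec_layer + 2L * ln +
    d * 44L + 44L
  expect_identical(n_small, expected)
})
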
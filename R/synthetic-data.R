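#' @title Synthetic spectra, decoys, and training sets
#'
#' @description
#' Every pipeline stage is testable without external data: the fixture
#' library ships a small panel of flavonoids, stilbenes and simple carbonyl
#' compounds (the substance classes the fragmentation rules target), and the
#' forward model re-uses [simulate_fragmentation()] to produce in-silico
#' MS2 spectra — so a spectrum generated from a molecule is, by
#' construction, explainable by the same rule chemistry the annotation side
#' applies. Decoys are single-edit structural neighbours (added/removed
#' methyl or hydroxyl, moved substituent), emulating the near-miss
#' candidates a generative model proposes.
#'
#' @name synthetic-data
NULL

#' The fixture molecule panel
#'
#' @return data.frame with columns `name`, `smiles`, `formula`, `class`.
#' @export
fixture_molecules <- function() {
  path <- system.file("extdata", "fixture_molecules.tsv", package = "fragtree")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$formula <- vapply(df$smiles, function(s) {
    format_formula(graph_formula(parse_smiles(s)))
  }, character(1), USE.NAMES = FALSE)
  df[, c("name", "smiles", "formula", "class")]
}

#' Simulate an MS2 spectrum for a molecule
#'
#' The protonated molecule is fragmented to depth 2; the spectrum contains
#' the precursor peak plus every fragment node. Intensities decay by a
#' factor 0.5 per fragmentation generation and, within a generation, scale
#' with m/z relative to the precursor — mimicking the low-mass transmission
#' roll-off of a quadrupole ion trap and keeping the high-mass diagnostic
#' fragments on top (the pipeline only uses intensities for peak selection,
#' so only their ordering matters). Optional uniform low-intensity noise
#' peaks can be added. In `"nominal"` mode (the
#' default) m/z values are integers, mimicking a unit-resolution ion trap;
#' `"exact"` mode keeps full-precision monoisotopic values.
#'
#' @param smiles molecule SMILES (or a row of [fixture_molecules()]).
#' @param cfg a [frag_config()]; depth is capped at 2 for the forward model.
#' @param noise_peaks number of random noise peaks to add.
#' @param seed RNG seed (noise placement).
#' @param mode `"nominal"` or `"exact"`.
#' @return an [ms_spectrum()] with `precursor_mz` set.
#' @export
in_silico_spectrum <- function(smiles, cfg = frag_config(max_depth = 2L),
                               noise_peaks = 0L, seed = 1L,
                               mode = c("nominal", "exact")) {
  mode <- match.arg(mode)
  if (is.data.frame(smiles)) smiles <- smiles$smiles[1]
  cfg$max_depth <- min(cfg$max_depth, 2L)
  st <- simulate_fragmentation(smiles, cfg)
  mz <- st$nodes$mz
  if (mode == "nominal") mz <- round(mz)
  # depth decay x within-depth mass factor (0.5..1): generations never
  # overlap in intensity, and among same-depth fragments the heavier ion
  # is the more intense, as in ion-trap CID spectra
  intensity <- 100 * 0.5^st$nodes$depth * (0.5 + 0.5 * mz / max(mz[1], 1))
  keep <- !duplicated(mz) & mz >= 50
  keep[1] <- TRUE
  mz <- mz[keep]; intensity <- intensity[keep]
  prec_mz <- mz[1]
  if (noise_peaks > 0L) {
    set.seed(seed)
    nmz <- runif(noise_peaks, 50, prec_mz - 1)
    if (mode == "nominal") nmz <- round(nmz)
    ok <- !nmz %in% mz
    mz <- c(mz, nmz[ok])
    intensity <- c(intensity, runif(sum(ok), 0.5, 3))
  }
  ms_spectrum(mz, intensity, precursor_mz = prec_mz, ms_level = 2L)
}

# single random structural edit on a molecular graph; returns SMILES or NA
.decoy_edit <- function(g) {
  ops <- c("add_methyl", "add_hydroxyl", "drop_terminal", "move_substituent")
  op <- sample(ops, 1)
  carbons_h <- which(g$atoms$element == "C" & g$atoms$nH > 0)
  deg <- integer(nrow(g$atoms))
  for (i in seq_len(nrow(g$bonds))) {
    deg[g$bonds$a1[i]] <- deg[g$bonds$a1[i]] + 1L
    deg[g$bonds$a2[i]] <- deg[g$bonds$a2[i]] + 1L
  }
  terminals <- which(deg == 1L & !g$atoms$ring)
  pick <- function(v) if (length(v) == 1L) v else sample(v, 1)
  if (op %in% c("add_methyl", "add_hydroxyl")) {
    if (!length(carbons_h)) return(NA_character_)
    at <- pick(carbons_h)
    el <- if (op == "add_methyl") "C" else "O"
    g$atoms <- rbind(g$atoms, data.frame(element = el, charge = 0L, nH = 0L,
                                         ring = FALSE))
    g$bonds <- rbind(g$bonds, data.frame(a1 = at, a2 = nrow(g$atoms),
                                         order = 1L, ring = FALSE))
  } else if (op == "drop_terminal") {
    if (!length(terminals)) return(NA_character_)
    at <- pick(terminals)
    keep <- setdiff(seq_len(nrow(g$atoms)), at)
    g <- .subgraph(g, keep)
  } else {
    if (!length(terminals) || !length(carbons_h)) return(NA_character_)
    at <- pick(terminals)
    bi <- which(g$bonds$a1 == at | g$bonds$a2 == at)
    anchor_old <- setdiff(c(g$bonds$a1[bi], g$bonds$a2[bi]), at)
    candidates <- setdiff(carbons_h, c(at, anchor_old))
    if (!length(candidates)) return(NA_character_)
    g$bonds <- g$bonds[-bi, , drop = FALSE]
    g$bonds <- rbind(g$bonds, data.frame(a1 = pick(candidates), a2 = at,
                                         order = 1L, ring = FALSE))
  }
  graph_to_smiles(g)
}

#' Generate structural decoys
#'
#' `n` distinct, valid single-edit variants of the parent molecule, each
#' differing from the parent's canonical SMILES. Deterministic under `seed`.
#'
#' @param smiles parent SMILES.
#' @param n number of decoys.
#' @param seed RNG seed.
#' @return character vector of `n` canonical SMILES.
#' @export
make_decoys <- function(smiles, n = 5L, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  parent_canon <- canonical_smiles(smiles)
  g0 <- parse_smiles(smiles)
  out <- character(0)
  attempts <- 0L
  while (length(out) < n && attempts < 200L * n) {
    attempts <- attempts + 1L
    smi <- .decoy_edit(g0)
    if (is.na(smi) || !nzchar(smi)) next
    canon <- canonical_smiles(smi)
    if (is.na(canon) || canon == parent_canon || canon %in% out) next
    out <- c(out, canon)
  }
  if (length(out) < n) {
    stop("could not generate ", n, " distinct decoys for ", smiles)
  }
  out
}

#' Build a paired training set for the sequence model
#'
#' For each molecule: a seeded in-silico spectrum, preprocessed with
#' [select_top_peaks()] and [encode_spectrum()], paired with the
#' [encode_target()] vector of its canonical SMILES. Pairs are shuffled
#' deterministically by `seed`.
#'
#' @param molecules data.frame with a `smiles` column (e.g.
#'   [fixture_molecules()]), or a character vector of SMILES.
#' @param cfg a [frag_config()] for the forward model.
#' @param seed RNG seed.
#' @param top_k peaks retained per spectrum (default 6, matching the
#'   acquisition protocol of a miniaturized ion trap).
#' @return list of `list(spectrum = integer tokens, target = length-100
#'   index vector, smiles = canonical SMILES)`.
#' @export
make_training_set <- function(molecules, cfg = frag_config(max_depth = 2L),
                              seed = 1L, top_k = 6L) {
  smiles <- if (is.data.frame(molecules)) molecules$smiles else molecules
  stopifnot(length(smiles) >= 1L)
  pairs <- lapply(seq_along(smiles), function(i) {
    s <- in_silico_spectrum(smiles[i], cfg, noise_peaks = 0L, seed = seed + i)
    s <- select_top_peaks(s, top_k)
    canon <- canonical_smiles(smiles[i])
    list(spectrum = as.integer(encode_spectrum(s)),
         target = encode_target(tokenize_smiles(canon)),
         smiles = canon)
  })
  set.seed(seed)
  pairs[sample(length(pairs))]
}
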
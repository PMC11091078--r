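---
title: "Annotating unit-resolution tandem mass spectra with fragmentation trees and simulated fragmentation"
author: "fragtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fragtree methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtree)
```

## The problem

Miniaturized ion-trap mass spectrometers produce centroided MS² spectra at
unit mass resolution: a protonated small molecule `[M+H]⁺` is isolated and
collisionally fragmented, and the instrument reports a handful (typically
3–6) of fragment peaks with integer-level m/z accuracy. High-resolution
annotation engines assume ppm-level mass accuracy and isotope envelopes,
neither of which such instruments provide. `fragtree` targets exactly this
regime, for small molecules under 500 Da over the elements C, H, O, N, P,
S, Cl, Br, I and F: natural products (flavonoids, stilbenes), drug
ingredients, and similar analytes.

The core idea couples two tree representations of fragmentation:

* a **fragmentation tree (FT)** built from the measured spectrum — each
  node is a molecular formula assigned to a peak, each edge a neutral
  loss — chosen to maximize a plausibility weight;
* a **SMILES tree** built from a candidate structure by simulating
  collision-induced dissociation with a registry of cleavage and
  rearrangement rules — each node a fragment structure, each edge the lost
  substructure's formula.

Candidates are ranked by an explicit tree-alignment similarity between the
two trees, normalized by the perfect-match score; the winning alignment
annotates each fragment peak with a substructure and a neutral loss.
Candidates may come from any external source (database hits, a SMILES
file) or from the package's spectrum-to-SMILES sequence model.

## Formula assignment and the fragmentation tree

**Enumeration.** For an observed m/z, candidate formulas are found by exact
branch-and-bound over element counts (heaviest element first, residual-mass
pruning) within per-element bounds and a tolerance window. The default
tolerance is 0.5 Da — matched to unit-resolution peaks, where the window
deliberately admits hydrogen-shifted variants of a composition (`CxHy` and
`CxHy±1` both lie within half a dalton); this is also how hydrogen
rearrangement during fragmentation is accommodated, rather than by a
special slack term in the tree optimizer, so every FT edge satisfies exact
elementwise conservation `loss = parent − child`. For cations the electron
mass is folded in before the neutral-composition search; the printed
theoretical m/z of `C15H24N3O⁺` (262.191) fixes this convention: only the
electron-subtracted value reproduces the reported third decimal.

**Filtering.** Candidates pass configurable chemical filters: ring/double-
bond equivalents `RDBE = C + 1 − (H + halogens)/2 + (N + P)/2` must be at
least 0 for neutral molecules (−0.5 for even-electron cations, which carry
an extra proton), and the H/C ratio must fall within 0.1–3.5 where carbon
is present. Both filters can be disabled; the defaults are deliberately
conservative because the low-resolution setting already constrains
formulas weakly.

**Tree optimization.** Every (peak, sub-formula-of-the-precursor) pair
becomes a node; an edge runs from u to v when v's formula is a proper
sub-formula of u's and v's m/z is smaller. The tree score sums node weights
(`1 − |mass error| × 2 /Da`) and edge weights (a common-loss bonus table
covering the losses the rule registry can produce — water 3, CO 3,
methanol 2.5, methyl 2, … — plus a −1 penalty for odd-electron losses,
identified by non-integer RDBE). Because m/z strictly decreases along
edges, once a per-peak formula assignment is fixed each node can
independently attach to its best feasible parent; enumerating assignments
(each peak: one candidate or unannotated) therefore yields the exact
optimum. With at most ~6 retained peaks and a per-peak candidate cap of 6,
exhaustive assignment enumeration is affordable; ties break
deterministically by mass error and formula string. The weight values are
a package-defined stand-in for the probabilistic models used by
high-resolution FT software, shipped as an editable configuration — at
unit resolution the data cannot support a finely calibrated model, and the
downstream alignment score is robust to the exact weights because they
only select among near-equivalent trees.

## Simulated fragmentation

A fragmentation rule couples a substructure pattern with a transformation:
which matched bonds are cut, an optional re-formed bond, how many hydrogens
migrate to the neutral loss, and which side keeps the charge. Patterns are
written in a documented SMARTS subset (element and atomic-number atoms,
ring/acyclic bond qualifiers, H-count, connectivity, charge; compiled by
the package and matched by backtracking subgraph search on the kekulized
molecular graph). The default registry implements: heterolytic cleavage of
acyclic C–C, C–O and C–N single bonds (charge retained on either side;
C–O cleavage additionally emits the proton-carried-by-the-leaving-group
channel, so protonated ethanol yields both `C2H6⁺• + OH•` and
`C2H5⁺ + H2O`), water and methanol neutral losses with one-hydrogen
migration, CO extrusion (including from rings, via a re-formed bond), the
McLafferty γ-hydrogen rearrangement, retro-Diels–Alder cleavage of the
flavone/flavonol and flavanol C-rings (the canonical A-ring fragment —
m/z 153 for 5,7-dihydroxyflavones), and aryl–vinyl cleavage with hydrogen
transfer for stilbenes. Rules are loaded from YAML/JSON and fully
replaceable; the registry file is the compatibility surface.

Expansion is breadth-first from the protonated molecule with deterministic
rule and match order, deduplicating nodes by (canonical SMILES, formula) —
the displayed SMILES is the heavy-atom skeleton (canonicalized through
OpenBabel), while the node formula, tracked by exact atom bookkeeping
through every cut and hydrogen transfer, is authoritative; this is why
hydroxyl-radical loss and water loss, which share a skeleton, remain
distinct nodes. Expansion stops when no rule matches, at a configurable
depth (default 4), or at a node cap (default 1500); because the order is
deterministic, truncation at the cap is reproducible and raising the cap
only appends nodes.

## Tree alignment and candidate ranking

The similarity score compares three object classes at three match levels.
A pair of formulas matches *all-atom* when every element count agrees,
*heavy-atom* when all non-hydrogen counts agree but hydrogen differs (the
signature of hydrogen rearrangement at unit resolution), and otherwise
mismatches. The scores are: parent (root vs root) 6 / 3 / 0, fragment 5 /
2 / 0, loss 4 / 1.5 / 0 — losses are deliberately scored below fragments
so that long loss chains cannot dominate. The total is normalized by the
perfect-match score of the measured tree, `6 + 5·(n−1) + 4·(n−1)` for an
n-node FT, giving a similarity in [0, 1]: the measured spectrum defines
what a perfect explanation is.

The alignment maps FT nodes injectively onto SMILES-tree nodes, root onto
root, with the mapped set connected and ancestor order preserved. An FT
edge may span several SMILES-tree generations: the composed loss along the
path (equal to the formula difference of its endpoints) is compared, so a
single observed loss can be explained by a multi-step cascade. The search
is an exact branch-and-bound for compact SMILES trees (≤ 40 nodes); for
larger trees the candidate images of each FT node are restricted to
descendants with positive marginal score plus the immediate children of
the parent's image, capped at the 16 best — zero-gain deep "bridge"
images, which can only tie, are dropped. Fragment trees wider than 12
nodes (which a 6-peak pipeline never produces) fall back to greedy
matching. Many-to-one images are forbidden; level skipping is allowed via
loss composition.

Candidates are ranked by normalized score, then generation frequency, then
canonical SMILES (determinism); invalid SMILES are dropped and counted. In
the peak report, an FT node whose image mismatches at the formula level is
reported as unannotated — a mismatching image is an alignment artifact,
not a structural annotation.

## The sequence model

The generative component is an encoder–decoder transformer implemented in
base R matrix code with hand-derived backpropagation (verified against
numerical differentiation in the test suite). Spectra enter as integer
tokens — each m/z truncated (not rounded) to two decimals and scaled by
100, preserving 0.01 Da — embedded through a learned table over the m/z
vocabulary; a learned embedding lookup is mathematically identical to
multiplying a one-hot matrix by a weight matrix, so no one-hot tensor is
materialized. No positional encoding is added on the encoder side: a peak
list is a set. The decoder is autoregressive over a 44-token SMILES
dictionary (3 specials, 10 uppercase elements, 5 aromatic lowercase
forms, 10 digits, 16 structural connectors), with targets framed as
`<SOS> … <EOS>` and padded to a fixed length of 100.

The full-scale configuration (6+6 layers, 8 heads, width 512,
feed-forward 2048 — the standard 4× width, as the reference setup leaves
it unstated) trains with SGD at learning rate 0.001 and batch size 150;
its parameter count is reported by `count_parameters()`. The test and
demonstration surface is the `"toy"` preset (2+2 layers, width 64, 4
heads), which trains on a CPU in minutes; it uses Adam with gradient-norm
clipping because plain SGD, at this scale and horizon, stalls at the
input-independent language-model optimum before the cross-attention learns
to use the spectrum. Decoding is greedy (argmax; deterministic — one
distinct candidate regardless of run count) or temperature sampling, which
is the package's stochasticity source for frequency-weighted candidate
lists across repeated runs; an autoregressive decoder with argmax decoding
cannot produce run-to-run variation by itself, so sampling is the explicit
mechanism behind multi-run candidate generation. Fragment-seeded
re-prediction forces the decoder through a trusted substructure prefix and
free-runs from there, guaranteeing the prefix verbatim.

## The synthetic-data generator

The generator closes the loop with the same rule chemistry the annotation
side uses: an in-silico spectrum is the protonated molecule plus its
simulated fragments to depth 2, with intensities decaying 0.5× per
generation and, within a generation, scaling with m/z relative to the
precursor — a simple stand-in for the low-mass transmission roll-off of
quadrupole ion traps that keeps the heavy diagnostic fragments on top of
the intensity ordering (a constant within-depth intensity would make
top-k selection degenerate to its tie-break). Nominal mode rounds m/z to
integers (unit resolution); exact mode keeps monoisotopic values. Decoys
are single structural edits — added or removed methyl/hydroxyl, moved
substituent — emulating the near-miss candidates a generative model
proposes. What passing the synthetic suite does *not* show: robustness to
real instrument noise, to fragmentation channels outside the registry, to
adducts other than protonation, or to isotope interference; the generator
shares its fragmentation model with the annotator, so these tests verify
the pipeline's internal consistency and exactness, not the chemical
completeness of the rules.

Fixture problem sizes were chosen for single-CPU practicality: 20-molecule
training sets, 6-peak spectra, depth-2 forward simulation, depth-2..3
candidate fragmentation, 5 decoys per spectrum.

## Numerical and design choices

* Masses come from a pinned NIST monoisotopic table inside the package;
  electron mass is subtracted for cations. Results are bit-stable across
  machines.
* Formula enumeration tie-breaks by |mass error| then formula string; peak
  selection tie-breaks intensity ties toward lower m/z; ranking tie-breaks
  score, then frequency, then canonical SMILES. All chosen once, for
  determinism, and covered by permutation-invariance tests.
* Truncation (floor at 2 dp), never rounding, in spectrum encoding — the
  two differ for `x.xx9…` values and truncation is the documented
  instrument convention.
* The engine fragments the neutral skeleton and tracks charge and protons
  in the formula ledger; when charge retention is ambiguous both
  assignments are emitted and deduplication keeps the distinct ones.
* Stereochemistry is intentionally dropped by the molecular graph:
  fragment formulas and masses are stereo-independent.
* Scan averaging is a plain greedy-alignment mean over repeat centroids, a
  deliberately simple hook standing in for instrument-specific
  deconvolution.

## Known limitations

Single protonation only (no adducts, no multiple charging); no
isotope-pattern scoring (the target instruments provide no usable
envelopes); the rule registry covers the named mechanism classes, not the
full diversity of CID chemistry; the full-scale transformer configuration
is provided but not trained here — library-scale training data and GPU
time are outside the package's scope; and the alignment's large-tree
regime is exact only within its documented candidate restriction.
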
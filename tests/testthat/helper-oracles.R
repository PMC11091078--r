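# Independent brute-force oracles used across test files. These deliberately
# use naive exhaustive strategies (expand.grid, full enumeration) so they stay
# structurally unrelated to the package's pruned/DP implementations.

# All formulas within `bounds` whose monoisotopic m/z (at `charge`) lies within
# tolerance of target_mz, via a full cartesian grid.
oracle_enumerate <- function(target_mz, bounds, charge = 0L) {
  mx <- bounds$max[bounds$max > 0]
  if (!length(mx)) return(character(0))
  grid <- do.call(expand.grid, lapply(mx, function(k) 0:k))
  masses <- c(C = 12.0, H = 1.00782503207, O = 15.9949146196, N = 14.0030740048,
              P = 30.97376163, S = 31.97207100, Cl = 34.96885268,
              Br = 78.9183371, I = 126.904473, F = 18.99840322)
  m <- as.numeric(as.matrix(grid) %*% masses[names(mx)]) -
    charge * 0.000548579909
  hits <- grid[abs(m - target_mz) <= bounds$tolerance &
                 rowSums(grid) > 0 &
                 (m + charge * 0.000548579909) <= bounds$max_mass, , drop = FALSE]
  if (!nrow(hits)) return(character(0))
  out <- apply(hits, 1, function(r) {
    format_formula(mol_formula(r[r > 0], charge))
  })
  sort(unname(out))
}

# Random plausible formula for property tests.
random_formula <- function() {
  v <- c(C = sample(1:15, 1), H = sample(0:25, 1), O = sample(0:6, 1),
         N = sample(0:3, 1))
  mol_formula(v[v > 0])
}
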
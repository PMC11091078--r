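# Exhaustive (assignment x parent-function) search over a candidate_graph:
# independent of max_weight_tree's best-parent shortcut.
oracle_max_tree_score <- function(g) {
  nd <- g$nodes
  roots <- nd$id[nd$root]
  frag_peaks <- setdiff(sort(unique(nd$peak)), 1L)
  cand <- lapply(frag_peaks, function(p) c(nd$id[nd$peak == p], 0L))
  grid <- if (length(cand)) do.call(expand.grid, cand) else data.frame(x = 0)[0, , drop = FALSE]
  best <- -Inf
  eval_assignment <- function(sel, root) {
    members <- c(root, sel[sel > 0])
    non_root <- setdiff(members, root)
    base <- sum(nd$weight[match(members, nd$id)])
    if (!length(non_root)) return(base)
    # all feasible parent choices per node, full cartesian enumeration
    choices <- lapply(non_root, function(v) {
      which(g$edges$to == v & g$edges$from %in% members)
    })
    if (any(vapply(choices, length, integer(1)) == 0L)) return(-Inf)
    pgrid <- do.call(expand.grid, choices)
    base + max(apply(pgrid, 1, function(r) sum(g$edges$weight[unlist(r)])))
  }
  for (root in roots) {
    if (nrow(grid) == 0) {
      best <- max(best, nd$weight[match(root, nd$id)])
    } else {
      for (i in seq_len(nrow(grid))) {
        best <- max(best, eval_assignment(as.integer(grid[i, ]), root))
      }
    }
  }
  best
}

# Greedy baseline: per peak, lowest-error candidate; attach to the best
# already-placed parent or drop the peak.
greedy_tree_score <- function(g) {
  nd <- g$nodes
  root <- nd$id[nd$root][order(nd$err[nd$root])][1]
  placed <- root
  score <- nd$weight[match(root, nd$id)]
  for (p in setdiff(sort(unique(nd$peak)), 1L)) {
    ids <- nd$id[nd$peak == p]
    ids <- ids[order(nd$err[match(ids, nd$id)])]
    done <- FALSE
    for (v in ids) {
      e <- which(g$edges$to == v & g$edges$from %in% placed)
      if (length(e)) {
        score <- score + nd$weight[match(v, nd$id)] + max(g$edges$weight[e])
        placed <- c(placed, v)
        done <- TRUE
        break
      }
    }
  }
  score
}

# Random small FT instance: a parent formula, a few true sub-formulas with
# mass jitter, occasionally a pure-noise peak.
random_ft_instance <- function(n_peaks = sample(3:5, 1)) {
  parent <- mol_formula(c(C = sample(8:16, 1), H = sample(8:18, 1),
                          O = sample(2:6, 1)), 1L)
  prec_mz <- monoisotopic_mz(parent) + runif(1, -0.2, 0.2)
  frag_mz <- numeric(0)
  while (length(frag_mz) < n_peaks) {
    if (runif(1) < 0.15) {
      m <- runif(1, 50, monoisotopic_mz(parent) - 20)  # noise peak
    } else {
      keep <- vapply(names(parent), function(e) sample(0:parent[[e]], 1),
                     integer(1))
      child <- keep[keep > 0]
      if (!length(child) || !"C" %in% names(child)) next
      m <- monoisotopic_mz(mol_formula(child, 1L)) + runif(1, -0.3, 0.3)
      if (m > prec_mz - 5 || m < 40) next
    }
    if (any(abs(frag_mz - m) < 1)) next
    frag_mz <- c(frag_mz, m)
  }
  s <- ms_spectrum(frag_mz, runif(n_peaks, 10, 100), precursor_mz = prec_mz)
  candidate_graph(s, list(parent), tolerance = 0.5, max_candidates = 3L)
}
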
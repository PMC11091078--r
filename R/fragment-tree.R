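#' @title Fragmentation trees from unit-resolution MS2 spectra
#'
#' @description
#' A fragmentation tree (FT) assigns one molecular formula to (a subset of)
#' the spectrum's peaks and connects them by neutral-loss edges: the root is
#' the precursor ion, every edge's loss is the exact elementwise formula
#' difference, and the tree maximizes a weight combining chemical
#' plausibility of losses with mass-error penalties. Peak-level candidates
#' come from [sub_formulas_of()]; the optimizer is exact (enumeration over
#' per-peak assignments with independent best-parent selection, valid
#' because m/z strictly decreases along every edge), affordable because
#' unit-resolution ion-trap spectra carry only a handful of fragment peaks.
#'
#' @name fragment-tree
NULL

#' Edge/node weight model for FT construction
#'
#' The score of a tree is `sum(node weights) + sum(edge weights)` with
#' `node weight = node_base - |mass error| * mass_error_penalty` and
#' `edge weight = common-loss bonus (0 for unknown losses) + radical penalty
#' for odd-electron losses`. The common-loss table ships with the package
#' and is fully editable; it mirrors the losses the rule registry can
#' produce (water, CO, methyl, methanol, ketene, ...).
#'
#' @param loss_bonus named numeric vector: canonical loss formula -> bonus.
#' @param mass_error_penalty score units per Da of |observed - theoretical|.
#' @param radical_penalty added (negative) score for odd-electron losses,
#'   identified by non-integer RDBE.
#' @param node_base base score for annotating a peak at all.
#' @return An `edge_weight_model`.
#' @export
edge_weight_model <- function(loss_bonus = NULL, mass_error_penalty = 2,
                              radical_penalty = -1, node_base = 1) {
  if (is.null(loss_bonus)) {
    loss_bonus <- c(H2O = 3, CO = 3, CH4O = 2.5, CO2 = 2.5, C2H2O = 2.5,
                    NH3 = 2.5, CH2O = 2, CH3 = 2, C2H4 = 1.5, C2H2 = 1.5,
                    C3H6 = 1.5, HO = 1.5, H2 = 1, CHN = 2, C6H6O = 1.5,
                    C2H4O2 = 1.5)
  }
  stopifnot(mass_error_penalty >= 0, all(is.finite(loss_bonus)))
  structure(list(loss_bonus = loss_bonus,
                 mass_error_penalty = mass_error_penalty,
                 radical_penalty = radical_penalty,
                 node_base = node_base),
            class = "edge_weight_model")
}

#' Bonus for a common neutral loss
#'
#' Table lookup on the canonical formula string; unknown losses score 0.
#' Odd-electron (radical) losses additionally receive the model's radical
#' penalty.
#'
#' @param loss a [mol_formula()] (neutral).
#' @param model an [edge_weight_model()].
#' @return score (units of the weight model).
#' @export
common_loss_bonus <- function(loss, model = edge_weight_model()) {
  key <- format_formula(loss, with_charge = FALSE)
  bonus <- if (key %in% names(model$loss_bonus)) model$loss_bonus[[key]] else 0
  if (rdbe(loss) %% 1 != 0) bonus <- bonus + model$radical_penalty
  bonus
}

#' Build the weighted candidate DAG for a spectrum
#'
#' One node per (peak, candidate formula) pair; candidates for fragment
#' peaks are sub-formulas of a precursor candidate within `tolerance`,
#' RDBE-filtered for singly charged ions and capped at `max_candidates` per
#' peak by mass error. A directed edge runs from u to v whenever v's formula
#' is a proper sub-formula of u's and v's m/z is smaller.
#'
#' @param s an [ms_spectrum()] whose precursor is either `s$precursor_mz` or
#'   its highest-m/z peak.
#' @param precursor_candidates non-empty list of [mol_formula()] for the
#'   precursor ion (charge +1).
#' @param tolerance matching tolerance in Da (default 0.5, unit resolution).
#' @param model an [edge_weight_model()].
#' @param max_candidates per-peak candidate cap (default 6).
#' @return a `candidate_graph`.
#' @export
candidate_graph <- function(s, precursor_candidates, tolerance = 0.5,
                            model = edge_weight_model(), max_candidates = 6L) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (!length(precursor_candidates)) {
    stop("uninterpretable precursor: no candidate formula")
  }
  prec_mz <- s$precursor_mz %||% max(s$peaks$mz)
  # fragment peaks: everything meaningfully below the precursor
  frag_ix <- which(s$peaks$mz < prec_mz - tolerance)
  peak_mz <- c(prec_mz, s$peaks$mz[frag_ix])
  peak_id <- c(0L, frag_ix)  # 0 = precursor pseudo-peak
  nodes <- list()
  for (pc in precursor_candidates) {
    if (abs(monoisotopic_mz(pc) - prec_mz) > tolerance + 1e-9) next
    nodes[[length(nodes) + 1L]] <- list(peak = 1L, formula = pc,
                                        err = abs(monoisotopic_mz(pc) - prec_mz),
                                        root = TRUE)
  }
  if (!length(nodes)) {
    stop("uninterpretable precursor: no candidate formula within tolerance")
  }
  for (k in seq_along(frag_ix)) {
    mzk <- s$peaks$mz[frag_ix[k]]
    cands <- list()
    for (pc in precursor_candidates) {
      cands <- c(cands, sub_formulas_of(pc, mzk, tolerance = tolerance))
    }
    if (!length(cands)) next  # peak stays unannotated
    keys <- vapply(cands, format_formula, character(1))
    cands <- cands[!duplicated(keys)]
    cands <- filter_formulas(cands, min_rdbe = -0.5, hc_range = NULL)
    if (!length(cands)) next
    errs <- vapply(cands, function(f) abs(monoisotopic_mz(f) - mzk), numeric(1))
    o <- order(errs, vapply(cands, format_formula, character(1)))
    o <- o[seq_len(min(length(o), max_candidates))]
    for (j in o) {
      nodes[[length(nodes) + 1L]] <- list(peak = k + 1L, formula = cands[[j]],
                                          err = errs[j], root = FALSE)
    }
  }
  n <- length(nodes)
  node_df <- data.frame(
    id = seq_len(n),
    peak = vapply(nodes, `[[`, integer(1), "peak"),
    peak_index = peak_id[vapply(nodes, `[[`, integer(1), "peak")],
    mz = peak_mz[vapply(nodes, `[[`, integer(1), "peak")],
    formula = vapply(nodes, function(x) format_formula(x$formula), character(1)),
    err = vapply(nodes, `[[`, numeric(1), "err"),
    root = vapply(nodes, `[[`, logical(1), "root"),
    stringsAsFactors = FALSE)
  node_df$weight <- model$node_base - node_df$err * model$mass_error_penalty
  formulas <- lapply(nodes, `[[`, "formula")
  # pairwise feasible edges (proper sub-formula, smaller m/z)
  e_from <- integer(0); e_to <- integer(0)
  e_loss <- character(0); e_weight <- numeric(0)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (node_df$mz[v] >= node_df$mz[u]) next
      fu <- formulas[[u]]; fv <- formulas[[v]]
      if (!is_subformula(fv, fu)) next
      loss <- subtract_formula(mol_formula(unclass(fu), 0L),
                               mol_formula(unclass(fv), 0L))
      if (length(loss) == 0L) next
      e_from <- c(e_from, u); e_to <- c(e_to, v)
      e_loss <- c(e_loss, format_formula(loss))
      e_weight <- c(e_weight, common_loss_bonus(loss, model))
    }
  }
  structure(list(nodes = node_df,
                 edges = data.frame(from = e_from, to = e_to, loss = e_loss,
                                    weight = e_weight,
                                    stringsAsFactors = FALSE),
                 formulas = formulas, spectrum = s, model = model),
            class = "candidate_graph")
}

#' Exact maximum-weight fragmentation tree
#'
#' Enumerates, for every choice of root (precursor candidate) and every
#' per-peak assignment (one candidate or unannotated), the optimal tree:
#' given an assignment, each node independently attaches to its best
#' feasible parent (larger m/z, proper super-formula), which is exact
#' because edges always point down in m/z. Deterministic tie-breaks:
#' assignments are scanned in (mass error, formula) order and a strictly
#' better score is required to replace the incumbent.
#'
#' @param g a [candidate_graph()].
#' @return a `fragment_tree`: list with `nodes` (data.frame `id`,
#'   `peak_index`, `mz`, `formula`, `weight`), `edges` (`parent`, `child`,
#'   `loss`, `weight`), `score`, `root` (node id).
#' @export
max_weight_tree <- function(g) {
  stopifnot(inherits(g, "candidate_graph"))
  nd <- g$nodes
  n <- nrow(nd)
  peaks <- sort(unique(nd$peak))
  root_ids <- nd$id[nd$root]
  if (!length(root_ids)) stop("no precursor candidate in graph")
  # edge lookup: for child v, candidate parents and weights
  parents_of <- split(seq_len(nrow(g$edges)), g$edges$to)
  best <- NULL
  best_score <- -Inf

  frag_peaks <- setdiff(peaks, 1L)
  cand_by_peak <- lapply(frag_peaks, function(p) c(nd$id[nd$peak == p], 0L))
  assign_cur <- integer(length(frag_peaks))

  evaluate <- function(chosen) {
    for (root in root_ids) {
      sel <- c(root, chosen[chosen > 0L])
      score <- sum(nd$weight[sel])
      edges <- integer(0)
      ok <- TRUE
      for (v in setdiff(sel, root)) {
        cand_e <- parents_of[[as.character(v)]]
        cand_e <- cand_e[g$edges$from[cand_e] %in% sel]
        if (!length(cand_e)) { ok <- FALSE; break }
        w <- g$edges$weight[cand_e]
        pick <- cand_e[order(-w, -nd$mz[g$edges$from[cand_e]],
                             nd$formula[g$edges$from[cand_e]])][1]
        edges <- c(edges, pick)
        score <- score + g$edges$weight[pick]
      }
      if (ok && score > best_score + 1e-12) {
        best_score <<- score
        best <<- list(root = root, sel = sel, edges = edges)
      }
    }
  }

  recurse <- function(i) {
    if (i > length(frag_peaks)) { evaluate(assign_cur); return() }
    for (ch in cand_by_peak[[i]]) {
      assign_cur[i] <<- ch
      recurse(i + 1L)
    }
  }
  recurse(1L)

  sel <- best$sel
  nodes <- nd[nd$id %in% sel, c("id", "peak_index", "mz", "formula", "weight")]
  rownames(nodes) <- NULL
  ed <- g$edges[best$edges, , drop = FALSE]
  edges <- data.frame(parent = ed$from, child = ed$to, loss = ed$loss,
                      weight = ed$weight, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, score = best_score,
                 root = best$root),
            class = "fragment_tree")
}

#' Build a fragmentation tree for a spectrum in one call
#'
#' Convenience wrapper: enumerate precursor candidates (unless supplied),
#' build the candidate graph, and optimize.
#'
#' @param s an [ms_spectrum()].
#' @param precursor_formula optional known precursor formula (string or
#'   [mol_formula()]); otherwise candidates are enumerated under `bounds`.
#' @param bounds an [element_bounds()] used when enumerating the precursor.
#' @param tolerance Da tolerance (default 0.5).
#' @param model an [edge_weight_model()].
#' @return a `fragment_tree`.
#' @export
fragment_tree <- function(s, precursor_formula = NULL,
                          bounds = element_bounds(C = 30, H = 40, O = 10,
                                                  N = 5, tolerance = 0.5),
                          tolerance = 0.5, model = edge_weight_model()) {
  if (!is.null(precursor_formula)) {
    pf <- if (is.character(precursor_formula)) {
      parse_formula(precursor_formula)
    } else precursor_formula
    if (attr(pf, "charge") == 0L) pf <- mol_formula(unclass(pf), 1L)
    pcs <- list(pf)
  } else {
    prec_mz <- s$precursor_mz %||% max(s$peaks$mz)
    bounds$tolerance <- tolerance
    pcs <- enumerate_formulas(prec_mz, bounds, charge = 1L)
    pcs <- filter_formulas(pcs, min_rdbe = -0.5, hc_range = c(0.1, 3.5))
  }
  g <- candidate_graph(s, pcs, tolerance = tolerance, model = model)
  max_weight_tree(g)
}

#' @export
print.fragment_tree <- function(x, ...) {
  cat("<fragment_tree> root ", x$nodes$formula[x$nodes$id == x$root],
      ", ", nrow(x$nodes), " nodes, score ", sprintf("%.3f", x$score),
      "\n", sep = "")
  invisible(x)
}
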
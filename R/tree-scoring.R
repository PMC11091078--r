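#' @title Tree-alignment similarity between SMILES trees and fragment trees
#'
#' @description
#' A candidate structure is judged by how well its simulated fragmentation
#' (SMILES tree) explains the measured fragmentation tree (FT). The two
#' trees are aligned: the roots are compared as the *parent* object, mapped
#' FT nodes as *fragments*, and each mapped FT edge's neutral loss as a
#' *loss*, scored per three-tier match levels (all-atom / heavy-atom /
#' mismatch). An FT edge may map across several SMILES-tree generations: the
#' composed loss along the path (the formula difference of its endpoints)
#' is compared, so one observed loss can be explained by a multi-step
#' cascade. The raw score is normalized by the perfect-match score, giving a
#' similarity in [0, 1].
#'
#' @name tree-scoring
NULL

#' The alignment score table
#'
#' Default values: parent 6/3/0, fragment 5/2/0, loss 4/1.5/0 for
#' all-atom/heavy-atom/mismatch. Loss scores are deliberately lower than
#' fragment scores so long loss chains cannot dominate the total.
#'
#' @param parent,fragment,loss numeric length-3 vectors named
#'   `all_atoms`, `heavy_atoms`, `mismatch`.
#' @return a `score_table`.
#' @export
score_table <- function(parent = c(all_atoms = 6, heavy_atoms = 3, mismatch = 0),
                        fragment = c(all_atoms = 5, heavy_atoms = 2, mismatch = 0),
                        loss = c(all_atoms = 4, heavy_atoms = 1.5, mismatch = 0)) {
  for (v in list(parent, fragment, loss)) {
    stopifnot(identical(names(v), c("all_atoms", "heavy_atoms", "mismatch")),
              diff(v) <= 0)
  }
  stopifnot(all(loss <= fragment))
  structure(list(parent = parent, fragment = fragment, loss = loss),
            class = "score_table")
}

#' Score one matched object
#'
#' @param object_class `"parent"`, `"fragment"` or `"loss"`.
#' @param level a match level (`"all_atoms"`, `"heavy_atoms"`, `"mismatch"`).
#' @param table a [score_table()].
#' @return numeric score.
#' @examples
#' pair_score("parent", "all_atoms") # 6
#' pair_score("loss", "heavy_atoms") # 1.5
#' @export
pair_score <- function(object_class = c("parent", "fragment", "loss"),
                       level = c("all_atoms", "heavy_atoms", "mismatch"),
                       table = score_table()) {
  object_class <- match.arg(object_class)
  level <- match.arg(level)
  table[[object_class]][[level]]
}

# internal: tree tables -> parsed formulas + structure index
.tree_index <- function(nodes, edges, root_id) {
  ids <- nodes$id
  formulas <- lapply(nodes$formula, parse_formula)
  names(formulas) <- as.character(ids)
  parent <- stats::setNames(rep(NA_integer_, length(ids)), as.character(ids))
  for (e in seq_len(nrow(edges))) {
    parent[as.character(edges$child[e])] <- edges$parent[e]
  }
  children <- lapply(ids, function(i) edges$child[edges$parent == i])
  names(children) <- as.character(ids)
  # descendants in BFS order
  descendants <- lapply(ids, function(i) {
    out <- integer(0); queue <- children[[as.character(i)]]
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      out <- c(out, x)
      queue <- c(queue, children[[as.character(x)]])
    }
    out
  })
  names(descendants) <- as.character(ids)
  list(ids = ids, formulas = formulas, parent = parent,
       children = children, descendants = descendants, root = root_id)
}

#' Align a SMILES tree against a fragmentation tree and score it
#'
#' Finds the ancestor-preserving injective mapping (FT nodes onto SMILES-tree
#' nodes, root onto root, mapped set connected) that maximizes the summed
#' pair scores. The search is an exact branch-and-bound for compact trees
#' (SMILES tree of at most 40 nodes); for larger SMILES trees the candidate
#' images of a node are restricted to descendants with a positive marginal
#' score plus the immediate children of its parent's image (zero-gain deep
#' bridges are dropped), capped at the `max_images` best per node, and for
#' fragment trees wider than 12 nodes a greedy per-node matcher takes over.
#'
#' @param st a `smiles_tree` from [simulate_fragmentation()].
#' @param ft a `fragment_tree` from [max_weight_tree()].
#' @param table a [score_table()].
#' @param max_images candidate-image cap per FT node in the large-tree
#'   regime (default 16).
#' @return an `ft_alignment`: list with `mapping` (named integer vector,
#'   FT node id -> SMILES-tree node id, NA when unmapped), `raw`,
#'   `normalized`, `denominator`.
#' @export
align_and_score <- function(st, ft, table = score_table(), max_images = 16L) {
  stopifnot(inherits(st, "smiles_tree"), inherits(ft, "fragment_tree"))
  sti <- .tree_index(st$nodes, st$edges, st$nodes$id[1])
  fti <- .tree_index(ft$nodes, ft$edges, ft$root)
  n_ft <- length(fti$ids)
  denom <- table$parent[["all_atoms"]] +
    table$fragment[["all_atoms"]] * (n_ft - 1L) +
    table$loss[["all_atoms"]] * nrow(ft$edges)

  # integer element-count matrices (10 fixed element rows x nodes): all
  # match-level decisions in the search reduce to column arithmetic
  cnt_of <- function(formulas, ids) {
    m <- matrix(0L, 10L, length(ids),
                dimnames = list(.FT_ELEMENTS, as.character(ids)))
    for (j in seq_along(ids)) {
      f <- formulas[[as.character(ids[j])]]
      m[names(f), j] <- as.integer(f)
    }
    m
  }
  st_ids <- sti$ids
  ft_ids <- fti$ids
  stpos <- stats::setNames(seq_along(st_ids), as.character(st_ids))
  ftpos <- stats::setNames(seq_along(ft_ids), as.character(ft_ids))
  cnt_st <- cnt_of(sti$formulas, st_ids)
  cnt_ft <- cnt_of(fti$formulas, ft_ids)
  heavy <- setdiff(.FT_ELEMENTS, "H")

  # level codes against a target count vector, vectorized over ST columns:
  # 2 = all_atoms, 1 = heavy_atoms, 0 = mismatch
  level_vs <- function(target, cols) {
    dh <- colSums(abs(cnt_st[heavy, cols, drop = FALSE] - target[heavy]))
    dH <- abs(cnt_st["H", cols] - target["H"])
    ifelse(dh == 0, ifelse(dH == 0, 2L, 1L), 0L)
  }
  frag_sc <- c(table$fragment[["mismatch"]], table$fragment[["heavy_atoms"]],
               table$fragment[["all_atoms"]])
  loss_sc <- c(table$loss[["mismatch"]], table$loss[["heavy_atoms"]],
               table$loss[["all_atoms"]])

  root_lv <- level_vs(cnt_ft[, ftpos[[as.character(fti$root)]]],
                      stpos[[as.character(sti$root)]])
  root_score <- c(table$parent[["mismatch"]], table$parent[["heavy_atoms"]],
                  table$parent[["all_atoms"]])[root_lv + 1L]

  # FT preorder with subtree spans so "unmap node" skips its subtree
  pre <- integer(0)
  span_end <- integer(0)
  build <- function(v) {
    pre <<- c(pre, v)
    my_pos <- length(pre)
    for (c in fti$children[[as.character(v)]]) build(c)
    span_end[my_pos] <<- length(pre)
  }
  build(fti$root)

  loss_cnt <- matrix(0L, 10L, n_ft, dimnames = list(.FT_ELEMENTS, NULL))
  has_loss <- logical(n_ft)
  for (e in seq_len(nrow(ft$edges))) {
    f <- parse_formula(ft$edges$loss[e])
    j <- ftpos[[as.character(ft$edges$child[e])]]
    loss_cnt[names(f), j] <- as.integer(f)
    has_loss[j] <- TRUE
  }
  # fragment scores for every (FT node, ST node) pair, precomputed
  fs_mat <- matrix(0, n_ft, length(st_ids))
  for (vi in seq_len(n_ft)) {
    fs_mat[vi, ] <- frag_sc[level_vs(cnt_ft[, vi], seq_along(st_ids)) + 1L]
  }
  desc_pos <- lapply(seq_along(st_ids), function(i) {
    unname(stpos[as.character(sti$descendants[[as.character(st_ids[i])]])])
  })
  child_pos <- lapply(seq_along(st_ids), function(i) {
    unname(stpos[as.character(sti$children[[as.character(st_ids[i])]])])
  })

  # memoized marginal vectors over desc(mu) for FT node v given parent image
  marg_cache <- new.env(parent = emptyenv())
  marginals_for <- function(vi, mui) {
    key <- paste0(vi, "_", mui)
    hit <- marg_cache[[key]]
    if (!is.null(hit)) return(hit)
    cand <- desc_pos[[mui]]
    if (!length(cand)) {
      out <- list(cand = integer(0), marg = numeric(0))
    } else {
      fsc <- fs_mat[vi, cand]
      lsc <- if (has_loss[vi]) {
        # composed loss matches iff cnt(x) == cnt(mu) - loss(v); a negative
        # heavy-row target can never equal a count, which level_vs already
        # reports as mismatch (the H row is free to differ at heavy level)
        target <- cnt_st[, mui] - loss_cnt[, vi]
        lv <- level_vs(target, cand)
        # a zero composed loss (x identical to mu) cannot explain an edge
        lv[colSums(abs(cnt_st[, cand, drop = FALSE] - cnt_st[, mui])) == 0] <- 0L
        loss_sc[lv + 1L]
      } else rep(0, length(cand))
      out <- list(cand = cand, marg = fsc + lsc)
    }
    marg_cache[[key]] <- out
    out
  }

  res <- if (n_ft > 12L) {
    .align_greedy(pre, ftpos, fti, stpos, sti, marginals_for, root_score)
  } else {
    .align_exact(pre, span_end, ftpos, fti, stpos, sti, marginals_for,
                 root_score, table, child_pos,
                 small_st = length(st_ids) <= 40L, max_images = max_images)
  }
  mapping <- stats::setNames(st_ids[res$map_pos], as.character(ft_ids))
  structure(list(mapping = mapping, raw = res$score,
                 normalized = max(0, min(1, res$score / denom)),
                 denominator = denom),
            class = "ft_alignment")
}

.align_exact <- function(pre, span_end, ftpos, fti, stpos, sti, marginals_for,
                         root_score, table, child_pos, small_st, max_images) {
  per_node_max <- table$fragment[["all_atoms"]] + table$loss[["all_atoms"]]
  m <- length(pre)
  best_score <- -Inf
  best_map <- NULL
  map_pos <- rep(NA_integer_, m)           # indexed by FT position (id order)
  map_pos[ftpos[[as.character(pre[1])]]] <- stpos[[as.character(sti$root)]]
  used <- logical(length(sti$ids))
  used[stpos[[as.character(sti$root)]]] <- TRUE
  parent_pos <- vapply(pre, function(v) {
    p <- fti$parent[[as.character(v)]]
    if (is.na(p)) NA_integer_ else ftpos[[as.character(p)]]
  }, integer(1))

  dfs <- function(pos, acc) {
    if (pos > m) {
      if (acc > best_score) {
        best_score <<- acc
        best_map <<- map_pos
      }
      return()
    }
    if (acc + per_node_max * (m - pos + 1L) <= best_score) return()
    vi <- ftpos[[as.character(pre[pos])]]
    mui <- map_pos[parent_pos[pos]]
    if (!is.na(mui)) {
      mm <- marginals_for(vi, mui)
      cand <- mm$cand; marg <- mm$marg
      free <- !used[cand]
      cand <- cand[free]; marg <- marg[free]
      if (length(cand)) {
        if (!small_st) {
          keep <- marg > 0 | cand %in% child_pos[[mui]]
          cand <- cand[keep]; marg <- marg[keep]
          if (length(cand) > max_images) {
            o <- order(-marg, cand)[seq_len(max_images)]
            cand <- cand[o]; marg <- marg[o]
          }
        }
        for (j in order(-marg, cand)) {
          x <- cand[j]
          map_pos[vi] <<- x
          used[x] <<- TRUE
          dfs(pos + 1L, acc + marg[j])
          used[x] <<- FALSE
          map_pos[vi] <<- NA_integer_
        }
      }
    }
    # leave this FT node (and its whole subtree) unmapped
    dfs(span_end[pos] + 1L, acc)
  }
  dfs(2L, root_score)
  if (is.null(best_map)) {
    best_map <- map_pos
    best_score <- root_score
  }
  list(map_pos = best_map, score = best_score)
}

.align_greedy <- function(pre, ftpos, fti, stpos, sti, marginals_for,
                          root_score) {
  m <- length(pre)
  map_pos <- rep(NA_integer_, m)
  map_pos[ftpos[[as.character(pre[1])]]] <- stpos[[as.character(sti$root)]]
  used <- logical(length(sti$ids))
  used[stpos[[as.character(sti$root)]]] <- TRUE
  score <- root_score
  for (pos in seq_len(m)[-1]) {
    vi <- ftpos[[as.character(pre[pos])]]
    p <- fti$parent[[as.character(pre[pos])]]
    mui <- map_pos[ftpos[[as.character(p)]]]
    if (is.na(mui)) next
    mm <- marginals_for(vi, mui)
    free <- !used[mm$cand]
    cand <- mm$cand[free]; marg <- mm$marg[free]
    if (!length(cand)) next
    j <- order(-marg, cand)[1]
    if (marg[j] > 0) {
      map_pos[vi] <- cand[j]
      used[cand[j]] <- TRUE
      score <- score + marg[j]
    }
  }
  list(map_pos = map_pos, score = score)
}

#' Rank candidate structures against a fragmentation tree
#'
#' Each candidate SMILES is validated, canonicalized (duplicates collapse
#' with summed generation frequency), fragmented with
#' [simulate_fragmentation()], aligned to the FT and scored. Invalid SMILES
#' are dropped; their count is recorded in the result.
#'
#' @param candidates character vector of SMILES (possibly repeated, e.g.
#'   accumulated over inference runs), or a data.frame with columns
#'   `smiles` and `frequency`.
#' @param ft a `fragment_tree`.
#' @param cfg a [frag_config()].
#' @param table a [score_table()].
#' @return a `scored_candidates` object: data.frame with columns `rank`,
#'   `smiles`, `score`, `frequency`; attributes `n_invalid` and `details`
#'   (per-row list with the alignment and SMILES tree used).
#' @export
rank_candidates <- function(candidates, ft, cfg = frag_config(max_depth = 3L),
                            table = score_table()) {
  if (is.data.frame(candidates)) {
    smiles <- rep(candidates$smiles, candidates$frequency)
  } else {
    smiles <- candidates
  }
  stopifnot(length(smiles) >= 1L)
  canon <- vapply(smiles, function(s) {
    if (is_valid_smiles(s)) canonical_smiles(s) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  n_invalid <- sum(is.na(canon))
  canon <- canon[!is.na(canon)]
  if (!length(canon)) stop("no valid candidate SMILES")
  freq <- table(canon)
  uniq <- names(freq)
  details <- vector("list", length(uniq))
  scores <- numeric(length(uniq))
  for (i in seq_along(uniq)) {
    st <- simulate_fragmentation(uniq[i], cfg)
    al <- align_and_score(st, ft, table)
    details[[i]] <- list(smiles = uniq[i], st = st, alignment = al)
    scores[i] <- al$normalized
  }
  o <- order(-scores, -as.integer(freq), uniq)
  out <- data.frame(rank = seq_along(uniq), smiles = uniq[o],
                    score = scores[o], frequency = as.integer(freq)[o],
                    stringsAsFactors = FALSE)
  structure(out, n_invalid = n_invalid, details = details[o],
            class = c("scored_candidates", "data.frame"))
}

#' Annotate spectrum peaks from the best-scoring candidate
#'
#' For every FT node the mapped SMILES-tree fragment (structure + incoming
#' neutral loss + match level) is reported; unmapped FT peaks are marked
#' `"unannotated"`.
#'
#' @param ranked a `scored_candidates` object (or a single entry of its
#'   `details` attribute).
#' @param ft the `fragment_tree` the candidates were ranked against.
#' @param which row of the ranking to use (default 1, the best).
#' @return data.frame with columns `peak_mz`, `formula`, `fragment_smiles`,
#'   `loss`, `match`.
#' @export
annotate_peaks <- function(ranked, ft, which = 1L) {
  det <- if (inherits(ranked, "scored_candidates")) {
    attr(ranked, "details")[[which]]
  } else ranked
  al <- det$alignment
  st <- det$st
  if (all(is.na(al$mapping))) stop("alignment is empty")
  ft_losses <- stats::setNames(rep(NA_character_, nrow(ft$nodes)),
                               as.character(ft$nodes$id))
  for (e in seq_len(nrow(ft$edges))) {
    ft_losses[as.character(ft$edges$child[e])] <- ft$edges$loss[e]
  }
  rows <- lapply(seq_len(nrow(ft$nodes)), function(i) {
    id <- ft$nodes$id[i]
    stid <- al$mapping[[as.character(id)]]
    if (is.na(stid)) {
      data.frame(peak_mz = ft$nodes$mz[i], formula = ft$nodes$formula[i],
                 fragment_smiles = "unannotated", loss = ft_losses[[as.character(id)]],
                 match = "unannotated", stringsAsFactors = FALSE)
    } else {
      lvl <- match_level(parse_formula(ft$nodes$formula[i]),
                         parse_formula(st$nodes$formula[st$nodes$id == stid]))
      if (lvl == "mismatch") {
        # a formula-mismatching image is not a structural annotation
        data.frame(peak_mz = ft$nodes$mz[i], formula = ft$nodes$formula[i],
                   fragment_smiles = "unannotated",
                   loss = ft_losses[[as.character(id)]],
                   match = "unannotated", stringsAsFactors = FALSE)
      } else {
        data.frame(peak_mz = ft$nodes$mz[i], formula = ft$nodes$formula[i],
                   fragment_smiles = st$nodes$smiles[st$nodes$id == stid],
                   loss = ft_losses[[as.character(id)]],
                   match = lvl, stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  out[order(-out$peak_mz), , drop = FALSE]
}

#' Fingerprint similarity between two structures
#'
#' MACCS keys or Morgan-type circular fingerprints (ECFP4), computed through
#' the OpenBabel command-line tool, compared by Tanimoto or Dice
#' coefficient.
#'
#' @param a,b SMILES strings.
#' @param kind `"maccs"` or `"morgan"`.
#' @param metric `"tanimoto"` or `"dice"`.
#' @return similarity in [0, 1].
#' @export
fingerprint_similarity <- function(a, b, kind = c("maccs", "morgan"),
                                   metric = c("tanimoto", "dice")) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  if (!is_valid_smiles(a)) stop("unparseable SMILES: ", a)
  if (!is_valid_smiles(b)) stop("unparseable SMILES: ", b)
  fa <- .ob_fingerprint(a, kind)
  fb <- .ob_fingerprint(b, kind)
  popcount16 <- function(w) {
    sum(vapply(0:15, function(b) sum(bitwAnd(bitwShiftR(w, b), 1L)), numeric(1)))
  }
  inter <- popcount16(bitwAnd(fa, fb))
  na <- popcount16(fa)
  nb <- popcount16(fb)
  if (na + nb == 0) return(1)  # both featureless
  if (metric == "tanimoto") inter / (na + nb - inter) else 2 * inter / (na + nb)
}

# 16-bit words of an OpenBabel fingerprint
.ob_fingerprint <- function(smiles, kind) {
  fpname <- switch(kind, maccs = "MACCS", morgan = "ECFP4")
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  writeLines(smiles, tmp)
  out <- suppressWarnings(
    system2("obabel", c(tmp, "-ofpt", paste0("-xf", fpname)),
            stdout = TRUE, stderr = FALSE))
  hexwords <- unlist(regmatches(out, gregexpr("\\b[0-9a-f]{8}\\b", out)))
  if (!length(hexwords)) stop("fingerprint computation failed for ", smiles)
  hi <- strtoi(substr(hexwords, 1, 4), 16L)
  lo <- strtoi(substr(hexwords, 5, 8), 16L)
  as.integer(rbind(hi, lo))
}
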
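# Exhaustive alignment oracle: enumerates every ancestor-preserving injective
# mapping (root fixed to root, mapped set connected upward) without any
# bounding or candidate restriction, scoring each from scratch.
oracle_align_score <- function(st, ft, table = score_table()) {
  sti <- fragtree:::.tree_index(st$nodes, st$edges, st$nodes$id[1])
  fti <- fragtree:::.tree_index(ft$nodes, ft$edges, ft$root)
  neutral <- function(f) mol_formula(unclass(f), 0L)
  ft_pre <- integer(0)
  walk <- function(v) {
    ft_pre <<- c(ft_pre, v)
    for (c in fti$children[[as.character(v)]]) walk(c)
  }
  walk(fti$root)
  m <- length(ft_pre); k <- length(sti$ids)
  ftpos <- stats::setNames(seq_len(m), as.character(ft_pre))
  stids <- sti$ids
  stpos <- stats::setNames(seq_len(k), as.character(stids))
  ft_loss <- vector("list", m)
  for (e in seq_len(nrow(ft$edges))) {
    ft_loss[[ftpos[[as.character(ft$edges$child[e])]]]] <-
      parse_formula(ft$edges$loss[e])
  }
  # precomputed score matrices (pure lookups inside the enumeration)
  fs <- matrix(0, m, k)
  for (vi in 2:max(2L, m)) {
    if (vi > m) break
    for (xi in seq_len(k)) {
      fs[vi, xi] <- table$fragment[[match_level(
        fti$formulas[[as.character(ft_pre[vi])]],
        sti$formulas[[as.character(stids[xi])]])]]
    }
  }
  ls <- array(0, c(m, k, k))  # v, mu, x
  for (vi in seq_len(m)[-1]) {
    for (mui in seq_len(k)) {
      for (xi in stpos[as.character(sti$descendants[[as.character(stids[mui])]])]) {
        comp <- subtract_formula(
          neutral(sti$formulas[[as.character(stids[mui])]]),
          neutral(sti$formulas[[as.character(stids[xi])]]))
        if (length(comp)) {
          ls[vi, mui, xi] <- table$loss[[match_level(ft_loss[[vi]], comp)]]
        }
      }
    }
  }
  desc_pos <- lapply(seq_len(k), function(i) {
    unname(stpos[as.character(sti$descendants[[as.character(stids[i])]])])
  })
  ft_parent_pos <- c(NA_integer_,
                     vapply(ft_pre[-1], function(v) {
                       ftpos[[as.character(fti$parent[[as.character(v)]])]]
                     }, integer(1)))
  root_score <- table$parent[[match_level(
    fti$formulas[[as.character(fti$root)]],
    sti$formulas[[as.character(sti$root)]])]]

  best <- -Inf
  assign_pos <- rep(NA_integer_, m)
  assign_pos[1] <- 1L
  used <- logical(k); used[1] <- TRUE
  enum <- function(i, acc) {
    if (i > m) { if (acc > best) best <<- acc; return() }
    mu <- assign_pos[ft_parent_pos[i]]
    assign_pos[i] <<- NA_integer_
    enum(i + 1L, acc)
    if (!is.na(mu)) {
      for (xi in desc_pos[[mu]]) {
        if (used[xi]) next
        assign_pos[i] <<- xi; used[xi] <<- TRUE
        enum(i + 1L, acc + fs[i, xi] + ls[i, mu, xi])
        used[xi] <<- FALSE; assign_pos[i] <<- NA_integer_
      }
    }
  }
  if (m >= 2L) enum(2L, root_score) else best <- root_score
  best
}

# Construct a tree object (usable as smiles_tree or fragment_tree) directly
# from formula strings and parent pointers.
manual_tree <- function(formulas, parents, as = c("smiles", "fragment")) {
  as <- match.arg(as)
  n <- length(formulas)
  mz <- vapply(formulas, function(f) monoisotopic_mz(parse_formula(f)), numeric(1))
  losses <- character(0)
  e_parent <- integer(0); e_child <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(parents[i])) next
    loss <- subtract_formula(
      mol_formula(unclass(parse_formula(formulas[parents[i]])), 0L),
      mol_formula(unclass(parse_formula(formulas[i])), 0L))
    e_parent <- c(e_parent, parents[i]); e_child <- c(e_child, i)
    losses <- c(losses, format_formula(loss))
  }
  if (as == "smiles") {
    structure(list(
      nodes = data.frame(id = seq_len(n), smiles = paste0("frag", seq_len(n)),
                         formula = formulas, mz = mz,
                         depth = 0L, stringsAsFactors = FALSE),
      edges = data.frame(parent = e_parent, child = e_child, loss = losses,
                         rule = "manual", stringsAsFactors = FALSE)),
      class = "smiles_tree")
  } else {
    structure(list(
      nodes = data.frame(id = seq_len(n), peak_index = seq_len(n), mz = mz,
                         formula = formulas, weight = 0,
                         stringsAsFactors = FALSE),
      edges = data.frame(parent = e_parent, child = e_child, loss = losses,
                         weight = 0, stringsAsFactors = FALSE),
      score = 0, root = 1L), class = "fragment_tree")
  }
}

# Random small tree over sub-formulas of a shared parent pool, with
# occasional +/-H perturbations so heavy-atom matches arise.
random_align_tree <- function(n_nodes, as) {
  parent <- c(C = 10L, H = 12L, O = 4L)
  fmls <- character(n_nodes)
  parents <- rep(NA_integer_, n_nodes)
  fmls[1] <- format_formula(mol_formula(parent, 1L))
  cur <- list(parent)
  for (i in seq.int(2L, length.out = n_nodes - 1L)) {
    # only nodes with at least two atoms admit a proper sub-formula with C >= 1
    eligible <- which(vapply(cur, sum, integer(1)) >= 2L)
    p <- if (length(eligible) == 1L) eligible else sample(eligible, 1)
    base <- cur[[p]]
    repeat {
      keep <- vapply(names(base), function(e) sample(0:base[[e]], 1), integer(1))
      keep["C"] <- max(keep["C"], 1L)
      if (runif(1) < 0.3) keep["H"] <- keep[["H"]] + sample(c(-1L, 1L), 1)
      keep["H"] <- min(max(0L, keep[["H"]]), base[["H"]])
      if (sum(keep) < sum(base)) break
    }
    cur[[i]] <- keep
    fmls[i] <- format_formula(mol_formula(keep[keep > 0], 1L))
    parents[i] <- p
  }
  manual_tree(fmls, parents, as)
}
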
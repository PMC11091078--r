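#' @title Simulated fragmentation: rule registry and SMILES-tree engine
#'
#' @description
#' Collision-induced dissociation is simulated by applying a registry of
#' fragmentation rules to a candidate structure. Each rule couples a
#' SMARTS-subset substructure pattern (see [parse_smarts()]) with a
#' transformation: which matched bonds to cut, an optional re-formed bond
#' (rearrangements such as CO extrusion), how many hydrogens migrate to the
#' neutral loss, and which side retains the charge. Breadth-first expansion
#' of the protonated molecule yields a *SMILES tree*: nodes are fragments
#' (canonical SMILES + formula + m/z), edges carry the neutral-loss formula
#' and the rule that fired.
#'
#' Hydrogen bookkeeping: fragment subgraphs inherit their atoms' hydrogen
#' counts from the parent, so `loss = parent formula - child formula` holds
#' exactly on every edge; the displayed node SMILES is the heavy-atom
#' skeleton (valence-filled by OpenBabel) and the node formula is always the
#' authoritative composition.
#'
#' @name frag-rules
NULL

#' Construct a fragmentation rule
#'
#' @param id short unique name.
#' @param smarts SMARTS-subset pattern (compiled at construction; a
#'   non-compiling pattern is rejected naming the rule).
#' @param class one of `"cleavage"`, `"rearrangement"`, `"domain_specific"`.
#' @param family free-text mechanism family (e.g. `"C-C"`, `"rda"`); used
#'   for registry summaries.
#' @param cut list of length-2 integer vectors: pattern-atom index pairs
#'   whose bonds are cut.
#' @param rejoin optional pattern-atom index pair bonded (order 1) after
#'   cutting, for extrusion-type rearrangements.
#' @param h_to_loss integer vector of hydrogen-migration variants: each value
#'   is the number of hydrogens moving from the charged fragment to the
#'   neutral loss (+1 for water-type losses and proton-carried-by-neutral
#'   channels, -1 for McLafferty-type gamma-H transfer to the ion, 0 for
#'   radical-type retention). One child set is emitted per variant.
#' @param loss_side `"either"` (emit both charge assignments) or a pattern
#'   atom index whose component is always the neutral loss.
#' @param enabled logical.
#' @return a `frag_rule`.
#' @export
frag_rule <- function(id, smarts, class = c("cleavage", "rearrangement",
                                            "domain_specific"),
                      family = id, cut, rejoin = NULL, h_to_loss = 0L,
                      loss_side = "either", enabled = TRUE) {
  class <- match.arg(class)
  pattern <- tryCatch(parse_smarts(smarts), error = function(e) {
    stop("rule '", id, "': ", conditionMessage(e), call. = FALSE)
  })
  stopifnot(length(cut) >= 1L, all(vapply(cut, length, integer(1)) == 2L))
  structure(list(id = id, smarts = smarts, pattern = pattern, class = class,
                 family = family, cut = cut, rejoin = rejoin,
                 h_to_loss = as.integer(h_to_loss), loss_side = loss_side,
                 enabled = isTRUE(enabled)),
            class = "frag_rule")
}

#' The default fragmentation-rule registry
#'
#' Heterolytic single-bond cleavages of acyclic C-C, C-O and C-N bonds
#' (charge retained on either side, H retained in place, so e.g. methyl and
#' hydroxyl radical-type losses arise naturally); water and methanol neutral
#' losses with one-H migration; CO extrusion (including ring CO loss, via a
#' re-formed bond); the McLafferty gamma-H rearrangement; retro-Diels-Alder
#' ring cleavage of the flavone/flavonol C-ring (the canonical A-ring
#' m/z 153 channel) and of the saturated flavanol C-ring; and aryl-vinyl
#' cleavage for stilbenes.
#'
#' @return named list of [frag_rule()] objects.
#' @export
default_rules <- function() {
  rules <- list(
    frag_rule("cleave_cc", "[#6]-!@[#6]", "cleavage", family = "C-C",
              cut = list(c(1L, 2L))),
    frag_rule("cleave_co", "[#6]-!@[#8]", "cleavage", family = "C-O",
              cut = list(c(1L, 2L)), h_to_loss = c(0L, 1L)),
    frag_rule("cleave_cn", "[#6]-!@[#7]", "cleavage", family = "C-N",
              cut = list(c(1L, 2L))),
    frag_rule("loss_water", "[#6]-!@[OX2H1]", "rearrangement",
              family = "neutral_loss", cut = list(c(1L, 2L)),
              h_to_loss = 1L, loss_side = 2L),
    frag_rule("loss_methanol", "[#6]-!@[OX2]-!@[CH3]", "rearrangement",
              family = "neutral_loss", cut = list(c(1L, 2L)),
              h_to_loss = 1L, loss_side = 2L),
    frag_rule("loss_co", "[#6]-[CX3](=[OX1])-[#6]", "rearrangement",
              family = "neutral_loss", cut = list(c(1L, 2L), c(2L, 4L)),
              rejoin = c(1L, 4L), loss_side = 2L),
    frag_rule("mclafferty", "[OX1]=[CX3]-[#6]-!@[#6]-[#6;!H0]",
              "rearrangement", family = "mclafferty",
              cut = list(c(3L, 4L)), h_to_loss = -1L, loss_side = 4L),
    frag_rule("rda_flavone", "[#8;R]1~[#6;R]~[#6;R]~[#6;R](=[OX1])~[#6;R]~[#6;R]1",
              "domain_specific", family = "rda",
              cut = list(c(1L, 2L), c(3L, 4L))),
    frag_rule("rda_flavanol", "[#8;R]1~[#6;R]~[#6;R]~[CX4;R]~[#6;R]~[#6;R]1",
              "domain_specific", family = "rda",
              cut = list(c(1L, 2L), c(3L, 4L))),
    frag_rule("stilbene_vinyl", "[#6;R]-!@[#6]=[#6]-!@[#6;R]",
              "domain_specific", family = "stilbene",
              cut = list(c(1L, 2L)), h_to_loss = 1L)
  )
  stats::setNames(rules, vapply(rules, `[[`, character(1), "id"))
}

#' Load a fragmentation-rule registry
#'
#' `"default"` returns [default_rules()]. A YAML or JSON file may replace or
#' extend the registry: a list of records with fields `id`, `smarts`,
#' `class`, `cut` (list of pairs) and optionally `family`, `rejoin`,
#' `h_to_loss`, `loss_side`, `enabled`. User rules are appended to the
#' default set unless `replace: true` appears at the top level.
#'
#' @param path `"default"`, or a `.yaml`/`.yml`/`.json` file path.
#' @return named list of [frag_rule()] objects.
#' @export
load_rules <- function(path = "default") {
  if (identical(path, "default")) return(default_rules())
  if (!file.exists(path)) stop("rule file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  replace <- isTRUE(raw$replace)
  recs <- if (!is.null(raw$rules)) raw$rules else raw
  user <- lapply(recs, function(r) {
    if (is.null(r$id) || is.null(r$smarts)) stop("rule needs 'id' and 'smarts'")
    frag_rule(id = r$id, smarts = r$smarts,
              class = if (is.null(r$class)) "cleavage" else r$class,
              family = if (is.null(r$family)) r$id else r$family,
              cut = lapply(r$cut, as.integer),
              rejoin = if (is.null(r$rejoin)) NULL else as.integer(r$rejoin),
              h_to_loss = if (is.null(r$h_to_loss)) 0L else r$h_to_loss,
              loss_side = if (is.null(r$loss_side)) "either" else r$loss_side,
              enabled = if (is.null(r$enabled)) TRUE else r$enabled)
  })
  user <- stats::setNames(user, vapply(user, `[[`, character(1), "id"))
  if (replace) user else c(default_rules(), user)
}

#' Fragmentation engine configuration
#'
#' @param max_nodes SMILES-tree node cap (default 1500).
#' @param max_depth maximum fragmentation cascade depth (default 4).
#' @param rules rule registry (default [default_rules()]).
#' @return a `frag_config`.
#' @export
frag_config <- function(max_nodes = 1500L, max_depth = 4L,
                        rules = default_rules()) {
  stopifnot(max_nodes >= 1L, max_depth >= 1L)
  structure(list(max_nodes = as.integer(max_nodes),
                 max_depth = as.integer(max_depth), rules = rules),
            class = "frag_config")
}

# Apply one rule to an engine node (graph + formula). Returns list of
# children: list(graph, formula, loss, rule_id). Internal workhorse shared by
# apply_rule() and simulate_fragmentation().
.apply_rule_node <- function(graph, formula, rule) {
  if (!rule$enabled) return(list())
  matches <- match_smarts(graph, rule$pattern)
  out <- list()
  for (mp in matches) {
    bond_idx <- vapply(rule$cut, function(pr) {
      .bond_between(graph, mp[pr[1]], mp[pr[2]])
    }, integer(1))
    if (any(bond_idx == 0L)) next
    g2 <- .cut_bonds(graph, bond_idx)
    if (!is.null(rule$rejoin)) {
      a <- mp[rule$rejoin[1]]; b <- mp[rule$rejoin[2]]
      if (.bond_between(g2, a, b) == 0L) {
        g2$bonds <- rbind(g2$bonds,
                          data.frame(a1 = a, a2 = b, order = 1L, ring = FALSE))
      }
    }
    comps <- .graph_components(g2)
    if (length(comps) != 2L) next
    sides <- if (identical(rule$loss_side, "either")) {
      list(c(1L, 2L), c(2L, 1L))  # (ion comp, loss comp)
    } else {
      loss_atom <- mp[rule$loss_side]
      li <- which(vapply(comps, function(cp) loss_atom %in% cp, logical(1)))
      list(c(setdiff(1:2, li), li))
    }
    for (sd in sides) {
      ion_g <- .subgraph(g2, comps[[sd[1]]])
      loss_g <- .subgraph(g2, comps[[sd[2]]])
      loss_counts <- unclass(graph_formula(loss_g, extra_h = 0L, charge = 0L))
      for (h in rule$h_to_loss) {
      # hydrogens migrating ion -> loss (or back, if negative)
      lh <- (if ("H" %in% names(loss_counts)) loss_counts[["H"]] else 0L) + h
      if (lh < 0L) next
      lc <- loss_counts[setdiff(names(loss_counts), "H")]
      if (lh > 0L) lc <- c(lc, H = lh)
      loss_f <- mol_formula(lc, 0L)
      if (length(loss_f) == 0L) next
      child_f <- tryCatch({
        els <- union(names(formula), names(loss_f))
        p <- stats::setNames(integer(length(els)), els)
        p[names(formula)] <- as.integer(formula)
        l <- stats::setNames(integer(length(els)), els)
        l[names(loss_f)] <- as.integer(loss_f)
        d <- p - l
        if (any(d < 0L)) NULL else mol_formula(d[d > 0L], attr(formula, "charge"))
      }, error = function(e) NULL)
      if (is.null(child_f) || length(child_f) == 0L) next
      if (!"C" %in% names(child_f) && nrow(ion_g$atoms) == 0L) next
      out[[length(out) + 1L]] <- list(graph = ion_g, formula = child_f,
                                      loss = loss_f, rule_id = rule$id)
      }
    }
  }
  out
}

#' Apply a single rule to a molecule
#'
#' The molecule is treated as the protonated even-electron ion `[M+H]+`:
#' fragment formulas are `parent - loss` with the proton retained on the
#' charged fragment.
#'
#' @param smiles molecule SMILES.
#' @param rule a [frag_rule()].
#' @return list of records `list(fragment = canonical SMILES,
#'   formula = mol_formula, loss = mol_formula)`, deduplicated.
#' @examples
#' r <- default_rules()$cleave_co
#' apply_rule("CCO", r)
#' @export
apply_rule <- function(smiles, rule) {
  g <- parse_smiles(smiles)
  root_f <- add_formula(graph_formula(g), parse_formula("H"))
  root_f <- mol_formula(unclass(root_f), 1L)
  kids <- .apply_rule_node(g, root_f, rule)
  seen <- character(0)
  out <- list()
  for (k in kids) {
    smi <- graph_to_smiles(k$graph)
    key <- paste0(smi, "|", format_formula(k$formula))
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(fragment = smi, formula = k$formula,
                                    loss = k$loss)
  }
  out
}

#' Simulate fragmentation of a candidate structure
#'
#' Breadth-first expansion of the protonated molecule under the registry in
#' `cfg`. Children are deduplicated tree-wide by their (canonical SMILES,
#' formula) pair -- the displayed SMILES is the heavy-atom skeleton, so the
#' formula disambiguates e.g. hydroxyl-radical loss from water loss (first
#' occurrence, i.e. shallowest depth, wins); expansion stops when no rule
#' matches, at `max_depth`, or at the `max_nodes` cap. Rule order and match
#' order are deterministic, so truncation at the cap is reproducible.
#'
#' @param smiles candidate structure (SMILES).
#' @param cfg a [frag_config()].
#' @return a `smiles_tree`: list with `nodes` (data.frame: `id`, `smiles`,
#'   `formula`, `mz`, `depth`) and `edges` (data.frame: `parent`, `child`,
#'   `loss`, `rule`).
#' @examples
#' st <- simulate_fragmentation("O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12",
#'                              frag_config(max_depth = 2))
#' @export
simulate_fragmentation <- function(smiles, cfg = frag_config()) {
  stopifnot(inherits(cfg, "frag_config"))
  g <- parse_smiles(smiles)
  root_smi <- graph_to_smiles(g)
  if (is.na(root_smi)) root_smi <- smiles
  root_f <- mol_formula(unclass(add_formula(graph_formula(g),
                                            parse_formula("H"))), 1L)
  cap <- cfg$max_nodes
  n_smiles <- character(cap); n_formula <- character(cap)
  n_mz <- numeric(cap); n_depth <- integer(cap)
  e_parent <- integer(0); e_child <- integer(0)
  e_loss <- character(0); e_rule <- character(0)
  n_smiles[1] <- root_smi; n_formula[1] <- format_formula(root_f)
  n_mz[1] <- monoisotopic_mz(root_f); n_depth[1] <- 0L
  n_count <- 1L
  graphs <- vector("list", cap)
  formulas <- vector("list", cap)
  graphs[[1]] <- g
  formulas[[1]] <- root_f
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste0(root_smi, "|", n_formula[1]), 1L, envir = seen)
  queue <- 1L
  qpos <- 1L
  smi_cache <- new.env(hash = TRUE, parent = emptyenv())
  while (qpos <= length(queue)) {
    ni <- queue[qpos]; qpos <- qpos + 1L
    if (n_depth[ni] >= cfg$max_depth) next
    if (n_count >= cap) break
    kids <- list()
    for (rule in cfg$rules) {
      kids <- c(kids, .apply_rule_node(graphs[[ni]], formulas[[ni]], rule))
    }
    if (!length(kids)) next
    {
      # canonicalize all children of this node in one OpenBabel batch call,
      # memoizing by molblock (symmetric matches regenerate identical blocks)
      mbs <- vapply(kids, function(k) .ft_molblock(k$graph), character(1))
      need <- which(vapply(mbs, function(m) is.null(smi_cache[[m]]),
                           logical(1)))
      need <- need[!duplicated(mbs[need])]
      if (length(need)) {
        batch <- paste0(vapply(seq_along(need), function(j) {
          sub("^", sprintf("m%d", j), mbs[need[j]])
        }, character(1)), collapse = "")
        out <- .ob_convert("SDF", "CAN", batch)
        got <- if (is.na(out)) character(0) else {
          strsplit(out, "\n", fixed = TRUE)[[1]]
        }
        res <- rep(NA_character_, length(need))
        for (ln in got) {
          parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
          if (length(parts) >= 2L && grepl("^m[0-9]+$", parts[2])) {
            j <- as.integer(sub("m", "", parts[2]))
            if (!is.na(j) && j >= 1L && j <= length(need)) res[j] <- parts[1]
          }
        }
        for (j in seq_along(need)) smi_cache[[mbs[need[j]]]] <- res[j]
      }
    }
    for (ki in seq_along(kids)) {
      if (n_count >= cap) break
      k <- kids[[ki]]
      smi <- smi_cache[[mbs[ki]]]
      if (is.null(smi) || is.na(smi)) smi <- paste0("*", format_formula(k$formula))
      key <- paste0(smi, "|", format_formula(k$formula))
      if (!is.null(seen[[key]])) next
      id <- n_count + 1L
      n_smiles[id] <- smi
      n_formula[id] <- format_formula(k$formula)
      n_mz[id] <- monoisotopic_mz(k$formula)
      n_depth[id] <- n_depth[ni] + 1L
      e_parent <- c(e_parent, ni); e_child <- c(e_child, id)
      e_loss <- c(e_loss, format_formula(k$loss))
      e_rule <- c(e_rule, k$rule_id)
      graphs[[id]] <- k$graph
      formulas[[id]] <- k$formula
      seen[[key]] <- id
      queue <- c(queue, id)
      n_count <- id
    }
  }
  ix <- seq_len(n_count)
  nodes <- data.frame(id = ix, smiles = n_smiles[ix], formula = n_formula[ix],
                      mz = n_mz[ix], depth = n_depth[ix],
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = e_parent, child = e_child, loss = e_loss,
                      rule = e_rule, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, root_smiles = root_smi),
            class = "smiles_tree")
}

#' @export
print.smiles_tree <- function(x, ...) {
  cat("<smiles_tree> root ", x$nodes$smiles[1], " (",
      x$nodes$formula[1], ", m/z ", sprintf("%.3f", x$nodes$mz[1]), "), ",
      nrow(x$nodes), " nodes / ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Serialize a SMILES tree or fragment tree
#'
#' @param tree a `smiles_tree` or `fragment_tree`.
#' @param path output file; `.json` or `.dot` (Graphviz) inferred from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(nodes = tree$nodes, edges = tree$edges), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.dot$", path)) {
    lab <- if ("smiles" %in% names(tree$nodes)) {
      sprintf("%s\\n%s", tree$nodes$smiles, tree$nodes$formula)
    } else {
      sprintf("%.3f\\n%s", tree$nodes$mz, tree$nodes$formula)
    }
    lines <- c("digraph tree {",
               sprintf('  n%d [label="%s"];', tree$nodes$id, lab),
               if (nrow(tree$edges)) {
                 sprintf('  n%d -> n%d [label="-%s"];', tree$edges$parent,
                         tree$edges$child, tree$edges$loss)
               },
               "}")
    writeLines(lines, path)
  } else {
    stop("unsupported extension (use .json or .dot): ", path)
  }
  invisible(path)
}
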
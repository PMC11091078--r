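#' @title Molecular graphs for the fragmentation engine
#'
#' @description
#' The simulated-fragmentation engine needs direct access to atoms and bonds:
#' SMILES strings are parsed through OpenBabel (via \pkg{ChemmineOB}), which
#' handles aromaticity perception and kekulization, and the resulting V2000
#' molblock is loaded into a light `mol_graph` structure (atom table + bond
#' table). Implicit hydrogens are assigned by standard valences on the
#' kekulized graph. Graphs are written back through OpenBabel to obtain
#' canonical SMILES for node labels and deduplication.
#'
#' @name mol-graph
NULL

.FT_VALENCE <- c(C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                 F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L)

# OpenBabel string conversion with failure detection. OB signals parse failure
# by returning an empty/whitespace string (errors go to its own stderr).
.ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text),
                  error = function(e) "")
  if (is.null(out) || !nzchar(trimws(out))) return(NA_character_)
  out
}

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a SMILES string (aromatic or Kekule form).
#' @return A `mol_graph`: list with `atoms` (data.frame: `element`, `charge`,
#'   `nH`, `ring`) and `bonds` (data.frame: `a1`, `a2`, `order`, `ring`).
#' @examples
#' g <- parse_smiles("CCO")
#' g$atoms
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- .ob_convert("SMI", "SDF", smiles)
  if (is.na(sdf)) stop("cannot parse SMILES: ", smiles)
  g <- .parse_molblock(sdf)
  if (is.null(g)) stop("cannot parse SMILES: ", smiles)
  g
}

# Minimal V2000 reader for OpenBabel output (atoms, bonds, M CHG).
.parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts_i <- grep("V2000", lines)[1]
  if (is.na(counts_i)) return(NULL)
  na <- as.integer(substr(lines[counts_i], 1, 3))
  nb <- as.integer(substr(lines[counts_i], 4, 6))
  if (is.na(na) || na < 1L) return(NULL)
  at <- lines[counts_i + seq_len(na)]
  element <- trimws(substr(at, 32, 34))
  charge <- integer(na)
  if (nb > 0L) {
    bl <- lines[counts_i + na + seq_len(nb)]
    a1 <- as.integer(substr(bl, 1, 3))
    a2 <- as.integer(substr(bl, 4, 6))
    ord <- as.integer(substr(bl, 7, 9))
  } else {
    a1 <- a2 <- ord <- integer(0)
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    xs <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- xs[1]
    for (j in seq_len(k)) charge[xs[2 * j]] <- xs[2 * j + 1]
  }
  unknown <- setdiff(unique(element), c(.FT_ELEMENTS, "H"))
  if (length(unknown)) {
    stop("element(s) outside the supported alphabet: ",
         paste(unknown, collapse = ","))
  }
  # fold explicit hydrogens (rare in OB output) into heavy-atom nH
  atoms <- data.frame(element = element, charge = charge, nH = 0L,
                      ring = FALSE, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = a1, a2 = a2, order = ord,
                      ring = logical(length(a1)))
  g <- structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
  g <- .collapse_explicit_h(g)
  g <- .assign_implicit_h(g)
  .mark_rings(g)
}

.collapse_explicit_h <- function(g) {
  hs <- which(g$atoms$element == "H")
  if (!length(hs)) return(g)
  extra <- integer(nrow(g$atoms))
  drop_bond <- logical(nrow(g$bonds))
  for (h in hs) {
    bi <- which(g$bonds$a1 == h | g$bonds$a2 == h)
    for (b in bi) {
      other <- if (g$bonds$a1[b] == h) g$bonds$a2[b] else g$bonds$a1[b]
      extra[other] <- extra[other] + 1L
      drop_bond[b] <- TRUE
    }
  }
  keep <- setdiff(seq_len(nrow(g$atoms)), hs)
  remap <- match(seq_len(nrow(g$atoms)), keep)
  atoms <- g$atoms[keep, , drop = FALSE]
  atoms$nH <- atoms$nH + extra[keep]
  bonds <- g$bonds[!drop_bond, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  rownames(atoms) <- rownames(bonds) <- NULL
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

.assign_implicit_h <- function(g) {
  deg <- integer(nrow(g$atoms))
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      deg[g$bonds$a1[i]] <- deg[g$bonds$a1[i]] + g$bonds$order[i]
      deg[g$bonds$a2[i]] <- deg[g$bonds$a2[i]] + g$bonds$order[i]
    }
  }
  val <- .FT_VALENCE[g$atoms$element]
  z <- g$atoms$charge
  # standard charge adjustment: heteroatoms gain a slot when cationic,
  # lose one when anionic; carbon loses a slot either way
  adj <- ifelse(g$atoms$element %in% c("N", "O", "P", "S"), z, -abs(z))
  # explicit H already folded in (collapse step) count against the valence
  g$atoms$nH <- pmax(0L, as.integer(val + adj - deg))
  g
}

.mark_rings <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(g)
  for (i in seq_len(nb)) {
    g$bonds$ring[i] <- .still_connected(g, g$bonds$a1[i], g$bonds$a2[i],
                                        skip_bond = i)
  }
  ring_atoms <- unique(c(g$bonds$a1[g$bonds$ring], g$bonds$a2[g$bonds$ring]))
  g$atoms$ring <- seq_len(nrow(g$atoms)) %in% ring_atoms
  g
}

# BFS connectivity between u and v ignoring one bond.
.still_connected <- function(g, u, v, skip_bond = 0L) {
  n <- nrow(g$atoms)
  adj <- .adjacency_list(g, skip_bond)
  seen <- logical(n)
  queue <- u
  seen[u] <- TRUE
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (y in adj[[x]]) {
      if (y == v) return(TRUE)
      if (!seen[y]) { seen[y] <- TRUE; queue <- c(queue, y) }
    }
  }
  FALSE
}

.adjacency_list <- function(g, skip_bond = 0L) {
  n <- nrow(g$atoms)
  keep <- setdiff(seq_len(nrow(g$bonds)), skip_bond)
  ends <- c(g$bonds$a1[keep], g$bonds$a2[keep])
  other <- c(g$bonds$a2[keep], g$bonds$a1[keep])
  adj <- rep(list(integer(0)), n)
  if (length(ends)) {
    sp <- split(other, factor(ends, levels = seq_len(n)))
    adj <- unname(sp)
  }
  adj
}

#' Molecular formula of a graph
#'
#' Element counts over heavy atoms plus assigned hydrogens. `extra_h` adds
#' (or removes, if negative) hydrogens beyond the graph's own count —
#' used for protonation and H-transfer bookkeeping in the fragmentation
#' engine.
#'
#' @param g a `mol_graph`.
#' @param extra_h integer hydrogen adjustment (default 0).
#' @param charge charge of the resulting formula (default sum of atom charges).
#' @return A [mol_formula()].
#' @export
graph_formula <- function(g, extra_h = 0L, charge = NULL) {
  stopifnot(inherits(g, "mol_graph"))
  if (is.null(charge)) charge <- sum(g$atoms$charge)
  tab <- tabulate(match(g$atoms$element, .FT_ELEMENTS), nbins = 10L)
  counts <- stats::setNames(tab, .FT_ELEMENTS)[tab > 0L]
  h <- sum(g$atoms$nH) + as.integer(extra_h)
  if (h < 0L) stop("hydrogen count would be negative")
  if (h > 0L) counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h
  mol_formula(counts, as.integer(charge))
}

# connected components as a list of atom-index vectors (deterministic order)
.graph_components <- function(g) {
  n <- nrow(g$atoms)
  adj <- .adjacency_list(g)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- s
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      for (y in adj[[x]]) if (!seen[y]) {
        seen[y] <- TRUE; queue <- c(queue, y); comp <- c(comp, y)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# fast data.frame constructor for internal parallel vectors
.quickdf <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = .set_row_names(length(lst[[1]])))
}

# induced subgraph on atom indices (sorted), bonds reindexed
.subgraph <- function(g, atom_idx) {
  atom_idx <- sort(atom_idx)
  n <- nrow(g$atoms)
  remap <- match(seq_len(n), atom_idx)
  keep_b <- !is.na(remap[g$bonds$a1]) & !is.na(remap[g$bonds$a2])
  atoms <- .quickdf(list(element = g$atoms$element[atom_idx],
                         charge = g$atoms$charge[atom_idx],
                         nH = g$atoms$nH[atom_idx],
                         ring = g$atoms$ring[atom_idx]))
  bonds <- .quickdf(list(a1 = remap[g$bonds$a1[keep_b]],
                         a2 = remap[g$bonds$a2[keep_b]],
                         order = g$bonds$order[keep_b],
                         ring = g$bonds$ring[keep_b]))
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

# drop listed bonds (indices into g$bonds), keep all atoms
.cut_bonds <- function(g, bond_idx) {
  keep <- setdiff(seq_len(nrow(g$bonds)), bond_idx)
  bonds <- .quickdf(list(a1 = g$bonds$a1[keep], a2 = g$bonds$a2[keep],
                         order = g$bonds$order[keep],
                         ring = g$bonds$ring[keep]))
  structure(list(atoms = g$atoms, bonds = bonds), class = "mol_graph")
}

# V2000 molblock text for a graph (zero coordinates; OB only needs topology)
.ft_molblock <- function(g, title = "") {
  na <- nrow(g$atoms); nb <- nrow(g$bonds)
  hdr <- sprintf("%s\n fragtree\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 title, na, nb)
  at <- vapply(seq_len(na), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g$atoms$element[i])
  }, character(1))
  bl <- if (nb) vapply(seq_len(nb), function(i) {
    sprintf("%3d%3d%3d  0  0  0  0", g$bonds$a1[i], g$bonds$a2[i],
            g$bonds$order[i])
  }, character(1)) else character(0)
  chg <- which(g$atoms$charge != 0L)
  chg_lines <- if (length(chg)) {
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, g$atoms$charge[i]),
           character(1))
  } else character(0)
  paste(c(hdr, at, bl, chg_lines, "M  END", "$$$$", ""), collapse = "\n")
}

#' Canonical SMILES of a graph or SMILES string
#'
#' Canonicalization is delegated to OpenBabel. For a graph whose hydrogen
#' count was adjusted by the engine (H transfer, protonation) the SMILES
#' describes the heavy-atom skeleton with standard valence filling; the
#' authoritative composition of a tree node is always its formula.
#'
#' @param g a `mol_graph`.
#' @return canonical SMILES, or `NA` if conversion fails.
#' @export
graph_to_smiles <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  out <- .ob_convert("SDF", "CAN", .ft_molblock(g))
  if (is.na(out)) return(NA_character_)
  strsplit(trimws(out), "[ \t\n]")[[1]][1]
}

#' @rdname graph_to_smiles
#' @param smiles a SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  out <- .ob_convert("SMI", "CAN", smiles)
  if (is.na(out)) return(NA_character_)
  strsplit(trimws(out), "[ \t\n]")[[1]][1]
}

#' Does a string parse as a valid SMILES?
#' @param smiles candidate string.
#' @return logical scalar.
#' @export
is_valid_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    return(FALSE)
  }
  !is.na(.ob_convert("SMI", "CAN", smiles))
}

# all simple cycles of exactly length k containing >= 1 of the given atoms;
# returns list of atom-index vectors in ring order, deduplicated
.rings_of_size <- function(g, k) {
  adj <- .adjacency_list(g)
  found <- list()
  seen_keys <- character(0)
  n <- nrow(g$atoms)
  path <- integer(k)
  dfs <- function(start, current, depth) {
    for (y in adj[[current]]) {
      if (depth == k) {
        if (y == start) {
          key <- paste(sort(path), collapse = ",")
          if (!key %in% seen_keys) {
            seen_keys <<- c(seen_keys, key)
            found[[length(found) + 1L]] <<- path
          }
        }
      } else if (y > start && !y %in% path[seq_len(depth)]) {
        path[depth + 1L] <<- y
        dfs(start, y, depth + 1L)
      }
    }
  }
  for (s in seq_len(n)) {
    path[1] <- s
    dfs(s, s, 1L)
  }
  found
}

# bond index between two atoms, or 0
.bond_between <- function(g, a, b) {
  i <- which((g$bonds$a1 == a & g$bonds$a2 == b) |
               (g$bonds$a1 == b & g$bonds$a2 == a))
  if (length(i)) i[1] else 0L
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds),
      " bonds, formula ", format_formula(graph_formula(x)), "\n", sep = "")
  invisible(x)
}
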
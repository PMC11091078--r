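#' @title SMARTS-subset pattern matching
#'
#' @description
#' Fragmentation rules are declared as substructure patterns in a documented
#' subset of SMARTS, compiled here into a small pattern graph and matched by
#' backtracking subgraph search against the kekulized [parse_smiles()] graph.
#'
#' Supported syntax: bare element symbols (`C`, `Cl`, ... ; lowercase
#' aromatic symbols match the element *and* require ring membership, since
#' the engine's graphs are kekulized), bracket atoms with AND-combined
#' primitives `#n` (atomic number), element symbol, `Xn` (total connection
#' count incl. H), `Hn` (exact H count), `!H0` (at least one H), `R` / `!R` /
#' `R0` (ring membership), `+` / `-` (charge); bonds `-`, `=`, `#`, `~` (any),
#' `:` (any; aromatic systems are kekulized) with optional `@` / `!@`
#' ring-bond qualifiers (separators `;`/`&` allowed); branches in
#' parentheses; ring-closure digits. Unqualified bonds match any order.
#' Disjunctions (`,`), recursive SMARTS (`$(...)`) and stereo primitives are
#' outside the subset and rejected at compile time.
#'
#' @name smarts
NULL

.FT_ATOMIC_NUM <- c("6" = "C", "7" = "N", "8" = "O", "15" = "P", "16" = "S",
                    "9" = "F", "17" = "Cl", "35" = "Br", "53" = "I", "1" = "H")

#' Compile a SMARTS-subset pattern
#'
#' @param smarts pattern string (see [smarts]).
#' @return a `smarts_pattern` (atom constraint list + bond table).
#' @export
parse_smarts <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L, nzchar(smarts))
  s <- smarts
  i <- 1L
  n <- nchar(s)
  atoms <- list()
  bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                      order = integer(0), ring = logical(0))
  prev <- 0L           # previous atom index
  stack <- integer(0)  # branch stack
  ring_open <- list()  # digit -> c(atom, order, ring)
  pend_order <- NA_integer_  # NA = any
  pend_ring <- NA             # NA = any, TRUE = ring, FALSE = acyclic
  pend_set <- FALSE

  fail <- function(msg) stop("SMARTS parse error in '", smarts, "': ", msg)

  add_atom <- function(spec) {
    atoms[[length(atoms) + 1L]] <<- spec
    idx <- length(atoms)
    if (prev > 0L) {
      ord <- if (pend_set) pend_order else NA_integer_
      rng <- if (pend_set) pend_ring else NA
      bonds <<- rbind(bonds, data.frame(a1 = prev, a2 = idx,
                                        order = ord, ring = rng))
    }
    prev <<- idx
    pend_order <<- NA_integer_; pend_ring <<- NA; pend_set <<- FALSE
  }

  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) fail("unclosed bracket")
      add_atom(.parse_bracket(substr(s, i + 1L, i + j - 2L), fail))
      i <- i + j
    } else if (ch %in% c("-", "=", "#", "~", ":", "@", "!", ";", "&")) {
      if (ch == "-") { pend_order <- 1L; pend_set <- TRUE }
      else if (ch == "=") { pend_order <- 2L; pend_set <- TRUE }
      else if (ch == "#") { pend_order <- 3L; pend_set <- TRUE }
      else if (ch %in% c("~", ":")) { pend_order <- NA_integer_; pend_set <- TRUE }
      else if (ch == "@") { pend_ring <- TRUE; pend_set <- TRUE }
      else if (ch == "!") {
        if (substr(s, i + 1L, i + 1L) != "@") fail("'!' only supported as '!@'")
        pend_ring <- FALSE; pend_set <- TRUE; i <- i + 1L
      }
      # ';' and '&' are AND separators within a bond expression: no-op
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) fail("unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (prev == 0L) fail("ring closure before any atom")
      if (!is.null(ring_open[[ch]])) {
        op <- ring_open[[ch]]
        ord <- if (pend_set) pend_order else op$order
        rng <- if (pend_set) pend_ring else op$ring
        bonds <- rbind(bonds, data.frame(a1 = op$atom, a2 = prev,
                                         order = ord, ring = rng))
        ring_open[[ch]] <- NULL
      } else {
        ring_open[[ch]] <- list(atom = prev,
                                order = if (pend_set) pend_order else NA_integer_,
                                ring = if (pend_set) pend_ring else NA)
      }
      pend_order <- NA_integer_; pend_ring <- NA; pend_set <- FALSE
      i <- i + 1L
    } else {
      # bare atom symbol: two-letter first
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(list(element = two)); i <- i + 2L
      } else if (ch %in% c("C", "N", "O", "P", "S", "F", "I")) {
        add_atom(list(element = ch)); i <- i + 1L
      } else if (ch %in% c("c", "n", "o", "s", "p")) {
        add_atom(list(element = toupper(ch), ring = TRUE)); i <- i + 1L
      } else {
        fail(paste0("unsupported character '", ch, "'"))
      }
    }
  }
  if (length(stack)) fail("unbalanced '('")
  if (length(ring_open)) fail("unclosed ring bond")
  if (!length(atoms)) fail("no atoms")
  # every atom after the first must connect to an earlier atom
  if (length(atoms) > 1L) {
    for (a in 2:length(atoms)) {
      if (!any(bonds$a2 == a & bonds$a1 < a | bonds$a1 == a & bonds$a2 < a)) {
        fail("disconnected pattern")
      }
    }
  }
  structure(list(atoms = atoms, bonds = bonds, smarts = smarts),
            class = "smarts_pattern")
}

# bracket-atom primitive parser; AND semantics, ';'/'&' separators ignored
.parse_bracket <- function(body, fail) {
  spec <- list()
  i <- 1L; n <- nchar(body)
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch %in% c(";", "&")) { i <- i + 1L; next }
    if (ch == ",") fail("disjunction ',' not supported")
    if (ch == "$") fail("recursive SMARTS not supported")
    if (ch == "#") {
      m <- regmatches(body, regexpr("^#[0-9]+", substr(body, i, n)))
      num <- sub("#", "", regmatches(substr(body, i, n), regexpr("^#[0-9]+", substr(body, i, n))))
      el <- .FT_ATOMIC_NUM[num]
      if (is.na(el)) fail(paste0("unsupported atomic number #", num))
      spec$element <- unname(el)
      i <- i + nchar(num) + 1L
    } else if (ch == "!") {
      nxt <- substr(body, i + 1L, i + 2L)
      if (nxt == "H0") { spec$min_h <- 1L; i <- i + 3L }
      else if (substr(body, i + 1L, i + 1L) == "R") { spec$ring <- FALSE; i <- i + 2L }
      else fail("only '!H0' and '!R' negations supported in brackets")
    } else if (ch == "X") {
      d <- substr(body, i + 1L, i + 1L)
      if (!grepl("[0-9]", d)) fail("X needs a digit")
      spec$conn <- as.integer(d); i <- i + 2L
    } else if (ch == "H") {
      d <- substr(body, i + 1L, i + 1L)
      if (grepl("[0-9]", d)) { spec$exact_h <- as.integer(d); i <- i + 2L }
      else { spec$exact_h <- 1L; i <- i + 1L }
    } else if (ch == "R") {
      d <- substr(body, i + 1L, i + 1L)
      if (d == "0") { spec$ring <- FALSE; i <- i + 2L }
      else { spec$ring <- TRUE; i <- i + 1L }
    } else if (ch == "+") {
      spec$charge <- 1L; i <- i + 1L
    } else if (ch == "-") {
      spec$charge <- -1L; i <- i + 1L
    } else {
      two <- substr(body, i, i + 1L)
      if (two %in% c("Cl", "Br")) { spec$element <- two; i <- i + 2L }
      else if (ch %in% c("C", "N", "O", "P", "S", "F", "I")) {
        spec$element <- ch; i <- i + 1L
      } else if (ch %in% c("c", "n", "o", "s", "p")) {
        spec$element <- toupper(ch); spec$ring <- TRUE; i <- i + 1L
      } else {
        fail(paste0("unsupported bracket primitive '", ch, "'"))
      }
    }
  }
  if (is.null(spec$element)) fail("bracket atom without element")
  spec
}

#' Match a compiled pattern against a molecular graph
#'
#' @param g a `mol_graph`.
#' @param pattern a `smarts_pattern` (or SMARTS string, compiled on the fly).
#' @return list of integer vectors; element `k` of each vector is the
#'   molecule-atom index matched to pattern atom `k`. Symmetric patterns
#'   yield one mapping per automorphic image (downstream consumers
#'   deduplicate at the product level).
#' @export
match_smarts <- function(g, pattern) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  stopifnot(inherits(g, "mol_graph"), inherits(pattern, "smarts_pattern"))
  np <- length(pattern$atoms)
  nm <- nrow(g$atoms)
  if (nm < np) return(list())
  el <- g$atoms$element; ring_a <- g$atoms$ring
  nH <- g$atoms$nH; chg <- g$atoms$charge
  ba1 <- g$bonds$a1; ba2 <- g$bonds$a2
  bord <- g$bonds$order; bring <- g$bonds$ring
  nb <- length(ba1)
  heavy_deg <- integer(nm)
  bmat <- matrix(0L, nm, nm)  # bond index lookup
  if (nb) {
    for (b in seq_len(nb)) {
      heavy_deg[ba1[b]] <- heavy_deg[ba1[b]] + 1L
      heavy_deg[ba2[b]] <- heavy_deg[ba2[b]] + 1L
      bmat[ba1[b], ba2[b]] <- b
      bmat[ba2[b], ba1[b]] <- b
    }
  }
  # vectorized per-pattern-atom candidate sets
  cands <- lapply(pattern$atoms, function(spec) {
    ok <- rep(TRUE, nm)
    if (!is.null(spec$element)) ok <- ok & el == spec$element
    if (!is.null(spec$ring) && !is.na(spec$ring)) ok <- ok & ring_a == spec$ring
    if (!is.null(spec$exact_h)) ok <- ok & nH == spec$exact_h
    if (!is.null(spec$min_h)) ok <- ok & nH >= spec$min_h
    if (!is.null(spec$conn)) ok <- ok & heavy_deg + nH == spec$conn
    if (!is.null(spec$charge)) ok <- ok & chg == spec$charge
    which(ok)
  })
  if (any(vapply(cands, length, integer(1)) == 0L)) return(list())
  # pattern bonds incident to atom k from earlier atoms
  pa1 <- pattern$bonds$a1; pa2 <- pattern$bonds$a2
  back_bonds <- lapply(seq_len(np), function(k) {
    which((pa1 == k & pa2 < k) | (pa2 == k & pa1 < k))
  })
  pord <- pattern$bonds$order; pring <- pattern$bonds$ring
  results <- list()
  assign_vec <- integer(np)
  used <- logical(nm)

  try_atom <- function(k) {
    for (cand in cands[[k]]) {
      if (used[cand]) next
      ok <- TRUE
      for (pb in back_bonds[[k]]) {
        other_p <- if (pa1[pb] == k) pa2[pb] else pa1[pb]
        mb <- bmat[cand, assign_vec[other_p]]
        if (mb == 0L ||
            (!is.na(pord[pb]) && bord[mb] != pord[pb]) ||
            (!is.na(pring[pb]) && bring[mb] != pring[pb])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_vec[k] <<- cand
      used[cand] <<- TRUE
      if (k == np) {
        results[[length(results) + 1L]] <<- assign_vec
      } else {
        try_atom(k + 1L)
      }
      used[cand] <<- FALSE
    }
  }
  try_atom(1L)
  results
}
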
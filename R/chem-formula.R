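#' @title Molecular formulas over the ten-element alphabet
#'
#' @description
#' Unit-resolution ion-trap spectra of small molecules (< 500 Da) are
#' interpreted here over the ten elements C, H, O, N, P, S, Cl, Br, I and F.
#' A `mol_formula` is a named non-negative integer vector over (a subset of)
#' that alphabet with an integer `charge` attribute; all arithmetic,
#' monoisotopic masses and match-level classification used by the tree
#' builders live in this file.
#'
#' @name chem-formula
NULL

# Permitted elements, heaviest-first (used by the enumeration pruning order).
.FT_ELEMENTS <- c("C", "H", "O", "N", "P", "S", "Cl", "Br", "I", "F")

# Pinned NIST monoisotopic masses (Da) so results are bit-stable across hosts.
.FT_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  O  = 15.9949146196,
  N  = 14.0030740048,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  F  = 18.99840322
)

.FT_ELECTRON <- 0.000548579909
.FT_PROTON <- .FT_MASS[["H"]] - .FT_ELECTRON

#' Construct a molecular formula
#'
#' @param counts named integer vector of element counts (names from
#'   C, H, O, N, P, S, Cl, Br, I, F). Zeros are dropped.
#' @param charge integer charge, e.g. `+1` for a cation. Default 0.
#' @return An object of class `mol_formula`.
#' @examples
#' mol_formula(c(C = 15, H = 10, O = 5))
#' @export
mol_formula <- function(counts, charge = 0L) {
  if (length(counts) == 0) {
    counts <- integer(0)
  } else {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("element counts must be named")
    }
    bad <- setdiff(names(counts), .FT_ELEMENTS)
    if (length(bad)) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    }
    if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
      stop("element counts must be non-negative integers")
    }
    counts <- counts[counts > 0]
    storage.mode(counts) <- "integer"
    # canonical internal order: Hill (C, H, then alphabetical)
    counts <- counts[order(.FT_HILL_RANK[names(counts)])]
  }
  structure(counts, charge = as.integer(charge), class = "mol_formula")
}

.ft_hill_order <- function(els) {
  els[order(.FT_HILL_RANK[els])]
}

# Hill ranking: C, H, then alphabetical
.FT_HILL_RANK <- c(C = 1L, H = 2L, Br = 3L, Cl = 4L, F = 5L, I = 6L,
                   N = 7L, O = 8L, P = 9L, S = 10L)

#' Parse a Hill-notation formula string
#'
#' Accepts e.g. `"C15H10O5"`, `"H2O"`, or with a trailing charge sign
#' `"C16H13N2O+"` / `"CHO2-"`. Multipliers must be positive integers.
#'
#' @param text formula string.
#' @return A [mol_formula()].
#' @examples
#' parse_formula("C16H13N2O+")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (!nzchar(s)) stop("empty formula string")
  charge <- 0L
  # trailing charge: +, -, unicode minus, optionally preceded by a digit (e.g. "2+" rejected: |z|<=1 handled downstream)
  if (grepl("[+−-]$", s)) {
    charge <- if (grepl("\\+$", s)) 1L else -1L
    s <- sub("[+−-]$", "", s)
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  matched <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (!length(matched) || nchar(paste(matched, collapse = "")) != nchar(s)) {
    stop("cannot parse formula: ", text)
  }
  counts <- integer(0)
  for (tok in matched) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .FT_ELEMENTS) stop("unknown element symbol: ", el)
    if (n == 0L) stop("zero multiplier for element ", el, " in ", text)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  mol_formula(counts, charge)
}

#' Format a formula in canonical Hill notation
#'
#' @param f a [mol_formula()].
#' @param with_charge append a trailing `+`/`-` for charged species.
#' @return character scalar; `""` for the empty formula.
#' @export
format_formula <- function(f, with_charge = TRUE) {
  stopifnot(inherits(f, "mol_formula"))
  els <- .ft_hill_order(names(f))
  out <- paste(vapply(els, function(el) {
    n <- f[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
  z <- attr(f, "charge")
  if (with_charge && !is.null(z) && z != 0L) {
    out <- paste0(out, if (z > 0) strrep("+", z) else strrep("-", -z))
  }
  out
}

#' @export
format.mol_formula <- function(x, ...) format_formula(x)

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "  (", sprintf("%.4f", monoisotopic_mz(x)),
      if (attr(x, "charge") == 0L) " Da)" else " m/z)", "\n", sep = "")
  invisible(x)
}

#' Charge of a formula
#' @param f a [mol_formula()].
#' @return integer charge.
#' @export
formula_charge <- function(f) attr(f, "charge")

#' Monoisotopic mass / m/z of a formula
#'
#' For a neutral formula (charge 0) this is the neutral monoisotopic mass;
#' for an ion the electron mass is subtracted (cation) or added (anion), so
#' the value is the mass-to-charge ratio of the singly charged species.
#'
#' @param f a [mol_formula()].
#' @return mass (Da) or m/z for `|charge| == 1`.
#' @examples
#' monoisotopic_mz(parse_formula("C15H24N3O+")) # 262.191
#' @export
monoisotopic_mz <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  if (length(f) == 0L) stop("empty formula has no mass")
  z <- attr(f, "charge")
  if (abs(z) > 1L) stop("only singly charged ions are supported")
  m <- sum(.FT_MASS[names(f)] * as.numeric(f))
  m - z * .FT_ELECTRON
}

#' Nominal (integer) mass of a formula
#'
#' Unit-resolution instruments report integer m/z; the nominal mass is the
#' rounded monoisotopic m/z.
#'
#' @param f a [mol_formula()].
#' @return integer.
#' @export
nominal_mz <- function(f) as.integer(round(monoisotopic_mz(f)))

#' Formula arithmetic
#'
#' `add_formula()` sums element counts; `subtract_formula()` computes the
#' neutral loss `parent - child` and rejects any pair in which `child` is not
#' an elementwise sub-formula of `parent`. Charges are not propagated to a
#' loss: a neutral loss is neutral by construction.
#'
#' @param parent,child,a,b [mol_formula()] objects.
#' @return A [mol_formula()].
#' @examples
#' subtract_formula(parse_formula("C16H13O4+"), parse_formula("C15H10O4+"))
#' @export
subtract_formula <- function(parent, child) {
  stopifnot(inherits(parent, "mol_formula"), inherits(child, "mol_formula"))
  els <- union(names(parent), names(child))
  p <- stats::setNames(integer(length(els)), els)
  p[names(parent)] <- as.integer(parent)
  cc <- stats::setNames(integer(length(els)), els)
  cc[names(child)] <- as.integer(child)
  d <- p - cc
  if (any(d < 0L)) {
    stop("child is not a sub-formula of parent (negative ",
         paste(els[d < 0L], collapse = ","), ")")
  }
  mol_formula(d[d > 0L], 0L)
}

#' @rdname subtract_formula
#' @export
add_formula <- function(a, b) {
  stopifnot(inherits(a, "mol_formula"), inherits(b, "mol_formula"))
  els <- union(names(a), names(b))
  v <- stats::setNames(integer(length(els)), els)
  v[names(a)] <- v[names(a)] + as.integer(a)
  v[names(b)] <- v[names(b)] + as.integer(b)
  mol_formula(v, attr(a, "charge") + attr(b, "charge"))
}

#' Is `child` an elementwise sub-formula of `parent`?
#' @param parent,child [mol_formula()] objects.
#' @return logical scalar.
#' @export
is_subformula <- function(child, parent) {
  els <- names(child)
  all(as.integer(child) <=
        vapply(els, function(e) if (e %in% names(parent)) parent[[e]] else 0L,
               integer(1)))
}

#' Classify how two formulas match
#'
#' Three tiers, as used by the tree-alignment score: `"all_atoms"` (every
#' element count equal), `"heavy_atoms"` (all non-hydrogen counts equal but H
#' differs — the signature of hydrogen rearrangement at unit resolution), or
#' `"mismatch"`. Charge is compared only when both formulas declare one;
#' ionization convention keeps protonated/neutral pairs comparable.
#'
#' @param a,b [mol_formula()] objects.
#' @return one of `"all_atoms"`, `"heavy_atoms"`, `"mismatch"`.
#' @examples
#' match_level(parse_formula("C16H13N2O"), parse_formula("C16H15N2O"))
#' @export
match_level <- function(a, b) {
  stopifnot(inherits(a, "mol_formula"), inherits(b, "mol_formula"))
  za <- attr(a, "charge"); zb <- attr(b, "charge")
  if (za != 0L && zb != 0L && za != zb) return("mismatch")
  els <- union(names(a), names(b))
  va <- stats::setNames(integer(length(els)), els); va[names(a)] <- as.integer(a)
  vb <- stats::setNames(integer(length(els)), els); vb[names(b)] <- as.integer(b)
  heavy <- setdiff(els, "H")
  if (!all(va[heavy] == vb[heavy])) return("mismatch")
  ha <- if ("H" %in% els) va[["H"]] else 0L
  hb <- if ("H" %in% els) vb[["H"]] else 0L
  if (ha == hb) "all_atoms" else "heavy_atoms"
}

#' Ring-plus-double-bond equivalents
#'
#' `RDBE = C + 1 - (H + halogens)/2 + N/2` in the default valence convention
#' (O, S divalent; P trivalent treated like N when `p_as_n = TRUE`). Used by
#' the formula filter to reject chemically impossible candidates
#' (negative RDBE).
#'
#' @param f a [mol_formula()].
#' @param p_as_n count phosphorus like nitrogen (trivalent). Default TRUE.
#' @return half-integer RDBE value.
#' @examples
#' rdbe(parse_formula("C15H10O5")) # 11
#' @export
rdbe <- function(f, p_as_n = TRUE) {
  g <- function(e) if (e %in% names(f)) f[[e]] else 0L
  hal <- g("F") + g("Cl") + g("Br") + g("I")
  n3 <- g("N") + if (p_as_n) g("P") else 0L
  g("C") + 1 - (g("H") + hal) / 2 + n3 / 2
}
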
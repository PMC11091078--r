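#' @title Molecular-formula enumeration under element bounds
#'
#' @description
#' Unit-resolution spectra admit many formulas per peak; candidates are found
#' by exact branch-and-bound search over element counts within per-element
#' bounds and a mass tolerance, then passed through configurable chemical
#' filters (RDBE, H/C ratio). The search is exhaustive: it returns exactly
#' the formulas whose monoisotopic m/z lies within the tolerance window.
#'
#' @name formula-enum
NULL

#' Element bounds for formula enumeration
#'
#' @param ... per-element maximum counts, e.g. `C = 20, H = 40, O = 8`.
#'   Elements not mentioned are excluded (max 0).
#' @param max_mass global neutral-mass cap in Da (default 500, the training-set
#'   cap for the small-molecule regime targeted here).
#' @param tolerance mass tolerance in Da. Default 0.5, matched to
#'   unit-resolution ion-trap peaks; use ~5e-3 (or ppm-scale) bounds for
#'   high-resolution cross-checks.
#' @return An `element_bounds` object.
#' @examples
#' element_bounds(C = 16, H = 20, O = 6, tolerance = 0.5)
#' @export
element_bounds <- function(..., max_mass = 500, tolerance = 0.5) {
  mx <- c(...)
  if (length(mx)) {
    bad <- setdiff(names(mx), .FT_ELEMENTS)
    if (length(bad)) stop("unknown element(s) in bounds: ", paste(bad, collapse = ","))
    if (any(mx < 0)) stop("bounds must be >= 0")
  }
  stopifnot(tolerance > 0, max_mass > 0)
  structure(list(max = mx, max_mass = max_mass, tolerance = tolerance),
            class = "element_bounds")
}

#' Enumerate candidate formulas for an observed m/z
#'
#' Exact depth-first search over elements in decreasing-mass order with
#' residual-mass pruning: a partial assignment is abandoned as soon as the
#' remaining elements cannot reach the target window. For a charged target
#' the electron mass is folded in before the neutral-composition search, so
#' returned formulas carry `charge` and their [monoisotopic_mz()] matches the
#' target directly.
#'
#' @param target_mz observed m/z (Da), > 0.
#' @param bounds an [element_bounds()].
#' @param charge assumed charge of the ion (default `+1`; use 0 for a neutral
#'   mass query).
#' @return list of [mol_formula()] sorted by absolute mass error, ties broken
#'   by the canonical formula string.
#' @examples
#' enumerate_formulas(18.0106, element_bounds(C = 2, H = 6, N = 2, O = 2,
#'                    tolerance = 0.005), charge = 0)
#' @export
enumerate_formulas <- function(target_mz, bounds, charge = 1L) {
  stopifnot(inherits(bounds, "element_bounds"), target_mz > 0)
  charge <- as.integer(charge)
  if (abs(charge) > 1L) stop("only |charge| <= 1 supported")
  # neutral-composition target: undo the electron correction
  neutral_target <- target_mz + charge * .FT_ELECTRON
  tol <- bounds$tolerance
  if (neutral_target - tol > bounds$max_mass) return(list())

  els <- names(bounds$max)[bounds$max > 0]
  if (!length(els)) return(list())
  els <- els[order(.FT_MASS[els], decreasing = TRUE)]
  masses <- .FT_MASS[els]
  maxima <- as.integer(bounds$max[els])
  n <- length(els)
  found_counts <- list()
  counts <- integer(n)

  recurse <- function(i, remaining) {
    if (remaining < -tol) return()
    if (i > n) {
      if (abs(remaining) <= tol) found_counts[[length(found_counts) + 1L]] <<- counts
      return()
    }
    # even taking max of everything left cannot reach the window?
    ub <- sum(masses[i:n] * maxima[i:n])
    if (remaining - ub > tol) return()
    k_hi <- min(maxima[i], floor((remaining + tol) / masses[i]))
    if (k_hi < 0L) k_hi <- 0L
    for (k in 0:k_hi) {
      counts[i] <<- k
      recurse(i + 1L, remaining - k * masses[i])
    }
    counts[i] <<- 0L
  }
  recurse(1L, neutral_target)

  if (!length(found_counts)) return(list())
  out <- lapply(found_counts, function(cv) {
    mol_formula(stats::setNames(cv, els)[cv > 0L], charge)
  })
  out <- Filter(function(f) length(f) > 0L, out)
  if (!length(out)) return(list())
  err <- vapply(out, function(f) abs(monoisotopic_mz(f) - target_mz), numeric(1))
  key <- vapply(out, format_formula, character(1))
  out[order(err, key)]
}

#' Chemical plausibility filter for candidate formulas
#'
#' Removes formulas with negative RDBE, non-half-integer RDBE (impossible
#' under standard valences), or an H/C ratio outside `hc_range` (only applied
#' when the formula contains carbon). Each rule can be toggled; order of the
#' survivors is preserved.
#'
#' @param candidates list of [mol_formula()].
#' @param min_rdbe minimum RDBE (default 0); `NULL` disables the check.
#' @param hc_range numeric length-2 H/C ratio window (default `c(0.1, 3.5)`);
#'   `NULL` disables.
#' @param bounds optional [element_bounds()] re-applied as a hard cap.
#' @return filtered list, order preserved.
#' @export
filter_formulas <- function(candidates, min_rdbe = 0, hc_range = c(0.1, 3.5),
                            bounds = NULL) {
  keep <- vapply(candidates, function(f) {
    r <- rdbe(f)
    if (!is.null(min_rdbe) && r < min_rdbe) return(FALSE)
    if (abs(r * 2 - round(r * 2)) > 1e-9) return(FALSE)
    if (!is.null(hc_range) && "C" %in% names(f)) {
      hc <- (if ("H" %in% names(f)) f[["H"]] else 0L) / f[["C"]]
      # allow pure-carbon losses (H = 0) such as C, C2
      if (hc > 0 && (hc < hc_range[1] || hc > hc_range[2])) return(FALSE)
    }
    if (!is.null(bounds)) {
      over <- vapply(names(f), function(e) {
        cap <- if (e %in% names(bounds$max)) bounds$max[[e]] else 0
        f[[e]] > cap
      }, logical(1))
      if (any(over)) return(FALSE)
      if (monoisotopic_mz(mol_formula(unclass(f), 0L)) > bounds$max_mass) return(FALSE)
    }
    TRUE
  }, logical(1))
  candidates[keep]
}

#' Sub-formulas of a parent matching a target m/z
#'
#' Equivalent to [enumerate_formulas()] with per-element bounds set to the
#' parent's counts: every fragment-peak formula must be an elementwise
#' sub-formula of its precursor.
#'
#' @param parent a non-empty [mol_formula()] (the precursor composition,
#'   including any ionizing proton).
#' @param target_mz observed fragment m/z.
#' @param tolerance Da window (default 0.5).
#' @param charge fragment charge (default the parent's charge, or +1).
#' @return list of [mol_formula()] sorted by absolute mass error.
#' @export
sub_formulas_of <- function(parent, target_mz, tolerance = 0.5, charge = NULL) {
  stopifnot(inherits(parent, "mol_formula"), length(parent) > 0L)
  if (is.null(charge)) {
    charge <- attr(parent, "charge")
    if (charge == 0L) charge <- 1L
  }
  b <- element_bounds(max_mass = Inf, tolerance = tolerance)
  b$max <- stats::setNames(as.integer(parent), names(parent))
  b$max_mass <- monoisotopic_mz(mol_formula(unclass(parent), 0L)) + 1
  enumerate_formulas(target_mz, b, charge = charge)
}
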
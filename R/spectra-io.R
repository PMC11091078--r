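#' @title Peak-list input, peak selection, and integer m/z encoding
#'
#' @description
#' Spectra enter the pipeline as centroided peak lists (MGF, mzML, or
#' two-column CSV). Preprocessing keeps the highest-intensity peaks (at most
#' 100), optionally merges clusters of adjacent points into centroids, and
#' encodes the retained m/z values for the sequence model: each m/z is
#' truncated (not rounded) to two decimals and scaled by 100 to an integer
#' token, preserving 0.01 Da resolution.
#'
#' @name spectra-io
NULL

#' Construct a spectrum
#'
#' @param mz numeric vector of m/z values (Da).
#' @param intensity numeric vector of intensities (arbitrary units, >= 0).
#' @param precursor_mz precursor m/z or `NULL`.
#' @param ms_level MS level (integer >= 1, default 2).
#' @return An `ms_spectrum`: list with `peaks` (data.frame `mz`, `intensity`,
#'   sorted ascending by m/z), `precursor_mz`, `ms_level`.
#' @export
ms_spectrum <- function(mz, intensity, precursor_mz = NULL, ms_level = 2L) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1L)
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("peaks must be finite (no NaN/NA)")
  }
  if (any(mz <= 0)) stop("m/z values must be positive")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  structure(list(peaks = data.frame(mz = as.numeric(mz[o]),
                                    intensity = as.numeric(intensity[o])),
                 precursor_mz = if (is.null(precursor_mz)) NULL
                                else as.numeric(precursor_mz),
                 ms_level = as.integer(ms_level)),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<ms_spectrum> MS", x$ms_level, ", ", nrow(x$peaks), " peaks",
      if (!is.null(x$precursor_mz)) {
        paste0(", precursor m/z ", sprintf("%.4f", x$precursor_mz))
      }, "\n", sep = "")
  invisible(x)
}

#' Read a spectrum from MGF, mzML or CSV
#'
#' MGF: the first `BEGIN IONS`/`END IONS` block (or the `scan`-th);
#' `PEPMASS` supplies the precursor. CSV: two columns `mz,intensity`, with
#' an optional header. mzML: read through \pkg{mzR}; `scan` selects the
#' spectrum (default: the first MS2 scan, or the first scan if none).
#'
#' @param path input file.
#' @param format `"auto"` (by extension) or one of `"mgf"`, `"mzml"`, `"csv"`.
#' @param scan 1-based spectrum index within the file (see above).
#' @return An [ms_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "mgf", "mzml", "csv"),
                          scan = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mgf = "mgf", mzml = "mzml", csv = "csv", txt = "csv",
                     stop("cannot infer format from extension: ", path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         mgf = .read_mgf(path, scan %||% 1L),
         csv = .read_csv_peaks(path),
         mzml = .read_mzml(path, scan))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_mgf <- function(path, scan = 1L) {
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^\\s*BEGIN IONS\\s*$", lines)
  ends <- grep("^\\s*END IONS\\s*$", lines)
  if (!length(begins) || length(begins) != length(ends)) {
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path)
  }
  if (scan > length(begins)) stop("MGF has only ", length(begins), " spectra")
  block <- lines[(begins[scan] + 1L):(ends[scan] - 1L)]
  prec <- NULL
  charge_line <- grep("^PEPMASS=", block, value = TRUE)
  if (length(charge_line)) {
    prec <- as.numeric(strsplit(sub("^PEPMASS=", "", charge_line[1]),
                                "[ \t]")[[1]][1])
  }
  peak_lines <- block[grepl("^\\s*[0-9]", block)]
  if (!length(peak_lines)) {
    stop("empty peak list in MGF spectrum ", scan, " of ", path)
  }
  parts <- strsplit(trimws(peak_lines), "[ \t]+")
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, function(p) {
    if (length(p) >= 2L) p[2] else "1"
  }, character(1))))
  if (any(is.na(mz)) || any(is.na(it))) {
    bad <- which(is.na(mz) | is.na(it))[1]
    stop("malformed MGF peak line ", begins[scan] + which(grepl("^\\s*[0-9]", block))[bad],
         " in ", path)
  }
  ms_spectrum(mz, it, precursor_mz = prec, ms_level = 2L)
}

.read_csv_peaks <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = header,
                        col.names = c("mz", "intensity"))
  if (!nrow(df)) stop("empty peak list: ", path)
  if (any(is.na(df$mz)) || any(is.na(df$intensity))) {
    stop("malformed CSV peak row ", which(is.na(df$mz) | is.na(df$intensity))[1] +
           as.integer(header), " in ", path)
  }
  ms_spectrum(df$mz, df$intensity, ms_level = 2L)
}

.read_mzml <- function(path, scan = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (!nrow(hdr)) stop("no spectra in ", path)
  if (is.null(scan)) {
    ms2 <- which(hdr$msLevel >= 2L)
    scan <- if (length(ms2)) ms2[1] else 1L
  }
  if (scan > nrow(hdr)) stop("mzML has only ", nrow(hdr), " spectra")
  pk <- mzR::peaks(handle, scan)
  if (!nrow(pk)) stop("empty peak list in scan ", scan, " of ", path)
  prec <- hdr$precursorMZ[scan]
  if (!is.na(prec) && prec == 0) prec <- NA_real_
  ms_spectrum(pk[, 1], pk[, 2],
              precursor_mz = if (is.na(prec)) NULL else prec,
              ms_level = hdr$msLevel[scan])
}

#' Keep the highest-intensity peaks
#'
#' Retains the `min(k, 100, n)` most intense peaks (the model input is
#' hard-capped at 100 peaks), breaking intensity ties in favour of the lower
#' m/z so the selection is invariant to input order. Peaks are re-sorted by
#' m/z.
#'
#' @param s an [ms_spectrum()].
#' @param k number of peaks to keep (>= 1).
#' @return An [ms_spectrum()].
#' @export
select_top_peaks <- function(s, k = 100L) {
  stopifnot(inherits(s, "ms_spectrum"), k >= 1L)
  k <- min(as.integer(k), 100L, nrow(s$peaks))
  o <- order(-s$peaks$intensity, s$peaks$mz)
  keep <- sort(o[seq_len(k)])
  ms_spectrum(s$peaks$mz[keep], s$peaks$intensity[keep],
              precursor_mz = s$precursor_mz, ms_level = s$ms_level)
}

#' Merge a cluster of adjacent peak points into one centroid
#'
#' Takes the peak at `center_mz` and its `window` nearest points on each
#' side, returning the intensity-weighted mean m/z and the summed intensity.
#' Models the acquisition protocol in which each fragmentation peak and a
#' few neighbouring points are read together from a unit-resolution trace.
#'
#' @param s an [ms_spectrum()].
#' @param center_mz m/z of the central point (must be present in `s`).
#' @param window number of flanking points on each side (>= 0).
#' @return list with `mz` (centroid) and `intensity` (sum).
#' @export
merge_peak_cluster <- function(s, center_mz, window = 0L) {
  stopifnot(inherits(s, "ms_spectrum"), window >= 0L)
  ci <- which(abs(s$peaks$mz - center_mz) < 1e-6)
  if (!length(ci)) stop("center m/z ", center_mz, " not found in spectrum")
  ci <- ci[1]
  lo <- max(1L, ci - as.integer(window))
  hi <- min(nrow(s$peaks), ci + as.integer(window))
  mzs <- s$peaks$mz[lo:hi]
  its <- s$peaks$intensity[lo:hi]
  if (sum(its) == 0) return(list(mz = mean(mzs), intensity = 0))
  list(mz = sum(mzs * its) / sum(its), intensity = sum(its))
}

#' Average repeat scans
#'
#' A deliberately simple replacement for full spectral deconvolution: peaks
#' are aligned greedily across scans within `tol` and aligned groups are
#' averaged (mean m/z, mean intensity). Adequate for the synthetic and
#' unit-resolution inputs this package targets.
#'
#' @param spectra list of [ms_spectrum()] from repeat measurements.
#' @param tol alignment tolerance in Da (default 0.3).
#' @return An [ms_spectrum()].
#' @export
average_spectra <- function(spectra, tol = 0.3) {
  stopifnot(length(spectra) >= 1L)
  if (length(spectra) == 1L) return(spectra[[1]])
  all_mz <- unlist(lapply(spectra, function(s) s$peaks$mz))
  all_it <- unlist(lapply(spectra, function(s) s$peaks$intensity))
  o <- order(all_mz)
  all_mz <- all_mz[o]; all_it <- all_it[o]
  group <- cumsum(c(TRUE, diff(all_mz) > tol))
  mz <- tapply(all_mz, group, mean)
  it <- tapply(all_it, group, sum) / length(spectra)
  prec <- spectra[[1]]$precursor_mz
  ms_spectrum(as.numeric(mz), as.numeric(it), precursor_mz = prec,
              ms_level = spectra[[1]]$ms_level)
}

#' Write a spectrum as MGF
#'
#' @param s an [ms_spectrum()].
#' @param path output path.
#' @param title optional TITLE line.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(s, path, title = NULL) {
  stopifnot(inherits(s, "ms_spectrum"))
  lines <- c("BEGIN IONS",
             if (!is.null(title)) paste0("TITLE=", title),
             if (!is.null(s$precursor_mz)) {
               sprintf("PEPMASS=%.6f", s$precursor_mz)
             },
             sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity),
             "END IONS")
  writeLines(lines, path)
  invisible(path)
}

#' Integer encoding of a spectrum for the sequence model
#'
#' Intensities are dropped; each retained m/z is truncated (floored, not
#' rounded) to two decimal places and multiplied by 100, giving one
#' non-negative integer token per peak at 0.01 Da resolution. At most 100
#' peaks are encoded (the most intense are kept if more are present); peak
#' order (ascending m/z) is preserved.
#'
#' @param s an [ms_spectrum()].
#' @return integer vector of class `encoded_spectrum`, length <= 100.
#' @examples
#' encode_spectrum(ms_spectrum(c(271.068, 153.999), c(100, 10)))
#' @export
encode_spectrum <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"), nrow(s$peaks) >= 1L)
  if (nrow(s$peaks) > 100L) s <- select_top_peaks(s, 100L)
  mz <- s$peaks$mz
  if (any(mz < 0)) stop("negative m/z cannot be encoded")
  # floor at 2 dp then scale; epsilon guards against 123.45 -> 12344.9999
  tokens <- as.integer(floor(mz * 100 + 1e-6))
  structure(tokens, class = "encoded_spectrum")
}
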
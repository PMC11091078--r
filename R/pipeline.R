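#' @title End-to-end annotation pipeline
#'
#' @description
#' The full workflow in one call: read and preprocess the spectrum, build
#' the maximum-weight fragmentation tree, obtain candidate structures
#' (from a SMILES file/vector or from a trained sequence model), simulate
#' each candidate's fragmentation, rank by tree-alignment similarity, and
#' annotate the fragment peaks of the best explanation. Identical inputs and
#' seed give an identical report.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param tolerance m/z matching tolerance in Da (default 0.5, unit
#'   resolution).
#' @param top_k fragment peaks retained (default 6, the acquisition
#'   protocol of the miniaturized ion trap this pipeline targets).
#' @param n_runs sequence-model decode runs when a model supplies the
#'   candidates (default 100).
#' @param frag a [frag_config()] for candidate fragmentation (depth 3 by
#'   default).
#' @param bounds an [element_bounds()] for precursor formula enumeration
#'   when no formula is given.
#' @param table a [score_table()].
#' @param model an [edge_weight_model()].
#' @param seed integer seed for all stochastic steps.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(tolerance = 0.5, top_k = 6L, n_runs = 100L,
                            frag = frag_config(max_depth = 3L),
                            bounds = element_bounds(C = 30, H = 40, O = 10,
                                                    N = 5, tolerance = 0.5),
                            table = score_table(),
                            model = edge_weight_model(), seed = 1L) {
  stopifnot(tolerance > 0, top_k >= 1L, n_runs >= 1L)
  structure(list(tolerance = tolerance, top_k = as.integer(top_k),
                 n_runs = as.integer(n_runs), frag = frag, bounds = bounds,
                 table = table, model = model, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Annotate a spectrum with candidate structures
#'
#' @param spectrum an [ms_spectrum()] or a path readable by
#'   [read_spectrum()].
#' @param candidates candidate source: a character vector of SMILES, a path
#'   to a SMILES file (one per line, optional whitespace-separated name), or
#'   a trained `seq_model` (decoded `cfg$n_runs` times in sample mode).
#' @param precursor_formula optional known precursor ion formula (string,
#'   e.g. `"C16H13O4+"`); enumerated from the precursor m/z under
#'   `cfg$bounds` when absent.
#' @param cfg a [pipeline_config()].
#' @return an `annotation_report`: list with `ranking` (a
#'   `scored_candidates` data.frame), `annotation` (peak table for the best
#'   candidate), `ft` (the fragment tree), `log` (named counters).
#' @export
annotate_spectrum <- function(spectrum, candidates,
                              precursor_formula = NULL,
                              cfg = pipeline_config()) {
  s <- if (is.character(spectrum)) read_spectrum(spectrum) else spectrum
  stopifnot(inherits(s, "ms_spectrum"))
  n_read <- nrow(s$peaks)
  s <- select_top_peaks(s, cfg$top_k)
  n_kept <- nrow(s$peaks)

  ft <- fragment_tree(s, precursor_formula = precursor_formula,
                      bounds = cfg$bounds, tolerance = cfg$tolerance,
                      model = cfg$model)

  if (inherits(candidates, "seq_model")) {
    enc <- encode_spectrum(s)
    cl <- generate_candidates(candidates, enc, n_runs = cfg$n_runs,
                              mode = "sample", seed = cfg$seed)
    if (!nrow(cl)) stop("sequence model produced no valid candidate")
    cand_df <- data.frame(smiles = cl$smiles, frequency = cl$frequency)
    n_invalid_gen <- attr(cl, "n_invalid")
  } else {
    if (is.character(candidates) && length(candidates) == 1L &&
        file.exists(candidates)) {
      lines <- readLines(candidates, warn = FALSE)
      lines <- trimws(lines)
      lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
      candidates <- vapply(strsplit(lines, "[ \t]+"), `[`, character(1), 1L)
    }
    cand_df <- data.frame(smiles = candidates,
                          frequency = rep(1L, length(candidates)))
    n_invalid_gen <- 0L
  }

  ranking <- rank_candidates(cand_df, ft, cfg = cfg$frag, table = cfg$table)
  annotation <- annotate_peaks(ranking, ft)
  st_nodes <- nrow(attr(ranking, "details")[[1]]$st$nodes)
  structure(list(
    ranking = ranking,
    annotation = annotation,
    ft = ft,
    log = c(peaks_read = n_read, peaks_retained = n_kept,
            candidates_in = sum(cand_df$frequency),
            invalid_generated = n_invalid_gen,
            invalid_candidates = attr(ranking, "n_invalid"),
            ft_nodes = nrow(ft$nodes),
            best_st_nodes = st_nodes)),
    class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat("<annotation_report>\n")
  cat("  peaks read/retained: ", x$log[["peaks_read"]], "/",
      x$log[["peaks_retained"]], "; FT nodes: ", x$log[["ft_nodes"]],
      "\n", sep = "")
  cat("  top candidates:\n")
  top <- utils::head(x$ranking, 3)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("   %d. %-40s score %.3f (freq %d)\n", top$rank[i],
                top$smiles[i], top$score[i], top$frequency[i]))
  }
  cat("  peak annotation (best candidate):\n")
  print(x$annotation, row.names = FALSE)
  invisible(x)
}

#' Write an annotation report
#'
#' @param report an `annotation_report`.
#' @param path output path: `.json` for the full report, `.tsv` for the
#'   peak-annotation table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      ranking = as.data.frame(report$ranking),
      annotation = report$annotation,
      ft = list(nodes = report$ft$nodes, edges = report$ft$edges),
      log = as.list(report$log)), path,
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.tsv$", path)) {
    utils::write.table(report$annotation, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported extension (use .json or .tsv): ", path)
  }
  invisible(path)
}
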
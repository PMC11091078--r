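#' @title Spectrum-to-SMILES sequence model: tokens and encodings
#'
#' @description
#' The generative half of the pipeline is an encoder-decoder sequence model:
#' the encoder consumes the integer m/z tokens of [encode_spectrum()], the
#' decoder emits SMILES one token at a time. This file defines the 44-entry
#' SMILES token dictionary, the greedy longest-match tokenizer, and the
#' fixed-length (100) target encoding; the network itself lives in
#' [train_seq_model()].
#'
#' @name seq-model
NULL

#' The 44-token SMILES dictionary
#'
#' Composition: 3 specials (`<SOS>`, `<EOS>`, `<PAD>`), the ten supported
#' elements in uppercase (`C H N O P S F Cl Br I`), five aromatic lowercase
#' forms (`c n o s p`), ten digits, and sixteen structural connectors
#' (`( ) = # [ ] + - / \ @ @@ . : % *`). Exactly 44 entries with stable,
#' contiguous indices; `<PAD>` is fixed at index 0 (R position 1).
#'
#' @return named integer vector token -> 0-based index, class
#'   `token_dictionary`.
#' @export
build_token_dictionary <- function() {
  tokens <- c("<PAD>", "<SOS>", "<EOS>",
              "C", "H", "N", "O", "P", "S", "F", "Cl", "Br", "I",
              "c", "n", "o", "s", "p",
              as.character(0:9),
              "(", ")", "=", "#", "[", "]", "+", "-", "/", "\\",
              "@", "@@", ".", ":", "%", "*")
  stopifnot(length(tokens) == 44L, !anyDuplicated(tokens))
  structure(stats::setNames(seq_along(tokens) - 1L, tokens),
            class = "token_dictionary")
}

#' Tokenize a SMILES string
#'
#' Greedy longest-match split: two-character tokens (`Cl`, `Br`, `@@`) are
#' consumed before their one-character prefixes, so `detokenize(tokenize(s))`
#' is the identity for any string over the dictionary alphabet.
#'
#' @param s SMILES string.
#' @param dict a [build_token_dictionary()].
#' @return character vector of tokens.
#' @examples
#' tokenize_smiles("CCl") # "C", "Cl"
#' @export
tokenize_smiles <- function(s, dict = build_token_dictionary()) {
  stopifnot(is.character(s), length(s) == 1L)
  two <- names(dict)[nchar(names(dict)) == 2L & !startsWith(names(dict), "<")]
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    pair <- substr(s, i, i + 1L)
    if (pair %in% two) {
      out <- c(out, pair); i <- i + 2L
    } else {
      ch <- substr(s, i, i)
      if (!ch %in% names(dict)) {
        stop("symbol outside the token dictionary: '", ch, "' in ", s)
      }
      out <- c(out, ch); i <- i + 1L
    }
  }
  out
}

#' @rdname tokenize_smiles
#' @param tokens character vector of tokens.
#' @export
detokenize_smiles <- function(tokens) paste(tokens, collapse = "")

#' Encode a token sequence as a fixed-length target vector
#'
#' `<SOS>` + tokens + `<EOS>`, padded with `<PAD>` to exactly length 100
#' (0-based dictionary indices).
#'
#' @param tokens character vector of SMILES tokens (length <= 98).
#' @param dict a [build_token_dictionary()].
#' @return integer vector of length 100.
#' @export
encode_target <- function(tokens, dict = build_token_dictionary()) {
  if (length(tokens) > 98L) {
    stop("token sequence too long (", length(tokens), " > 98)")
  }
  bad <- setdiff(tokens, names(dict))
  if (length(bad)) stop("unknown token(s): ", paste(bad, collapse = " "))
  idx <- c(dict[["<SOS>"]], unname(dict[tokens]), dict[["<EOS>"]])
  c(idx, rep(dict[["<PAD>"]], 100L - length(idx)))
}

#' Decode a target index vector back to a SMILES string
#'
#' @param idx integer vector of dictionary indices.
#' @param dict a [build_token_dictionary()].
#' @return character SMILES (specials stripped, stops at first `<EOS>`).
#' @export
decode_target <- function(idx, dict = build_token_dictionary()) {
  tokens <- names(dict)[match(idx, dict)]
  tokens <- tokens[tokens != "<SOS>"]
  eos <- which(tokens == "<EOS>")
  if (length(eos)) tokens <- tokens[seq_len(eos[1] - 1L)]
  detokenize_smiles(tokens[tokens != "<PAD>"])
}
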
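#' Default nine-symbol secondary-structure alphabet
#'
#' Eight DSSP-style states (helices `H`/`G`/`I`, strands `E`/`B`, turn `T`,
#' bend `S`, coil `C`) plus `-` for "no prediction". Only the cardinality
#' (nine) and ordering are load-bearing: predicted secondary structure is a
#' pluggable external input and any nine-symbol alphabet may be supplied.
#'
#' @export
SS_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "C", "-")

#' One-hot encode a predicted secondary-structure string
#'
#' @param ss_string Per-residue symbol string.
#' @param alphabet Ordered character vector of 9 distinct symbols ending in
#'   `-` (default [SS_ALPHABET]).
#' @return L x 9 numeric matrix; row `i` is the indicator of `ss_string[i]`.
#' @export
encode_ss <- function(ss_string, alphabet = SS_ALPHABET) {
  stopifnot(length(alphabet) == 9L, !anyDuplicated(alphabet),
            alphabet[9L] == "-")
  chars <- strsplit(ss_string, "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("unknown secondary-structure symbol '%s' at position %d",
                 chars[p], p), call. = FALSE)
  }
  m <- matrix(0, nrow = length(chars), ncol = 9L,
              dimnames = list(NULL, alphabet))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Assemble the 12-column residue feature matrix
#'
#' Horizontal concatenation, conservation profile first: columns 1-3 are the
#' `{O,N,D}` conservation probabilities, columns 4-12 the one-hot predicted
#' secondary structure. The two blocks are recoverable by column slicing.
#'
#' @param mcs An `mcs_profile` (see [compute_profile()]).
#' @param ss_block L x 9 one-hot matrix from [encode_ss()].
#' @return L x 12 numeric matrix of class `feature_matrix`.
#' @export
assemble_features <- function(mcs, ss_block) {
  stopifnot(inherits(mcs, "mcs_profile"))
  if (nrow(mcs$values) != nrow(ss_block)) {
    stop(sprintf("feature assembly error: profile length %d != SS length %d",
                 nrow(mcs$values), nrow(ss_block)), call. = FALSE)
  }
  fm <- cbind(mcs$values, ss_block)
  colnames(fm) <- c(paste0("MCS_", RESIDUE_STATES),
                    paste0("SS_", colnames(ss_block) %||% seq_len(9L)))
  structure(fm, class = c("feature_matrix", class(fm)))
}

#' Read per-chain secondary-structure strings
#'
#' FASTA-like records of per-residue symbols, one record per chain, ids
#' matching the query FASTA.
#'
#' @param path Path to the SS FASTA file.
#' @return Named character vector of symbol strings.
#' @export
read_ss_fasta <- function(path) read_fasta_named(path)
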
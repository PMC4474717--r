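RESIDUE_STATES <- c("O", "N", "D")

AMINO_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a per-chain disorder annotation
#'
#' A chain annotation pairs an amino-acid sequence with a logical mask saying
#' which residues have a resolved backbone C-alpha atom in the deposited
#' structure. Residues with a missing C-alpha are the operational definition
#' of intrinsic disorder used throughout the package.
#'
#' @param chain_id Non-empty chain identifier (no whitespace).
#' @param sequence Amino-acid string over the 20 standard letters plus `X`.
#' @param resolved Logical vector, one element per residue; `TRUE` means the
#'   backbone C-alpha is present (ordered).
#' @return An object of class `chain_annotation`.
#' @export
chain_annotation <- function(chain_id, sequence, resolved) {
  sequence <- toupper(as.character(sequence))
  if (!is.character(chain_id) || length(chain_id) != 1L || !nzchar(chain_id) ||
      grepl("[[:space:]]", chain_id)) {
    stop("chain_id must be a single non-empty string without whitespace",
         call. = FALSE)
  }
  n <- nchar(sequence)
  if (n < 1L) stop("sequence must have length >= 1", call. = FALSE)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AMINO_LETTERS)
  if (length(bad)) {
    stop(sprintf("invalid residue letter(s) in chain '%s': %s",
                 chain_id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  resolved <- as.logical(resolved)
  if (length(resolved) != n || anyNA(resolved)) {
    stop(sprintf(
      "invalid annotation for chain '%s': resolved mask length %d != sequence length %d or contains NA",
      chain_id, length(resolved), n), call. = FALSE)
  }
  structure(list(chain_id = chain_id, sequence = sequence, resolved = resolved),
            class = "chain_annotation")
}

#' Two-state disorder labels from a resolved-C-alpha mask
#'
#' Position `i` is labeled `D` (disorder) when `resolved[i]` is `FALSE`
#' (missing C-alpha), and `O` (order) otherwise.
#'
#' @param chain A [chain_annotation()].
#' @return A label string over `{O, D}` of the chain's length.
#' @export
two_state_labels <- function(chain) {
  if (!inherits(chain, "chain_annotation")) {
    chain <- chain_annotation(chain$chain_id, chain$sequence, chain$resolved)
  }
  paste(ifelse(chain$resolved, "O", "D"), collapse = "")
}

#' Augment two-state labels with near-disorder regions
#'
#' Near-disorder regions are the `K` residues at the start and the end
#' terminus of every ordered region: they absorb the boundary errors that
#' concentrate at order/disorder transitions and soften the class imbalance.
#' For each maximal run of `O` of length `m`, the first `K` and last `K`
#' positions become `N`; runs with `m <= 2K` are relabeled `N` entirely.
#' `D` positions are never modified. The rule applies at every run terminus,
#' including runs abutting the chain ends.
#'
#' @param labels Label string over `{O, D}`.
#' @param K Non-negative integer near-disorder width (default 5).
#' @return Label string over `{O, N, D}` of the same length.
#' @export
add_near_disorder <- function(labels, K = 5L) {
  stopifnot(length(labels) == 1L, is.character(labels))
  K <- as.integer(K)
  if (is.na(K) || K < 0L) stop("K must be a non-negative integer", call. = FALSE)
  chars <- strsplit(labels, "")[[1]]
  if (length(chars) && any(!chars %in% c("O", "D"))) {
    stop(sprintf("invalid label symbol(s): %s; expected only O/D",
                 paste(setdiff(unique(chars), c("O", "D")), collapse = ", ")),
         call. = FALSE)
  }
  if (K == 0L || !length(chars)) return(labels)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] != "O") next
    m <- r$lengths[i]
    if (m <= 2L * K) {
      chars[starts[i]:ends[i]] <- "N"
    } else {
      chars[starts[i]:(starts[i] + K - 1L)] <- "N"
      chars[(ends[i] - K + 1L):ends[i]] <- "N"
    }
  }
  paste(chars, collapse = "")
}

#' Residue-class composition of a labeled collection
#'
#' Counts `O`, `N` and `D` residues pooled over a collection of label strings
#' and reports pairwise ratios normalized to a chosen unit class, the report
#' style used when describing dataset imbalance (e.g. an order:disorder ratio
#' of 14.5:1).
#'
#' @param labels Character vector of label strings over `{O, N, D}`.
#' @param unit Class whose count is scaled to 1 in the ratio (default `"D"`).
#' @return List with `counts` (named integer vector `O`, `N`, `D`), `total`,
#'   and `ratio` (named numeric vector of counts divided by the unit count;
#'   `NA` if the unit class is empty).
#' @export
class_composition <- function(labels, unit = c("D", "N")) {
  unit <- match.arg(unit)
  pooled <- paste(labels, collapse = "")
  chars <- strsplit(pooled, "")[[1]]
  bad <- setdiff(unique(chars), RESIDUE_STATES)
  if (length(bad)) {
    stop(sprintf("invalid label symbol(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  counts <- vapply(RESIDUE_STATES, function(s) sum(chars == s), integer(1))
  ratio <- if (counts[[unit]] > 0) counts / counts[[unit]] else
    stats::setNames(rep(NA_real_, 3L), RESIDUE_STATES)
  list(counts = counts, total = sum(counts), ratio = ratio)
}

#' Read per-chain resolved-index annotations
#'
#' Reads a two-column tab-separated file (`chain_id`, comma-separated 1-based
#' indices of resolved residues) and pairs it with sequences from a FASTA
#' file, producing a list of [chain_annotation()] objects.
#'
#' @param fasta_path Path to the query FASTA file.
#' @param tsv_path Path to the resolved-index TSV.
#' @return Named list of `chain_annotation` objects in FASTA order.
#' @export
read_annotations <- function(fasta_path, tsv_path) {
  seqs <- read_fasta_named(fasta_path)
  tab <- utils::read.delim(tsv_path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("resolved-index TSV must have two columns", call. = FALSE)
  idx <- stats::setNames(as.list(tab[[2]]), tab[[1]])
  out <- lapply(names(seqs), function(id) {
    if (is.null(idx[[id]])) {
      stop(sprintf("no resolved-index entry for chain '%s'", id), call. = FALSE)
    }
    n <- nchar(seqs[[id]])
    resolved <- rep(FALSE, n)
    spec <- trimws(idx[[id]])
    if (nzchar(spec)) {
      ii <- as.integer(strsplit(spec, ",", fixed = TRUE)[[1]])
      if (anyNA(ii) || any(ii < 1L) || any(ii > n)) {
        stop(sprintf("resolved indices out of range for chain '%s'", id),
             call. = FALSE)
      }
      resolved[ii] <- TRUE
    }
    chain_annotation(id, seqs[[id]], resolved)
  })
  stats::setNames(out, names(seqs))
}

# Named character vector of sequences from a FASTA file (first token of the
# header line is the id).
read_fasta_named <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(as.character(ss), ids)
}
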
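#' Construct an MCSbase knowledge database
#'
#' MCSbase pairs amino-acid sequences with per-residue structural-state
#' strings over `{O, N, D}` (order / near-disorder / disorder). Queries are
#' aligned against it and the states of homologous residues are tallied into
#' the multi-class conservation profile.
#'
#' @param ids Character vector of unique, non-empty record ids (no whitespace).
#' @param sequences Character vector of amino-acid strings.
#' @param labels Character vector of `{O,N,D}` strings, same lengths as
#'   `sequences`.
#' @return An object of class `mcs_database`: a data.frame with columns
#'   `id`, `sequence`, `labels`, iteration order stable.
#' @export
mcs_database <- function(ids = character(), sequences = character(),
                         labels = character()) {
  stopifnot(length(ids) == length(sequences), length(ids) == length(labels))
  ids <- as.character(ids)
  if (any(!nzchar(ids)) || any(grepl("[[:space:]]", ids))) {
    stop("record ids must be non-empty and contain no whitespace", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  sequences <- toupper(as.character(sequences))
  labels <- as.character(labels)
  bad_len <- nchar(sequences) != nchar(labels)
  if (any(bad_len)) {
    stop(sprintf("sequence/label length mismatch for id(s): %s",
                 paste(ids[bad_len], collapse = ", ")), call. = FALSE)
  }
  bad_lab <- vapply(labels, function(l) grepl("[^OND]", l), logical(1))
  if (any(bad_lab)) {
    stop(sprintf("labels must be over {O,N,D}; offending id(s): %s",
                 paste(ids[bad_lab], collapse = ", ")), call. = FALSE)
  }
  structure(
    data.frame(id = ids, sequence = sequences, labels = labels,
               stringsAsFactors = FALSE),
    class = c("mcs_database", "data.frame"))
}

#' @export
print.mcs_database <- function(x, ...) {
  cat(sprintf("MCSbase knowledge database: %d record(s), %d residue(s)\n",
              nrow(x), sum(nchar(x$sequence))))
  if (nrow(x)) {
    comp <- class_composition(x$labels)
    cat(sprintf("  state composition O/N/D: %d / %d / %d\n",
                comp$counts[["O"]], comp$counts[["N"]], comp$counts[["D"]]))
  }
  invisible(x)
}

#' Write an MCSbase database file
#'
#' Serializes each record as two consecutive FASTA entries: `>id` with the
#' sequence, then `>id|labels` with the state string, both wrapped at 60
#' columns. The file remains a valid FASTA readable by standard parsers.
#'
#' @param db An [mcs_database()].
#' @param path Output file path.
#' @export
write_mcsbase <- function(db, path) {
  stopifnot(inherits(db, "mcs_database"))
  if (nrow(db) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  entries <- character(2L * nrow(db))
  nms <- character(2L * nrow(db))
  entries[c(TRUE, FALSE)] <- db$sequence
  entries[c(FALSE, TRUE)] <- db$labels
  nms[c(TRUE, FALSE)] <- db$id
  nms[c(FALSE, TRUE)] <- paste0(db$id, "|labels")
  ss <- Biostrings::BStringSet(stats::setNames(entries, nms))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read an MCSbase database file
#'
#' Inverse of [write_mcsbase()]. Sequence and `|labels` entries for an id may
#' appear in either adjacent order; records are paired by id. Record order
#' follows first appearance of each id.
#'
#' @param path Path to an MCSbase file.
#' @return An [mcs_database()].
#' @export
read_mcsbase <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) return(mcs_database())
  nms <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1L)
  is_lab <- grepl("\\|labels$", nms)
  ids <- ifelse(is_lab, sub("\\|labels$", "", nms), nms)
  vals <- as.character(ss)
  seq_ids <- ids[!is_lab]
  lab_ids <- ids[is_lab]
  if (anyDuplicated(seq_ids)) {
    stop(sprintf("MCSbase format error: duplicate id '%s'",
                 seq_ids[duplicated(seq_ids)][1]), call. = FALSE)
  }
  if (anyDuplicated(lab_ids)) {
    stop(sprintf("MCSbase format error: duplicate labels entry for id '%s'",
                 lab_ids[duplicated(lab_ids)][1]), call. = FALSE)
  }
  miss_lab <- setdiff(seq_ids, lab_ids)
  if (length(miss_lab)) {
    stop(sprintf("MCSbase format error: missing '|labels' partner for id '%s'",
                 miss_lab[1]), call. = FALSE)
  }
  miss_seq <- setdiff(lab_ids, seq_ids)
  if (length(miss_seq)) {
    stop(sprintf("MCSbase format error: labels entry without sequence for id '%s'",
                 miss_seq[1]), call. = FALSE)
  }
  order_ids <- unique(ids)
  seqs <- stats::setNames(vals[!is_lab], seq_ids)[order_ids]
  labs <- stats::setNames(vals[is_lab], lab_ids)[order_ids]
  mismatch <- nchar(seqs) != nchar(labs)
  if (any(mismatch)) {
    stop(sprintf("MCSbase format error: sequence/label length mismatch for id '%s'",
                 order_ids[mismatch][1]), call. = FALSE)
  }
  mcs_database(order_ids, unname(seqs), unname(labs))
}

#' Drop database records identical to any query sequence
#'
#' Fairness rule for evaluation: any record whose sequence is exactly equal
#' (case-insensitively) to a query sequence is removed from the database, so
#' a query can never borrow its own deposited annotation. No similarity
#' threshold is involved — only exact full-sequence matches are dropped.
#'
#' @param db An [mcs_database()].
#' @param queries Character vector of query sequences.
#' @return The filtered [mcs_database()].
#' @export
exclude_matches <- function(db, queries) {
  stopifnot(inherits(db, "mcs_database"))
  if (nrow(db) == 0L || length(queries) == 0L) return(db)
  keep <- !(toupper(db$sequence) %in% toupper(as.character(queries)))
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mcs_database", "data.frame")
  out
}

#' Build an MCSbase database from chain annotations
#'
#' Convenience conversion: derives two-state labels from resolved-C-alpha
#' masks, augments them with near-disorder regions of width `K`, and collects
#' the result into an [mcs_database()].
#'
#' @param chains List of [chain_annotation()] objects.
#' @param K Near-disorder width passed to [add_near_disorder()] (default 5).
#' @return An [mcs_database()].
#' @export
mcsbase_from_annotations <- function(chains, K = 5L) {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  seqs <- vapply(chains, function(ch) ch$sequence, character(1))
  labs <- vapply(chains, function(ch) add_near_disorder(two_state_labels(ch), K),
                 character(1))
  mcs_database(ids, seqs, labs)
}
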
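HIT_COLUMNS <- c("query_id", "subject_id", "e_value",
                 "query_start", "query_end", "subject_start", "subject_end",
                 "aligned_query", "aligned_subject")

#' Construct a table of local-alignment hits
#'
#' One row per high-scoring segment pair (HSP): query/subject ids, e-value,
#' 1-based inclusive coordinates on both sequences (BLAST tabular
#' convention), and the gapped aligned strings. Validates that the gap-free
#' length of each aligned string matches its coordinate span.
#'
#' @param query_id,subject_id Character vectors.
#' @param e_value Non-negative numeric vector.
#' @param query_start,query_end,subject_start,subject_end 1-based inclusive
#'   integer coordinates.
#' @param aligned_query,aligned_subject Equal-length gapped strings
#'   (`-` = gap).
#' @return A data.frame of class `alignment_hits`.
#' @export
alignment_hits <- function(query_id = character(), subject_id = character(),
                           e_value = numeric(), query_start = integer(),
                           query_end = integer(), subject_start = integer(),
                           subject_end = integer(), aligned_query = character(),
                           aligned_subject = character()) {
  h <- data.frame(query_id = as.character(query_id),
                  subject_id = as.character(subject_id),
                  e_value = as.numeric(e_value),
                  query_start = as.integer(query_start),
                  query_end = as.integer(query_end),
                  subject_start = as.integer(subject_start),
                  subject_end = as.integer(subject_end),
                  aligned_query = toupper(as.character(aligned_query)),
                  aligned_subject = toupper(as.character(aligned_subject)),
                  stringsAsFactors = FALSE)
  if (nrow(h)) {
    if (any(h$e_value < 0)) stop("e-values must be non-negative", call. = FALSE)
    if (any(nchar(h$aligned_query) != nchar(h$aligned_subject))) {
      stop("aligned strings must have equal length", call. = FALSE)
    }
    qlen <- nchar(gsub("-", "", h$aligned_query, fixed = TRUE))
    slen <- nchar(gsub("-", "", h$aligned_subject, fixed = TRUE))
    bad <- qlen != h$query_end - h$query_start + 1L |
      slen != h$subject_end - h$subject_start + 1L
    if (any(bad)) {
      stop(sprintf(
        "invalid hit: aligned-string gap-free length disagrees with coordinates (query '%s', subject '%s')",
        h$query_id[bad][1], h$subject_id[bad][1]), call. = FALSE)
    }
  }
  structure(h, class = c("alignment_hits", "data.frame"))
}

#' Select homology hits by e-value
#'
#' Keeps hits with e-value strictly below `e_threshold`, sorts them by
#' e-value in ascending order, and truncates to the top `S`; if fewer than
#' `S` survive the filter, all are retained. Ties in e-value are broken by
#' (subject_id, query_start) lexicographic order so the top-S set is
#' deterministic across platforms.
#'
#' @param hits An [alignment_hits()] table (any query mix; filter per query
#'   before calling if needed).
#' @param e_threshold Strict e-value cutoff (default 10).
#' @param S Maximum number of hits to retain (default 10).
#' @return The selected [alignment_hits()] rows, ascending by e-value.
#' @export
select_hits <- function(hits, e_threshold = 10, S = 10L) {
  stopifnot(e_threshold > 0, S >= 1L)
  h <- hits[hits$e_value < e_threshold, , drop = FALSE]
  if (nrow(h)) {
    ord <- order(h$e_value, h$subject_id, h$query_start)
    h <- h[ord, , drop = FALSE]
    h <- h[seq_len(min(nrow(h), as.integer(S))), , drop = FALSE]
  }
  rownames(h) <- NULL
  class(h) <- c("alignment_hits", "data.frame")
  h
}

#' Read local-alignment hits from PSI-BLAST tabular output
#'
#' Parses the nine-column tabular format produced by
#' `psiblast ... -outfmt "6 qseqid sseqid evalue qstart qend sstart send qseq sseq"`
#' (the documented external run against an MCSbase uses six iterations and
#' 500 maximum target sequences, other parameters default). The same format
#' is written by [write_hits_tsv()] and by the built-in [toy_align()] path,
#' so synthetic corpora exercise this exact parser.
#'
#' @param path Path to the tab-separated hits file (no header).
#' @return An [alignment_hits()] table.
#' @export
read_hits_tsv <- function(path) {
  if (file.size(path) == 0L) return(alignment_hits())
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "integer", "integer",
                                          "integer", "character", "character"))
  if (ncol(tab) != 9L) {
    stop("hits file must have 9 tab-separated columns (qseqid sseqid evalue qstart qend sstart send qseq sseq)",
         call. = FALSE)
  }
  names(tab) <- HIT_COLUMNS
  do.call(alignment_hits, tab)
}

#' Write local-alignment hits as BLAST-style tabular output
#'
#' @param hits An [alignment_hits()] table.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits)[, HIT_COLUMNS], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
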
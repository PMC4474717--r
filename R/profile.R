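#' Accumulate per-position state counts from one alignment hit
#'
#' Walks the alignment columns left to right with cursors starting at
#' `query_start` / `subject_start`. Columns where both symbols are non-gap
#' add one tally to the query position's box for the subject residue's state
#' (`O`, `N` or `D`); a gap on either side advances only the non-gap cursor
#' and contributes nothing.
#'
#' @param hit One row of an [alignment_hits()] table (list or 1-row
#'   data.frame).
#' @param subject_labels `{O,N,D}` state string of the subject record; must
#'   cover `subject_end`.
#' @param counts L x 3 integer matrix (columns `O`, `N`, `D`) to update,
#'   where L is the query length.
#' @return The updated counts matrix.
#' @export
accumulate_counts <- function(hit, subject_labels, counts) {
  qa <- strsplit(hit$aligned_query, "")[[1]]
  sa <- strsplit(hit$aligned_subject, "")[[1]]
  if (length(qa) != length(sa)) {
    stop("invalid hit: aligned strings differ in length", call. = FALSE)
  }
  if (nchar(subject_labels) < hit$subject_end) {
    stop(sprintf("invalid hit: subject labels (length %d) shorter than subject_end %d",
                 nchar(subject_labels), hit$subject_end), call. = FALSE)
  }
  qgap <- qa == "-"
  sgap <- sa == "-"
  # 1-based residue index at each column, for the sequence the column consumes
  qpos <- hit$query_start - 1L + cumsum(!qgap)
  spos <- hit$subject_start - 1L + cumsum(!sgap)
  both <- !qgap & !sgap
  if (any(both)) {
    qp <- qpos[both]
    if (max(qp) > nrow(counts)) {
      stop("invalid hit: query coordinates exceed counts matrix", call. = FALSE)
    }
    lab <- strsplit(subject_labels, "")[[1]][spos[both]]
    col <- match(lab, RESIDUE_STATES)
    if (anyNA(col)) {
      stop("invalid subject labels: symbols outside {O,N,D}", call. = FALSE)
    }
    for (k in seq_along(qp)) {
      counts[qp[k], col[k]] <- counts[qp[k], col[k]] + 1L
    }
  }
  counts
}

#' Normalize state counts into a multi-class conservation profile
#'
#' Each query position carries three boxes counting how often homologous
#' residues among the selected hits are ordered, near-disordered or
#' disordered. The profile value for state `s` at position `p` is the count
#' divided by the total over the three states at `p` — a probability.
#' Positions covered by no hit emit `(0, 0, 0)` rather than a uniform 1/3,
#' so downstream models can distinguish "no homology signal" from uniform
#' evidence.
#'
#' @param counts L x 3 non-negative integer matrix (columns `O`, `N`, `D`).
#' @return An object of class `mcs_profile`: list with `values` (L x 3
#'   matrix of probabilities, rows with coverage summing to 1) and
#'   `coverage` (integer vector of per-position hit counts).
#' @export
compute_profile <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 3L, all(counts >= 0))
  coverage <- as.integer(rowSums(counts))
  values <- counts
  pos <- coverage > 0L
  values[pos, ] <- counts[pos, , drop = FALSE] / coverage[pos]
  values[!pos, ] <- 0
  dimnames(values) <- list(NULL, RESIDUE_STATES)
  structure(list(values = values, coverage = coverage), class = "mcs_profile")
}

#' Multi-class conservation profile for a query sequence
#'
#' Composes the full scoring path: hits for the query are filtered and
#' ranked by e-value ([select_hits()]), each selected hit projects its
#' subject's `{O,N,D}` states onto the query positions it covers
#' ([accumulate_counts()]), and the tallies are normalized into a
#' probability profile ([compute_profile()]). Deterministic for fixed
#' inputs.
#'
#' @param query Query amino-acid sequence (string).
#' @param db An [mcs_database()] resolving every `subject_id` in `hits`.
#' @param hits [alignment_hits()] for this query.
#' @param e_threshold,S Hit-selection parameters (defaults 10 and 10).
#' @return An `mcs_profile` of the query's length.
#' @export
mcs_for_query <- function(query, db, hits, e_threshold = 10, S = 10L) {
  L <- nchar(query)
  counts <- matrix(0L, nrow = L, ncol = 3L,
                   dimnames = list(NULL, RESIDUE_STATES))
  sel <- select_hits(hits, e_threshold = e_threshold, S = S)
  if (nrow(sel)) {
    unknown <- setdiff(unique(sel$subject_id), db$id)
    if (length(unknown)) {
      stop(sprintf("unknown subject id(s) in hits: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    labs <- stats::setNames(db$labels, db$id)
    for (i in seq_len(nrow(sel))) {
      hit <- as.list(sel[i, ])
      counts <- accumulate_counts(hit, labs[[hit$subject_id]], counts)
    }
  }
  compute_profile(counts)
}

#' @export
print.mcs_profile <- function(x, ...) {
  L <- length(x$coverage)
  cat(sprintf("Multi-class conservation profile: %d position(s), %d covered\n",
              L, sum(x$coverage > 0)))
  invisible(x)
}
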
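# Self-contained synthetic corpora: query chains with ground-truth disorder,
# mutated homolog families forming a toy knowledge database, a noisy
# label-correlated secondary-structure oracle, and local-alignment hits from
# a built-in aligner. Everything downstream of real data (PSI-BLAST output,
# a curated MCSbase, an external SS predictor) has a synthetic stand-in here
# so the full pipeline runs with no download.

# Background amino-acid frequencies (rounded database composition) and a
# disorder-biased table: disordered segments are enriched in the
# disorder-promoting residues P,E,S,K,G,Q and depleted in the
# order-promoting hydrophobics W,C,F,I,Y,V.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

aa_background <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1,
                   H = 2.3, I = 5.9, K = 5.8, L = 9.7, M = 2.4, N = 4.1,
                   P = 4.7, Q = 3.9, R = 5.5, S = 6.7, T = 5.4, V = 6.9,
                   W = 1.1, Y = 2.9)

aa_disorder_bias <- local({
  w <- aa_background
  up <- c("P", "E", "S", "K", "G", "Q")
  down <- c("W", "C", "F", "I", "Y", "V")
  w[up] <- w[up] * 2.5
  w[down] <- w[down] * 0.25
  w
})

#' Synthetic corpus configuration
#'
#' Defaults emulate the study conditions the rest of the package is built
#' for: chains of 80-300 residues with roughly 5% disordered residues
#' concentrated in terminal and occasional internal segments, families of
#' moderately diverged homologs carrying noisy copies of the structural
#' labels, and a secondary-structure oracle correlated with the truth but
#' corrupted at a fixed rate.
#'
#' @param n_families Number of query chains / homolog families (default 20).
#' @param length_range Chain length range, inclusive (default `c(80, 300)`).
#' @param disorder_target Target pooled disordered fraction (default 0.05).
#' @param terminal_disorder_prob Probability that a terminus carries a
#'   disordered segment (default 0.6 per terminus).
#' @param internal_segment_rate Per-residue probability of starting an
#'   internal disordered segment (default 0.0008).
#' @param segment_length_mean Mean (geometric) disordered-segment length
#'   (default 8).
#' @param n_homologs Homologs per family (default 15).
#' @param substitution_prob Per-residue substitution probability in
#'   homologs (default 0.15).
#' @param indel_prob Per-residue probability of a single-residue indel
#'   (default 0.01); kept rare so labels transfer positionally.
#' @param label_flip_prob Per-residue probability of flipping a homolog's
#'   two-state label (default 0.05).
#' @param ss_noise Probability that an SS symbol is replaced by a uniformly
#'   random alphabet symbol (default 0.2).
#' @param K Near-disorder width used to three-state the homolog labels
#'   (default 5).
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_families = 20L, length_range = c(80L, 300L),
                         disorder_target = 0.05, terminal_disorder_prob = 0.6,
                         internal_segment_rate = 0.0008,
                         segment_length_mean = 8, n_homologs = 15L,
                         substitution_prob = 0.15, indel_prob = 0.01,
                         label_flip_prob = 0.05, ss_noise = 0.2,
                         K = 5L, seed = 1L) {
  stopifnot(length_range[1] < length_range[2], length_range[1] >= 10,
            disorder_target >= 0, disorder_target <= 1,
            terminal_disorder_prob >= 0, terminal_disorder_prob <= 1,
            substitution_prob >= 0, substitution_prob <= 1,
            indel_prob >= 0, indel_prob <= 1,
            label_flip_prob >= 0, label_flip_prob <= 1,
            ss_noise >= 0, ss_noise <= 1, segment_length_mean >= 1)
  structure(as.list(environment()), class = "synth_config")
}

rgeom_len <- function(n, mean_len) 1L + stats::rgeom(n, prob = 1 / mean_len)

#' Generate one synthetic chain with ground-truth disorder
#'
#' Chain length is uniform over the configured range. Disordered segments of
#' geometric length are placed at each terminus with the configured
#' probability and internally as a marked point process. Amino acids are
#' drawn from a background table; disordered positions use a table enriched
#' in disorder-promoting residues (P, E, S, K, G, Q) and depleted in
#' hydrophobics (W, C, F, I, Y, V), mirroring the low hydrophobicity of real
#' disordered segments.
#'
#' @param config A [synth_config()]. The caller controls the RNG state
#'   (use `set.seed`).
#' @return List with `sequence` and two-state `labels`.
#' @export
generate_chain <- function(config) {
  L <- sample(config$length_range[1]:config$length_range[2], 1L)
  disordered <- rep(FALSE, L)
  if (config$disorder_target > 0) {
    if (stats::runif(1) < config$terminal_disorder_prob) {
      disordered[seq_len(min(L, rgeom_len(1, config$segment_length_mean)))] <- TRUE
    }
    if (stats::runif(1) < config$terminal_disorder_prob) {
      len <- min(L, rgeom_len(1, config$segment_length_mean))
      disordered[(L - len + 1L):L] <- TRUE
    }
    starts <- which(stats::runif(L) < config$internal_segment_rate)
    for (s in starts) {
      e <- min(L, s + rgeom_len(1, config$segment_length_mean) - 1L)
      disordered[s:e] <- TRUE
    }
  }
  aa <- character(L)
  n_dis <- sum(disordered)
  if (n_dis < L) {
    aa[!disordered] <- sample(AA20, L - n_dis, replace = TRUE,
                              prob = aa_background)
  }
  if (n_dis > 0) {
    aa[disordered] <- sample(AA20, n_dis, replace = TRUE,
                             prob = aa_disorder_bias)
  }
  list(sequence = paste(aa, collapse = ""),
       labels = paste(ifelse(disordered, "D", "O"), collapse = ""))
}

#' Generate a family of noisy homologs for a chain
#'
#' The parent's two-state labels are first augmented with near-disorder
#' regions of width `K`; each homolog then carries a noisy copy of that
#' three-state annotation. Noise per homolog: independent per-residue
#' substitutions, rare single-residue insertions/deletions (an inserted
#' residue copies its left neighbour's label; a deletion removes the
#' label), and per-residue label flips that replace a state with one of the
#' other two uniformly. Flipping the copied annotation keeps each flip's
#' footprint to a single residue, so family majority vote recovers the
#' parent's annotation at a rate set directly by `label_flip_prob`.
#'
#' @param chain Result of [generate_chain()] (fields `sequence`, `labels`).
#' @param chain_id Parent id; homologs are named `<chain_id>_h<i>`.
#' @param config A [synth_config()].
#' @return An [mcs_database()] of `n_homologs` records.
#' @export
generate_family <- function(chain, chain_id, config) {
  n <- config$n_homologs
  if (n == 0L) return(mcs_database())
  ids <- sprintf("%s_h%d", chain_id, seq_len(n))
  seqs <- character(n)
  labs <- character(n)
  base_aa <- strsplit(chain$sequence, "")[[1]]
  base_lab <- strsplit(add_near_disorder(chain$labels, config$K), "")[[1]]
  for (h in seq_len(n)) {
    aa <- base_aa
    lab <- base_lab
    sub <- stats::runif(length(aa)) < config$substitution_prob
    if (any(sub)) {
      aa[sub] <- sample(AA20, sum(sub), replace = TRUE, prob = aa_background)
    }
    flip <- which(stats::runif(length(lab)) < config$label_flip_prob)
    for (p in flip) {
      lab[p] <- sample(setdiff(RESIDUE_STATES, lab[p]), 1L)
    }
    if (config$indel_prob > 0) {
      pos <- which(stats::runif(length(aa)) < config$indel_prob)
      for (p in rev(pos)) {   # right-to-left keeps earlier positions valid
        if (stats::runif(1) < 0.5 && length(aa) > 1L) {
          aa <- aa[-p]; lab <- lab[-p]
        } else {
          ins <- sample(AA20, 1L, prob = aa_background)
          aa <- append(aa, ins, after = p)
          lab <- append(lab, lab[p], after = p)
        }
      }
    }
    seqs[h] <- paste(aa, collapse = "")
    labs[h] <- paste(lab, collapse = "")
  }
  mcs_database(ids, seqs, labs)
}

#' Noisy secondary-structure oracle correlated with the truth labels
#'
#' Ordered runs are segmented into blocks of geometric length emitting H, E
#' or T; disordered residues emit `-` or C. Each symbol is then replaced by
#' a uniformly random alphabet symbol with probability `ss_noise`.
#'
#' @param labels Two-state `{O,D}` truth string.
#' @param config A [synth_config()].
#' @return Nine-symbol SS string of the same length.
#' @export
generate_ss <- function(labels, config) {
  lab <- strsplit(labels, "")[[1]]
  L <- length(lab)
  ss <- character(L)
  ss[lab == "D"] <- sample(c("-", "C"), sum(lab == "D"), replace = TRUE,
                           prob = c(0.7, 0.3))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] != "O") next
    p <- starts[i]
    while (p <= ends[i]) {
      blk <- min(ends[i], p + rgeom_len(1, 6) - 1L)
      ss[p:blk] <- sample(c("H", "E", "T"), 1L, prob = c(0.45, 0.35, 0.2))
      p <- blk + 1L
    }
  }
  noisy <- stats::runif(L) < config$ss_noise
  if (any(noisy)) {
    ss[noisy] <- sample(SS_ALPHABET, sum(noisy), replace = TRUE)
  }
  paste(ss, collapse = "")
}

#' Local alignment of a query against the knowledge database
#'
#' Smith-Waterman-style local alignment (match +2, mismatch -1, affine gaps:
#' open -5, extend -1 per residue), one best hit per subject, computed with
#' `Biostrings::pairwiseAlignment`. Hits with score <= 10 are dropped. Each
#' hit carries a pseudo e-value \eqn{m \cdot n \cdot 2^{-score/4}} (m =
#' query length, n = total database residues) — a simplified Karlin-Altschul
#' form that orders hits consistently with score, which is all downstream
#' selection uses.
#'
#' @param query Query sequence (string).
#' @param query_id Query id used in the hit table.
#' @param db An [mcs_database()].
#' @param min_score Hits scoring at or below this are dropped (default 10).
#' @return An [alignment_hits()] table.
#' @export
toy_align <- function(query, query_id, db, min_score = 10) {
  if (nrow(db) == 0L) return(alignment_hits())
  mat <- matrix(-1, nrow = 21L, ncol = 21L,
                dimnames = list(AMINO_LETTERS, AMINO_LETTERS))
  diag(mat) <- 2
  subjects <- Biostrings::AAStringSet(stats::setNames(db$sequence, db$id))
  # cheap score-only pass over the whole database, full traceback only for
  # subjects clearing the score cutoff (identical scores either way)
  sc <- Biostrings::pairwiseAlignment(
    pattern = subjects, subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1,   # first gap residue costs 5, each further 1
    scoreOnly = TRUE)
  keep <- which(sc > min_score)
  if (!length(keep)) return(alignment_hits())
  aln <- Biostrings::pairwiseAlignment(
    pattern = subjects[keep], subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  score <- Biostrings::score(aln)
  m <- nchar(query)
  n_db <- sum(nchar(db$sequence))
  pat <- Biostrings::pattern(aln)   # the subject records
  sub <- Biostrings::subject(aln)   # the query
  hits <- alignment_hits(
    query_id = rep(query_id, length(keep)),
    subject_id = db$id[keep],
    e_value = m * n_db * 2^(-score / 4),
    query_start = Biostrings::start(sub),
    query_end = Biostrings::end(sub),
    subject_start = Biostrings::start(pat),
    subject_end = Biostrings::end(pat),
    aligned_query = as.character(Biostrings::alignedSubject(aln)),
    aligned_subject = as.character(Biostrings::alignedPattern(aln)))
  hits[order(hits$e_value, hits$subject_id), , drop = FALSE]
}

#' Generate a full synthetic corpus
#'
#' Composes chain, family, secondary-structure and alignment generation into
#' a corpus that exercises every production stage: queries with two-state
#' truth, a knowledge database of all homologs, per-query SS strings, and
#' local-alignment hits of every query against the pooled database.
#' Byte-identical for identical `(config, seed)`.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_corpus`: `queries` (data.frame id,
#'   sequence, labels), `db` ([mcs_database()]), `ss` (named character),
#'   `hits` ([alignment_hits()]), `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  set.seed(config$seed)
  ids <- sprintf("synth%03d", seq_len(config$n_families))
  chains <- vector("list", config$n_families)
  fams <- vector("list", config$n_families)
  ss <- character(config$n_families)
  for (i in seq_len(config$n_families)) {
    chains[[i]] <- generate_chain(config)
    fams[[i]] <- generate_family(chains[[i]], ids[i], config)
    ss[i] <- generate_ss(chains[[i]]$labels, config)
  }
  db <- do.call(rbind, lapply(fams, as.data.frame))
  db <- if (is.null(db)) mcs_database() else
    mcs_database(db$id, db$sequence, db$labels)
  queries <- data.frame(id = ids,
                        sequence = vapply(chains, `[[`, character(1), "sequence"),
                        labels = vapply(chains, `[[`, character(1), "labels"),
                        stringsAsFactors = FALSE)
  hits <- do.call(rbind, lapply(seq_len(config$n_families), function(i) {
    as.data.frame(toy_align(queries$sequence[i], ids[i], db))
  }))
  hits <- if (is.null(hits) || nrow(hits) == 0L) alignment_hits() else
    do.call(alignment_hits, hits)
  structure(list(queries = queries, db = db,
                 ss = stats::setNames(ss, ids), hits = hits, config = config),
            class = "synth_corpus")
}

#' Write a synthetic corpus to the pipeline's file formats
#'
#' Emits query FASTA, truth-label TSV (`chain_id`, two-state label string),
#' the knowledge-database file, SS FASTA and the hits TSV — the same formats
#' the production parsers consume.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the five paths.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(queries = file.path(dir, "queries.fasta"),
             truth = file.path(dir, "truth.tsv"),
             mcsbase = file.path(dir, "mcsbase.fasta"),
             ss = file.path(dir, "ss.fasta"),
             hits = file.path(dir, "hits.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(corpus$queries$sequence,
                                           corpus$queries$id)),
    paths[["queries"]], width = 60L)
  utils::write.table(corpus$queries[, c("id", "labels")], paths[["truth"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_mcsbase(corpus$db, paths[["mcsbase"]])
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(corpus$ss), paths[["ss"]], width = 60L)
  write_hits_tsv(corpus$hits, paths[["hits"]])
  paths
}

#' Read a truth-label TSV
#'
#' @param path Two-column TSV (`chain_id`, `{O,D}` label string), no header.
#' @return Named character vector of label strings.
#' @export
read_truth_tsv <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  stats::setNames(tab[[2]], tab[[1]])
}
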
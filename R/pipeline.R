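# File-based orchestration: featurize, train, predict, evaluate, sweep.
# Errors raised here carry classes ("idrcrf_input_error",
# "idrcrf_dimension_error") that the command-line wrapper maps to exit
# codes 2 and 3.

input_error <- function(fmt, ...) {
  stop(structure(class = c("idrcrf_input_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

dimension_error <- function(fmt, ...) {
  stop(structure(class = c("idrcrf_dimension_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

check_paths <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    input_error("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  invisible(paths)
}

# Feature matrices for a set of query sequences from files already parsed
# into objects: per-query conservation profile + one-hot SS.
featurize_queries <- function(queries, db, hits, ss,
                              e_threshold = 10, S = 10L) {
  lapply(seq_len(nrow(queries)), function(i) {
    id <- queries$id[i]
    if (is.null(ss[[id]]) || is.na(ss[[id]])) {
      dimension_error("no secondary-structure record for chain '%s'", id)
    }
    if (nchar(ss[[id]]) != nchar(queries$sequence[i])) {
      dimension_error("SS length %d != sequence length %d for chain '%s'",
                      nchar(ss[[id]]), nchar(queries$sequence[i]), id)
    }
    h <- hits[hits$query_id == id, , drop = FALSE]
    class(h) <- c("alignment_hits", "data.frame")
    prof <- mcs_for_query(queries$sequence[i], db, h,
                          e_threshold = e_threshold, S = S)
    tryCatch(assemble_features(prof, encode_ss(ss[[id]])),
             error = function(e) dimension_error("chain '%s': %s", id,
                                                 conditionMessage(e)))
  })
}

read_query_table <- function(queries_path) {
  seqs <- read_fasta_named(queries_path)
  data.frame(id = names(seqs), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Train the disorder CRF from pipeline input files
#'
#' Reads query sequences (FASTA), two-state truth labels (TSV), the
#' knowledge database, secondary-structure strings and alignment hits;
#' three-states the truth with near-disorder width `K`; optionally drops
#' database records exactly matching a training query (the fairness rule);
#' featurizes; fits [idr_crf()]; and serializes the model.
#'
#' @param queries,truth,mcsbase,ss,hits Input file paths (formats per
#'   [write_corpus()]).
#' @param model_out Output path for the serialized model.
#' @param K Near-disorder width (default 5).
#' @param e_threshold,S Hit-selection parameters.
#' @param exclude_exact_matches Apply [exclude_matches()] against the
#'   training queries (default `TRUE`).
#' @param sigma2,max_iter,tol,seed Passed to [idr_crf()].
#' @param quiet Suppress the progress log on stderr.
#' @return The fitted `idr_crf` (invisibly); the model file is written.
#' @export
run_train <- function(queries, truth, mcsbase, ss, hits, model_out,
                      K = 5L, e_threshold = 10, S = 10L,
                      exclude_exact_matches = TRUE,
                      sigma2 = 10, max_iter = 200L, tol = 1e-6, seed = 1L,
                      quiet = FALSE) {
  check_paths(queries, truth, mcsbase, ss, hits)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  qtab <- tryCatch(read_query_table(queries),
                   error = function(e) if (inherits(e, "idrcrf_input_error")) stop(e) else
                     input_error("cannot read queries '%s': %s", queries,
                                 conditionMessage(e)))
  if (nrow(qtab) == 0L) input_error("empty training set: %s", queries)
  truth_labels <- read_truth_tsv(truth)
  db <- read_mcsbase(mcsbase)
  ss_tab <- read_ss_fasta(ss)
  hit_tab <- read_hits_tsv(hits)
  miss <- setdiff(qtab$id, names(truth_labels))
  if (length(miss)) input_error("no truth labels for chain(s): %s",
                                paste(miss, collapse = ", "))
  if (exclude_exact_matches) {
    n0 <- nrow(db)
    db <- exclude_matches(db, qtab$sequence)
    log_msg("fairness filter: dropped %d exact-match record(s) from the database",
            n0 - nrow(db))
    # hits against excluded records no longer resolve and are dropped too
    hit_tab <- hit_tab[hit_tab$subject_id %in% db$id, , drop = FALSE]
    class(hit_tab) <- c("alignment_hits", "data.frame")
  }
  y <- lapply(qtab$id, function(id) {
    lab <- truth_labels[[id]]
    if (nchar(lab) != nchar(qtab$sequence[qtab$id == id])) {
      dimension_error("truth labels length mismatch for chain '%s'", id)
    }
    add_near_disorder(lab, K)
  })
  log_msg("featurizing %d training chain(s) against %d database record(s)",
          nrow(qtab), nrow(db))
  x <- featurize_queries(qtab, db, hit_tab, ss_tab,
                         e_threshold = e_threshold, S = S)
  log_msg("fitting CRF (sigma2=%g, max_iter=%d, seed=%d)", sigma2, max_iter,
          as.integer(seed))
  fit <- idr_crf(x, y, sigma2 = sigma2, max_iter = max_iter, tol = tol,
                 seed = seed)
  write_crf_model(fit, model_out)
  log_msg("objective %.3f after %d evaluation(s); training token accuracy %.4f; model written to %s",
          fit$objective, fit$niter, fit$token_accuracy, model_out)
  invisible(fit)
}

#' Predict disorder for query chains from pipeline input files
#'
#' @param model Path to a serialized model ([write_crf_model()]) or an
#'   `idr_crf` object.
#' @param queries,mcsbase,ss,hits Input file paths.
#' @param out Output TSV path.
#' @param e_threshold,S Hit-selection parameters.
#' @param scheme,tau Decision scheme reducing the three-class posterior to
#'   the binary call column.
#' @return Invisibly, the prediction data.frame: `chain_id`, `position`
#'   (1-based), `residue`, `P_order`, `P_near`, `P_disorder` (6 decimals in
#'   the file), `three_state_call`, `binary_call` (`O`/`D`).
#' @export
run_predict <- function(model, queries, mcsbase, ss, hits, out,
                        e_threshold = 10, S = 10L,
                        scheme = c("I", "II"), tau = NULL) {
  scheme <- match.arg(scheme)
  check_paths(queries, mcsbase, ss, hits)
  if (is.character(model)) {
    check_paths(model)
    model <- read_crf_model(model)
  }
  qtab <- read_query_table(queries)
  db <- read_mcsbase(mcsbase)
  ss_tab <- read_ss_fasta(ss)
  hit_tab <- read_hits_tsv(hits)
  x <- featurize_queries(qtab, db, hit_tab, ss_tab,
                         e_threshold = e_threshold, S = S)
  marg <- predict(model, x, type = "marginal")
  rows <- lapply(seq_len(nrow(qtab)), function(i) {
    m <- marg[[i]]
    mask <- apply_scheme(m, scheme, tau)
    data.frame(chain_id = qtab$id[i],
               position = seq_len(nrow(m)),
               residue = strsplit(qtab$sequence[i], "")[[1]],
               P_order = m[, 1L], P_near = m[, 2L], P_disorder = m[, 3L],
               three_state_call = strsplit(base_call(m), "")[[1]],
               binary_call = ifelse(mask, "D", "O"),
               stringsAsFactors = FALSE)
  })
  pred <- do.call(rbind, rows)
  fmt <- pred
  fmt$P_order <- sprintf("%.6f", fmt$P_order)
  fmt$P_near <- sprintf("%.6f", fmt$P_near)
  fmt$P_disorder <- sprintf("%.6f", fmt$P_disorder)
  utils::write.table(fmt, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pred)
}

#' Read a prediction TSV written by [run_predict()]
#'
#' @param path Prediction file path.
#' @return data.frame with the columns documented in [run_predict()].
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "numeric", "numeric", "numeric",
                                   "character", "character"))
}

#' Evaluate pipeline predictions against two-state truth
#'
#' Pools residues over the chains shared between the prediction file and
#' the truth file and computes the full measure set; optionally per-chain
#' bootstrap standard errors. Evaluation is invariant to chain order in the
#' input files.
#'
#' @param predictions Path to a [run_predict()] TSV (or its data.frame).
#' @param truth Path to a truth TSV (or a named character vector of `{O,D}`
#'   strings).
#' @param out_json,out_tsv Optional report output paths.
#' @param bootstrap_reps If > 0, compute bootstrap SEs for Sn, Sp, ACC,
#'   MCC, Sw and AUC with this many replicates.
#' @param bootstrap_frac Chain fraction per replicate (default 0.8).
#' @param seed Bootstrap seed.
#' @return An `eval_report` (with an `SE` component when requested).
#' @export
run_evaluate <- function(predictions, truth, out_json = NULL, out_tsv = NULL,
                         bootstrap_reps = 0L, bootstrap_frac = 0.8,
                         seed = 1L) {
  pred <- if (is.character(predictions)) {
    check_paths(predictions)
    read_predictions(predictions)
  } else predictions
  truth_labels <- if (is.character(truth) && length(truth) == 1L &&
                      file.exists(truth)) read_truth_tsv(truth) else truth
  ids <- intersect(unique(pred$chain_id), names(truth_labels))
  if (!length(ids)) input_error("no overlapping chain ids between predictions and truth")
  ids <- sort(ids)
  pred_list <- list(); truth_list <- list(); score_list <- list()
  for (id in ids) {
    p <- pred[pred$chain_id == id, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    tl <- truth_labels[[id]]
    if (nchar(tl) != nrow(p)) {
      dimension_error("chain '%s': %d predictions vs %d truth labels",
                      id, nrow(p), nchar(tl))
    }
    pred_list[[id]] <- p$binary_call == "D"
    truth_list[[id]] <- tl
    score_list[[id]] <- p$P_disorder
  }
  report <- evaluate_predictions(unlist(pred_list),
                                 strsplit(paste(unlist(truth_list), collapse = ""), "")[[1]],
                                 scores = unlist(score_list))
  if (bootstrap_reps > 0L) {
    report$SE <- vapply(c("Sn", "Sp", "ACC", "MCC", "Sw", "AUC"), function(ms) {
      bootstrap_se(pred_list, truth_list, measure = ms,
                   scores_list = score_list, frac = bootstrap_frac,
                   reps = bootstrap_reps, seed = seed)
    }, numeric(1))
  }
  if (!is.null(out_json)) {
    cc <- report$counts
    payload <- list(TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
                    Sn = report$Sn, Sp = report$Sp, ACC = report$ACC,
                    MCC = report$MCC, Sw = report$Sw, AUC = report$AUC)
    if (!is.null(report$SE)) payload$SE <- as.list(report$SE)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
               out_json)
  }
  if (!is.null(out_tsv)) {
    tab <- data.frame(measure = c("Sn", "Sp", "ACC", "MCC", "Sw", "AUC"),
                      value = c(report$Sn, report$Sp, report$ACC,
                                report$MCC, report$Sw, report$AUC))
    utils::write.table(format(tab, digits = 6), out_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  report
}

#' Threshold sweep over pipeline predictions
#'
#' @inheritParams run_evaluate
#' @param scheme Decision scheme to sweep (`"I"` or `"II"`).
#' @param grid Threshold grid (default `seq(0, 1, by = 0.01)`).
#' @param out Optional TSV path for the sweep table.
#' @return The [sweep_threshold()] result.
#' @export
run_sweep <- function(predictions, truth, scheme = c("I", "II"),
                      grid = seq(0, 1, by = 0.01), out = NULL) {
  scheme <- match.arg(scheme)
  pred <- if (is.character(predictions)) {
    check_paths(predictions)
    read_predictions(predictions)
  } else predictions
  truth_labels <- if (is.character(truth) && length(truth) == 1L &&
                      file.exists(truth)) read_truth_tsv(truth) else truth
  ids <- sort(intersect(unique(pred$chain_id), names(truth_labels)))
  if (!length(ids)) input_error("no overlapping chain ids between predictions and truth")
  marg <- lapply(ids, function(id) {
    p <- pred[pred$chain_id == id, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    as.matrix(p[, c("P_order", "P_near", "P_disorder")])
  })
  res <- sweep_threshold(marg, unname(truth_labels[ids]), scheme = scheme,
                         grid = grid)
  if (!is.null(out)) write_sweep_tsv(res, out)
  res
}
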
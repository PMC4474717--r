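# Reduction of three-class posteriors to binary order/disorder calls.

#' Base three-state call from posterior marginals
#'
#' Per-position argmax of the (O, N, D) posterior; exact ties are broken
#' toward disorder, then near-disorder (D > N > O), the conservative choice
#' for a rare positive class.
#'
#' @param marginals L x 3 matrix, columns in order (O, N, D).
#' @return `{O,N,D}` label string.
#' @export
base_call <- function(marginals) {
  m <- as.matrix(marginals)
  stopifnot(ncol(m) == 3L)
  if (!nrow(m)) return("")
  # argmax over reversed columns -> first max is D, then N, then O
  idx <- 4L - max.col(m[, 3:1, drop = FALSE], ties.method = "first")
  paste(RESIDUE_STATES[idx], collapse = "")
}

#' Decision scheme I: threshold the near-disorder probability
#'
#' A residue is called disorder when its base three-state call is `D`, or
#' when it is not `D` but its near-disorder posterior exceeds `tau`
#' (strictly). Everything else is order. The default `tau = 0.4` is the
#' operating point that maximizes the weighted score in the original
#' calibration of this rule.
#'
#' @param marginals L x 3 posterior matrix (columns O, N, D).
#' @param tau Threshold in `[0, 1]` (default 0.4).
#' @return Logical vector, `TRUE` = disorder.
#' @export
apply_scheme_I <- function(marginals, tau = 0.4) {
  stopifnot(tau >= 0, tau <= 1)
  m <- as.matrix(marginals)
  base <- strsplit(base_call(m), "")[[1]]
  as.logical(base == "D" | (base != "D" & m[, 2L] > tau))
}

#' Decision scheme II: threshold the disorder probability
#'
#' A residue is called disorder when its disorder posterior exceeds `tau`
#' (strictly). The default `tau = 0.03` is the weighted-score-maximizing
#' operating point of the original calibration; its small value reflects the
#' rarity of the disorder class.
#'
#' @inheritParams apply_scheme_I
#' @param tau Threshold in `[0, 1]` (default 0.03).
#' @return Logical vector, `TRUE` = disorder.
#' @export
apply_scheme_II <- function(marginals, tau = 0.03) {
  stopifnot(tau >= 0, tau <= 1)
  m <- as.matrix(marginals)
  as.logical(m[, 3L] > tau)
}

#' Apply a decision scheme by name
#'
#' @param marginals L x 3 posterior matrix.
#' @param scheme `"I"` or `"II"`.
#' @param tau Threshold; defaults to 0.4 (scheme I) or 0.03 (scheme II).
#' @return Logical disorder mask.
#' @export
apply_scheme <- function(marginals, scheme = c("I", "II"), tau = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "I") {
    apply_scheme_I(marginals, tau %||% 0.4)
  } else {
    apply_scheme_II(marginals, tau %||% 0.03)
  }
}

#' Sweep a decision threshold and locate the weighted-score optimum
#'
#' Evaluates a decision scheme over a grid of thresholds against two-state
#' ground truth, pooling residues over chains, and reports sensitivity,
#' specificity and the weighted score Sw at each grid point. The optimal
#' threshold is the grid point maximizing Sw; ties go to the smallest tau.
#' For scheme II the (Sn, 1 - Sp) pairs across the sweep trace the ROC of
#' the disorder posterior.
#'
#' @param marginals List of L x 3 posterior matrices, one per chain.
#' @param truth List (or vector) of `{O,D}` two-state truth strings.
#' @param scheme `"I"` or `"II"`.
#' @param grid Numeric threshold grid (default `seq(0, 1, by = 0.01)`).
#' @return List with `table` (data.frame: tau, TP, FP, TN, FN, Sn, Sp, Sw)
#'   and `tau_star`.
#' @export
sweep_threshold <- function(marginals, truth, scheme = c("I", "II"),
                            grid = seq(0, 1, by = 0.01)) {
  scheme <- match.arg(scheme)
  if (!length(grid)) stop("threshold grid must be non-empty", call. = FALSE)
  if (is.matrix(marginals)) marginals <- list(marginals)
  truth_chars <- strsplit(paste(unlist(truth), collapse = ""), "")[[1]]
  rows <- lapply(grid, function(tau) {
    pred <- unlist(lapply(marginals, apply_scheme, scheme = scheme, tau = tau))
    cc <- confusion(pred, truth_chars)
    r <- basic_rates(cc)
    data.frame(tau = tau, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               Sn = r[["Sn"]], Sp = r[["Sp"]], Sw = sw(cc))
  })
  tab <- do.call(rbind, rows)
  tau_star <- tab$tau[which.max(tab$Sw)]   # first max: smallest tau on ties
  list(table = tab, tau_star = tau_star)
}

#' Write a threshold-sweep table as TSV
#'
#' @param sweep Result of [sweep_threshold()].
#' @param path Output path.
#' @export
write_sweep_tsv <- function(sweep, path) {
  utils::write.table(sweep$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
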
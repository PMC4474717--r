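# Binary evaluation with disorder as the positive class. Ground truth is
# always the pre-augmentation two-state annotation: predicted near-disorder
# never reaches evaluation, it is resolved by a decision scheme first.

#' Confusion counts for binary disorder calls
#'
#' @param pred Logical disorder mask (`TRUE` = disorder), or a `{O,D}`
#'   character vector/string.
#' @param truth Two-state truth: `{O,D}` character vector or string, or a
#'   logical mask.
#' @return List of class `confusion_counts`: `TP`, `FP`, `TN`, `FN`, plus
#'   the class totals `Nd = TP + FN` and `No = TN + FP`.
#' @export
confusion <- function(pred, truth) {
  pred <- as_disorder_mask(pred)
  truth <- as_disorder_mask(truth)
  if (length(pred) != length(truth)) {
    stop(sprintf("length mismatch: %d predictions vs %d truth labels",
                 length(pred), length(truth)), call. = FALSE)
  }
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth)
  fn <- sum(!pred & truth)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 Nd = tp + fn, No = tn + fp),
            class = "confusion_counts")
}

as_disorder_mask <- function(x) {
  if (is.logical(x)) return(x)
  if (is.character(x)) {
    if (length(x) == 1L && nchar(x) != 1L) x <- strsplit(x, "")[[1]]
    bad <- setdiff(unique(x), c("O", "D"))
    if (length(bad)) {
      stop(sprintf("two-state labels must be over {O,D}; found: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    return(x == "D")
  }
  stop("expected a logical mask or {O,D} labels", call. = FALSE)
}

#' Sensitivity, specificity and balanced accuracy (percent)
#'
#' Sn = 100 TP / Nd, Sp = 100 TN / No, ACC = (Sn + Sp) / 2. A rate whose
#' class is absent is reported as `NA` and propagates into ACC.
#'
#' @param c A [confusion()] result.
#' @return Named numeric vector `c(Sn, Sp, ACC)` in percent.
#' @export
basic_rates <- function(c) {
  sn <- if (c$Nd > 0) 100 * c$TP / c$Nd else NA_real_
  sp <- if (c$No > 0) 100 * c$TN / c$No else NA_real_
  c(Sn = sn, Sp = sp, ACC = (sn + sp) / 2)
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' When any factor of the denominator is zero the coefficient is undefined;
#' 0 is returned with attribute `undefined = TRUE` so reports stay numeric.
#'
#' @param c A [confusion()] result.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$TP); fp <- as.numeric(c$FP)
  tn <- as.numeric(c$TN); fn <- as.numeric(c$FN)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    return(structure(0, undefined = TRUE))
  }
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Weighted score Sw (percent)
#'
#' Class-weighted accuracy
#' \deqn{S_w = \frac{W_d TP - W_o FP + W_o TN - W_d FN}{W_d N_d + W_o N_o}}
#' where the weight attached to the disorder terms is the ordered-residue
#' fraction \eqn{W_d = N_o/(N_d+N_o)} and vice versa
#' \eqn{W_o = N_d/(N_d+N_o)}, so each class contributes in proportion to the
#' other's prevalence. Algebraically identical to Sn + Sp - 100 (percent),
#' which the test suite verifies on random tables; both classes must be
#' present.
#'
#' @param c A [confusion()] result.
#' @return Sw in percent (`NA` if a class is absent).
#' @export
sw <- function(c) {
  if (c$Nd == 0 || c$No == 0) return(NA_real_)
  n <- c$Nd + c$No
  wo <- c$Nd / n   # weight carried by the order terms: disordered fraction
  wd <- c$No / n   # weight carried by the disorder terms: ordered fraction
  100 * (wd * c$TP - wo * c$FP + wo * c$TN - wd * c$FN) /
    (wd * c$Nd + wo * c$No)
}

#' Area under the ROC curve of a disorder score
#'
#' Tie-corrected rank statistic: the probability that a random disordered
#' residue scores above a random ordered one, counting exact ties as one
#' half — equivalently the trapezoidal area under the full ROC curve.
#' Invariant under strictly monotone transforms of the score.
#'
#' @param scores Numeric per-residue scores (typically the disorder
#'   posterior).
#' @param truth Two-state truth (`{O,D}` labels or logical mask).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as_disorder_mask(truth)
  if (length(scores) != length(truth)) {
    stop("scores and truth differ in length", call. = FALSE)
  }
  nd <- sum(truth)
  no <- sum(!truth)
  if (nd == 0 || no == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)   # midranks handle ties
  (sum(r[truth]) - nd * (nd + 1) / 2) / (nd * no)
}

#' ROC curve points of a disorder score
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `Sn`, `FPR` (both in
#'   `[0, 1]`), one row per distinct score plus the endpoints, suitable for
#'   plotting or TSV export.
#' @export
roc_points <- function(scores, truth) {
  truth <- as_disorder_mask(truth)
  nd <- sum(truth)
  no <- sum(!truth)
  if (nd == 0 || no == 0) {
    stop("ROC undefined: both classes must be present", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(sum(pred & truth) / nd, sum(pred & !truth) / no)
  }, numeric(2)))
  data.frame(threshold = thr, Sn = pts[, 1], FPR = pts[, 2])
}

#' Full evaluation report
#'
#' @param pred Logical disorder mask (pooled residues) or `{O,D}` labels.
#' @param truth Two-state truth.
#' @param scores Optional per-residue disorder scores for AUC.
#' @return List of class `eval_report`: `counts` plus `Sn`, `Sp`, `ACC`,
#'   `MCC`, `Sw` (percent where applicable) and `AUC` (or `NA`).
#' @export
evaluate_predictions <- function(pred, truth, scores = NULL) {
  cc <- confusion(pred, truth)
  r <- basic_rates(cc)
  auc <- if (!is.null(scores)) roc_auc(scores, truth) else NA_real_
  structure(list(counts = cc, Sn = r[["Sn"]], Sp = r[["Sp"]], ACC = r[["ACC"]],
                 MCC = as.numeric(mcc(cc)), Sw = sw(cc), AUC = auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cc <- x$counts
  cat("Disorder prediction evaluation (positive = disorder)\n")
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d (Nd=%d, No=%d)\n",
              cc$TP, cc$FP, cc$TN, cc$FN, cc$Nd, cc$No))
  cat(sprintf("  Sn=%.2f%%  Sp=%.2f%%  ACC=%.2f%%  Sw=%.2f%%  MCC=%.4f  AUC=%s\n",
              x$Sn, x$Sp, x$ACC, x$Sw, x$MCC,
              if (is.na(x$AUC)) "NA" else sprintf("%.4f", x$AUC)))
  invisible(x)
}

#' Bootstrap standard error of an evaluation measure
#'
#' Chains (the evaluation "targets") are resampled: each replicate draws
#' `floor(frac * n)` chains without replacement, pools their residues,
#' and recomputes the measure; the standard error is the sample standard
#' deviation across replicates.
#'
#' @param pred_list List of per-chain logical disorder masks (or `{O,D}`
#'   labels).
#' @param truth_list List of per-chain two-state truths.
#' @param measure One of `"Sn"`, `"Sp"`, `"ACC"`, `"MCC"`, `"Sw"`, `"AUC"`;
#'   or a function of `(pred, truth)` returning a scalar.
#' @param scores_list Per-chain score vectors, required for `"AUC"`.
#' @param frac Fraction of chains per replicate (default 0.8).
#' @param reps Number of replicates (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return Standard error (scalar). Replicates where the measure is
#'   undefined (a class absent from the resample) are dropped.
#' @export
bootstrap_se <- function(pred_list, truth_list, measure = "Sw",
                         scores_list = NULL, frac = 0.8, reps = 1000L,
                         seed = 1L) {
  n <- length(pred_list)
  if (n < 2L) stop("bootstrap requires at least 2 chains", call. = FALSE)
  if (reps < 2L) stop("bootstrap requires at least 2 replicates", call. = FALSE)
  if (length(truth_list) != n) stop("pred/truth chain counts differ", call. = FALSE)
  measure_fun <- if (is.function(measure)) {
    measure
  } else {
    nm <- match.arg(measure, c("Sn", "Sp", "ACC", "MCC", "Sw", "AUC"))
    if (nm == "AUC" && is.null(scores_list)) {
      stop("scores_list is required for the AUC measure", call. = FALSE)
    }
    function(idx) {
      truth <- unlist(lapply(truth_list[idx], as_disorder_mask))
      if (nm == "AUC") {
        if (!any(truth) || all(truth)) return(NA_real_)
        return(roc_auc(unlist(scores_list[idx]), truth))
      }
      cc <- confusion(unlist(lapply(pred_list[idx], as_disorder_mask)), truth)
      switch(nm,
             Sn = basic_rates(cc)[["Sn"]],
             Sp = basic_rates(cc)[["Sp"]],
             ACC = basic_rates(cc)[["ACC"]],
             MCC = as.numeric(mcc(cc)),
             Sw = sw(cc))
    }
  }
  k <- max(1L, floor(frac * n))
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(as.integer(reps)), function(r) {
    idx <- sample.int(n, k, replace = FALSE)
    if (is.function(measure)) {
      measure(pred_list[idx], truth_list[idx])
    } else {
      measure_fun(idx)
    }
  }, numeric(1))
  stats::sd(vals[!is.na(vals)])
}
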
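# Independent oracles used across the suite. These deliberately avoid the
# package's own recursions: the CRF oracle enumerates every label path, the
# AUC oracle counts disordered/ordered residue pairs directly.

# Exhaustive enumeration over all 3^L label paths of a linear-chain CRF.
# Returns logZ, exact marginals, and the best path (ties toward the label
# earlier in O,N,D order, matching the decoder's contract).
enumerate_crf <- function(W, Tm, E) {
  L <- nrow(E)
  phi <- E %*% t(W)
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))[, L:1, drop = FALSE]
  scores <- apply(paths, 1L, function(y) {
    s <- sum(phi[cbind(seq_len(L), y)])
    if (L > 1L) s <- s + sum(Tm[cbind(y[-L], y[-1L])])
    s
  })
  m <- max(scores)
  logZ <- m + log(sum(exp(scores - m)))
  post <- exp(scores - logZ)
  marg <- matrix(0, L, 3L)
  for (p in seq_len(L)) {
    for (s in 1:3) marg[p, s] <- sum(post[paths[, p] == s])
  }
  # expand.grid varies the first factor fastest; after column reversal the
  # first row is all-1 and ties resolve toward lower label indices
  best <- paths[which.max(scores), ]
  list(logZ = logZ, marginals = marg,
       best_path = paste(c("O", "N", "D")[best], collapse = ""),
       best_score = max(scores))
}

# Pair-counting AUC: P(score_D > score_O) + 0.5 P(equal) over all D-O pairs.
brute_auc <- function(scores, truth_mask) {
  d <- scores[truth_mask]
  o <- scores[!truth_mask]
  tot <- 0
  for (x in d) tot <- tot + sum(x > o) + 0.5 * sum(x == o)
  tot / (length(d) * length(o))
}

random_confusion <- function() {
  list(TP = sample(0:200, 1), FP = sample(0:200, 1),
       TN = sample(0:200, 1), FN = sample(0:200, 1))
}

# Random small CRF instance for oracle comparisons.
random_crf_instance <- function(L, F = 3L, offsets = -1:1) {
  fm <- matrix(stats::rnorm(L * F), L, F)
  E <- expand_features(fm, offsets)
  W <- matrix(stats::rnorm(3L * ncol(E), sd = 0.7), 3L, ncol(E))
  Tm <- matrix(stats::rnorm(9L, sd = 0.7), 3L, 3L)
  list(E = E, W = W, Tm = Tm, fm = fm)
}

# Small fast corpus for pipeline tests.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_families = 6L, length_range = c(60L, 120L),
                                 n_homologs = 4L),
                            list(...))
  do.call(synth_config, args)
}
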
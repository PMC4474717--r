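# Linear-chain CRF over labels (O, N, D) with linear (real-valued) unigram
# potentials and label-pair transition weights. All recursions run in the
# log domain.

#' Expand a feature matrix over a window template
#'
#' For every position the features of neighbouring positions at the template
#' offsets are concatenated (default -4..+4: four upward and four downward
#' neighbours plus the position itself), followed by a constant bias 1.
#' Offsets falling outside the chain contribute zeros, matching the
#' "no observation" semantics of zero-coverage conservation rows.
#'
#' @param fm L x F numeric feature matrix.
#' @param offsets Integer offsets, must contain 0 (default `-4:4`).
#' @return L x (F*|offsets| + 1) matrix; column block `k` holds the features
#'   at offset `offsets[k]`.
#' @export
expand_features <- function(fm, offsets = -4:4) {
  offsets <- as.integer(offsets)
  stopifnot(0L %in% offsets)
  fm <- as.matrix(fm)
  L <- nrow(fm)
  F <- ncol(fm)
  out <- matrix(0, nrow = L, ncol = F * length(offsets) + 1L)
  if (L > 0L) {
    for (k in seq_along(offsets)) {
      o <- offsets[k]
      src <- seq_len(L) + o
      ok <- src >= 1L & src <= L
      cols <- (k - 1L) * F + seq_len(F)
      out[ok, cols] <- fm[src[ok], , drop = FALSE]
    }
    out[, F * length(offsets) + 1L] <- 1
  }
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# State (emission) log-potentials: E (L x P expanded features) times W'
# (3 x P state weights) -> L x 3.
crf_potentials <- function(W, E) E %*% t(W)

#' Forward-backward recursion: partition function and posterior marginals
#'
#' Computes the exact posterior label probabilities of every position under
#' the chain model, and the log partition function. The backward recursion
#' recomputes logZ independently; the two agree to numerical precision, a
#' property asserted by the test suite.
#'
#' @param W 3 x P state-weight matrix (rows in label order O, N, D).
#' @param Tm 3 x 3 transition-weight matrix (`Tm[i, j]` scores label `i`
#'   followed by label `j`).
#' @param E L x P expanded feature matrix from [expand_features()].
#' @return List: `logZ`, `marginals` (L x 3, rows sum to 1), and the log
#'   `alpha`/`beta` tables and emission scores `phi` for internal reuse.
#' @export
forward_backward <- function(W, Tm, E) {
  if (ncol(E) != ncol(W)) {
    stop(sprintf("dimension mismatch: expanded features have %d columns, weights %d",
                 ncol(E), ncol(W)), call. = FALSE)
  }
  L <- nrow(E)
  phi <- crf_potentials(W, E)
  alpha <- matrix(0, L, 3L)
  beta <- matrix(0, L, 3L)
  alpha[1L, ] <- phi[1L, ]
  eTm <- exp(Tm)
  if (L > 1L) {
    for (p in 2:L) {
      prev <- alpha[p - 1L, ]
      m <- max(prev)
      alpha[p, ] <- phi[p, ] + m + log(as.vector(exp(prev - m) %*% eTm))
    }
    for (p in (L - 1L):1L) {
      nxt <- beta[p + 1L, ] + phi[p + 1L, ]
      m <- max(nxt)
      beta[p, ] <- m + log(as.vector(eTm %*% exp(nxt - m)))
    }
  }
  logZ <- log_sum_exp(alpha[L, ])
  logZ_b <- log_sum_exp(beta[1L, ] + phi[1L, ])
  lm <- alpha + beta - logZ
  marg <- exp(lm)
  marg <- marg / rowSums(marg)
  colnames(marg) <- RESIDUE_STATES
  list(logZ = logZ, logZ_backward = logZ_b, marginals = marg,
       alpha = alpha, beta = beta, phi = phi)
}

#' Viterbi decoding: most probable label path
#'
#' Maximizes the joint chain score. Ties are broken toward the label earlier
#' in the order (O, N, D) at every backtrack step, so an all-zero model
#' decodes to all-`O` deterministically.
#'
#' @inheritParams forward_backward
#' @return `{O,N,D}` label string of length `nrow(E)`.
#' @export
viterbi <- function(W, Tm, E) {
  if (ncol(E) != ncol(W)) {
    stop("dimension mismatch between expanded features and weights", call. = FALSE)
  }
  L <- nrow(E)
  if (L == 0L) return("")
  phi <- crf_potentials(W, E)
  delta <- matrix(-Inf, L, 3L)
  back <- matrix(1L, L, 3L)
  delta[1L, ] <- phi[1L, ]
  if (L > 1L) {
    for (p in 2:L) {
      for (j in 1:3) {
        sc <- delta[p - 1L, ] + Tm[, j]
        back[p, j] <- which.max(sc)   # first max: tie toward O, then N
        delta[p, j] <- sc[back[p, j]] + phi[p, j]
      }
    }
  }
  path <- integer(L)
  path[L] <- which.max(delta[L, ])
  if (L > 1L) {
    for (p in L:2) path[p - 1L] <- back[p, path[p]]
  }
  paste(RESIDUE_STATES[path], collapse = "")
}

# Penalized conditional log-likelihood and analytic gradient over a dataset.
# expanded: list of L x P matrices; ylist: list of integer label vectors
# (1=O, 2=N, 3=D). Returns function value (to MINIMIZE: negative penalized
# log-likelihood) and gradient, parameter vector layout c(W, Tm).
crf_objective <- function(par, expanded, ylist, sigma2) {
  P <- ncol(expanded[[1]])
  W <- matrix(par[seq_len(3L * P)], nrow = 3L, ncol = P)
  Tm <- matrix(par[3L * P + seq_len(9L)], 3L, 3L)
  ll <- 0
  gW <- matrix(0, 3L, P)
  gT <- matrix(0, 3L, 3L)
  for (i in seq_along(expanded)) {
    E <- expanded[[i]]
    y <- ylist[[i]]
    L <- nrow(E)
    fb <- forward_backward(W, Tm, E)
    # observed score
    ll <- ll + sum(fb$phi[cbind(seq_len(L), y)]) - fb$logZ
    if (L > 1L) ll <- ll + sum(Tm[cbind(y[-L], y[-1L])])
    # observed - expected feature counts
    Yind <- matrix(0, L, 3L)
    Yind[cbind(seq_len(L), y)] <- 1
    gW <- gW + t(Yind - fb$marginals) %*% E
    if (L > 1L) {
      obsT <- matrix(0, 3L, 3L)
      trans <- table(factor(y[-L], levels = 1:3), factor(y[-1L], levels = 1:3))
      obsT[] <- as.numeric(trans)
      expT <- matrix(0, 3L, 3L)
      for (p in 2:L) {
        q <- outer(fb$alpha[p - 1L, ], fb$phi[p, ] + fb$beta[p, ], `+`) +
          Tm - fb$logZ
        expT <- expT + exp(q)
      }
      gT <- gT + obsT - expT
    }
  }
  pen <- sum(par^2) / (2 * sigma2)
  gpen <- par / sigma2
  list(value = -(ll - pen), gradient = -(c(gW, gT) - gpen),
       loglik = ll, penalized = ll - pen)
}
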
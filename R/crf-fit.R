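#' Fit the disorder-tagging conditional random field
#'
#' Trains a linear-chain CRF over the three residue states (order,
#' near-disorder, disorder) from per-chain feature matrices. State
#' potentials are linear in the windowed features (each of the 12 feature
#' columns expanded over the template offsets, default -4..+4, plus a bias),
#' and a 3 x 3 label-pair transition matrix couples neighbouring residues.
#' The fit maximizes the L2-penalized conditional log-likelihood
#' \deqn{\sum_i \log P(y_i \mid x_i) - \lVert w \rVert^2 / (2\sigma^2)}
#' by L-BFGS with the analytic gradient (observed minus expected feature
#' counts from the forward-backward recursion). Weights are initialized at
#' zero, so the fit is deterministic.
#'
#' @param x List of L x 12 feature matrices (see [assemble_features()]).
#' @param y List of `{O,N,D}` label strings matching `x` in length.
#' @param sigma2 L2 regularization variance (default 10).
#' @param max_iter Maximum L-BFGS iterations (default 200); `0` returns the
#'   zero-weight model.
#' @param tol Relative objective tolerance for convergence (default 1e-6).
#' @param offsets Window template offsets (default `-4:4`; must contain 0).
#' @param seed Integer recorded in the object; the deterministic zero
#'   initialization means it does not affect the fit.
#' @return Object of class `idr_crf` with components `W` (3 x P state
#'   weights), `Tm` (3 x 3 transitions), `offsets`, `n_features`, `sigma2`,
#'   `logLik` (unpenalized conditional log-likelihood at the optimum),
#'   `objective` (penalized), `niter`, `convergence`, `token_accuracy`
#'   (training Viterbi accuracy), `n_chains`, `n_tokens`.
#' @examples
#' fm <- matrix(runif(20 * 12), ncol = 12)
#' fit <- idr_crf(list(fm), list(strrep("O", 20)), max_iter = 5)
#' predict(fit, list(fm), type = "viterbi")
#' @export
idr_crf <- function(x, y, sigma2 = 10, max_iter = 200L, tol = 1e-6,
                    offsets = -4:4, seed = 1L) {
  stopifnot(sigma2 > 0, max_iter >= 0L, tol > 0)
  if (!length(x)) stop("empty training set", call. = FALSE)
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  x <- lapply(x, as.matrix)
  nf <- unique(vapply(x, ncol, integer(1)))
  if (length(nf) != 1L) stop("feature matrices differ in column count", call. = FALSE)
  ylist <- vector("list", length(y))
  for (i in seq_along(y)) {
    yi <- match(strsplit(y[[i]], "")[[1]], RESIDUE_STATES)
    if (anyNA(yi)) stop(sprintf("labels of chain %d contain symbols outside {O,N,D}", i),
                        call. = FALSE)
    if (length(yi) != nrow(x[[i]])) {
      stop(sprintf("chain %d: %d labels for %d feature rows", i,
                   length(yi), nrow(x[[i]])), call. = FALSE)
    }
    ylist[[i]] <- yi
  }
  expanded <- lapply(x, expand_features, offsets = offsets)
  P <- nf * length(offsets) + 1L
  npar <- 3L * P + 9L
  par0 <- numeric(npar)

  trace_env <- new.env(parent = emptyenv())
  trace_env$trace <- numeric()
  fn <- function(par) {
    v <- crf_objective(par, expanded, ylist, sigma2)$value
    trace_env$trace <- c(trace_env$trace, -v)
    v
  }
  gr <- function(par) crf_objective(par, expanded, ylist, sigma2)$gradient

  if (max_iter == 0L) {
    par <- par0
    niter <- 0L
    conv <- 0L
  } else {
    opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = as.integer(max_iter),
                                       factr = tol / .Machine$double.eps))
    par <- opt$par
    niter <- opt$counts[["function"]]
    conv <- opt$convergence
  }
  W <- matrix(par[seq_len(3L * P)], 3L, P)
  Tm <- matrix(par[3L * P + seq_len(9L)], 3L, 3L,
               dimnames = list(RESIDUE_STATES, RESIDUE_STATES))
  obj <- crf_objective(par, expanded, ylist, sigma2)

  pred <- vapply(expanded, function(E) viterbi(W, Tm, E), character(1))
  truth <- vapply(ylist, function(yi) paste(RESIDUE_STATES[yi], collapse = ""),
                  character(1))
  tok_ok <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, pred, truth))
  n_tok <- sum(lengths(ylist))

  structure(list(W = W, Tm = Tm, offsets = as.integer(offsets),
                 n_features = nf, sigma2 = sigma2,
                 logLik = obj$loglik, objective = obj$penalized,
                 trace = trace_env$trace,
                 niter = niter, convergence = conv,
                 token_accuracy = tok_ok / n_tok,
                 n_chains = length(x), n_tokens = n_tok,
                 seed = as.integer(seed), call = match.call()),
            class = "idr_crf")
}

#' Predict from a fitted disorder CRF
#'
#' @param object An [idr_crf()] fit.
#' @param newdata List of L x 12 feature matrices (or a single matrix).
#' @param type `"marginal"` for posterior per-residue probabilities (list of
#'   L x 3 matrices, columns O/N/D), `"viterbi"` for MAP label strings,
#'   `"class"` for per-residue argmax label strings (ties toward D, then N).
#' @param ... Unused.
#' @return List parallel to `newdata` (marginal matrices or label strings).
#' @export
predict.idr_crf <- function(object, newdata, type = c("marginal", "viterbi", "class"),
                            ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(newdata)
  out <- lapply(newdata, function(fm) {
    fm <- as.matrix(fm)
    if (ncol(fm) != object$n_features) {
      stop(sprintf("newdata has %d feature columns; model expects %d",
                   ncol(fm), object$n_features), call. = FALSE)
    }
    E <- expand_features(fm, object$offsets)
    switch(type,
           marginal = forward_backward(object$W, object$Tm, E)$marginals,
           viterbi = viterbi(object$W, object$Tm, E),
           class = base_call(forward_backward(object$W, object$Tm, E)$marginals))
  })
  out
}

#' @export
print.idr_crf <- function(x, ...) {
  cat("Linear-chain CRF for protein disorder tagging\n")
  cat(sprintf("  labels: %s; features: %d x %d offsets + bias (%d state weights)\n",
              paste(RESIDUE_STATES, collapse = "/"), x$n_features,
              length(x$offsets), length(x$W)))
  cat(sprintf("  chains: %d (%d residues); sigma2 = %g\n",
              x$n_chains, x$n_tokens, x$sigma2))
  cat(sprintf("  conditional logLik: %.3f; training token accuracy: %.4f\n",
              x$logLik, x$token_accuracy))
  invisible(x)
}

#' @export
summary.idr_crf <- function(object, ...) {
  structure(list(fit = object), class = "summary.idr_crf")
}

#' @export
print.summary.idr_crf <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  objective (penalized logLik): %.3f after %d evaluation(s), convergence code %d\n",
              f$objective, f$niter, f$convergence))
  cat("  transition weights:\n")
  print(round(f$Tm, 4))
  w <- f$W
  cat(sprintf("  |state weights|: max %.4f, mean %.4f\n",
              max(abs(w)), mean(abs(w))))
  invisible(x)
}

#' @export
coef.idr_crf <- function(object, ...) {
  list(state = object$W, transition = object$Tm)
}

#' @export
logLik.idr_crf <- function(object, ...) {
  structure(object$logLik, df = length(object$W) + length(object$Tm),
            nobs = object$n_tokens, class = "logLik")
}

#' @export
plot.idr_crf <- function(x, ...) {
  if (!length(x$trace)) {
    warning("no objective trace recorded (max_iter = 0)")
    return(invisible(x))
  }
  plot(seq_along(x$trace), x$trace, type = "l",
       xlab = "objective evaluation", ylab = "penalized log-likelihood",
       main = "CRF training trajectory", ...)
  invisible(x)
}

#' Sample label paths from the posterior of a fitted CRF
#'
#' Exact posterior path sampling by the forward-filtering backward-sampling
#' recursion.
#'
#' @param object An [idr_crf()] fit.
#' @param nsim Number of paths per chain (default 1).
#' @param seed Optional integer seed.
#' @param newdata List of feature matrices (or a single matrix).
#' @param ... Unused.
#' @return List (per chain) of character vectors of `nsim` label strings.
#' @export
simulate.idr_crf <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(newdata)) newdata <- list(newdata)
  lapply(newdata, function(fm) {
    E <- expand_features(as.matrix(fm), object$offsets)
    fb <- forward_backward(object$W, object$Tm, E)
    L <- nrow(E)
    vapply(seq_len(nsim), function(s) {
      path <- integer(L)
      pL <- exp(fb$alpha[L, ] - max(fb$alpha[L, ]))
      path[L] <- sample.int(3L, 1L, prob = pL)
      if (L > 1L) {
        for (p in (L - 1L):1L) {
          lp <- fb$alpha[p, ] + object$Tm[, path[p + 1L]]
          path[p] <- sample.int(3L, 1L, prob = exp(lp - max(lp)))
        }
      }
      paste(RESIDUE_STATES[path], collapse = "")
    }, character(1))
  })
}

#' Serialize a fitted CRF to portable JSON
#'
#' Versioned text representation (label alphabet, template offsets, weight
#' arrays at full precision); [read_crf_model()] restores it bit-exactly.
#'
#' @param object An [idr_crf()] fit.
#' @param path Output path.
#' @export
write_crf_model <- function(object, path) {
  stopifnot(inherits(object, "idr_crf"))
  payload <- list(
    format = "idrcrf-model",
    version = 1L,
    labels = RESIDUE_STATES,
    offsets = object$offsets,
    n_features = object$n_features,
    sigma2 = object$sigma2,
    seed = object$seed,
    logLik = object$logLik,
    token_accuracy = object$token_accuracy,
    W = sprintf("%.17g", as.vector(object$W)),
    Tm = sprintf("%.17g", as.vector(object$Tm)))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Restore a fitted CRF from JSON
#'
#' @param path Path written by [write_crf_model()].
#' @return An object of class `idr_crf` (weights and metadata; no training
#'   trace).
#' @export
read_crf_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$format, "idrcrf-model")) {
    stop("not an idrcrf model file", call. = FALSE)
  }
  W <- matrix(as.numeric(payload$W), nrow = 3L)
  Tm <- matrix(as.numeric(payload$Tm), 3L, 3L)
  dimnames(Tm) <- list(RESIDUE_STATES, RESIDUE_STATES)
  structure(list(W = W, Tm = Tm, offsets = as.integer(payload$offsets),
                 n_features = as.integer(payload$n_features),
                 sigma2 = payload$sigma2, seed = payload$seed,
                 logLik = payload$logLik,
                 token_accuracy = payload$token_accuracy,
                 trace = numeric(), niter = NA_integer_,
                 convergence = NA_integer_,
                 n_chains = NA_integer_, n_tokens = NA_integer_,
                 call = NULL),
            class = "idr_crf")
}
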
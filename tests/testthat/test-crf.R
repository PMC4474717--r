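test_that("window expansion copies neighbours and zero-pads boundaries", {
  fm <- matrix(1:12, 4, 3)   # L=4, F=3
  # offsets = 0: original row plus bias
  e0 <- expand_features(fm, 0)
  expect_equal(e0, cbind(fm, 1))
  e <- expand_features(fm, -4:4)
  expect_equal(ncol(e), 3 * 9 + 1)
  # position 1: all negative-offset blocks zero
  expect_equal(unname(e[1, 1:12]), rep(0, 12))
  # interior element-wise check: block k holds fm[p + offsets[k], ]
  for (p in 1:4) for (k in 1:9) {
    src <- p + (-4:4)[k]
    want <- if (src >= 1 && src <= 4) fm[src, ] else rep(0, 3)
    expect_equal(unname(e[p, (k - 1) * 3 + 1:3]), unname(want))
  }
  expect_equal(e[, 28], rep(1, 4))   # bias column
})

test_that("uniform model gives uniform marginals and logZ = L log 3", {
  E <- expand_features(matrix(0, 7, 12))
  W <- matrix(0, 3, ncol(E)); Tm <- matrix(0, 3, 3)
  fb <- forward_backward(W, Tm, E)
  expect_equal(fb$logZ, 7 * log(3), tolerance = 1e-12)
  expect_equal(fb$logZ_backward, fb$logZ, tolerance = 1e-8)
  expect_equal(unname(fb$marginals), matrix(1/3, 7, 3), tolerance = 1e-12)
  expect_equal(viterbi(W, Tm, E), "OOOOOOO")   # tie-break toward O
})

test_that("length-1 chain reduces to a softmax of state scores", {
  set.seed(3)
  inst <- random_crf_instance(1)
  fb <- forward_backward(inst$W, inst$Tm, inst$E)
  s <- as.vector(inst$E %*% t(inst$W))
  expect_equal(unname(fb$marginals[1, ]), exp(s) / sum(exp(s)), tolerance = 1e-12)
})

test_that("marginals, logZ and Viterbi agree with exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:100) {
    L <- sample(2:6, 1)
    inst <- random_crf_instance(L)
    fb <- forward_backward(inst$W, inst$Tm, inst$E)
    oracle <- enumerate_crf(inst$W, inst$Tm, inst$E)
    expect_equal(fb$logZ, oracle$logZ, tolerance = 1e-9)
    expect_equal(fb$logZ_backward, fb$logZ, tolerance = 1e-8)
    expect_equal(unname(fb$marginals), oracle$marginals, tolerance = 1e-9)
    expect_equal(rowSums(fb$marginals), rep(1, L), tolerance = 1e-9)
    path <- viterbi(inst$W, inst$Tm, inst$E)
    expect_equal(path, oracle$best_path)
  }
})

test_that("with zero transitions Viterbi equals the per-position argmax", {
  set.seed(5)
  inst <- random_crf_instance(12)
  phi <- inst$E %*% t(inst$W)
  path <- viterbi(inst$W, matrix(0, 3, 3), inst$E)
  expect_equal(path, paste(c("O", "N", "D")[max.col(phi, "first")], collapse = ""))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(9)
  make_inst <- function(L) {
    fm <- matrix(rnorm(L * 2), L, 2)
    y <- sample(1:3, L, TRUE)
    list(E = expand_features(fm, -1:1), y = y)
  }
  insts <- list(make_inst(5), make_inst(4))
  expanded <- lapply(insts, `[[`, "E")
  ylist <- lapply(insts, `[[`, "y")
  P <- ncol(expanded[[1]])
  npar <- 3 * P + 9
  par <- rnorm(npar, sd = 0.4)
  obj <- idrcrf:::crf_objective(par, expanded, ylist, sigma2 = 5)
  h <- 1e-5
  fd <- vapply(seq_len(npar), function(k) {
    up <- par; up[k] <- up[k] + h
    dn <- par; dn[k] <- dn[k] - h
    (idrcrf:::crf_objective(up, expanded, ylist, 5)$value -
       idrcrf:::crf_objective(dn, expanded, ylist, 5)$value) / (2 * h)
  }, numeric(1))
  expect_equal(obj$gradient, fd, tolerance = 1e-4)
})

test_that("training fits a separable synthetic set to high token accuracy", {
  set.seed(21)
  mk <- function() {
    L <- sample(30:60, 1)
    y <- sample(c("O", "N", "D"), L, TRUE, prob = c(0.7, 0.2, 0.1))
    fm <- cbind(t(vapply(y, function(s) as.numeric(c("O", "N", "D") == s),
                         numeric(3))),
                matrix(1/9, L, 9))
    list(x = fm, y = paste(y, collapse = ""))
  }
  chains <- replicate(20, mk(), simplify = FALSE)
  fit <- idr_crf(lapply(chains, `[[`, "x"), lapply(chains, `[[`, "y"),
                 max_iter = 80)
  expect_gte(fit$token_accuracy, 0.99)
  # more optimization never worsens the penalized objective
  fit_short <- idr_crf(lapply(chains, `[[`, "x"), lapply(chains, `[[`, "y"),
                       max_iter = 10)
  expect_gte(fit$objective, fit_short$objective - 1e-6)
  # the zero-iteration model is the zero-weight model
  fit0 <- idr_crf(lapply(chains, `[[`, "x"), lapply(chains, `[[`, "y"),
                  max_iter = 0)
  expect_true(all(fit0$W == 0) && all(fit0$Tm == 0))
  expect_gte(fit$objective, fit0$objective)
})

test_that("fit validates its inputs", {
  expect_error(idr_crf(list(), list()), "empty training set")
  fm <- matrix(runif(12), 1, 12)
  expect_error(idr_crf(list(fm), list("OO")), "1 labels for|labels")
  expect_error(idr_crf(list(fm), list("Q")), "outside")
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(13)
  fm <- matrix(runif(15 * 12), 15, 12)
  fit <- idr_crf(list(fm), list(strrep("OND", 5)), max_iter = 15)
  d <- withr::local_tempdir()
  p <- file.path(d, "model.json")
  write_crf_model(fit, p)
  back <- read_crf_model(p)
  expect_identical(back$W, fit$W)
  expect_identical(unname(back$Tm), unname(fit$Tm))
  expect_identical(back$offsets, fit$offsets)
  # restored model predicts identically
  expect_identical(predict(fit, list(fm), type = "marginal"),
                   predict(back, list(fm), type = "marginal"))
  expect_identical(predict(fit, list(fm), type = "viterbi"),
                   predict(back, list(fm), type = "viterbi"))
})

test_that("S3 methods expose the fit", {
  set.seed(2)
  fm <- matrix(runif(10 * 12), 10, 12)
  fit <- idr_crf(list(fm), list(strrep("O", 10)), max_iter = 5)
  expect_output(print(fit), "Linear-chain CRF")
  expect_output(print(summary(fit)), "transition weights")
  co <- coef(fit)
  expect_equal(dim(co$state), c(3L, 12L * 9L + 1L))
  expect_equal(dim(co$transition), c(3L, 3L))
  expect_s3_class(logLik(fit), "logLik")
  marg <- predict(fit, fm)[[1]]
  expect_equal(rowSums(marg), rep(1, 10), tolerance = 1e-9)
  sim <- simulate(fit, nsim = 3, seed = 1, newdata = fm)
  expect_equal(nchar(sim[[1]]), rep(10L, 3))
  sim2 <- simulate(fit, nsim = 3, seed = 1, newdata = fm)
  expect_identical(sim, sim2)
})
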
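rand_xy <- function(n, p, seed, signal = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%03d", 1:p)))
  beta <- if (signal) rnorm(p, 0, 0.3) else rep(0, p)
  list(X = X, y = drop(X %*% beta) + rnorm(n))
}

test_that("ridge at lambda = 0 equals OLS; huge lambda shrinks to the mean", {
  d <- rand_xy(40, 8, 1)
  fit <- fit_ridge(d$X, d$y, lambda = 0)
  ols <- lm(d$y ~ d$X)
  expect_equal(unname(predict(fit, d$X)), unname(fitted(ols)),
               tolerance = 1e-8)
  big <- fit_ridge(d$X, d$y, lambda = 1e12)
  expect_equal(unname(predict(big, d$X)), rep(mean(d$y), 40),
               tolerance = 1e-4)
  expect_error(fit_ridge(d$X, d$y, lambda = -1), "lambda")
})

test_that("ridge primal and dual solutions agree on random instances", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(5:100, 1); p <- sample(2:100, 1)
    d <- rand_xy(n, p, s + 500)
    lam <- runif(1, 0.1, 10)
    fit <- fit_ridge(d$X, d$y, lambda = lam)
    Xs <- apply_standardizer(fit$std, d$X)
    yc <- d$y - mean(d$y)
    dual <- crossprod(Xs, solve(tcrossprod(Xs) + diag(lam, n), yc))
    primal <- solve(crossprod(Xs) + diag(lam, p), crossprod(Xs, yc))
    expect_equal(unname(drop(dual)), unname(drop(primal)), tolerance = 1e-8)
    expect_equal(unname(fit$coef), unname(drop(primal)), tolerance = 1e-8)
  }
})

test_that("REML lambda recovers the signal-to-noise regime", {
  # strong signal, tiny noise -> small lambda; pure noise -> large lambda
  set.seed(7)
  X <- matrix(rnorm(60 * 30), 60, 30, dimnames = list(NULL, sprintf("f%d", 1:30)))
  y_sig <- drop(X %*% rnorm(30)) + rnorm(60, 0, 0.05)
  y_noise <- rnorm(60)
  f_sig <- fit_ridge(X, y_sig, lambda = "reml")
  f_noise <- fit_ridge(X, y_noise, lambda = "reml")
  expect_lt(f_sig$lambda, f_noise$lambda)
  expect_gt(cor(predict(f_sig, X), y_sig), 0.99)
})

test_that("PLSR reproduces rank-1 responses and equals OLS at full rank", {
  set.seed(2)
  t1 <- rnorm(30); pvec <- rnorm(6)
  X1 <- tcrossprod(t1, pvec) + 0  # rank 1
  colnames(X1) <- sprintf("f%d", 1:6)
  y1 <- 2 * t1
  f1 <- fit_plsr(X1, y1, ncomp = 1)
  expect_lt(max(abs(predict(f1, X1) - y1)), 1e-8)

  d <- rand_xy(50, 6, 3)
  ffull <- fit_plsr(d$X, d$y, ncomp = 6)
  ols <- lm(d$y ~ d$X)
  expect_equal(unname(predict(ffull, d$X)), unname(fitted(ols)),
               tolerance = 1e-6)
  expect_error(fit_plsr(d$X, d$y, ncomp = 51), "ncomp")
})

test_that("NIPALS component scores are mutually orthogonal", {
  d <- rand_xy(40, 12, 4)
  fit <- fit_plsr(d$X, d$y, ncomp = 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
})

test_that("PLSR inner CV picks a sensible component count deterministically", {
  d <- rand_xy(60, 20, 5)
  set.seed(1); f1 <- fit_plsr(d$X, d$y, ncomp = "cv")
  set.seed(1); f2 <- fit_plsr(d$X, d$y, ncomp = "cv")
  expect_identical(f1$ncomp, f2$ncomp)
  expect_true(f1$ncomp >= 1 && f1$ncomp <= 15)
})

test_that("BayesB with pi = 1 returns the all-null model", {
  d <- rand_xy(30, 50, 6)
  expect_warning(fit <- fit_bayesb(d$X, d$y, pi = 1, s2 = 0.01,
                                   n_iter = 500, burnin = 100, seed = 1),
                 "all-null")
  expect_true(all(fit$coef == 0))
  expect_equal(unname(predict(fit, d$X)), rep(fit$intercept, 30))
  expect_lt(abs(fit$intercept - mean(d$y)), 0.2)
})

test_that("BayesB chains are bit-identical under a fixed seed", {
  d <- rand_xy(40, 60, 8)
  f1 <- fit_bayesb(d$X, d$y, n_iter = 400, burnin = 100, seed = 11)
  f2 <- fit_bayesb(d$X, d$y, n_iter = 400, burnin = 100, seed = 11)
  expect_identical(f1$coef, f2$coef)
  expect_identical(f1$diagnostics$trace_sigma2_e, f2$diagnostics$trace_sigma2_e)
  expect_error(fit_bayesb(d$X, d$y, n_iter = 100, burnin = 100), "burnin")
})

test_that("BayesB concentrates inclusion on a single causal marker", {
  hits <- vapply(1:5, function(s) {
    set.seed(s + 40)
    X <- matrix(rnorm(97 * 200), 97, 200,
                dimnames = list(NULL, sprintf("f%03d", 1:200)))
    y <- 3 * X[, 17] + rnorm(97, 0, 0.5)
    fit <- fit_bayesb(X, y, pi = 0.95, n_iter = 1500, burnin = 500,
                      seed = s)
    which.max(fit$pip) == 17 && fit$pip[17] > 0.9
  }, logical(1))
  expect_true(all(hits))
})

test_that("BayesB with a dense prior behaves like ridge", {
  # pi = 0 and a heavy, nearly Gaussian slab: predictions track ridge
  set.seed(9)
  X <- matrix(rnorm(80 * 40), 80, 40, dimnames = list(NULL, sprintf("f%d", 1:40)))
  y <- drop(X %*% rnorm(40, 0, 0.3)) + rnorm(80)
  fb <- fit_bayesb(X, y, pi = 0, nu = 100, n_iter = 2000, burnin = 500,
                   seed = 2)
  fr <- fit_ridge(X, y, lambda = "reml")
  expect_gt(cor(predict(fb, X), predict(fr, X)), 0.99)
})

test_that("random forest respects constant responses and the response range", {
  set.seed(10)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, sprintf("f%d", 1:5)))
  fc <- fit_random_forest(X, rep(2.5, 50), ntree = 20, seed = 1)
  expect_equal(unname(predict(fc, X)), rep(2.5, 50))

  y <- drop(X %*% rnorm(5)) + rnorm(50)
  fr <- fit_random_forest(X, y, ntree = 50, seed = 2)
  preds <- predict(fr, X)
  expect_true(all(preds >= min(y) - 1e-12 & preds <= max(y) + 1e-12))
  expect_error(fit_random_forest(X, y, ntree = 0), "ntree")
  expect_error(fit_random_forest(X, y, mtry = 99), "mtry")
})

test_that("random forest recovers a one-dimensional step function", {
  set.seed(11)
  x <- matrix(runif(200, -1, 1), ncol = 1, dimnames = list(NULL, "x"))
  y <- as.numeric(x[, 1] > 0)
  fit <- fit_random_forest(x, y, ntree = 200, mtry = 1, min_node = 1,
                           seed = 3)
  expect_lt(mean((predict(fit, x) - y)^2), 0.01)
})

test_that("forests are seed-deterministic and OOB error stabilizes with ntree", {
  d <- rand_xy(120, 10, 12)
  f1 <- fit_random_forest(d$X, d$y, ntree = 60, seed = 5)
  f2 <- fit_random_forest(d$X, d$y, ntree = 60, seed = 5)
  expect_identical(predict(f1, d$X), predict(f2, d$X))
  # OOB MSE at larger ntree does not get materially worse
  oob_mse <- function(ntree) {
    f <- fit_random_forest(d$X, d$y, ntree = ntree, seed = 6)
    mean((f$oob - d$y)^2, na.rm = TRUE)
  }
  m50 <- oob_mse(50); m500 <- oob_mse(500)
  expect_lt(m500, m50 * 1.1)
})

test_that("our forest agrees with the reference randomForest implementation", {
  skip_if_not_installed("randomForest")
  set.seed(13)
  X <- matrix(rnorm(150 * 8), 150, 8, dimnames = list(NULL, sprintf("f%d", 1:8)))
  y <- sin(X[, 1]) + 0.5 * X[, 2]^2 + 0.3 * X[, 3] + rnorm(150, 0, 0.2)
  ours <- fit_random_forest(X, y, ntree = 300, seed = 7)
  ref <- randomForest::randomForest(X, y, ntree = 300)
  expect_gt(cor(predict(ours, X), predict(ref, X)), 0.95)
})

test_that("prediction is affine-equivariant and rejects mismatched features", {
  d <- rand_xy(40, 6, 14)
  f <- fit_ridge(d$X, d$y, lambda = 2)
  f2 <- fit_ridge(d$X, 3 * d$y + 1, lambda = 2)
  expect_equal(predict(f2, d$X), 3 * predict(f, d$X) + 1, tolerance = 1e-8)
  Xbad <- d$X; colnames(Xbad)[2] <- "zzz"
  expect_error(predict(f, Xbad), "zzz")
})

test_that("learners survive zero-variance columns via the standardizer", {
  d <- rand_xy(30, 5, 15)
  X <- cbind(d$X, const = 1)
  fr <- fit_ridge(X, d$y, lambda = 1)
  expect_equal(unname(fr$coef["const"]), 0)
  fp <- fit_plsr(X, d$y, ncomp = 3)
  expect_false(anyNA(predict(fp, X)))
})

test_that("models round-trip through JSON", {
  d <- rand_xy(30, 6, 16)
  fr <- fit_ridge(d$X, d$y, lambda = 1.5)
  path <- tempfile(fileext = ".json")
  write_learner_json(fr, path)
  back <- read_learner_json(path)
  expect_equal(predict(back, d$X), predict(fr, d$X), tolerance = 1e-12)

  ff <- fit_random_forest(d$X, d$y, ntree = 10, seed = 1)
  write_learner_json(ff, path)
  backf <- read_learner_json(path)
  expect_equal(predict(backf, d$X), predict(ff, d$X), tolerance = 1e-12)
})
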
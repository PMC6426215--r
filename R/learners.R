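# ---- feature standardization ------------------------------------------------

#' Fit a column standardizer
#'
#' Records per-column means and SDs on the training matrix. Missing values
#' are mean-imputed before standardization; zero-variance columns are
#' flagged and passed through with unit scale (they carry no information and
#' end up with zero coefficients).
#'
#' @param X numeric matrix with column names.
#' @return list of class `pgebv_std` with `center`, `scale`, `zero_var`,
#'   `features`.
#' @export
fit_standardizer <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  center <- colMeans(X, na.rm = TRUE)
  center[is.na(center)] <- 0
  Xi <- X
  for (j in seq_len(ncol(X))) {
    nas <- is.na(Xi[, j])
    if (any(nas)) Xi[nas, j] <- center[j]
  }
  scl <- apply(Xi, 2L, sd)
  zero_var <- !is.finite(scl) | scl < 1e-10
  scl[zero_var] <- 1
  structure(list(center = center, scale = scl, zero_var = zero_var,
                 features = colnames(X)),
            class = "pgebv_std")
}

#' Apply a fitted standardizer
#'
#' Mean-imputes with the training means and standardizes with the training
#' center/scale. Errors if the new matrix's columns do not match the
#' training features.
#'
#' @param std a [fit_standardizer()] result.
#' @param X new numeric matrix.
#' @return standardized matrix.
#' @export
apply_standardizer <- function(std, X) {
  if (is.null(colnames(X)) && ncol(X) == length(std$features))
    colnames(X) <- std$features
  if (!identical(colnames(X), std$features)) {
    bad <- c(setdiff(std$features, colnames(X)), setdiff(colnames(X), std$features))
    stop("feature mismatch: ", paste(unique(bad), collapse = ", "))
  }
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- std$center[j]
  }
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")
}

new_learner <- function(method, std, intercept, extra) {
  structure(c(list(method = method, std = std, intercept = intercept), extra),
            class = c(paste0("pgebv_", tolower(method)), "pgebv_learner"))
}

#' @export
print.pgebv_learner <- function(x, ...) {
  cat(sprintf("pgebv %s model: %d features, intercept %.4g\n",
              x$method, length(x$std$features), x$intercept))
  invisible(x)
}

# ---- ridge regression -------------------------------------------------------

#' Ridge regression with optional REML shrinkage
#'
#' Solves `beta = (X'X + lambda I)^-1 X'y` on standardized features with an
#' unpenalized intercept. `lambda = "reml"` estimates the shrinkage from the
#' equivalent random-effects model `y = 1 mu + g`, `g ~ N(0, sigma_u^2 XX')`,
#' by restricted maximum likelihood on the spectral decomposition of `XX'`
#' (lambda = sigma_e^2 / sigma_u^2), the standard genomic-BLUP equivalence.
#' For p > n the dual (kernel) form is used; the two forms agree exactly.
#'
#' @param X numeric feature matrix (rows = observations).
#' @param y response vector, length `nrow(X)` (>= 3).
#' @param lambda non-negative penalty, or `"reml"`.
#' @return A `pgebv_learner` with `coef` (standardized scale), `lambda`, and
#'   for REML fits `sigma2_u`, `sigma2_e`.
#' @export
fit_ridge <- function(X, y, lambda = "reml") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y) || n < 3L) stop("need nrow(X) == length(y) >= 3")
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  yc <- y - mean(y)
  s2u <- s2e <- NA_real_
  if (identical(lambda, "reml")) {
    K <- tcrossprod(Xs)
    # project out the intercept: REML on mean-centered contrasts
    C <- diag(n) - matrix(1 / n, n, n)
    M <- C %*% K %*% C
    em <- eigen(M, symmetric = TRUE)
    keep <- seq_len(n - 1L)
    xi <- pmax(em$values[keep], 0)
    eta <- drop(crossprod(em$vectors[, keep, drop = FALSE], yc))
    rll <- function(ldelta) {
      d <- exp(ldelta)
      -0.5 * ((n - 1) * log(sum(eta^2 / (xi + d))) + sum(log(xi + d)))
    }
    opt <- optimize(rll, c(-12, 12), maximum = TRUE, tol = 1e-8)
    delta <- exp(opt$maximum)
    s2u <- sum(eta^2 / (xi + delta)) / (n - 1)
    s2e <- delta * s2u
    lambda <- delta
  } else {
    if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0 or \"reml\"")
  }
  if (p <= n) {
    beta <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, yc))
  } else {
    if (lambda <= 0) stop("lambda = 0 requires p <= n (singular kernel)")
    K <- tcrossprod(Xs)
    beta <- crossprod(Xs, solve(K + diag(lambda, n), yc))
  }
  new_learner("RR", std, mean(y),
              list(coef = setNames(drop(beta), std$features), lambda = lambda,
                   sigma2_u = s2u, sigma2_e = s2e))
}

# ---- partial least squares --------------------------------------------------

# NIPALS loop on standardized X and centered y; returns weights, loadings,
# y-loadings and scores for up to ncomp components.
.nipals <- function(Xs, yc, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp); TT <- matrix(0, n, ncomp)
  Xd <- Xs; yd <- yc
  k_used <- 0L
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(Xd, t_)) / tt
    q <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, pl)
    yd <- yd - q * t_
    W[, k] <- w; P[, k] <- pl; Q[k] <- q; TT[, k] <- t_
    k_used <- k
  }
  list(W = W[, seq_len(k_used), drop = FALSE],
       P = P[, seq_len(k_used), drop = FALSE],
       Q = Q[seq_len(k_used)], scores = TT[, seq_len(k_used), drop = FALSE],
       ncomp = k_used)
}

# regression coefficients (standardized-X scale) using the first k components
.pls_coef <- function(fit, k) {
  W <- fit$W[, seq_len(k), drop = FALSE]
  P <- fit$P[, seq_len(k), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), fit$Q[seq_len(k)]))
}

#' Partial least squares regression (NIPALS)
#'
#' Fits PLSR by NIPALS deflation on standardized features and centered
#' response. `ncomp = "cv"` chooses the component count on a 1..`max_comp`
#' grid by inner k-fold cross-validation (minimum PRESS) within the
#' training data.
#'
#' @param X numeric feature matrix.
#' @param y response vector.
#' @param ncomp number of latent components, or `"cv"`.
#' @param max_comp grid upper bound for `"cv"`.
#' @param cv_folds inner folds.
#' @return A `pgebv_learner` with `coef`, `ncomp`, `scores` (training
#'   component scores).
#' @export
fit_plsr <- function(X, y, ncomp = "cv", max_comp = 15L, cv_folds = 5L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("dimension mismatch")
  kmax_feasible <- min(n - 1L, p)
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  yc <- y - mean(y)
  if (identical(ncomp, "cv")) {
    kmax <- min(max_comp, n - 2L, p)
    folds <- sample(rep(seq_len(cv_folds), length.out = n))
    press <- numeric(kmax)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      if (sum(tr) < 3L || sum(!tr) < 1L) next
      sub_std <- fit_standardizer(X[tr, , drop = FALSE])
      Xtr <- apply_standardizer(sub_std, X[tr, , drop = FALSE])
      ytr <- y[tr] - mean(y[tr])
      fit <- .nipals(Xtr, ytr, min(kmax, sum(tr) - 1L))
      Xva <- apply_standardizer(sub_std, X[!tr, , drop = FALSE])
      for (k in seq_len(kmax)) {
        kk <- min(k, fit$ncomp)
        if (kk < 1L) next
        pred <- mean(y[tr]) + drop(Xva %*% .pls_coef(fit, kk))
        press[k] <- press[k] + sum((y[!tr] - pred)^2)
      }
    }
    ncomp <- which.min(press)
  }
  if (!is.numeric(ncomp) || ncomp < 1L || ncomp > kmax_feasible)
    stop("ncomp must be in 1..min(n-1, p)")
  fit <- .nipals(Xs, yc, ncomp)
  if (fit$ncomp < 1L) stop("no usable PLS component (constant response?)")
  beta <- .pls_coef(fit, fit$ncomp)
  new_learner("PLSR", std, mean(y),
              list(coef = setNames(beta, std$features), ncomp = fit$ncomp,
                   scores = fit$scores))
}

# ---- BayesB -----------------------------------------------------------------

#' BayesB: Bayesian marker regression with a point mass at zero and a t-slab
#'
#' Gibbs sampler over the intercept, per-marker inclusion indicators,
#' per-marker effects with marker-specific scaled-inverse-chi-squared
#' variances (the standard data augmentation of the t-slab), and the
#' residual variance. Returns posterior-mean effects and posterior
#' inclusion probabilities; a fixed seed reproduces the chain bit for bit.
#'
#' The default slab scale (`s2 = "auto"`) targets half of the response
#' variance as marker-explained: s2 = 0.5 var(y) (nu-2) / (nu (1-pi) p).
#'
#' @param X numeric feature matrix.
#' @param y response vector.
#' @param pi prior probability of a zero effect (point mass), in [0, 1].
#' @param nu slab degrees of freedom (> 2 for the auto scale).
#' @param s2 slab scale, or `"auto"`.
#' @param n_iter,burnin,thin chain length controls (`n_iter > burnin`;
#'   `n_iter >= 200` for any inferential use).
#' @param seed RNG seed for the chain.
#' @return A `pgebv_learner` with `coef` (posterior means, standardized
#'   scale), `pip`, `hyper`, and chain traces in `diagnostics`.
#' @export
fit_bayesb <- function(X, y, pi = 0.95, nu = 5, s2 = "auto",
                       n_iter = 6000L, burnin = 1000L, thin = 1L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("dimension mismatch")
  if (pi < 0 || pi > 1) stop("pi must be in [0, 1]")
  if (n_iter <= burnin) stop("n_iter must exceed burnin")
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  vy <- var(y)
  p_eff <- max(1L, sum(!std$zero_var))
  if (identical(s2, "auto")) {
    if (nu <= 2) stop("auto slab scale needs nu > 2")
    s2 <- 0.5 * vy * (nu - 2) / (nu * max(1 - pi, 1 / p_eff) * p_eff)
    s2 <- max(s2, 1e-8)
  }
  nu_e <- 5
  se2 <- max(1e-8, 0.5 * vy * (nu_e + 2) / nu_e)
  if (pi >= 1) warning("pi = 1: all-null model, predictions are the intercept")
  set.seed(seed)
  res <- bayesb_gibbs(Xs, as.numeric(y), pi, nu, s2, nu_e, se2,
                      as.integer(n_iter), as.integer(burnin), as.integer(thin))
  new_learner("BayesB", std, res$mu,
              list(coef = setNames(res$beta, std$features),
                   pip = setNames(res$pip, std$features),
                   hyper = list(pi = pi, nu = nu, s2 = s2, nu_e = nu_e,
                                se2 = se2, n_iter = n_iter, burnin = burnin,
                                thin = thin, seed = seed),
                   diagnostics = list(trace_sigma2_e = res$trace_sigma2_e,
                                      trace_mu = res$trace_mu,
                                      n_samples = res$n_samples)))
}

# ---- random forest ----------------------------------------------------------

#' Random forest regression (CART ensemble)
#'
#' `ntree` unpruned CART regression trees on bootstrap resamples; each split
#' maximizes the variance reduction over `mtry` randomly drawn candidate
#' features, with at least `min_node` observations per leaf. The prediction
#' is the ensemble mean; out-of-bag predictions are returned for the
#' training rows.
#'
#' @param X numeric feature matrix.
#' @param y response vector.
#' @param ntree number of trees (>= 1).
#' @param mtry candidate features per split; default `floor(p/3)` as usual
#'   for regression forests.
#' @param min_node minimum leaf size.
#' @param seed RNG seed (bootstrap + feature sampling).
#' @return A `pgebv_learner` with `forest` (tree arrays), `oob`
#'   (out-of-bag predictions, NA where a row was never out of bag), and the
#'   hyperparameters.
#' @export
fit_random_forest <- function(X, y, ntree = 500L,
                              mtry = max(1L, floor(ncol(X) / 3)),
                              min_node = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("dimension mismatch")
  if (ntree < 1L) stop("ntree must be >= 1")
  if (mtry < 1L || mtry > ncol(X)) stop("mtry must be in 1..p")
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  set.seed(seed)
  res <- rf_fit(Xs, as.numeric(y), as.integer(ntree), as.integer(mtry),
                as.integer(max(1L, min_node)))
  new_learner("RF", std, mean(y),
              list(forest = res$trees, oob = res$oob,
                   ntree = as.integer(ntree), mtry = as.integer(mtry),
                   min_node = as.integer(min_node), seed = as.integer(seed)))
}

# ---- prediction -------------------------------------------------------------

#' Predict from a fitted learner
#'
#' Applies the training standardization (training means for imputation and
#' scaling) and the fitted model. Deterministic given the model. Errors if
#' the new matrix's columns do not match the training features.
#'
#' @param object a `pgebv_learner`.
#' @param X_new numeric feature matrix.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pgebv_learner <- function(object, X_new, ...) {
  Xs <- apply_standardizer(object$std, as.matrix(X_new))
  if (object$method == "RF") {
    drop(rf_predict_cpp(object$forest, Xs))
  } else {
    object$intercept + drop(Xs %*% object$coef)
  }
}

# ---- JSON save/load ---------------------------------------------------------

#' Save / load a fitted learner as JSON
#'
#' Plain-text serialization of coefficients (or tree arrays), hyperparameters
#' and the standardization record; no binary formats.
#'
#' @param model a `pgebv_learner`.
#' @param path file path.
#' @return `read_learner_json` returns the restored `pgebv_learner`.
#' @export
write_learner_json <- function(model, path) {
  obj <- unclass(model)
  obj$std <- unclass(obj$std)
  obj$scores <- NULL  # training scores are not part of the model
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_learner_json
#' @export
read_learner_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- obj$std
  std$center <- setNames(as.numeric(std$center), std$features)
  std$scale <- setNames(as.numeric(std$scale), std$features)
  std$zero_var <- setNames(as.logical(std$zero_var), std$features)
  class(std) <- "pgebv_std"
  obj$std <- std
  if (!is.null(obj$coef)) obj$coef <- setNames(as.numeric(obj$coef), std$features)
  if (!is.null(obj$forest)) {
    f <- obj$forest  # simplification may yield a data.frame of list columns
    ntree <- if (is.data.frame(f)) nrow(f) else length(f)
    obj$forest <- lapply(seq_len(ntree), function(t) {
      tr <- if (is.data.frame(f))
        lapply(f, function(col) col[[t]]) else f[[t]]
      list(feature = as.integer(tr$feature),
           threshold = as.numeric(tr$threshold),
           left = as.integer(tr$left), right = as.integer(tr$right),
           value = as.numeric(tr$value))
    })
  }
  structure(obj, class = c(paste0("pgebv_", tolower(obj$method)), "pgebv_learner"))
}
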
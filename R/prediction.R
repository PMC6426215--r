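# ---- dataset assembly -------------------------------------------------------

#' Assemble a prediction dataset from BLUEs and the bin map
#'
#' Records are genotype x environment cells. The target is the grain-yield
#' BLUE; the feature blocks are M (coded bin calls, identical for a genotype
#' across its environments), H (band x flight BLUEs, environment-specific),
#' or their column concatenation HM. Standardization is *not* applied here:
#' the learners fit it on the training partition at cross-validation time.
#'
#' @param blues a [build_blue_table()] result (or data.frame with `genotype`,
#'   `env`, `GY` and feature columns).
#' @param binmap a [merge_bins()] / [build_binmap()] result, or a
#'   [geno_matrix()] for raw-SNP marker features instead of bins.
#' @param input_set one of `"M"`, `"H"`, `"HM"`.
#' @param trait target column in `blues`.
#' @return Object of class `pgebv_dataset`: `records` (genotype, env), `y`,
#'   `M`, `H` matrices (NULL when unused), `input_set`. Genotypes absent
#'   from the bin map are excluded and listed in attribute
#'   `"excluded_genotypes"`.
#' @export
build_dataset <- function(blues, binmap, input_set = c("HM", "M", "H"),
                          trait = "GY") {
  input_set <- match.arg(input_set)
  h_cols <- grep("^B\\d+_F\\d+$", names(blues), value = TRUE)
  marker_calls <- if (inherits(binmap, "pgebv_geno")) binmap$calls
                  else binmap$bin_calls
  excluded <- character(0)
  keep <- rep(TRUE, nrow(blues))
  if (input_set %in% c("M", "HM")) {
    keep <- blues$genotype %in% binmap$line_ids
    excluded <- unique(blues$genotype[!keep])
    if (length(excluded))
      message(length(excluded), " genotype(s) absent from bin map excluded")
  }
  d <- blues[keep, , drop = FALSE]
  records <- data.frame(genotype = d$genotype, env = d$env,
                        stringsAsFactors = FALSE)
  M <- NULL; H <- NULL
  if (input_set %in% c("M", "HM")) {
    M <- marker_calls[d$genotype, , drop = FALSE]
    storage.mode(M) <- "double"
    M[M == 0] <- NA  # het calls carry no parental information; imputed later
    rownames(M) <- NULL
  }
  if (input_set %in% c("H", "HM")) {
    if (!length(h_cols)) stop("no hyperspectral feature columns in blues")
    H <- as.matrix(d[, h_cols, drop = FALSE])
    rownames(H) <- NULL
  }
  structure(list(records = records, y = d[[trait]], M = M, H = H,
                 input_set = input_set),
            class = "pgebv_dataset",
            excluded_genotypes = excluded)
}

# feature matrix for a row subset (HM = M block then H block)
.dataset_X <- function(data, rows) {
  blocks <- list()
  if (!is.null(data$M)) blocks$M <- data$M[rows, , drop = FALSE]
  if (!is.null(data$H)) blocks$H <- data$H[rows, , drop = FALSE]
  do.call(cbind, unname(blocks))
}

# ---- learner specs ----------------------------------------------------------

#' Specify a learner for cross-validation
#'
#' @param method one of `"plsr"`, `"rf"`, `"rr"`, `"bayesb"`, or the test
#'   helpers `"oracle"` (returns the observed target) and `"constant"`
#'   (returns the training mean).
#' @param ... hyperparameter overrides passed to the `fit_*` function.
#' @return list of class `pgebv_learner_spec`.
#' @export
learner_spec <- function(method = c("plsr", "rf", "rr", "bayesb",
                                    "oracle", "constant"), ...) {
  method <- match.arg(method)
  structure(list(method = method, args = list(...)),
            class = "pgebv_learner_spec")
}

# fit a learner spec on training data; seed feeds the stochastic learners
fit_learner <- function(spec, X, y, seed = 1L) {
  a <- spec$args
  switch(spec$method,
    rr = do.call(fit_ridge, c(list(X = X, y = y), a)),
    plsr = { set.seed(seed); do.call(fit_plsr, c(list(X = X, y = y), a)) },
    bayesb = do.call(fit_bayesb, c(list(X = X, y = y, seed = seed), a)),
    rf = do.call(fit_random_forest, c(list(X = X, y = y, seed = seed), a)),
    stop("fit_learner cannot fit method ", spec$method))
}

# ---- accuracy statistics ----------------------------------------------------

#' Prediction accuracy: Pearson correlation
#'
#' Sample Pearson correlation between predicted values and observed BLUEs,
#' the r_GP accuracy measure. Returns NA (undefined) when either vector is
#' constant or shorter than 4.
#'
#' @param predicted,observed numeric vectors of equal length >= 4.
#' @return correlation, or NA when undefined.
#' @export
pearson_rgp <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 4L) return(NA_real_)
  if (sd(predicted) == 0 || sd(observed) == 0) return(NA_real_)
  cor(predicted, observed)
}

#' Bootstrap standard error of a correlation
#'
#' Resamples index pairs with replacement and reports the SD of the
#' bootstrap correlations. Degenerate resamples (either vector constant)
#' are skipped and counted; more than 50% degenerate is an error.
#'
#' @param predicted,observed numeric vectors of equal length >= 4.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return SE (numeric); attribute `"n_degenerate"` counts skipped
#'   resamples.
#' @export
bootstrap_se <- function(predicted, observed, n_boot = 10000L, seed = 1L) {
  n <- length(predicted)
  if (n != length(observed)) stop("length mismatch")
  if (n < 4L) stop("need length >= 4")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  P <- matrix(predicted[idx], n, n_boot)
  O <- matrix(observed[idx], n, n_boot)
  Pc <- sweep(P, 2L, colMeans(P)); Oc <- sweep(O, 2L, colMeans(O))
  sp <- sqrt(colSums(Pc^2)); so <- sqrt(colSums(Oc^2))
  deg <- sp < 1e-12 | so < 1e-12
  if (mean(deg) > 0.5) stop("more than 50% of bootstrap resamples degenerate")
  r <- colSums(Pc * Oc)[!deg] / (sp[!deg] * so[!deg])
  structure(sd(r), n_degenerate = sum(deg))
}

# ---- cross-validation schemes -----------------------------------------------

#' Within-environment two-fold cross-validation
#'
#' Per environment, genotypes are split at random into halves; the learner
#' is trained on one half and predicts the other, in both directions, and
#' the per-rep accuracy is the mean of the two directional Pearson
#' correlations. The scheme accuracy averages over replicates and
#' environments. Undefined correlations (constant predictions) contribute 0
#' and are counted rather than dropped.
#'
#' @param data a [build_dataset()] result.
#' @param learner a [learner_spec()].
#' @param n_reps random-split replicates.
#' @param seed master seed for splits and stochastic learners.
#' @param n_boot bootstrap replicates for the per-rep accuracy SE.
#' @param stratify_env split within each environment (the default); `FALSE`
#'   pools all records and splits them jointly, scoring one pooled
#'   correlation per direction.
#' @return Object of class `pgebv_scheme_result` with `r_gp`, `se_boot`,
#'   `per_env` breakdown, `n_reps`, `n_undefined`, `n_skipped`.
#' @export
twofold_cv <- function(data, learner, n_reps = 50L, seed = 1L,
                       n_boot = 1000L, stratify_env = TRUE) {
  set.seed(seed)
  envs <- if (stratify_env) unique(data$records$env) else "pooled"
  per_env <- list(); n_undef <- 0L; n_skip <- 0L
  for (env in envs) {
    rows <- if (identical(env, "pooled")) seq_len(nrow(data$records))
            else which(data$records$env == env)
    n <- length(rows)
    r_reps <- numeric(0); se_reps <- numeric(0)
    for (rep_i in seq_len(n_reps)) {
      half <- sample.int(n, n %/% 2L)
      parts <- list(half, setdiff(seq_len(n), half))
      r_dir <- numeric(0)
      pred_all <- obs_all <- numeric(0)
      for (d in 1:2) {
        tr <- rows[parts[[d]]]; te <- rows[parts[[3L - d]]]
        if (length(te) < 4L) { n_skip <- n_skip + 1L; next }
        preds <- switch(learner$method,
          oracle = data$y[te],
          constant = rep(mean(data$y[tr]), length(te)),
          { m <- fit_learner(learner, .dataset_X(data, tr), data$y[tr],
                             seed = sample.int(2^30, 1L))
            predict(m, .dataset_X(data, te)) })
        r <- pearson_rgp(preds, data$y[te])
        if (is.na(r)) { n_undef <- n_undef + 1L; r <- 0 }
        r_dir <- c(r_dir, r)
        pred_all <- c(pred_all, preds); obs_all <- c(obs_all, data$y[te])
      }
      if (!length(r_dir)) next
      r_reps <- c(r_reps, mean(r_dir))
      if (sd(pred_all) > 0 && sd(obs_all) > 0)
        se_reps <- c(se_reps, as.numeric(
          bootstrap_se(pred_all, obs_all, n_boot,
                       seed = sample.int(2^30, 1L))))
    }
    per_env[[env]] <- data.frame(
      env = env, r_gp = mean(r_reps),
      se = if (length(se_reps)) mean(se_reps) else NA_real_,
      n_reps = length(r_reps), stringsAsFactors = FALSE)
  }
  per_env <- do.call(rbind, per_env)
  rownames(per_env) <- NULL
  structure(list(scheme = "within_2fold", learner = learner$method,
                 input_set = data$input_set,
                 r_gp = mean(per_env$r_gp),
                 se_boot = mean(per_env$se, na.rm = TRUE),
                 per_env = per_env, n_reps = n_reps,
                 n_undefined = n_undef, n_skipped = n_skip),
            class = "pgebv_scheme_result")
}

#' Leave-one-environment-out cross-validation
#'
#' For each environment, the learner is trained on all records of the other
#' environments and predicts the held-out environment's records, using that
#' environment's own hyperspectral features (pre-harvest spectra of the
#' predicted entries are available) and the shared marker features. The
#' scheme accuracy averages the per-fold Pearson correlations.
#'
#' @param data a [build_dataset()] result spanning >= 2 environments.
#' @param learner a [learner_spec()].
#' @param seed seed for stochastic learners and bootstrap.
#' @param n_boot bootstrap replicates for per-fold SEs.
#' @param use_target_spectra feed the held-out environment's own H features
#'   at prediction time (the default; entries are predicted pre-harvest
#'   with their spectra already measured). `FALSE` blanks the test
#'   environment's H block (every value imputed to the training mean), so
#'   predictions rely on markers and the intercept only.
#' @return A `pgebv_scheme_result` (scheme `"across_LOEO"`).
#' @export
leave_one_env_out <- function(data, learner, seed = 1L, n_boot = 1000L,
                              use_target_spectra = TRUE) {
  envs <- unique(data$records$env)
  if (length(envs) < 2L) stop("need >= 2 environments")
  set.seed(seed)
  per_env <- list(); n_undef <- 0L
  for (env in envs) {
    te <- which(data$records$env == env)
    tr <- which(data$records$env != env)
    X_te <- .dataset_X(data, te)
    if (!use_target_spectra && !is.null(data$H)) {
      h_cols <- colnames(data$H)
      X_te[, h_cols] <- NA_real_  # imputed to training means by the learner
    }
    preds <- switch(learner$method,
      oracle = data$y[te],
      constant = rep(mean(data$y[tr]), length(te)),
      { m <- fit_learner(learner, .dataset_X(data, tr), data$y[tr],
                         seed = sample.int(2^30, 1L))
        predict(m, X_te) })
    r <- pearson_rgp(preds, data$y[te])
    if (is.na(r)) { n_undef <- n_undef + 1L; r <- 0 }
    se <- if (sd(preds) > 0)
      as.numeric(bootstrap_se(preds, data$y[te], n_boot,
                              seed = sample.int(2^30, 1L))) else NA_real_
    per_env[[env]] <- data.frame(env = env, r_gp = r, se = se, n_reps = 1L,
                                 stringsAsFactors = FALSE)
  }
  per_env <- do.call(rbind, per_env)
  rownames(per_env) <- NULL
  structure(list(scheme = "across_LOEO", learner = learner$method,
                 input_set = data$input_set,
                 r_gp = mean(per_env$r_gp),
                 se_boot = mean(per_env$se, na.rm = TRUE),
                 per_env = per_env, n_reps = 1L,
                 n_undefined = n_undef, n_skipped = 0L),
            class = "pgebv_scheme_result")
}

#' @export
print.pgebv_scheme_result <- function(x, ...) {
  cat(sprintf("%s | %s | %s : r_GP = %.3f (boot SE %.3f)\n",
              x$scheme, x$learner, x$input_set, x$r_gp, x$se_boot))
  invisible(x)
}

# ---- full experiment grid ---------------------------------------------------

#' Study-scale replication preset: per-learner two-fold CV counts
#'
#' @return named integer vector (plsr, rf, rr, bayesb).
#' @export
paper_reps <- function() c(plsr = 1000L, rf = 2000L, rr = 3000L, bayesb = 1000L)

#' Run the full scheme x learner x input-set grid
#'
#' The 2 schemes x 4 learners x 3 input sets factorial (24 cells by
#' default), each cell reporting r_GP and its bootstrap SE. Failed cells are
#' recorded with their error message and the grid continues.
#'
#' @param blues BLUE table.
#' @param binmap bin map.
#' @param learners character subset of `c("plsr","rf","rr","bayesb")`.
#' @param inputs character subset of `c("M","H","HM")`.
#' @param schemes character subset of `c("within_2fold","across_LOEO")`.
#' @param n_reps two-fold replicates: a single count, a named per-learner
#'   vector, or `"paper"` for the study preset (1000/2000/3000/1000).
#' @param seed master seed.
#' @param n_boot bootstrap replicates per cell.
#' @param hyper named list of per-learner hyperparameter overrides, e.g.
#'   `list(rf = list(ntree = 150), bayesb = list(n_iter = 1500))`.
#' @return data.frame (scheme, learner, input_set, r_gp, se_boot, n_reps,
#'   n_undefined, error) with attribute `"per_env"` (long per-environment
#'   table) and `"seed"`.
#' @export
run_experiment_grid <- function(blues, binmap,
                                learners = c("plsr", "rf", "rr", "bayesb"),
                                inputs = c("M", "H", "HM"),
                                schemes = c("within_2fold", "across_LOEO"),
                                n_reps = 50L, seed = 1L, n_boot = 1000L,
                                hyper = list()) {
  reps_of <- function(l) {
    if (identical(n_reps, "paper")) return(paper_reps()[[l]])
    if (!is.null(names(n_reps)) && l %in% names(n_reps)) return(n_reps[[l]])
    as.integer(n_reps[[1L]])
  }
  datasets <- lapply(setNames(inputs, inputs), function(i)
    build_dataset(blues, binmap, i))
  rows <- list(); per_env <- list(); cell <- 0L
  for (scheme in schemes) for (l in learners) for (i in inputs) {
    cell <- cell + 1L
    cell_seed <- as.integer((as.numeric(seed) * 1009 + cell * 131) %% 2147483629)
    spec <- do.call(learner_spec, c(list(method = l), hyper[[l]]))
    res <- tryCatch({
      if (scheme == "within_2fold")
        twofold_cv(datasets[[i]], spec, n_reps = reps_of(l),
                   seed = cell_seed, n_boot = n_boot)
      else
        leave_one_env_out(datasets[[i]], spec, seed = cell_seed,
                          n_boot = n_boot)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[cell]] <- data.frame(scheme = scheme, learner = l, input_set = i,
                                 r_gp = NA_real_, se_boot = NA_real_,
                                 n_reps = NA_integer_, n_undefined = NA_integer_,
                                 error = conditionMessage(res),
                                 stringsAsFactors = FALSE)
    } else {
      rows[[cell]] <- data.frame(scheme = scheme, learner = l, input_set = i,
                                 r_gp = res$r_gp, se_boot = res$se_boot,
                                 n_reps = res$n_reps,
                                 n_undefined = res$n_undefined,
                                 error = NA_character_,
                                 stringsAsFactors = FALSE)
      pe <- res$per_env
      pe$scheme <- scheme; pe$learner <- l; pe$input_set <- i
      per_env[[cell]] <- pe
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_env") <- do.call(rbind, per_env)
  attr(out, "seed") <- seed
  out
}

#' Summarize a grid: mean accuracy per scheme, learner and input set
#'
#' @param results a [run_experiment_grid()] table.
#' @return list of data.frames `by_scheme`, `by_learner`, `by_input`.
#' @export
grid_summary <- function(results) {
  ok <- results[is.na(results$error), , drop = FALSE]
  agg <- function(by) {
    a <- aggregate(ok$r_gp, by = ok[by], FUN = mean)
    names(a)[ncol(a)] <- "mean_r_gp"
    a
  }
  list(by_scheme = agg("scheme"), by_learner = agg("learner"),
       by_input = agg("input_set"))
}
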
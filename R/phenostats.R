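#' Per-environment mixed model: BLUEs and variance components
#'
#' Fits, within one environment, `trait ~ 0 + genotype + (1 | rep) +
#' (1 | rep:block)` by REML. Genotype is fixed, so its estimates are the
#' best linear unbiased estimators (BLUEs) of the genotype means;
#' replicate and block-within-replicate are random.
#'
#' @param plots a plot table (see [simulate_trials()]).
#' @param environment environment id to subset on.
#' @param trait name of the trait column.
#' @return A list of class `pgebv_env_fit`: `blues` (named vector),
#'   `se` (named vector), `vc` (sigma_rep2, sigma_block2, sigma_e2),
#'   `environment`, `trait`, `n_plots`, and `fit` (the lme4 model).
#' @export
fit_env_model <- function(plots, environment, trait = "GY") {
  d <- plots[plots$env == environment, , drop = FALSE]
  if (nrow(d) == 0L) stop("no plots for environment ", environment)
  if (length(unique(d$genotype)) < 2L) stop("need >= 2 genotypes")
  d$genotype <- factor(d$genotype)
  d$rep_f <- factor(d$rep)
  d$block_f <- factor(paste(d$rep, d$block, sep = ":"))
  d$.y <- d[[trait]]
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(.y ~ 0 + genotype + (1 | rep_f) + (1 | block_f),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  b <- lme4::fixef(fit)
  names(b) <- sub("^genotype", "", names(b))
  se <- sqrt(diag(as.matrix(vcov(fit))))
  names(se) <- names(b)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
  structure(list(blues = b, se = se,
                 vc = c(sigma_rep2 = getv("rep_f"),
                        sigma_block2 = getv("block_f"),
                        sigma_e2 = getv("Residual")),
                 environment = environment, trait = trait,
                 n_plots = nrow(d), fit = fit),
            class = "pgebv_env_fit")
}

#' Combined all-random mixed model across environments
#'
#' Fits `trait ~ (1|genotype) + (1|env) + (1|genotype:env) + (1|env:rep) +
#' (1|env:rep:block)` by REML: the full trial model with every factor
#' random, yielding the variance components that feed the entry-mean
#' repeatability. Negative components are truncated at zero by the REML
#' boundary itself.
#'
#' @param plots a plot table spanning >= 2 environments.
#' @param trait name of the trait column.
#' @return Object of class `pgebv_vc`: named numeric vector components
#'   `sigma_G2`, `sigma_GxE2`, `sigma_rep2`, `sigma_block2`, `sigma_e2`,
#'   plus `n_envs` and `n_reps` attributes and the lme4 fit.
#' @export
fit_combined_model <- function(plots, trait = "GY") {
  if (length(unique(plots$env)) < 2L) stop("need >= 2 environments")
  d <- plots
  d$genotype <- factor(d$genotype)
  d$env_f <- factor(d$env)
  d$rep_f <- factor(paste(d$env, d$rep, sep = ":"))
  d$block_f <- factor(paste(d$env, d$rep, d$block, sep = ":"))
  d$.y <- d[[trait]]
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(.y ~ 1 + (1 | genotype) + (1 | env_f) + (1 | genotype:env_f) +
                 (1 | rep_f) + (1 | block_f),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
  out <- c(sigma_G2 = getv("genotype"),
           sigma_GxE2 = getv("genotype:env_f"),
           sigma_env2 = getv("env_f"),
           sigma_rep2 = getv("rep_f"),
           sigma_block2 = getv("block_f"),
           sigma_e2 = getv("Residual"))
  structure(out, class = "pgebv_vc",
            n_envs = length(unique(plots$env)),
            n_reps = max(plots$rep), fit = fit)
}

#' Entry-mean broad-sense repeatability
#'
#' h2 = sigma_G^2 / (sigma_G^2 + sigma_GxE^2 / l + sigma_e^2 / (r l)), with
#' l the number of environments and r the number of replicates. Components
#' are truncated at zero before use.
#'
#' @param vc a [fit_combined_model()] result, or a named numeric vector with
#'   `sigma_G2`, `sigma_GxE2`, `sigma_e2`.
#' @param n_envs,n_reps l and r; default taken from `vc` attributes.
#' @return A list of class `pgebv_h2` with `h2` (NA with `defined = FALSE`
#'   when the denominator is zero), `n_envs`, `n_reps`.
#' @export
repeatability <- function(vc, n_envs = attr(vc, "n_envs"),
                          n_reps = attr(vc, "n_reps")) {
  if (is.null(n_envs) || is.null(n_reps) || n_envs < 1L || n_reps < 1L)
    stop("n_envs and n_reps must be >= 1")
  sG <- max(0, vc[["sigma_G2"]])
  sGE <- max(0, vc[["sigma_GxE2"]])
  sE <- max(0, vc[["sigma_e2"]])
  den <- sG + sGE / n_envs + sE / (n_reps * n_envs)
  if (den == 0)
    return(structure(list(h2 = NA_real_, defined = FALSE,
                          n_envs = n_envs, n_reps = n_reps),
                     class = "pgebv_h2"))
  structure(list(h2 = sG / den, defined = TRUE,
                 n_envs = n_envs, n_reps = n_reps),
            class = "pgebv_h2")
}

#' Within-environment repeatability
#'
#' The single-environment variant: genotype is random alongside replicate
#' and block, and h2 = sigma_G^2 / (sigma_G^2 + sigma_e^2 / r). Useful for
#' per-environment trait and per-band repeatability profiles.
#'
#' @param plots plot table.
#' @param environment environment id.
#' @param trait trait column name.
#' @return A `pgebv_h2` list with the within-environment h2 and the
#'   variance components in attribute `"vc"`.
#' @export
repeatability_env <- function(plots, environment, trait = "GY") {
  d <- plots[plots$env == environment, , drop = FALSE]
  if (nrow(d) == 0L) stop("no plots for environment ", environment)
  d$genotype <- factor(d$genotype)
  d$rep_f <- factor(d$rep)
  d$block_f <- factor(paste(d$rep, d$block, sep = ":"))
  d$.y <- d[[trait]]
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(.y ~ 1 + (1 | genotype) + (1 | rep_f) + (1 | block_f),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
  sG <- getv("genotype"); sE <- getv("Residual")
  r <- max(d$rep)
  den <- sG + sE / r
  structure(list(h2 = if (den > 0) sG / den else NA_real_, defined = den > 0,
                 n_envs = 1L, n_reps = r),
            class = "pgebv_h2",
            vc = c(sigma_G2 = sG, sigma_rep2 = getv("rep_f"),
                   sigma_block2 = getv("block_f"), sigma_e2 = sE))
}

#' Genotype x environment BLUE table
#'
#' Runs the per-environment BLUE model for grain yield and every reflectance
#' feature (columns named `B<wavelength>_F<flight>`), assembling the
#' two-step pipeline's intermediate: one row per genotype x environment,
#' one column per trait/feature. For the feature columns the fitted
#' grain-yield model is refit with the new response (same design), which is
#' much faster than refitting from scratch.
#'
#' @param plots plot table with reflectance columns.
#' @param features character vector of feature columns; defaults to every
#'   `B*_F*` column present.
#' @param trait target trait (default `"GY"`).
#' @return A data.frame of class `pgebv_blues`: columns `genotype`, `env`,
#'   `<trait>`, then features; attributes `gy_se` (data.frame of BLUE
#'   standard errors) and `n_missing` (count of non-estimable BLUEs).
#' @export
build_blue_table <- function(plots, features = NULL, trait = "GY") {
  if (is.null(features))
    features <- grep("^B\\d+_F\\d+$", names(plots), value = TRUE)
  envs <- unique(plots$env)
  out <- list(); ses <- list(); n_missing <- 0L
  for (env in envs) {
    ef <- fit_env_model(plots, env, trait)
    genos <- names(ef$blues)
    tab <- data.frame(genotype = genos, env = env, stringsAsFactors = FALSE)
    tab[[trait]] <- as.numeric(ef$blues)
    # refit() reuses the design, so responses must follow the fit's row order
    d_env <- plots[plots$env == env, , drop = FALSE]
    for (f in features) {
      y <- d_env[[f]]
      if (all(is.na(y))) { tab[[f]] <- NA_real_; n_missing <- n_missing + length(genos); next }
      rf <- suppressMessages(suppressWarnings(lme4::refit(ef$fit, newresp = y)))
      b <- lme4::fixef(rf)
      names(b) <- sub("^genotype", "", names(b))
      tab[[f]] <- as.numeric(b[genos])
    }
    out[[env]] <- tab
    ses[[env]] <- data.frame(genotype = genos, env = env,
                             se = as.numeric(ef$se), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pgebv_blues", "data.frame")
  attr(res, "gy_se") <- do.call(rbind, ses)
  attr(res, "n_missing") <- n_missing
  res
}
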
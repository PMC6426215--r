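#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: population and trial design,
#' variance components of the plot-level mixed model, GBS-like genotyping
#' noise, and the canopy-reflectance model. Defaults emulate the study
#' conditions of a 97-line biparental DH maize population evaluated as
#' testcrosses in 4 environments (2 years x well-watered/drought) in an
#' alpha-lattice with 2 replicates, imaged at 62 bands (392-850 nm) on 5
#' post-flowering flights.
#'
#' Variance components are on the grain-yield scale (Mg ha^-1)^2. The default
#' environment main effects reproduce the spread of reported treatment means
#' (about 5.7, 3.6, 5.9 and 1.9 Mg ha^-1 around a 4.28 Mg ha^-1 mean).
#'
#' @param n_lines number of DH lines.
#' @param n_envs number of environments (year x treatment cells).
#' @param n_reps replicates per environment.
#' @param block_size incomplete-block size within each replicate.
#' @param n_snps total SNPs simulated before QC.
#' @param n_qtl number of additive QTL behind grain yield (few-QTL
#'   architecture by default).
#' @param mu overall mean grain yield, Mg ha^-1.
#' @param var_g,var_gxe,var_rep,var_block,var_e variance components of the
#'   plot model: genotype, genotype-by-environment, replicate within
#'   environment, block within replicate, residual.
#' @param missing_rate,het_error_rate GBS-like noise: per-call missingness and
#'   residual heterozygote-call rate.
#' @param n_bands,n_flights,band_min_nm,band_max_nm hyperspectral layout.
#' @param flight_days days after planting of each flight (labels F1..Fn).
#' @param vis_loading latent-physiology loading of visible bands (<= 700 nm),
#'   relative to the NIR loading of 1 in unstressed environments.
#' @param nir_stress_factor multiplier on the >700 nm loading in stressed
#'   (drought) environments; captures the stronger genotype/treatment
#'   differentiation in the red/IR range under stress.
#' @param reflect_alpha,reflect_gamma,reflect_tau latent physiology
#'   s = alpha * standardized genetic value + gamma * standardized GxE +
#'   tau * noise, per line x environment.
#' @param w_scale reflectance-units amplitude of one latent SD at NIR loading 1.
#' @param env_band_jitter SD of the multiplicative environment-specific
#'   deviation of each band's loading (`w * (1 + jitter * u)`, `u ~ N(0,1)`
#'   per band x environment). Encodes that each environment expresses its
#'   own spectral response to the crop's physiological status — the reason
#'   a spectra-to-yield mapping trained in other environments transfers
#'   imperfectly, as multi-environment canopy-sensing trials report.
#' @param env_nuisance SD of the environment-specific band loadings of a
#'   second, yield-unrelated physiological latent (phenology / canopy
#'   structure). Spectra express it alongside yield physiology, and because
#'   its loadings differ by environment it degrades the transfer of a
#'   spectra-to-yield model across environments while leaving
#'   within-environment prediction intact.
#' @param band_noise_sd per-plot, per-band measurement noise SD
#'   (reflectance units).
#' @param env_names,env_effects,stressed environment labels, main effects
#'   (must average 0) and stress indicators; defaults follow the 2 years x 2
#'   treatments layout when `n_envs == 4`.
#' @param seed master seed; every stage derives its own stream from it.
#'
#' @return Object of class `pgebv_config` (a validated list).
#' @export
sim_config <- function(n_lines = 97L, n_envs = 4L, n_reps = 2L,
                       block_size = 10L,
                       n_snps = 2000L, n_qtl = 5L,
                       mu = 4.28,
                       var_g = 1, var_gxe = 0.5, var_rep = 0.1,
                       var_block = 0.1, var_e = 2,
                       missing_rate = 0.08, het_error_rate = 0.025,
                       n_bands = 62L, n_flights = 5L,
                       band_min_nm = 392, band_max_nm = 850,
                       flight_days = c(55, 62, 69, 75, 83),
                       vis_loading = 0.3, nir_stress_factor = 2.5,
                       reflect_alpha = 1, reflect_gamma = 0.7,
                       reflect_tau = 0.5,
                       w_scale = 0.02, env_band_jitter = 0.5,
                       env_nuisance = 1, band_noise_sd = 0.01,
                       env_names = NULL, env_effects = NULL, stressed = NULL,
                       seed = 1L) {
  counts <- c(n_lines = n_lines, n_envs = n_envs, n_reps = n_reps,
              block_size = block_size, n_snps = n_snps,
              n_bands = n_bands, n_flights = n_flights)
  if (any(counts < 1L)) stop("counts must be >= 1")
  if (n_qtl < 0L) stop("n_qtl must be >= 0")
  rates <- c(missing_rate = missing_rate, het_error_rate = het_error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  vars <- c(var_g, var_gxe, var_rep, var_block, var_e)
  if (any(vars < 0)) stop("variance components must be >= 0")
  if (band_min_nm > 392 || band_max_nm < 850)
    stop("band grid must span 392-850 nm")
  if (length(flight_days) != n_flights)
    flight_days <- seq(55, 83, length.out = n_flights)
  if (is.null(env_names)) {
    env_names <- if (n_envs == 4L) c("14WW", "14DS", "16WW", "16DS")
                 else sprintf("E%d", seq_len(n_envs))
  }
  if (is.null(env_effects)) {
    env_effects <- if (n_envs == 4L) c(1.42, -0.68, 1.62, -2.36)
                   else rep(0, n_envs)
  }
  env_effects <- env_effects - mean(env_effects)
  if (is.null(stressed)) {
    stressed <- if (n_envs == 4L) c(FALSE, TRUE, FALSE, TRUE)
                else rep(FALSE, n_envs)
  }
  stopifnot(length(env_names) == n_envs, length(env_effects) == n_envs,
            length(stressed) == n_envs)
  cfg <- list(n_lines = as.integer(n_lines), n_envs = as.integer(n_envs),
              n_reps = as.integer(n_reps), block_size = as.integer(block_size),
              n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
              mu = mu, var_g = var_g, var_gxe = var_gxe, var_rep = var_rep,
              var_block = var_block, var_e = var_e,
              missing_rate = missing_rate, het_error_rate = het_error_rate,
              n_bands = as.integer(n_bands), n_flights = as.integer(n_flights),
              band_min_nm = band_min_nm, band_max_nm = band_max_nm,
              flight_days = flight_days,
              vis_loading = vis_loading, nir_stress_factor = nir_stress_factor,
              reflect_alpha = reflect_alpha, reflect_gamma = reflect_gamma,
              reflect_tau = reflect_tau,
              w_scale = w_scale, env_band_jitter = env_band_jitter,
              env_nuisance = env_nuisance, band_noise_sd = band_noise_sd,
              env_names = env_names, env_effects = env_effects,
              stressed = stressed, seed = as.integer(seed))
  class(cfg) <- "pgebv_config"
  cfg
}

#' Plot-level heritability implied by a configuration
#'
#' sigma_G^2 over the sum of all plot-level variance components.
#' @param config a [sim_config()] object.
#' @return fraction in [0, 1].
#' @export
plot_h2 <- function(config) {
  tot <- config$var_g + config$var_gxe + config$var_rep +
    config$var_block + config$var_e
  config$var_g / tot
}

#' Entry-mean repeatability implied by a configuration
#'
#' The truth-implied broad-sense repeatability
#' h2 = sigma_G^2 / (sigma_G^2 + sigma_GxE^2 / l + sigma_e^2 / (r l)),
#' with l environments and r replicates.
#' @param config a [sim_config()] object.
#' @return fraction in [0, 1].
#' @export
true_repeatability <- function(config) {
  l <- config$n_envs; r <- config$n_reps
  config$var_g / (config$var_g + config$var_gxe / l + config$var_e / (r * l))
}

#' @export
print.pgebv_config <- function(x, ...) {
  cat(sprintf(paste0(
    "pgebv simulation config: %d lines, %d envs x %d reps, %d SNPs, %d QTL\n",
    "  variances G=%.2f GxE=%.2f rep=%.2f block=%.2f e=%.2f ",
    "(plot h2 = %.2f, entry-mean h2 = %.2f)\n",
    "  %d bands x %d flights, seed %d\n"),
    x$n_lines, x$n_envs, x$n_reps, x$n_snps, x$n_qtl,
    x$var_g, x$var_gxe, x$var_rep, x$var_block, x$var_e,
    plot_h2(x), true_repeatability(x), x$n_bands, x$n_flights, x$seed))
  invisible(x)
}

# wavelength centers of the band grid (nm)
band_grid <- function(config) {
  seq(config$band_min_nm, config$band_max_nm, length.out = config$n_bands)
}
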
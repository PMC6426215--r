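#' Simulate doubled-haploid genotypes
#'
#' Each DH line is one recombinant gamete of the biparental F1, doubled:
#' per chromosome the number of crossovers is Poisson(length/100) with
#' positions uniform and no interference (the Haldane model), the starting
#' parental phase is a fair coin, and the phase flips at each crossover.
#' Calls are fully homozygous (-1 = parent A, +1 = parent B), with no
#' heterozygous or missing calls before GBS noise injection.
#'
#' @param map_spec a [genetic_map_spec()].
#' @param n_lines number of DH lines (>= 1).
#' @param seed RNG seed.
#' @return A [geno_matrix()].
#' @export
simulate_dh_genotypes <- function(map_spec, n_lines, seed = 1L) {
  if (!inherits(map_spec, "pgebv_map")) stop("map_spec must be a pgebv_map")
  if (sum(lengths(map_spec$positions)) == 0L) stop("empty map")
  if (n_lines < 1L) stop("n_lines must be >= 1")
  set.seed(seed)
  n_chrom <- nrow(map_spec$chromosomes)
  lens <- map_spec$chromosomes$length_cM
  cols <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    pos <- map_spec$positions[[ci]]
    m <- length(pos)
    calls <- matrix(0L, n_lines, m)
    for (li in seq_len(n_lines)) {
      n_co <- rpois(1L, lens[ci] / 100)
      phase0 <- if (runif(1L) < 0.5) -1L else 1L
      if (n_co == 0L || m == 0L) {
        calls[li, ] <- phase0
      } else {
        xo <- sort(runif(n_co, 0, lens[ci]))
        flips <- findInterval(pos, xo)
        calls[li, ] <- phase0 * as.integer((-1L)^flips)
      }
    }
    cols[[ci]] <- calls
  }
  calls <- do.call(cbind, cols)
  geno_matrix(calls, sprintf("L%03d", seq_len(n_lines)), marker_table(map_spec))
}

#' Inject GBS-like genotyping noise
#'
#' Emulates the error structure of un-imputed genotyping-by-sequencing calls:
#' each call is independently set to missing with probability `missing_rate`,
#' and each surviving call is flipped to a (spurious) heterozygote with
#' probability `het_error_rate`.
#'
#' @param geno a [geno_matrix()].
#' @param missing_rate,het_error_rate per-call probabilities in [0, 1].
#' @param seed RNG seed.
#' @return A [geno_matrix()] with noise applied.
#' @export
apply_gbs_noise <- function(geno, missing_rate, het_error_rate, seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1 ||
      het_error_rate < 0 || het_error_rate > 1)
    stop("rates must be in [0, 1]")
  set.seed(seed)
  calls <- geno$calls
  n <- length(calls)
  drop <- runif(n) < missing_rate
  het <- runif(n) < het_error_rate
  calls[het & !drop] <- 0L
  calls[drop] <- NA_integer_
  geno_matrix(calls, geno$line_ids, geno$map)
}

#' Assign additive QTL effects and compute genetic values
#'
#' Samples `n_qtl` QTL without replacement from the marker positions, draws
#' Gaussian additive effects and rescales them so that the in-sample variance
#' of the genetic values equals `genetic_variance` exactly. A few-QTL
#' architecture (the default configuration) is the regime where
#' variable-selection priors such as BayesB are expected to beat ridge-type
#' shrinkage.
#'
#' @param geno a noise-free [geno_matrix()] (QTL genotypes must be observed).
#' @param n_qtl number of QTL (0 allowed: all genetic values 0).
#' @param genetic_variance target in-sample variance of genetic values.
#' @param seed RNG seed.
#' @return Object of class `pgebv_truth` with fields `line_ids`,
#'   `genetic_values` (named, trait units), `qtl` (data.frame marker, chrom,
#'   pos_cM, effect) and `genetic_variance`.
#' @export
assign_qtl_effects <- function(geno, n_qtl, genetic_variance = 1, seed = 1L) {
  p <- ncol(geno$calls)
  if (n_qtl > p) stop("n_qtl exceeds number of SNPs")
  set.seed(seed)
  if (n_qtl == 0L) {
    g <- setNames(rep(0, nrow(geno$calls)), geno$line_ids)
    qtl <- geno$map[0, ]
    qtl$effect <- numeric(0)
  } else {
    idx <- sort(sample.int(p, n_qtl))
    eff <- rnorm(n_qtl)
    gcalls <- geno$calls[, idx, drop = FALSE]
    if (anyNA(gcalls)) stop("QTL genotypes must be non-missing; use the pre-noise matrix")
    g <- drop(gcalls %*% eff)
    v <- var(g)
    if (v == 0) stop("genetic values are constant; cannot rescale to target variance")
    scl <- sqrt(genetic_variance / v)
    eff <- eff * scl
    g <- g * scl
    qtl <- geno$map[idx, c("marker", "chrom", "pos_cM")]
    qtl$effect <- eff
    rownames(qtl) <- NULL
    g <- setNames(g, geno$line_ids)
  }
  structure(list(line_ids = geno$line_ids, genetic_values = g, qtl = qtl,
                 genetic_variance = genetic_variance),
            class = "pgebv_truth")
}

#' Draw environment main effects and genotype-by-environment deviations
#'
#' Augments a truth bundle with the environment layer: fixed environment main
#' effects from the configuration and Gaussian GxE deviations with variance
#' `var_gxe`, centered to zero mean within each environment.
#'
#' @param truth a `pgebv_truth` from [assign_qtl_effects()].
#' @param config a [sim_config()].
#' @return The truth bundle with `env_effects` (named) and `gxe` (lines x
#'   envs matrix, zero column means) added.
#' @export
draw_env_structure <- function(truth, config) {
  n <- length(truth$line_ids)
  if (n != config$n_lines) stop("lines in truth do not match config")
  set.seed(derive_seed(config$seed, "env"))
  gxe <- matrix(rnorm(n * config$n_envs, sd = sqrt(config$var_gxe)),
                n, config$n_envs,
                dimnames = list(truth$line_ids, config$env_names))
  gxe <- sweep(gxe, 2L, colMeans(gxe))
  truth$env_effects <- setNames(config$env_effects, config$env_names)
  truth$gxe <- gxe
  truth
}

#' Simulate multi-environment alpha-lattice trials
#'
#' Generates plot-level records under the trial mixed model: plot value =
#' overall mean + genotype + environment + GxE + replicate(environment) +
#' block(replicate) + residual. Within each replicate the genotypes are
#' randomized and partitioned into consecutive incomplete blocks of
#' `block_size` (the last block is smaller when the line count does not
#' divide evenly; the table records this in the `"padded_blocks"` attribute).
#' Companion agronomic traits (anthesis date AD, silking date SD, plant
#' height PH) are generated as simple correlated traits for realism.
#'
#' @param truth a truth bundle; if it lacks the environment layer,
#'   [draw_env_structure()] is applied first.
#' @param config a [sim_config()].
#' @return A plot table (data.frame with columns env, year, treatment, rep,
#'   block, plot_id, genotype, GY, AD, SD, PH) with attributes `truth` (the
#'   augmented bundle) and `padded_blocks`.
#' @export
simulate_trials <- function(truth, config) {
  if (length(truth$line_ids) != config$n_lines)
    stop("lines in truth do not match config")
  if (is.null(truth$gxe)) truth <- draw_env_structure(truth, config)
  set.seed(derive_seed(config$seed, "trials"))
  n <- config$n_lines
  n_blocks <- ceiling(n / config$block_size)
  padded <- n %% config$block_size != 0L
  g <- truth$genetic_values
  zg <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g * 0
  # simple genetic signals for companion traits
  ad_g <- rnorm(n, 0, 1.2); ph_g <- 8 * zg + rnorm(n, 0, 4)
  rows <- vector("list", config$n_envs * config$n_reps)
  k <- 0L
  for (e in seq_len(config$n_envs)) {
    env <- config$env_names[e]
    ad_env <- if (config$stressed[e]) 1.5 else 0
    asi_env <- if (config$stressed[e]) 2.5 else 0.8
    for (r in seq_len(config$n_reps)) {
      ord <- sample.int(n)
      block <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(n)]
      rep_eff <- rnorm(1L, 0, sqrt(config$var_rep))
      blk_eff <- rnorm(n_blocks, 0, sqrt(config$var_block))
      eps <- rnorm(n, 0, sqrt(config$var_e))
      gy <- config$mu + g[ord] + truth$env_effects[e] + truth$gxe[ord, e] +
        rep_eff + blk_eff[block] + eps
      ad <- 57 + ad_g[ord] + ad_env + rnorm(n, 0, 0.8)
      asi <- pmax(0, asi_env + 0.3 * -zg[ord] + rnorm(n, 0, 0.7))
      ph <- 180 + ph_g[ord] + 5 * truth$env_effects[e] + rnorm(n, 0, 6)
      k <- k + 1L
      rows[[k]] <- data.frame(
        env = env,
        year = paste0("20", substr(env, 1L, 2L)),
        treatment = if (config$stressed[e]) "DS" else "WW",
        rep = r, block = block,
        plot_id = sprintf("%s_R%d_P%03d", env, r, seq_len(n)),
        genotype = truth$line_ids[ord],
        GY = as.numeric(gy), AD = round(ad, 1), SD = round(ad + asi, 1),
        PH = round(ph, 1), stringsAsFactors = FALSE)
    }
  }
  plots <- do.call(rbind, rows)
  rownames(plots) <- NULL
  attr(plots, "truth") <- truth
  attr(plots, "padded_blocks") <- padded
  plots
}

#' Simulate canopy hyperspectral reflectance linked to yield physiology
#'
#' A latent physiological status per line x environment,
#' `s = alpha * z_g + gamma * z_GxE + tau * noise` (z_g the standardized
#' genetic value), drives reflectance on top of a vegetation-like baseline
#' spectrum: `reflectance(plot, band, flight) = baseline(band) +
#' w(band, flight, env) * s + measurement noise`. Loadings `w` are larger
#' above 700 nm than in the visible range, are amplified by
#' `nir_stress_factor` in stressed (drought) environments, and grow with
#' flight index, so that later flights and the red/IR range carry most of the
#' genotype signal under stress — the qualitative pattern canopy sensing
#' shows in drought trials.
#'
#' @param plots a plot table from [simulate_trials()].
#' @param truth the truth bundle carried by `plots` (defaults to its
#'   attribute).
#' @param config a [sim_config()].
#' @return The plot table with `n_bands * n_flights` reflectance columns
#'   appended, named `B<wavelength>_F<flight>`; the truth attribute gains
#'   `latent_physiology` (lines x envs).
#' @export
simulate_reflectance <- function(plots, truth = attr(plots, "truth"), config) {
  if (config$n_bands < 1L || config$n_flights < 1L)
    stop("bands and flights must be >= 1")
  if (is.null(truth$gxe)) stop("truth lacks environment structure")
  set.seed(derive_seed(config$seed, "reflectance"))
  n <- config$n_lines
  g <- truth$genetic_values
  zg <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g * 0
  zgxe <- truth$gxe
  sds <- apply(zgxe, 2L, sd)
  sds[sds == 0] <- 1
  zgxe <- sweep(zgxe, 2L, sds, "/")
  s <- config$reflect_alpha * matrix(zg, n, config$n_envs) +
    config$reflect_gamma * zgxe +
    config$reflect_tau * matrix(rnorm(n * config$n_envs), n, config$n_envs)
  dimnames(s) <- list(truth$line_ids, config$env_names)

  wl <- band_grid(config)
  baseline <- 0.04 + 0.04 * exp(-((wl - 550) / 40)^2) +
    0.41 / (1 + exp(-(wl - 718) / 12))
  flight_gain <- seq(0.6, 1.4, length.out = config$n_flights)
  band_names <- as.vector(outer(round(wl), seq_len(config$n_flights),
                                function(b, f) sprintf("B%d_F%d", b, f)))

  # environment-specific deviation of each band's response: every
  # environment expresses its own spectral signature of crop status, which
  # is what limits the transfer of a spectra-to-yield mapping across
  # environments
  jitter <- matrix(rnorm(config$n_bands * config$n_envs,
                         sd = config$env_band_jitter),
                   config$n_bands, config$n_envs)
  # yield-unrelated physiological latent (phenology, canopy structure) that
  # bands express coherently -- one environment-level loading shared by the
  # whole spectrum. Within an environment the yield latent has its own band
  # fingerprint (the jitter above) and can be separated from it; a model
  # transferred from other environments cannot, and reads the nuisance as
  # signal.
  q <- matrix(rnorm(n * config$n_envs), n, config$n_envs)
  c_env <- rnorm(config$n_envs, sd = config$env_nuisance)

  env_idx <- match(plots$env, config$env_names)
  line_idx <- match(plots$genotype, truth$line_ids)
  s_plot <- s[cbind(line_idx, env_idx)]
  q_plot <- q[cbind(line_idx, env_idx)]
  n_plots <- nrow(plots)
  refl <- matrix(NA_real_, n_plots, config$n_bands * config$n_flights,
                 dimnames = list(NULL, band_names))
  for (f in seq_len(config$n_flights)) {
    for (b in seq_len(config$n_bands)) {
      m_b <- ifelse(wl[b] > 700,
                    ifelse(config$stressed[env_idx], config$nir_stress_factor, 1),
                    config$vis_loading)
      w <- config$w_scale * m_b * flight_gain[f] * (1 + jitter[b, env_idx])
      v <- config$w_scale * m_b * flight_gain[f] * c_env[env_idx]
      col <- (f - 1L) * config$n_bands + b
      refl[, col] <- baseline[b] + w * s_plot + v * q_plot +
        rnorm(n_plots, 0, config$band_noise_sd)
    }
  }
  out <- cbind(plots, as.data.frame(refl, check.names = FALSE))
  truth$latent_physiology <- s
  attr(out, "truth") <- truth
  attr(out, "padded_blocks") <- attr(plots, "padded_blocks")
  out
}

#' Simulate the complete synthetic study
#'
#' Runs the full generative chain: genetic map, DH genotypes, GBS noise, QTL
#' effects, environment structure, alpha-lattice trials and hyperspectral
#' reflectance. Every stage derives its own seed from `config$seed`, so an
#' identical configuration reproduces the study bit for bit.
#'
#' @param config a [sim_config()].
#' @return A list of class `pgebv_study`: `map_spec`, `geno_clean` (pre-noise
#'   truth genotypes), `geno` (with GBS noise), `truth`, `plots` (with
#'   reflectance columns), `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  map_spec <- genetic_map_spec(n_snps = config$n_snps)
  geno_clean <- simulate_dh_genotypes(map_spec, config$n_lines,
                                      seed = derive_seed(config$seed, "geno"))
  geno <- apply_gbs_noise(geno_clean, config$missing_rate,
                          config$het_error_rate,
                          seed = derive_seed(config$seed, "noise"))
  truth <- assign_qtl_effects(geno_clean, config$n_qtl,
                              genetic_variance = config$var_g,
                              seed = derive_seed(config$seed, "qtl"))
  truth <- draw_env_structure(truth, config)
  plots <- simulate_trials(truth, config)
  plots <- simulate_reflectance(plots, attr(plots, "truth"), config)
  structure(list(map_spec = map_spec, geno_clean = geno_clean, geno = geno,
                 truth = attr(plots, "truth"), plots = plots, config = config),
            class = "pgebv_study")
}

#' @export
print.pgebv_study <- function(x, ...) {
  cat(sprintf(paste0("pgebv synthetic study: %d lines, %d envs, %d plots, ",
                     "%d SNPs, %d reflectance features\n"),
              x$config$n_lines, x$config$n_envs, nrow(x$plots),
              ncol(x$geno$calls), x$config$n_bands * x$config$n_flights))
  invisible(x)
}
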
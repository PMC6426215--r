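# Shared fixtures and independent oracles used across the test files.

# small two-chromosome map for fast simulator tests
tiny_map <- function(lens = c(80, 60), n_snps = 60) {
  genetic_map_spec(chrom_lengths = lens, n_snps = n_snps)
}

# a small noise-free study used by several files
small_clean_geno <- function(n_lines = 50, n_snps = 300, seed = 42) {
  simulate_dh_genotypes(genetic_map_spec(n_snps = n_snps), n_lines, seed = seed)
}

# brute-force bin partition: consecutive SNPs with identical full call
# vectors belong to one bin (pattern-hash oracle for noise-free data)
pattern_hash_bins <- function(geno) {
  hashes <- apply(geno$calls, 2L, paste, collapse = ",")
  chrom <- geno$map$chrom
  new_bin <- c(TRUE, hashes[-1L] != hashes[-length(hashes)] |
                 chrom[-1L] != chrom[-length(chrom)])
  cumsum(new_bin)
}

# method-of-moments variance components from a balanced genotype x env x rep
# table (two-way ANOVA expected mean squares)
mom_components <- function(plots, trait = "GY") {
  y <- plots[[trait]]
  g <- factor(plots$genotype); e <- factor(plots$env)
  n_g <- nlevels(g); n_e <- nlevels(e); n_r <- nrow(plots) / (n_g * n_e)
  cell <- tapply(y, list(g, e), mean)
  gm <- rowMeans(cell); em <- colMeans(cell); mu <- mean(cell)
  ss_g <- n_e * n_r * sum((gm - mu)^2)
  ss_e <- n_g * n_r * sum((em - mu)^2)
  inter <- sweep(sweep(cell, 1, gm), 2, em) + mu
  ss_ge <- n_r * sum(inter^2)
  ss_w <- sum((y - cell[cbind(g, e)])^2)
  ms_g <- ss_g / (n_g - 1); ms_ge <- ss_ge / ((n_g - 1) * (n_e - 1))
  ms_w <- ss_w / (n_g * n_e * (n_r - 1))
  c(var_g = (ms_g - ms_ge) / (n_e * n_r),
    var_gxe = (ms_ge - ms_w) / n_r,
    var_w = ms_w)
}

# explicit-covariance generalized least squares for the per-environment BLUE
# model: y = X beta + Z_r u_r + Z_b u_b + e with known variances
gls_blues_oracle <- function(d, var_rep, var_block, var_e) {
  X <- stats::model.matrix(~ 0 + factor(genotype), d)
  Zr <- stats::model.matrix(~ 0 + factor(rep), d)
  Zb <- stats::model.matrix(~ 0 + factor(paste(rep, block)), d)
  V <- var_rep * tcrossprod(Zr) + var_block * tcrossprod(Zb) +
    var_e * diag(nrow(d))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$GY)
  setNames(drop(b), levels(factor(d$genotype)))
}

# one-environment alpha-lattice sample with known variance components
sim_env_plots <- function(n_geno = 12, n_rep = 2, block_size = 4,
                          var_rep = 0.3, var_block = 0.2, var_e = 1,
                          g_eff = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(g_eff)) g_eff <- rnorm(n_geno)
  n_blocks <- ceiling(n_geno / block_size)
  rows <- list()
  for (r in seq_len(n_rep)) {
    ord <- sample.int(n_geno)
    block <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_geno)]
    re <- rnorm(1, 0, sqrt(var_rep)); be <- rnorm(n_blocks, 0, sqrt(var_block))
    rows[[r]] <- data.frame(
      env = "E1", rep = r, block = block,
      genotype = sprintf("G%02d", ord),
      GY = 5 + g_eff[ord] + re + be[block] + rnorm(n_geno, 0, sqrt(var_e)))
  }
  do.call(rbind, rows)
}

# tiny two-environment BLUE table + bin map pair for prediction tests
toy_prediction_inputs <- function(n_geno = 24, n_bins = 30, n_envs = 2,
                                  n_h = 8, seed = 99) {
  set.seed(seed)
  genos <- sprintf("G%02d", seq_len(n_geno))
  calls <- matrix(sample(c(-1L, 1L), n_geno * n_bins, replace = TRUE),
                  n_geno, n_bins, dimnames = list(genos, sprintf("bin%03d", seq_len(n_bins))))
  bm <- structure(list(
    bins = data.frame(bin = colnames(calls), chrom = 1L,
                      first_snp = colnames(calls), last_snp = colnames(calls),
                      n_snps = 1L, pos_cM = seq_len(n_bins)),
    bin_calls = calls, line_ids = genos), class = "pgebv_binmap")
  eff <- rnorm(n_bins, 0, 0.3)
  g <- drop(calls %*% eff)
  rows <- list()
  for (e in seq_len(n_envs)) {
    H <- matrix(rnorm(n_geno * n_h, 0.2, 0.02), n_geno, n_h)
    H <- H + 0.03 * g  # spectra track genetic value
    colnames(H) <- sprintf("B%d_F1", 400 + seq_len(n_h))
    d <- data.frame(genotype = genos, env = sprintf("E%d", e),
                    GY = 5 + g + rnorm(n_geno, 0, 0.5),
                    stringsAsFactors = FALSE)
    rows[[e]] <- cbind(d, as.data.frame(H))
  }
  blues <- do.call(rbind, rows)
  class(blues) <- c("pgebv_blues", "data.frame")
  list(blues = blues, binmap = bm, genetic = g)
}
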
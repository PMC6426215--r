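#' Genetic map specification
#'
#' Defines chromosomes, their genetic lengths and ordered SNP positions for
#' the doubled-haploid genotype simulator. By default SNPs are placed on an
#' evenly spaced grid within each chromosome, with the number per chromosome
#' proportional to its genetic length.
#'
#' @param chrom_lengths numeric vector of chromosome lengths in cM. The
#'   default is a 10-chromosome maize-like map totalling 1150.16 cM, with
#'   lengths decreasing from chromosome 1 to 10.
#' @param n_snps total number of SNPs to place across the genome.
#' @param positions optional list (one numeric vector per chromosome) of SNP
#'   positions in cM; overrides `n_snps`.
#'
#' @return An object of class `pgebv_map`: a list with `chromosomes`
#'   (data.frame `chrom`, `length_cM`) and `positions` (list of ordered cM
#'   positions per chromosome).
#' @export
genetic_map_spec <- function(chrom_lengths = default_chrom_lengths(),
                             n_snps = 2000L,
                             positions = NULL) {
  if (length(chrom_lengths) < 1L || any(chrom_lengths < 0))
    stop("chromosome lengths must be non-negative and non-empty")
  if (sum(chrom_lengths) <= 0)
    stop("total map length must be > 0")
  n_chrom <- length(chrom_lengths)
  chroms <- data.frame(chrom = seq_len(n_chrom), length_cM = chrom_lengths)
  if (is.null(positions)) {
    if (n_snps < n_chrom) stop("need at least one SNP per chromosome")
    # proportional allocation, at least 1 per chromosome
    alloc <- pmax(1L, round(n_snps * chrom_lengths / sum(chrom_lengths)))
    positions <- lapply(seq_len(n_chrom), function(i) {
      k <- alloc[i]
      if (chrom_lengths[i] == 0) return(rep(0, k))
      seq(0, chrom_lengths[i], length.out = k + 2L)[-c(1L, k + 2L)]
    })
  } else {
    if (length(positions) != n_chrom)
      stop("positions must have one vector per chromosome")
    for (i in seq_len(n_chrom)) {
      p <- positions[[i]]
      if (any(p < 0) || is.unsorted(p) || any(p > chrom_lengths[i]))
        stop("positions must be non-negative, non-decreasing and <= length on chromosome ", i)
    }
  }
  out <- list(chromosomes = chroms, positions = positions)
  class(out) <- "pgebv_map"
  out
}

# Maize-like relative chromosome lengths scaled to a 1150.16 cM genome.
default_chrom_lengths <- function(total_cM = 1150.16) {
  w <- c(1.55, 1.30, 1.25, 1.18, 1.10, 0.95, 0.93, 0.90, 0.88, 0.85)
  total_cM * w / sum(w)
}

#' @export
print.pgebv_map <- function(x, ...) {
  cat(sprintf("pgebv genetic map: %d chromosomes, %d SNPs, %.2f cM\n",
              nrow(x$chromosomes), sum(lengths(x$positions)),
              sum(x$chromosomes$length_cM)))
  invisible(x)
}

# Flat marker table (marker, chrom, pos_cM) from a map spec.
marker_table <- function(map_spec) {
  n_per <- lengths(map_spec$positions)
  chrom <- rep(map_spec$chromosomes$chrom, n_per)
  pos <- unlist(map_spec$positions, use.names = FALSE)
  data.frame(marker = sprintf("S%d_%d", chrom,
                              unlist(lapply(n_per, seq_len), use.names = FALSE)),
             chrom = chrom, pos_cM = pos, stringsAsFactors = FALSE)
}
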
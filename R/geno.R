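#' Genotype matrix container
#'
#' Lines x SNP calls from a biparental DH population in symmetric coding:
#' parent A homozygote = -1, parent B homozygote = +1, heterozygote = 0,
#' missing = NA. On CSV/VCF export this maps to the conventional
#' \{0, 1, 2, NA\} dosage coding (A hom = 0, het = 1, B hom = 2).
#'
#' @param calls integer matrix (lines x SNPs) over \{-1, 0, 1, NA\}.
#' @param line_ids character vector of line names (rownames of `calls`).
#' @param map data.frame with columns `marker`, `chrom`, `pos_cM`, ordered by
#'   (chrom, pos_cM), one row per column of `calls`.
#'
#' @return Object of class `pgebv_geno`.
#' @export
geno_matrix <- function(calls, line_ids = rownames(calls), map) {
  if (!is.matrix(calls)) stop("calls must be a matrix")
  if (is.null(line_ids)) line_ids <- sprintf("L%03d", seq_len(nrow(calls)))
  if (nrow(map) != ncol(calls))
    stop("map rows must match genotype columns")
  if (!all(c("marker", "chrom", "pos_cM") %in% names(map)))
    stop("map needs columns marker, chrom, pos_cM")
  ord <- order(map$chrom, map$pos_cM)
  if (!identical(ord, seq_len(nrow(map))))
    stop("map must be ordered by (chrom, pos_cM)")
  if (anyDuplicated(map$marker)) stop("duplicate marker ids in map")
  bad <- calls[!is.na(calls)]
  if (!all(bad %in% c(-1L, 0L, 1L)))
    stop("calls must be in {-1, 0, 1, NA}")
  rownames(calls) <- line_ids
  colnames(calls) <- map$marker
  structure(list(calls = calls, line_ids = line_ids, map = map),
            class = "pgebv_geno")
}

#' @export
print.pgebv_geno <- function(x, ...) {
  cat(sprintf("pgebv genotypes: %d lines x %d SNPs on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$calls))
  het <- mean(x$calls == 0, na.rm = TRUE)
  cat(sprintf("  missing %.2f%%, heterozygous %.2f%%\n", 100 * miss, 100 * het))
  invisible(x)
}

#' @export
dim.pgebv_geno <- function(x) dim(x$calls)

# subset a pgebv_geno by line / snp index, keeping map in sync
subset_geno <- function(geno, lines = NULL, snps = NULL) {
  calls <- geno$calls
  map <- geno$map
  if (!is.null(snps)) {
    calls <- calls[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
    rownames(map) <- NULL
  }
  ids <- geno$line_ids
  if (!is.null(lines)) {
    calls <- calls[lines, , drop = FALSE]
    ids <- ids[lines]
  }
  geno_matrix(calls, ids, map)
}
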
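#' Per-SNP and per-line quality-control statistics
#'
#' Minor allele frequency is computed from non-missing calls, counting a
#' heterozygote as half of each allele; missing and heterozygosity rates are
#' simple call fractions.
#'
#' @param geno a [geno_matrix()].
#' @return A list of class `pgebv_qc`: `maf`, `missing_rate_snp` (per SNP;
#'   `maf` is NA for all-missing SNPs), `het_rate_line`, `missing_rate_line`
#'   (per line).
#' @export
compute_qc_stats <- function(geno) {
  calls <- geno$calls
  if (length(calls) == 0L) stop("empty genotype matrix")
  n_obs <- colSums(!is.na(calls))
  nB <- colSums(calls == 1L, na.rm = TRUE)
  nH <- colSums(calls == 0L, na.rm = TRUE)
  fB <- ifelse(n_obs > 0, (nB + 0.5 * nH) / n_obs, NA_real_)
  maf <- pmin(fB, 1 - fB)
  missing_snp <- 1 - n_obs / nrow(calls)
  n_obs_l <- rowSums(!is.na(calls))
  het_line <- ifelse(n_obs_l > 0, rowSums(calls == 0L, na.rm = TRUE) / n_obs_l, 0)
  missing_line <- 1 - n_obs_l / ncol(calls)
  structure(list(maf = setNames(maf, colnames(calls)),
                 missing_rate_snp = setNames(missing_snp, colnames(calls)),
                 het_rate_line = setNames(het_line, rownames(calls)),
                 missing_rate_line = setNames(missing_line, rownames(calls))),
            class = "pgebv_qc")
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' Retains SNPs with MAF strictly greater than `maf_min` and missing rate
#' strictly less than `missing_max` (strict inequalities, matching the usual
#' "MAF greater than 0.05, missing rate less than 20%" QC phrasing).
#'
#' @param geno a [geno_matrix()].
#' @param maf_min,missing_max thresholds.
#' @return Filtered [geno_matrix()]; attribute `"removed_snps"` lists dropped
#'   marker ids.
#' @export
filter_snps <- function(geno, maf_min = 0.05, missing_max = 0.20) {
  qc <- compute_qc_stats(geno)
  keep <- !is.na(qc$maf) & qc$maf > maf_min & qc$missing_rate_snp < missing_max
  if (!any(keep)) stop("all SNPs removed by filtering")
  out <- subset_geno(geno, snps = which(keep))
  attr(out, "removed_snps") <- colnames(geno$calls)[!keep]
  out
}

#' Filter DH lines on heterozygosity and missingness
#'
#' Removes lines whose heterozygosity rate exceeds `het_max` or whose missing
#' rate exceeds `missing_max` (strictly greater than, so a line at exactly
#' the threshold is retained).
#'
#' @param geno a [geno_matrix()].
#' @param het_max,missing_max thresholds.
#' @return Filtered [geno_matrix()]; attribute `"removed_lines"` lists
#'   dropped line ids.
#' @export
filter_lines <- function(geno, het_max = 0.05, missing_max = 0.20) {
  if (nrow(geno$calls) < 1L) stop("no lines")
  qc <- compute_qc_stats(geno)
  keep <- qc$het_rate_line <= het_max & qc$missing_rate_line <= missing_max
  if (!any(keep)) stop("all lines removed by filtering")
  out <- subset_geno(geno, lines = which(keep))
  attr(out, "removed_lines") <- geno$line_ids[!keep]
  out
}

#' Orientation-free similarity between two SNP call vectors
#'
#' Over lines where both calls are homozygous (heterozygous and missing calls
#' are excluded), similarity = max(p, 1 - p) with p the fraction of matching
#' calls. This is invariant to arbitrary allele labeling. Pairs with fewer
#' than `min_lines` comparable lines are non-informative and return NA.
#'
#' @param calls_i,calls_j call vectors in \{-1, 0, 1, NA\} of equal length.
#' @param min_lines minimum comparable lines for a defined similarity.
#' @return fraction in [0.5, 1], or NA when undefined.
#' @export
pairwise_similarity <- function(calls_i, calls_j, min_lines = 10L) {
  if (length(calls_i) != length(calls_j)) stop("columns must have equal length")
  ok <- !is.na(calls_i) & !is.na(calls_j) & calls_i != 0L & calls_j != 0L
  n <- sum(ok)
  if (n < min_lines) return(NA_real_)
  p <- sum(calls_i[ok] == calls_j[ok]) / n
  max(p, 1 - p)
}

# Similarities between each SNP and its neighbour at +d columns, vectorized
# over a homozygous-call matrix (lines x snps). Returns a numeric vector of
# length ncol - d; NA where fewer than min_lines comparable lines.
.shifted_similarity <- function(calls, d, min_lines = 10L) {
  p <- ncol(calls)
  if (p <= d) return(numeric(0))
  a <- calls[, seq_len(p - d), drop = FALSE]
  b <- calls[, seq_len(p - d) + d, drop = FALSE]
  ok <- !is.na(a) & !is.na(b) & a != 0L & b != 0L
  n <- colSums(ok)
  eq <- colSums(ok & (a == b), na.rm = TRUE)
  pm <- ifelse(n >= min_lines, eq / n, NA_real_)
  pmax(pm, 1 - pm)
}

#' Remove unlinked SNPs by windowed similarity
#'
#' A SNP is retained iff its maximum orientation-free similarity to any other
#' SNP within a centered window of `window` SNPs on the same chromosome
#' (window/2 neighbours on each side, truncated at chromosome ends) reaches
#' `threshold`. Removal is decided in one pass on the input matrix, so
#' removals do not cascade. Chromosomes with fewer than 2 SNPs keep their
#' SNPs with a warning.
#'
#' @param geno a [geno_matrix()] ordered by map position.
#' @param window window size in SNPs (total; half on each side).
#' @param threshold similarity threshold.
#' @param min_lines minimum comparable lines for a defined similarity.
#' @return Filtered [geno_matrix()]; attribute `"removed_snps"`.
#' @export
remove_unlinked_snps <- function(geno, window = 8L, threshold = 0.95,
                                 min_lines = 10L) {
  half <- max(1L, window %/% 2L)
  map <- geno$map
  keep <- logical(ncol(geno$calls))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    if (m < 2L) {
      warning("chromosome ", ch, " has fewer than 2 SNPs; retained unchecked")
      keep[idx] <- TRUE
      next
    }
    calls <- geno$calls[, idx, drop = FALSE]
    best <- rep(-Inf, m)
    for (d in seq_len(min(half, m - 1L))) {
      s <- .shifted_similarity(calls, d, min_lines)
      s[is.na(s)] <- -Inf  # undefined pairs do not support retention
      left <- seq_len(m - d)
      best[left] <- pmax(best[left], s)
      best[left + d] <- pmax(best[left + d], s)
    }
    keep[idx] <- best >= threshold
  }
  if (!any(keep)) stop("all SNPs removed as unlinked")
  out <- subset_geno(geno, snps = which(keep))
  attr(out, "removed_snps") <- colnames(geno$calls)[!keep]
  out
}

#' Merge consecutive co-segregating SNPs into bins
#'
#' Greedy left-to-right scan per chromosome: a SNP joins the current bin iff
#' its orientation-free similarity to the bin's running consensus reaches
#' `threshold`, otherwise it starts a new bin. SNPs whose best orientation is
#' the complement of the bin consensus are flipped before their calls are
#' added, so the consensus stays phase-coherent. The bin's consensus call per
#' line is the majority non-missing homozygous call (ties give a missing
#' call); bin position is the cM midpoint of the first and last member SNP.
#'
#' @param geno a filtered, map-ordered [geno_matrix()].
#' @param threshold similarity threshold for joining a bin.
#' @param min_lines minimum comparable lines for a defined similarity;
#'   undefined similarities start a new bin.
#' @return Object of class `pgebv_binmap`: `bins` (data.frame bin, chrom,
#'   first_snp, last_snp, n_snps, pos_cM), `bin_calls` (lines x bins matrix
#'   over \{-1, 1, NA\}), `line_ids`.
#' @export
merge_bins <- function(geno, threshold = 0.95, min_lines = 10L) {
  map <- geno$map
  n <- nrow(geno$calls)
  bins <- list(); bin_calls <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    # votes per line for the current bin: +1 for call +1, -1 for call -1
    votesA <- NULL; votesB <- NULL
    first <- NULL; last <- NULL; count <- 0L
    close_bin <- function() {
      cons <- ifelse(votesB > votesA, 1L, ifelse(votesA > votesB, -1L, NA_integer_))
      bins[[length(bins) + 1L]] <<- data.frame(
        chrom = ch, first_snp = map$marker[first], last_snp = map$marker[last],
        n_snps = count,
        pos_cM = (map$pos_cM[first] + map$pos_cM[last]) / 2,
        stringsAsFactors = FALSE)
      bin_calls[[length(bin_calls) + 1L]] <<- cons
    }
    for (j in idx) {
      col <- geno$calls[, j]
      if (is.null(votesA)) {
        votesA <- as.integer(!is.na(col) & col == -1L)
        votesB <- as.integer(!is.na(col) & col == 1L)
        first <- j; last <- j; count <- 1L
        next
      }
      cons <- ifelse(votesB > votesA, 1L, ifelse(votesA > votesB, -1L, NA_integer_))
      ok <- !is.na(cons) & !is.na(col) & col != 0L
      ncmp <- sum(ok)
      if (ncmp < min_lines) sim <- NA_real_
      else {
        p <- sum(col[ok] == cons[ok]) / ncmp
        sim <- max(p, 1 - p)
      }
      if (!is.na(sim) && sim >= threshold) {
        if (ncmp > 0 && sum(col[ok] == cons[ok]) / ncmp < 0.5) col <- -col
        votesA <- votesA + as.integer(!is.na(col) & col == -1L)
        votesB <- votesB + as.integer(!is.na(col) & col == 1L)
        last <- j; count <- count + 1L
      } else {
        close_bin()
        votesA <- as.integer(!is.na(col) & col == -1L)
        votesB <- as.integer(!is.na(col) & col == 1L)
        first <- j; last <- j; count <- 1L
      }
    }
    close_bin()
  }
  bins <- do.call(rbind, bins)
  bins <- cbind(bin = sprintf("bin%04d", seq_len(nrow(bins))), bins,
                stringsAsFactors = FALSE)
  calls <- do.call(cbind, bin_calls)
  dimnames(calls) <- list(geno$line_ids, bins$bin)
  structure(list(bins = bins, bin_calls = calls, line_ids = geno$line_ids),
            class = "pgebv_binmap")
}

#' @export
print.pgebv_binmap <- function(x, ...) {
  cat(sprintf("pgebv bin map: %d bins over %d chromosome(s), %d lines\n",
              nrow(x$bins), length(unique(x$bins$chrom)), length(x$line_ids)))
  if (!is.null(x$bins$est_pos_cM))
    cat(sprintf("  estimated map length %.2f cM (%d unresolved interval(s))\n",
                sum(tapply(x$bins$est_pos_cM, x$bins$chrom, max), na.rm = TRUE),
                sum(attr(x, "unresolved", exact = TRUE) %||% 0)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate genetic distances between adjacent bins
#'
#' For each adjacent bin pair on a chromosome the recombination fraction
#' r-hat is the fraction of lines with opposite parental calls among lines
#' where both bins are called, mapped to cM with the Haldane function
#' d = -50 ln(1 - 2 r). Pairs with r-hat >= 0.5 are unresolved: their
#' distance is NA and they are counted in the `"unresolved"` attribute.
#'
#' @param binmap a [merge_bins()] result.
#' @return The bin map with columns `est_dist_cM` (distance to the previous
#'   bin; NA for the first bin of a chromosome or unresolved pairs) and
#'   `est_pos_cM` (cumulative position, carrying unresolved distances as 0
#'   with the flag preserved) added to `bins`.
#' @export
estimate_map_distances <- function(binmap) {
  bins <- binmap$bins
  calls <- binmap$bin_calls
  dist <- rep(NA_real_, nrow(bins))
  unresolved <- 0L
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    if (length(idx) < 2L) next
    for (k in seq_along(idx)[-1L]) {
      i <- idx[k - 1L]; j <- idx[k]
      a <- calls[, i]; b <- calls[, j]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) { unresolved <- unresolved + 1L; next }
      r <- mean(a[ok] != b[ok])
      if (r >= 0.5) { unresolved <- unresolved + 1L; next }
      dist[j] <- -50 * log(1 - 2 * r)
    }
  }
  pos <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    d <- dist[idx]; d[1L] <- 0; d[is.na(d)] <- 0
    pos[idx] <- cumsum(d)
  }
  bins$est_dist_cM <- dist
  bins$est_pos_cM <- pos
  out <- binmap
  out$bins <- bins
  attr(out, "unresolved") <- unresolved
  out
}

#' Run the full 5-step bin-map construction
#'
#' Convenience wrapper chaining the QC and binning steps: (1) SNP filtering
#' on MAF and missingness, (2) line filtering on heterozygosity and
#' missingness, (3) windowed removal of unlinked SNPs, (4) greedy merging of
#' consecutive co-segregating SNPs into bins, (5) Haldane distance
#' estimation so the bins can serve as genetic markers.
#'
#' @param geno a [geno_matrix()].
#' @param maf_min,missing_max_snp SNP filter thresholds.
#' @param het_max,missing_max_line line filter thresholds.
#' @param window,sim_threshold unlinked-SNP window and similarity threshold.
#' @param bin_threshold similarity threshold for bin merging.
#' @return A `pgebv_binmap` with estimated distances; attribute `"qc_log"`
#'   records counts removed at each step.
#' @export
build_binmap <- function(geno, maf_min = 0.05, missing_max_snp = 0.20,
                         het_max = 0.05, missing_max_line = 0.20,
                         window = 8L, sim_threshold = 0.95,
                         bin_threshold = 0.95) {
  n0 <- ncol(geno$calls); l0 <- nrow(geno$calls)
  g1 <- filter_snps(geno, maf_min, missing_max_snp)
  g2 <- filter_lines(g1, het_max, missing_max_line)
  g3 <- remove_unlinked_snps(g2, window, sim_threshold)
  bm <- merge_bins(g3, bin_threshold)
  bm <- estimate_map_distances(bm)
  attr(bm, "qc_log") <- list(
    snps_in = n0, snps_after_maf_missing = ncol(g1$calls),
    lines_in = l0, lines_retained = nrow(g2$calls),
    snps_after_unlinked = ncol(g3$calls), n_bins = nrow(bm$bins))
  bm
}
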
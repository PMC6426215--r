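make_geno <- function(calls, chrom = rep(1L, ncol(calls)),
                      pos = seq_len(ncol(calls))) {
  map <- data.frame(marker = sprintf("m%03d", seq_len(ncol(calls))),
                    chrom = chrom, pos_cM = as.numeric(pos))
  geno_matrix(calls, sprintf("L%02d", seq_len(nrow(calls))), map)
}

test_that("QC statistics match direct counting", {
  # SNP1: (A,A,B,B) -> maf 0.5; SNP2: (A,A,A,NA) -> maf 0, missing 0.25
  calls <- cbind(c(-1L, -1L, 1L, 1L), c(-1L, -1L, -1L, NA))
  g <- make_geno(calls)
  qc <- compute_qc_stats(g)
  expect_equal(unname(qc$maf), c(0.5, 0))
  expect_equal(unname(qc$missing_rate_snp), c(0, 0.25))

  # het counts as half of each allele: (A, het, B, B) -> fB = 2.5/4
  g2 <- make_geno(cbind(c(-1L, 0L, 1L, 1L)))
  expect_equal(unname(compute_qc_stats(g2)$maf), 1 - 2.5 / 4)

  # random fixture vs brute-force recount
  set.seed(1)
  calls <- matrix(sample(c(-1L, 0L, 1L, NA), 97 * 200, replace = TRUE,
                         prob = c(0.45, 0.03, 0.44, 0.08)), 97, 200)
  g3 <- make_geno(calls)
  qc3 <- compute_qc_stats(g3)
  brute_maf <- apply(calls, 2L, function(x) {
    x <- x[!is.na(x)]
    fB <- (sum(x == 1) + 0.5 * sum(x == 0)) / length(x)
    min(fB, 1 - fB)
  })
  expect_equal(unname(qc3$maf), brute_maf)
  expect_equal(unname(qc3$missing_rate_line), rowMeans(is.na(calls)))
})

test_that("SNP filter applies strict thresholds", {
  set.seed(2)
  n <- 97
  base <- matrix(sample(c(-1L, 1L), n * 1000, replace = TRUE), n, 1000)
  # 100 SNPs given maf < 0.05, 50 SNPs given missing >= 0.20, 10 overlap
  low_maf <- 1:100; high_miss <- 91:140
  for (j in low_maf) { base[, j] <- 1L; base[sample(n, 3), j] <- -1L }  # maf ~0.03
  g <- make_geno(base)
  for (j in high_miss) g$calls[sample(n, 25), j] <- NA  # missing ~0.26
  kept <- filter_snps(g)
  expect_equal(ncol(kept$calls), 1000 - 100 - 50 + 10)

  # pass-through thresholds keep every polymorphic SNP
  g_clean <- make_geno(base)
  expect_identical(ncol(filter_snps(g_clean, maf_min = 0, missing_max = 1.01)$calls),
                   1000L)
  # idempotence
  expect_identical(filter_snps(kept)$calls, kept$calls)
})

test_that("line filter removes high-het lines, strict at the boundary", {
  g <- small_clean_geno(97, 400)
  p <- ncol(g$calls)
  gh <- g
  gh$calls[1:3, ] <- 0L  # 100% het lines
  gh$calls[4, sample(p, floor(0.05 * p))] <- 0L  # at most 5% het: retained
  kept <- filter_lines(gh)
  expect_equal(nrow(kept$calls), 94)
  expect_true("L004" %in% kept$line_ids)
  expect_identical(attr(kept, "removed_lines"), c("L001", "L002", "L003"))
  # clean simulation: nothing removed; idempotent
  expect_equal(nrow(filter_lines(g)$calls), 97)
  expect_identical(filter_lines(kept)$calls, kept$calls)
})

test_that("pairwise similarity is orientation-free and excludes het/missing", {
  a <- rep(c(-1L, 1L), 20)
  expect_equal(pairwise_similarity(a, a), 1)
  expect_equal(pairwise_similarity(a, -a), 1)   # complement: still 1
  b <- a; b[1:4] <- -b[1:4]
  expect_equal(pairwise_similarity(a, b), 36 / 40)
  # 90 of 95 comparable agree
  set.seed(3)
  x <- sample(c(-1L, 1L), 95, TRUE); y <- x; y[sample(95, 5)] <- -y[sample(95, 5)]
  expect_equal(pairwise_similarity(x, y), max(mean(x == y), 1 - mean(x == y)))
  # fewer than 10 comparable lines -> undefined
  expect_true(is.na(pairwise_similarity(c(a[1:9], rep(NA, 31)), a)))
})

test_that("windowed unlinked-SNP removal drops shuffled intruders only", {
  set.seed(4)
  n <- 97
  pattern <- sample(c(-1L, 1L), n, TRUE)
  removed <- vapply(1:100, function(i) {
    calls <- matrix(pattern, n, 9)
    calls[, 5] <- sample(pattern)   # independent shuffle in the middle
    g <- make_geno(calls)
    out <- remove_unlinked_snps(g)
    "m005" %in% attr(out, "removed_snps")
  }, logical(1))
  expect_equal(mean(removed), 1)   # expected similarity ~0.5 << 0.95

  # 8 identical consecutive SNPs: all retained; idempotent
  g8 <- make_geno(matrix(pattern, n, 8))
  out8 <- remove_unlinked_snps(g8)
  expect_equal(ncol(out8$calls), 8)
  expect_identical(remove_unlinked_snps(out8)$calls, out8$calls)

  # noise-free DH simulation at sub-cM marker spacing: nothing is unlinked
  gd <- simulate_dh_genotypes(genetic_map_spec(chrom_lengths = c(100, 80),
                                               n_snps = 600), 97, seed = 12)
  expect_equal(ncol(remove_unlinked_snps(gd)$calls), ncol(gd$calls))
})

test_that("bin merging matches the pattern-hash oracle on noise-free data", {
  g <- small_clean_geno(97, 800, seed = 11)
  bm <- merge_bins(g, threshold = 1.0)
  oracle <- pattern_hash_bins(g)
  expect_equal(nrow(bm$bins), max(oracle))
  # same partition: members per bin equal oracle run lengths
  expect_equal(bm$bins$n_snps, as.integer(table(oracle)[unique(oracle)]))
  # consensus of a noise-free bin equals its member calls
  first_bin <- which(oracle == 1)
  expect_equal(unname(bm$bin_calls[, 1]), unname(g$calls[, first_bin[1]]))
})

test_that("one bin per identical chromosome; alternating patterns stay separate", {
  set.seed(5)
  pattern <- sample(c(-1L, 1L), 97, TRUE)
  g100 <- make_geno(matrix(pattern, 97, 100))
  bm <- merge_bins(g100)
  expect_equal(nrow(bm$bins), 1L)
  expect_equal(bm$bins$n_snps, 100L)
  expect_equal(bm$bins$pos_cM, (1 + 100) / 2)

  # two interleaved dissimilar patterns -> every SNP its own bin
  p2 <- sample(c(-1L, 1L), 97, TRUE)
  while (max(mean(p2 == pattern), 1 - mean(p2 == pattern)) >= 0.95)
    p2 <- sample(c(-1L, 1L), 97, TRUE)
  alt <- matrix(rbind(pattern, p2), 97, 10, byrow = FALSE)
  alt <- sapply(1:10, function(j) if (j %% 2) pattern else p2)
  bm2 <- merge_bins(make_geno(alt))
  expect_equal(nrow(bm2$bins), 10L)
})

test_that("lowering the merge threshold never increases the bin count", {
  st <- simulate_study(sim_config(n_lines = 60, n_snps = 500, seed = 6))
  g <- filter_lines(filter_snps(st$geno))
  n_bins <- vapply(c(1.0, 0.98, 0.95, 0.9, 0.8),
                   function(th) nrow(merge_bins(g, th)$bins), numeric(1))
  expect_true(all(diff(n_bins) <= 0))
})

test_that("Haldane distances recover the simulated map length", {
  expect_equal(-50 * log(1 - 2 * 0.25), 34.65736, tolerance = 1e-5)
  map <- genetic_map_spec(chrom_lengths = 150, n_snps = 120)
  g <- simulate_dh_genotypes(map, 2000, seed = 21)
  bm <- estimate_map_distances(merge_bins(g, threshold = 1.0))
  est_len <- max(bm$bins$est_pos_cM)
  expect_lt(abs(est_len - 150) / 150, 0.10)
  # r-hat = 0 -> distance 0
  twin <- make_geno(cbind(g$calls[1:97, 1], g$calls[1:97, 1]))
  bm2 <- estimate_map_distances(merge_bins(twin, threshold = 1.0))
  expect_equal(nrow(bm2$bins), 1L)  # identical SNPs merge; nothing to estimate
})

test_that("bins partition retained SNPs in map order", {
  st <- simulate_study(sim_config(n_lines = 50, n_snps = 600, seed = 7))
  g <- remove_unlinked_snps(filter_lines(filter_snps(st$geno)))
  bm <- merge_bins(g)
  expect_equal(sum(bm$bins$n_snps), ncol(g$calls))
  expect_true(all(diff(order(bm$bins$chrom, bm$bins$pos_cM)) > 0))
  first_idx <- match(bm$bins$first_snp, g$map$marker)
  last_idx <- match(bm$bins$last_snp, g$map$marker)
  expect_equal(unname(last_idx - first_idx + 1L), bm$bins$n_snps)
})
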
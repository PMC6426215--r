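#!/usr/bin/env Rscript
# Stage 2: 5-step QC and bin-map construction from the noisy GBS-like
# genotypes written by 01_simulate.R: SNP filters (MAF > 0.05, missing <
# 20%), line filters (het > 5% or missing > 20% removed), windowed removal
# of unlinked SNPs (window 8, similarity 95%), greedy merging of consecutive
# co-segregating SNPs into bins (similarity 95%), Haldane distances.

suppressMessages(library(pgebv))

geno <- read_genotypes_csv("results/genotypes.csv", "results/marker_map.csv")
bm <- build_binmap(geno)
write_binmap_csv(bm, "results/bins.csv", "results/bin_calls.csv")

qc <- attr(bm, "qc_log")
message(sprintf("SNPs: %d -> %d (MAF/missing) -> %d (linkage); lines %d -> %d",
                qc$snps_in, qc$snps_after_maf_missing, qc$snps_after_unlinked,
                qc$lines_in, qc$lines_retained))
message(sprintf("%d bins; estimated map length %.1f cM",
                nrow(bm$bins),
                sum(tapply(bm$bins$est_pos_cM, bm$bins$chrom, max))))
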
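#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study — a 97-line biparental DH maize
# population, genotyped with GBS-like noise, evaluated in 4 environments
# (2 years x well-watered/drought) as a 2-replicate alpha-lattice, with 62
# reflectance bands on 5 post-flowering flights. Writes the raw artifacts
# under results/.

suppressMessages(library(pgebv))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1)
print(cfg)
study <- simulate_study(cfg)

write_genotypes_csv(study$geno, "results/genotypes.csv")
write_marker_map_csv(study$geno, "results/marker_map.csv")
write_plot_table_csv(study$plots, "results/plots.csv")
write_truth_json(study$truth, "results/truth.json")

message(sprintf("simulated %d plots, %d SNPs (%.1f%% missing, %.1f%% het), %d spectral features",
                nrow(study$plots), ncol(study$geno$calls),
                100 * mean(is.na(study$geno$calls)),
                100 * mean(study$geno$calls == 0, na.rm = TRUE),
                cfg$n_bands * cfg$n_flights))
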
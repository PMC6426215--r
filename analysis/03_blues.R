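#!/usr/bin/env Rscript
# Stage 3: per-environment mixed-model BLUEs (genotype fixed; replicate and
# block-in-replicate random) for grain yield and every band x flight
# feature, plus all-random variance components and entry-mean repeatability
# across the four environments.

suppressMessages(library(pgebv))

plots <- read_plot_table_csv("results/plots.csv")

blues <- build_blue_table(plots)
write_blue_table_csv(blues, "results/blues.csv")

vc <- fit_combined_model(plots)
h2 <- repeatability(vc)
jsonlite::write_json(
  list(variance_components = as.list(unclass(vc)),
       repeatability = h2$h2),
  "results/variance_components.json", auto_unbox = TRUE, digits = NA)

message(sprintf("BLUE table: %d genotype x environment rows, %d feature columns",
                nrow(blues), sum(grepl("^B\\d+_F\\d+$", names(blues)))))
message(sprintf("sigma_G2 = %.3f, sigma_GxE2 = %.3f, sigma_e2 = %.3f; entry-mean h2 = %.3f",
                vc[["sigma_G2"]], vc[["sigma_GxE2"]], vc[["sigma_e2"]], h2$h2))

# per-environment repeatability profile for grain yield
for (env in unique(plots$env)) {
  r <- repeatability_env(plots, env)
  message(sprintf("  within-environment h2 (%s): %.2f", env, r$h2))
}
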
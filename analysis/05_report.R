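#!/usr/bin/env Rscript
# Stage 5: summary figure and compact report of the grid results.

suppressMessages(library(pgebv))

res <- read.csv("results/results.csv", stringsAsFactors = FALSE)
ok <- res[is.na(res$error) | res$error == "", ]

# accuracy surface, one panel per scheme (base graphics; plain PDF)
pdf("results/accuracy_grid.pdf", width = 8, height = 4)
op <- par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
for (scheme in unique(ok$scheme)) {
  d <- ok[ok$scheme == scheme, ]
  m <- tapply(d$r_gp, list(d$input_set, d$learner), mean)
  bp <- barplot(m, beside = TRUE, ylim = c(0, max(ok$r_gp) * 1.2),
                legend.text = rownames(m), las = 2,
                main = scheme, ylab = expression(r[GP]))
  se <- tapply(d$se_boot, list(d$input_set, d$learner), mean)
  arrows(bp, m - se, bp, m + se, angle = 90, code = 3, length = 0.02)
}
par(op)
invisible(dev.off())

summ <- grid_summary(ok)
jsonlite::write_json(summ, "results/summary.json", auto_unbox = TRUE,
                     digits = NA)
message("scheme means:")
print(summ$by_scheme)
message("wrote results/accuracy_grid.pdf and results/summary.json")
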
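#!/usr/bin/env Rscript
# Sample sizes required to detect 4-12% effects in each metric and ROI,
# from the between-subject CVs (two-group design, van Belle) and from the
# SDs of test-retest differences (paired design), at alpha = 0.05 and
# power 0.80.

library(ogmua)

repro_dir <- "results/repro"
out <- "results/sample_sizes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

effect_sizes <- c(0.04, 0.06, 0.08, 0.10, 0.12)
files <- list.files(repro_dir, pattern = "^repro_.*\\.tsv$",
                    full.names = TRUE)
grid <- NULL
for (f in files) {
  m <- sub("^repro_(.*)\\.tsv$", "\\1", basename(f))
  rep_m <- utils::read.table(f, header = TRUE, sep = "\t")
  for (i in seq_len(nrow(rep_m))) {
    for (d in effect_sizes) {
      grid <- rbind(grid, data.frame(
        metric = m, roi = rep_m$roi[i], effect_pct = 100 * d,
        n_between = rep_m[[sprintf("n_between_%g", 100 * d)]][i],
        n_within = rep_m[[sprintf("n_within_%g", 100 * d)]][i]))
    }
  }
}
utils::write.table(grid, file.path(out, "sample_sizes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("Sample size per group to detect an 8% change (between-subject):")
sub8 <- grid[grid$effect_pct == 8, ]
print(reshape(sub8[, c("metric", "roi", "n_between")],
              idvar = "metric", timevar = "roi", direction = "wide"),
      row.names = FALSE)
message("Paired design, 8% change:")
print(reshape(sub8[, c("metric", "roi", "n_within")],
              idvar = "metric", timevar = "roi", direction = "wide"),
      row.names = FALSE)
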
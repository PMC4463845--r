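#!/usr/bin/env Rscript
# Stage 5 — pooled-heterozygosity scan with permutation thresholds.
#
# For every line: 40 kb / 20 kb sliding-window Hp over the filtered calls,
# chromosome-wise critical values from 1,000 within-chromosome
# permutations, and flagging of windows below the critical Hp at
# alpha = 0.05. Writes one window table per line.

suppressPackageStartupMessages(library(poolsweep))

dir.create("results/scan", showWarnings = FALSE, recursive = TRUE)
layout <- read_chrom_sizes("results/sim/chrom_sizes.tsv")
files <- list.files("results/filtered", pattern = "^[BW].*\\.tsv$",
                    full.names = TRUE)

for (f in files) {
  line <- sub("\\.tsv$", "", basename(f))
  calls <- read.delim(f)
  sc <- site_counts(calls)
  w <- hp_scan(sc, layout)
  th <- suppressMessages(
    permute_thresholds(sc, layout, n_perm = 1000,
                       seed = 20260920 + match(f, files)))
  fl <- significant_windows(w, th, alpha = 0.05)
  write.table(fl, file.path("results/scan", paste0(line, "_windows.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%s: %d analysable windows, mean Hp %.3f, %d significant at 0.05\n",
    line, sum(!is.na(fl$hp)), mean(fl$hp, na.rm = TRUE),
    sum(fl$significant, na.rm = TRUE)))
}
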
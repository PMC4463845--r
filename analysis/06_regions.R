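#!/usr/bin/env Rscript
# Stage 6 — cross-line pSS region calling and pfVar prioritization.
#
# Intersects the flagged windows across all lines of each group, merges
# the common windows into discrete pSS regions, overlaps them with a small
# synthetic QTL track, and classifies the fixed putatively functional
# variants inside each region.

suppressPackageStartupMessages(library(poolsweep))

dir.create("results/regions", showWarnings = FALSE, recursive = TRUE)
files <- list.files("results/scan", pattern = "_windows\\.tsv$",
                    full.names = TRUE)
flagged <- lapply(files, read.delim)
names(flagged) <- sub("_windows\\.tsv$", "", basename(files))
ann <- read_annotation_table("results/sim/annotation.tsv")
groups <- data.frame(line_id = names(flagged))
groups$group <- ifelse(grepl("^B", groups$line_id), "broiler", "WEL")

# synthetic QTL track for the overlap report (labelled synthetic: these are
# not curated QTL annotations)
qtl <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(1.10e6, 1.45e6, 0.2e6),
                  end = c(1.30e6, 1.60e6, 0.5e6),
                  name = c("growth_syn", "bodyweight_syn", "egg_syn"))

for (g in unique(groups$group)) {
  members <- groups$line_id[groups$group == g]
  common <- common_windows(flagged, lines = members)
  regions <- merge_regions(common)
  cat(sprintf("%s: %d common windows -> %d pSS region(s)\n",
              g, nrow(common), nrow(regions)))
  if (nrow(regions) == 0) next
  ov <- qtl_overlap(regions, qtl)
  cat(sprintf("  %.0f%% of regions overlap a QTL\n",
              100 * ov$fraction_overlapping))
  pf <- prioritize_pfvars(regions, ann, groups)
  write_bed(data.frame(chrom = regions$chrom, start = regions$start,
                       end = regions$end, name = regions$region_id,
                       score = regions$n_windows),
            file.path("results/regions", paste0(g, "_regions.bed")))
  write.table(pf, file.path("results/regions", paste0(g, "_pfvars.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(pf) > 0)
    print(table(pf$status))
}
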
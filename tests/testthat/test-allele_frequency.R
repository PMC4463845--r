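test_that("AAF is the alt-read proportion", {
  calls <- snp_calls("L1", "chr1", 1:3, "A", "G", 45, c(10, 10, 12),
                     c(3, 5, 2), c(2, 5, 1))
  expect_equal(estimate_aaf(calls), c(0.5, 1.0, 0.25))
  calls$depth[1] <- 0L
  calls$alt_fwd[1] <- 0L
  calls$alt_rev[1] <- 0L
  expect_error(estimate_aaf(calls), "zero depth")
})

test_that("mean AAF averages only the lines where the SNP was detected", {
  df <- data.frame(chrom = "chr1", pos = 1:3, category = "synonymous",
                   in_mce = FALSE, rna_struct = FALSE,
                   L1 = c(0.8, 0.6, 0.2), L2 = c(1.0, NA, 0.4),
                   L3 = c(NA, NA, 0.9))
  ann <- annotated_snps(df, c("L1", "L2", "L3"))
  expect_equal(mean_aaf(ann), c(0.9, 0.6, 0.5))
})

test_that("fixation and privacy status follow the line-count rules", {
  # 12 lines; SNP A detected in all with high AAF, B private fixed,
  # C detected in 2 lines
  df <- data.frame(chrom = "chr1", pos = 1:3, category = "intergenic",
                   in_mce = FALSE, rna_struct = FALSE)
  df <- cbind(df, rbind(rep(0.95, 12),
                        c(0.95, rep(NA, 11)),
                        c(0.5, 0.6, rep(NA, 10))))
  names(df)[6:17] <- paste0("L", 1:12)
  ann <- annotated_snps(df, paste0("L", 1:12))
  st <- classify_status(ann)
  expect_equal(st$n_lines_detected, c(12, 1, 2))
  expect_equal(st$is_multi_line_fixed, c(TRUE, FALSE, FALSE))
  expect_equal(st$is_all_lines_fixed, c(TRUE, FALSE, FALSE))
  expect_equal(st$is_private_fixed, c(FALSE, TRUE, FALSE))
  expect_equal(st$is_private, c(FALSE, TRUE, FALSE))
  # a SNP at exactly the threshold is not fixed (strict >)
  df$L1[2] <- 0.9
  ann2 <- annotated_snps(df, paste0("L", 1:12))
  expect_false(classify_status(ann2)$is_fixed_mean[2])
})

test_that("spectra are per-line observations normalized to 100 percent", {
  df <- data.frame(chrom = "chr1", pos = 1:2, category = "synonymous",
                   in_mce = FALSE, rna_struct = FALSE,
                   L1 = c(1.0, 1.0), L2 = c(1.0, NA))
  ann <- annotated_snps(df, c("L1", "L2"))
  groups <- data.frame(line_id = c("L1", "L2"), group = "broiler")
  sp <- build_spectra(ann, groups)
  expect_equal(sum(sp$pct), 100)
  expect_equal(sp$pct[sp$bin_hi == 1], 100)  # all mass in the top bin
  expect_equal(sp$n[sp$bin_hi == 1], 3)      # 3 line-observations
})

test_that("uniform AAFs give an approximately flat spectrum", {
  set.seed(41)
  n <- 10000
  df <- data.frame(chrom = "chr1", pos = seq_len(n),
                   category = "intergenic", in_mce = FALSE,
                   rna_struct = FALSE, L1 = runif(n))
  ann <- annotated_snps(df, "L1")
  sp <- build_spectra(ann, data.frame(line_id = "L1", group = "broiler"))
  expect_equal(nrow(sp), 20)
  expect_equal(sum(sp$pct), 100)
  gof <- chisq.test(sp$n, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("pool detection limits empty the lowest frequency bin", {
  # pools of 10-15 individuals sequenced at 8-17X with >=2 alt reads on
  # both strands cannot yield detected AAF <= 0.05 at depth <= 17:
  # 2 alt reads of <=17 is already a frequency above 0.05
  set.seed(42)
  layout <- genome_layout("chr1", 3e5)
  lines <- data.frame(line_id = c("L1", "L2"), group = "broiler",
                      n_individuals = 12, depth_lambda = 12)
  sim <- simulate_poolseq(sim_config(seed = 5, layout = layout,
                                     lines = lines))
  stats <- line_stats("L1", "broiler", 12, 12, sqrt(12))
  filt <- apply_filters(sim$calls$L1, stats)$calls
  filt <- filt[filt$depth <= 17, ]
  aaf <- estimate_aaf(filt)
  expect_true(all(aaf > 0.05))
})

test_that("non-coding/coding pfVar ratio handles zero denominators", {
  df <- data.frame(
    chrom = "chr1", pos = 1:16,
    category = c(rep("intronic", 10), rep("nonsyn_intol", 5), "intronic"),
    in_mce = c(rep(TRUE, 10), rep(FALSE, 5), TRUE),
    rna_struct = FALSE,
    L1 = c(rep(0.52, 10), rep(0.52, 5), 0.98))
  ann <- annotated_snps(df, "L1")
  rt <- noncoding_coding_ratio(ann)
  # bin (0.50,0.55]: 10 non-coding pfVars over 5 coding -> 2.0
  expect_equal(rt$ratio[rt$bin_lo == 0.50], 2.0)
  # bin (0.95,1.00]: non-coding present, no coding -> NA not Inf
  expect_equal(rt$n_noncoding[rt$bin_lo == 0.95], 1)
  expect_true(is.na(rt$ratio[rt$bin_lo == 0.95]))
})

test_that("category summary matches the hand-computed fixture", {
  ann <- annotation_fixture()
  tab <- table1_summary(ann, min_lines = 2)
  total_row <- tab[tab$category != "within_mce", ]
  expect_equal(sum(total_row$n_snps), 12)
  expect_equal(sum(total_row$pct_of_total), 100)
  ig <- tab[tab$category == "intergenic", ]
  expect_equal(ig$n_snps, 3)
  expect_equal(ig$pct_of_total, 25)
  expect_equal(ig$mean_aaf, mean(c(mean(c(1, 0.95, 0.92)), 0.5, 0.95)))
  expect_equal(ig$n_multi_line_fixed, 1)  # the 3-line fixed SNP
  expect_equal(ig$n_all_lines_fixed, 1)
  expect_equal(ig$n_private_fixed, 1)     # pos 3000, single line 0.95
  ni <- tab[tab$category == "nonsyn_intol", ]
  expect_equal(ni$n_snps, 1)
  expect_equal(ni$n_multi_line_fixed, 1)
  # intronic: two SNPs; the 2-line 0.91/0.92 SNP is fixed-by-mean but
  # detected in exactly min_lines, hence in no fixed column
  intr <- tab[tab$category == "intronic", ]
  expect_equal(intr$n_snps, 2)
  expect_equal(intr$n_multi_line_fixed, 0)
  expect_equal(intr$n_private_fixed, 0)
  # stop-gain/loss: mean 0.92 but only 2 lines -> no fixed columns
  sg <- tab[tab$category == "stopgain_loss", ]
  expect_equal(sg$n_multi_line_fixed, 0)
  # MCE overlay row counts the single MCE SNP and is excluded above
  mce <- tab[tab$category == "within_mce", ]
  expect_equal(mce$n_snps, 1)
  # all-lines-fixed implies multi-line-fixed in every category
  expect_true(all(tab$n_all_lines_fixed <= tab$n_multi_line_fixed))
})

test_that("single-category input accounts for 100 percent of SNPs", {
  df <- data.frame(chrom = "chr1", pos = 1:4, category = "splicing",
                   in_mce = FALSE, rna_struct = FALSE, L1 = 0.5)
  ann <- annotated_snps(df, "L1")
  tab <- table1_summary(ann)
  expect_equal(tab$pct_of_total[tab$category == "splicing"], 100)
  expect_equal(tab$n_multi_line_fixed[tab$category == "splicing"], 0)
})
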
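make_flagged <- function(sig, chrom = "chr1") {
  n <- length(sig)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * 20000,
             end = (seq_len(n) - 1) * 20000 + 40000, n_snps = 20,
             hp = 0.1, threshold = 0.2, significant = sig)
}

test_that("common windows require significance in every line", {
  five <- list(L1 = make_flagged(c(TRUE, TRUE)),
               L2 = make_flagged(c(TRUE, TRUE)),
               L3 = make_flagged(c(TRUE, FALSE)),
               L4 = make_flagged(c(TRUE, TRUE)),
               L5 = make_flagged(c(TRUE, NA)))
  cw <- common_windows(five)
  expect_equal(nrow(cw), 1)  # window 2 flagged in only 3 of 5 lines
  expect_equal(cw$start, 0)
  # dropping the failing lines rescues the window
  cw2 <- common_windows(five, drop_lines = c("L3", "L5"))
  expect_equal(nrow(cw2), 2)
  # per-line Hp columns are carried along
  expect_true(all(c("hp.L1", "hp.L2") %in% names(cw)))
})

test_that("inconsistent window grids are a hard error", {
  a <- make_flagged(c(TRUE, TRUE))
  b <- make_flagged(c(TRUE, TRUE))
  b$start <- b$start + 1
  expect_error(common_windows(list(L1 = a, L2 = b)), "grids differ")
  expect_error(common_windows(list(L1 = a), lines = "L2"), "missing")
})

test_that("overlapping and abutting windows merge; gaps split", {
  w <- data.frame(chrom = "chr1", start = c(0, 20000, 60000),
                  end = c(40000, 60000, 100000))
  r <- merge_regions(w)
  expect_equal(nrow(r), 1)  # [20k,60k) abuts [60k,100k)
  expect_equal(r$start, 0)
  expect_equal(r$end, 100000)
  w2 <- data.frame(chrom = "chr1", start = c(0, 60000),
                   end = c(40000, 100000))
  r2 <- merge_regions(w2)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$n_windows, c(1, 1))
  expect_equal(nrow(merge_regions(w[0, ])), 0)
})

test_that("merging matches a brute-force interval union and is idempotent", {
  set.seed(61)
  for (i in 1:10) {
    n <- 5
    start <- sample.int(20, n) * 20000
    w <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = start, end = start + 40000)
    r <- merge_regions(w)
    # brute force: per-base union per chromosome
    for (ch in unique(w$chrom)) {
      covered <- rep(FALSE, 30 * 20000 + 40000)
      for (k in which(w$chrom == ch))
        covered[(w$start[k] + 1):w$end[k]] <- TRUE
      runs <- rle(covered)
      ends <- cumsum(runs$lengths)
      want_start <- ends[which(runs$values) - 1]
      if (runs$values[1]) want_start <- c(0, want_start)
      want_end <- ends[runs$values]
      r_ch <- r[r$chrom == ch, ]
      expect_equal(r_ch$start, want_start)
      expect_equal(r_ch$end, want_end)
    }
    # idempotent and order-independent
    again <- merge_regions(r[sample(nrow(r)), c("chrom", "start", "end")])
    expect_equal(again[, c("chrom", "start", "end")],
                 r[, c("chrom", "start", "end")])
    # every region at least one window long; count can only shrink
    expect_true(all(r$end - r$start >= 40000))
    expect_lte(nrow(r), nrow(w))
  }
})

test_that("QTL overlap uses half-open intersection", {
  regions <- merge_regions(data.frame(chrom = "chr1", start = 0,
                                      end = 60000))
  qtl1 <- data.frame(chrom = "chr1", start = 59000, end = 80000,
                     name = "growth")
  ov <- qtl_overlap(regions, qtl1)
  expect_equal(ov$regions$n_qtl, 1)
  expect_equal(ov$fraction_overlapping, 1)
  # QTL starting exactly at the region end does not overlap
  qtl2 <- data.frame(chrom = "chr1", start = 60000, end = 80000,
                     name = "growth")
  expect_equal(qtl_overlap(regions, qtl2)$fraction_overlapping, 0)
})

test_that("QTL overlap fraction equals a brute-force pairwise count", {
  set.seed(62)
  start <- sort(sample.int(50, 10)) * 10000
  regions <- data.frame(region_id = paste0("R", 1:10), chrom = "chr1",
                        start = start, end = start + 8000,
                        n_windows = 1)
  qs <- sample.int(60, 6) * 9000
  qtl <- data.frame(chrom = "chr1", start = qs, end = qs + 15000,
                    name = paste0("Q", 1:6))
  ov <- qtl_overlap(regions, qtl)
  want <- vapply(seq_len(10), function(i)
    any(qtl$start < regions$end[i] & qtl$end > regions$start[i]),
    logical(1))
  expect_equal(ov$regions$n_qtl > 0, unname(want))
  expect_equal(ov$fraction_overlapping, mean(want))
})

test_that("pfVar prioritization labels fixation patterns by group", {
  groups <- data.frame(line_id = c("B1", "B2", "W1", "W2"),
                       group = c("broiler", "broiler", "WEL", "WEL"))
  df <- data.frame(
    chrom = "chr1", pos = c(1000, 2000, 3000, 4000),
    category = c("nonsyn_intol", "splicing", "synonymous", "ncrna"),
    in_mce = FALSE, rna_struct = FALSE,
    # broiler-specific: fixed in broilers, segregating in WELs
    B1 = c(0.95, 0.95, 0.95, 0.50),
    B2 = c(0.98, 0.95, 0.95, NA),
    # ubiquitous: fixed everywhere detected
    W1 = c(0.40, 0.95, 0.95, 0.60),
    W2 = c(0.45, NA, 0.95, NA))
  ann <- annotated_snps(df, groups$line_id)
  regions <- data.frame(region_id = "R01", chrom = "chr1", start = 0,
                        end = 10000, n_windows = 1)
  pf <- prioritize_pfvars(regions, ann, groups)
  # synonymous non-MCE SNP is not a pfVar and is excluded
  expect_false(3000 %in% pf$pos)
  expect_equal(pf$status[pf$pos == 1000], "group_specific")
  expect_equal(pf$fixed_groups[pf$pos == 1000], "broiler")
  # fixed in every line where detected, seen in both groups
  expect_equal(pf$status[pf$pos == 2000], "ubiquitous_fixed")
  # detected in both groups but nowhere fixed
  expect_equal(pf$status[pf$pos == 4000], "segregating")
})

test_that("pfVars outside every region are not reported", {
  groups <- data.frame(line_id = "L1", group = "broiler")
  df <- data.frame(chrom = "chr1", pos = 50000, category = "splicing",
                   in_mce = FALSE, rna_struct = FALSE, L1 = 0.95)
  ann <- annotated_snps(df, "L1")
  regions <- data.frame(region_id = "R01", chrom = "chr1", start = 0,
                        end = 40000, n_windows = 1)
  expect_equal(nrow(prioritize_pfvars(regions, ann, groups)), 0)
})
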
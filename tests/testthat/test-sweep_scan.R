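test_that("site counts split reads into major and minor alleles", {
  calls <- snp_calls("L1", "chr1", 1:3, "A", "G", 45, c(10, 10, 8),
                     c(2, 3, 4), c(1, 2, 4))
  sc <- site_counts(calls)
  expect_equal(sc$n_maj, c(7, 5, 8))
  expect_equal(sc$n_min, c(3, 5, 0))
  calls$depth[1] <- 0L
  calls$alt_fwd[1] <- 0L
  calls$alt_rev[1] <- 0L
  expect_error(site_counts(calls), "zero depth")
})

test_that("Hp follows the pooled-heterozygosity formula and its bounds", {
  expect_equal(hp(5, 5), 0.5)           # single balanced site
  expect_equal(hp(c(8, 6), c(0, 0)), 0) # local fixation
  expect_equal(hp(c(8, 6), c(2, 4)), 0.42)  # 2*14*6/20^2
  expect_error(hp(numeric(0), numeric(0)), "at least one site")
  # invariant under swapping labels at a tied site, bounded by [0, 0.5],
  # 0.5 iff the sums tie
  set.seed(51)
  for (i in 1:50) {
    nmaj <- rpois(5, 8)
    nmin <- pmin(nmaj, rpois(5, 3))
    h <- hp(nmaj, nmin)
    expect_gte(h, 0)
    expect_lte(h, 0.5)
    if (sum(nmaj) == sum(nmin)) expect_equal(h, 0.5)
    tie <- nmaj == nmin
    if (any(tie)) {
      k <- which(tie)[1]
      nmaj2 <- nmaj; nmin2 <- nmin
      nmaj2[k] <- nmin[k]; nmin2[k] <- nmaj[k]
      expect_equal(hp(nmaj2, nmin2), h)
    }
  }
})

test_that("the window grid tiles from zero with a 20 kb step", {
  g <- poolsweep:::window_grid
  expect_equal(g(100000), data.frame(start = c(0, 20000, 40000, 60000),
                                     end = c(40000, 60000, 80000, 100000)))
  # terminal truncated window kept when at least half a window long and
  # not nested in its predecessor
  expect_equal(g(90000)$end, c(40000, 60000, 80000, 90000))
  expect_equal(g(90000)$start, c(0, 20000, 40000, 60000))
  # too-short remainders are dropped
  expect_equal(g(50000), data.frame(start = c(0, 20000),
                                    end = c(40000, 50000)))
  expect_equal(g(10000), data.frame(start = numeric(0), end = numeric(0)))
})

test_that("windows need strictly more than min_snps SNPs to be analysed", {
  layout <- genome_layout("chr1", 40000)
  mk <- function(n) data.frame(chrom = "chr1", pos = seq_len(n) * 100,
                               n_maj = 8, n_min = 2)
  w10 <- hp_scan(mk(10), layout)
  expect_equal(w10$n_snps, 10)
  expect_true(is.na(w10$hp))
  w11 <- hp_scan(mk(11), layout)
  expect_false(is.na(w11$hp))
  # 11 fully fixed sites: analysed, Hp exactly 0
  s <- mk(11); s$n_min <- 0
  expect_equal(hp_scan(s, layout)$hp, 0)
  # site beyond the chromosome end is a hard error
  s$pos[11] <- 40001
  expect_error(hp_scan(s, layout), "beyond chromosome length")
})

test_that("sliding scan equals brute-force recomputation on random sites", {
  set.seed(52)
  layout <- genome_layout(c("chr1", "chr2", "chr3"), c(4e5, 3e5, 1.7e5))
  sites <- do.call(rbind, lapply(seq_len(3), function(i) {
    n <- c(500, 330, 170)[i]
    data.frame(chrom = layout$chrom[i],
               pos = sort(sample.int(layout$length[i], n)),
               n_maj = rpois(n, 9) + 1L, n_min = rpois(n, 3))
  }))
  sites$n_min <- pmin(sites$n_min, sites$n_maj)
  got <- hp_scan(sites, layout)
  want <- brute_force_scan(sites, layout)
  expect_equal(got$hp, want$hp)
  expect_equal(got$n_snps, want$n_snps)
  expect_true(all(got$hp >= 0 & got$hp <= 0.5, na.rm = TRUE))
})

test_that("shuffle-invariant input makes every permutation identical", {
  layout <- genome_layout("chr1", 40000)
  sites <- data.frame(chrom = "chr1", pos = seq(1000, 21000, by = 1000),
                      n_maj = 6, n_min = 4)
  obs <- hp_scan(sites, layout)
  th <- permute_thresholds(sites, layout, n_perm = 50, seed = 1)
  expect_true(all(th$threshold == obs$hp[1]))
  fl <- significant_windows(obs, th, 0.05)
  expect_false(any(fl$significant))  # hp == threshold is not significant
})

test_that("two seeded permutations replay exactly against an R oracle", {
  set.seed(53)
  layout <- genome_layout("chr1", 80000)  # three windows
  n <- 60
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(80000, n)),
                      n_maj = rpois(n, 9) + 1L, n_min = rpois(n, 3))
  sites$n_min <- pmin(sites$n_min, sites$n_maj)
  got <- permute_thresholds(sites, layout, n_perm = 2, alphas = 0.5,
                            seed = 99)
  want <- ref_permute_thresholds(sites, layout, n_perm = 2, alphas = 0.5,
                                 seed = 99)
  expect_equal(got$threshold, want$threshold)
})

test_that("chromosome-wise thresholds match the pure-R reference", {
  set.seed(54)
  layout <- genome_layout(c("chr1", "chr2"), c(120000, 80000))
  sites <- do.call(rbind, lapply(1:2, function(i) {
    n <- c(90, 60)[i]
    data.frame(chrom = layout$chrom[i],
               pos = sort(sample.int(layout$length[i], n)),
               n_maj = rpois(n, 9) + 1L, n_min = rpois(n, 3))
  }))
  sites$n_min <- pmin(sites$n_min, sites$n_maj)
  alphas <- c(0.05, 0.2, 0.5)
  got <- permute_thresholds(sites, layout, n_perm = 40, alphas = alphas,
                            seed = 7)
  want <- ref_permute_thresholds(sites, layout, n_perm = 40,
                                 alphas = alphas, seed = 7)
  expect_equal(got$threshold, want$threshold)
  # thresholds weakly increase with alpha on every chromosome
  for (ch in unique(got$chrom)) {
    t_ch <- got[got$chrom == ch, ]
    expect_true(all(diff(t_ch$threshold[order(t_ch$alpha)]) >= 0))
  }
})

test_that("per-window mode returns empirical P values in [0,1]", {
  set.seed(55)
  n <- 80
  layout <- genome_layout("chr1", 120000)
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(120000, n)),
                      n_maj = rpois(n, 9) + 1L, n_min = rpois(n, 3))
  sites$n_min <- pmin(sites$n_min, sites$n_maj)
  pw <- permute_thresholds(sites, layout, n_perm = 50, seed = 3,
                           mode = "perwindow")
  expect_true(all(pw$p_value >= 0 & pw$p_value <= 1, na.rm = TRUE))
  expect_true(all(is.na(pw$p_value) == is.na(pw$hp)))
})

test_that("window flagging is strict and tolerates missing thresholds", {
  w <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(0, 20000, 0), end = c(40000, 60000, 40000),
                  n_snps = 20, hp = c(0.10, 0.25, 0.10))
  th <- data.frame(chrom = "chr1", alpha = 0.05, threshold = 0.25,
                   n_perm = 100)
  fl <- significant_windows(w, th, 0.05)
  expect_equal(fl$significant, c(TRUE, FALSE, NA))
  # empty threshold table: everything untested
  fl0 <- significant_windows(w, th[0, ], 0.05)
  expect_true(all(is.na(fl0$significant)))
})

test_that("an explicit seed is required for permutations", {
  sites <- data.frame(chrom = "chr1", pos = 1:20 * 1000, n_maj = 6,
                      n_min = 4)
  expect_error(permute_thresholds(sites, genome_layout("chr1", 40000),
                                  n_perm = 5), "seed")
})
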
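# Fixtures and independent oracles shared across the test files.

# --- hand-written VCF with one biallelic SNP, one indel, one triallelic ---
write_vcf_fixture <- function(path = tempfile(fileext = ".vcf"),
                              with_dp4 = TRUE) {
  info1 <- if (with_dp4) "DP=12;DP4=4,3,3,2" else "DP=12"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"strand depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr1\t100\t.\tA\tG\t45\t.\t", info1),
    "chr1\t200\t.\tC\tCT\t50\t.\tDP=10;DP4=3,3,2,2",
    "chr1\t300\t.\tG\tA,T\t60\t.\tDP=20;DP4=5,5,6,4")
  writeLines(lines, path)
  path
}

# --- 20-call filtration fixture ------------------------------------------
# Line stats: mean coverage 10, SD 2 -> acceptable depth [5, 16].
# Expected attrition with default thresholds, stage by stage:
#   pos 100            snpq 39                 -> fail_snpq
#   pos 300            depth 4                 -> fail_coverage (floor)
#   pos 400            depth 17                -> fail_coverage (mean+3SD=16)
#   pos 500            alt (2,0)               -> fail_strand (one strand)
#   pos 700            alt (1,0)               -> fail_strand (single read)
#   pos 800, 801       1 base apart            -> fail_spacing (both)
#   pos 900..920 by 2  11 calls in 21 bases    -> fail_density (>10/50)
#   pos 200 (snpq 40, depth 5, alt 1,1) and
#   pos 600 (depth 16, alt 3,3)               -> retained (boundaries)
filter_fixture <- function() {
  dense_pos <- seq(900, 920, by = 2)
  pos <- c(100, 200, 300, 400, 500, 600, 700, 800, 801, dense_pos)
  snpq <- c(39, 40, 50, 50, 45, 45, 45, 45, 45, rep(45, 11))
  depth <- c(10, 5, 4, 17, 10, 16, 10, 10, 10, rep(10, 11))
  alt_fwd <- c(2, 1, 1, 5, 2, 3, 1, 1, 1, rep(2, 11))
  alt_rev <- c(2, 1, 1, 5, 0, 3, 0, 1, 1, rep(2, 11))
  list(calls = snp_calls("L1", "chr1", pos, "A", "G", snpq, depth,
                         alt_fwd, alt_rev),
       stats = line_stats("L1", "broiler", 12, 10, 2),
       survivors = c(200, 600),
       report = c(input = 20, fail_snpq = 1, fail_coverage = 2,
                  fail_strand = 2, fail_spacing = 2, fail_density = 11,
                  retained = 2))
}

# Pass-through configuration: no stage removes anything.
identity_config <- function() {
  filter_config(min_snpq = 0, min_depth = 0, max_depth_sd = Inf,
                min_alt_reads = 0, require_both_strands = FALSE,
                min_gap = 0, dense_max_snps = Inf)
}

# --- random call generator (plain, for property tests) -------------------
random_calls <- function(n, chrom = "chr1", max_pos = 1e6, line = "L1") {
  pos <- sort(sample.int(max_pos, n))
  depth <- rpois(n, 12) + 1L
  alt <- rbinom(n, depth, runif(n, 0.05, 1))
  alt_fwd <- rbinom(n, alt, 0.5)
  snp_calls(line, chrom, pos, "A", "C", round(runif(n, 0, 200)), depth,
            alt_fwd, alt - alt_fwd)
}

# --- brute-force per-base gold-standard classification -------------------
brute_force_eval <- function(ngs_calls, gold) {
  tp <- fp <- fn <- tn <- 0L
  calls <- unique(paste(ngs_calls$chrom, ngs_calls$pos))
  truth <- unique(paste(gold$truth$chrom, gold$truth$pos))
  for (k in seq_len(nrow(gold$covered))) {
    iv <- gold$covered[k, ]
    for (p in (iv$start + 1):iv$end) {
      key <- paste(iv$chrom, p)
      in_call <- key %in% calls
      in_truth <- key %in% truth
      if (in_call && in_truth) tp <- tp + 1L
      else if (in_call) fp <- fp + 1L
      else if (in_truth) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# --- brute-force windowed Hp recomputation -------------------------------
brute_force_scan <- function(sites, layout, window = 40000, step = 20000,
                             min_snps = 10) {
  out <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    len <- layout$length[i]
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + window, len)
    keep <- (ends - starts) >= window / 2
    at_end <- ends == len
    if (any(at_end)) keep <- keep & (!at_end | starts == min(starts[at_end]))
    starts <- starts[keep]; ends <- ends[keep]
    s <- sites[sites$chrom == ch, , drop = FALSE]
    for (k in seq_along(starts)) {
      sel <- s$pos - 1 >= starts[k] & s$pos - 1 < ends[k]
      n <- sum(sel)
      h <- if (n > min_snps) {
        smaj <- sum(s$n_maj[sel]); smin <- sum(s$n_min[sel])
        2 * smaj * smin / (smaj + smin)^2
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = starts[k],
                                           end = ends[k], n_snps = n,
                                           hp = h)
    }
  }
  do.call(rbind, out)
}

# --- reference (pure R) permutation threshold computation -----------------
# Replays the identical RNG draws as the C++ permutation engine: one
# Fisher-Yates pass per permutation, consuming one runif(1) per site from
# the stream seeded by set.seed(seed), chromosomes in layout order.
fisher_yates_perm <- function(n) {
  pool <- seq_len(n)
  out <- integer(n)
  N <- n
  for (i in seq_len(n)) {
    j <- floor(N * runif(1)) + 1
    out[i] <- pool[j]
    pool[j] <- pool[N]
    N <- N - 1
  }
  out
}

ref_permute_thresholds <- function(sites, layout, n_perm, alphas, seed,
                                   window = 40000, step = 20000,
                                   min_snps = 10) {
  set.seed(seed)
  obs <- brute_force_scan(sites, layout, window, step, min_snps)
  rows <- list()
  for (ch in layout$chrom) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    w <- obs[obs$chrom == ch & !is.na(obs$hp), , drop = FALSE]
    if (nrow(w) == 0 || nrow(s) == 0) next
    minima <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      perm <- fisher_yates_perm(nrow(s))
      s2 <- s
      s2$n_maj <- s$n_maj[perm]
      s2$n_min <- s$n_min[perm]
      hps <- vapply(seq_len(nrow(w)), function(k) {
        sel <- s2$pos - 1 >= w$start[k] & s2$pos - 1 < w$end[k]
        smaj <- sum(s2$n_maj[sel]); smin <- sum(s2$n_min[sel])
        2 * smaj * smin / (smaj + smin)^2
      }, numeric(1))
      minima[p] <- min(hps)
    }
    minima <- sort(minima)
    for (a in alphas)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, alpha = a, threshold = minima[ceiling(a * n_perm)],
        n_perm = n_perm)
  }
  do.call(rbind, rows)
}

# --- small hand-annotated table (3 lines) --------------------------------
annotation_fixture <- function() {
  df <- data.frame(
    chrom = "chr1",
    pos = seq(1000, by = 1000, length.out = 12),
    category = c("intergenic", "intergenic", "intergenic", "synonymous",
                 "nonsyn_intol", "nonsyn_tol", "splicing", "intronic",
                 "intronic", "utr", "ncrna", "stopgain_loss"),
    in_mce = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
               FALSE, FALSE, FALSE, FALSE),
    rna_struct = FALSE,
    L1 = c(1.00, 0.50, 0.95, 0.20, 0.95, 0.10, NA,   0.50, 0.91, 1.00, 0.30, 0.95),
    L2 = c(0.95, NA,   NA,   0.40, 0.95, NA,   0.92, 0.60, 0.92, NA,   0.50, 0.89),
    L3 = c(0.92, NA,   NA,   NA,   0.95, NA,   NA,   0.70, NA,   NA,   0.99, NA),
    stringsAsFactors = FALSE)
  annotated_snps(df, c("L1", "L2", "L3"))
}
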
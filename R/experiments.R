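#' Build a Sanger-style benchmark fixture at given marginal counts
#'
#' Constructs a gold standard with the given total covered length split
#' into short intervals, then draws a call set of `n_calls` positions that
#' contains all `n_truth` truth SNPs — the configuration under which
#' pre-filtration error rates are quoted.
#'
#' @param covered_bases total covered length (default 11801).
#' @param n_truth truth SNPs (default 97).
#' @param n_calls pipeline calls, superset of the truth (default 200).
#' @param n_intervals number of covered intervals (default 25).
#' @param seed integer seed.
#' @return `list(gold, calls)` ready for [evaluate_calls()].
#' @export
gold_benchmark <- function(covered_bases = 11801, n_truth = 97,
                           n_calls = 200, n_intervals = 25, seed = 1) {
  set.seed(seed)
  base_w <- covered_bases %/% n_intervals
  widths <- rep(base_w, n_intervals)
  widths[n_intervals] <- widths[n_intervals] + covered_bases %% n_intervals
  starts <- seq(0, by = max(widths) + 500, length.out = n_intervals)
  covered <- data.frame(chrom = "chr1", start = starts,
                        end = starts + widths)
  all_pos <- unlist(lapply(seq_len(n_intervals), function(i)
    (covered$start[i] + 1):covered$end[i]))
  call_pos <- sort(sample(all_pos, n_calls))
  truth_pos <- sort(sample(call_pos, n_truth))
  list(gold = gold_standard(data.frame(chrom = "chr1", pos = truth_pos),
                            covered),
       calls = data.frame(chrom = "chr1", pos = call_pos))
}

#' Null calibration of the chromosome-wise permutation thresholds
#'
#' Simulates neutral (sweep-free) chromosomes, runs the Hp scan and the
#' permutation threshold on each, and reports the fraction of chromosomes
#' with at least one significant window — which should approximate `alpha`
#' when the chromosome-wise control is calibrated.
#'
#' @param n_chrom number of independent neutral chromosomes (default 200).
#' @param chrom_len chromosome length in bases (default 2 Mb).
#' @param lambda mean sequencing depth (default 12).
#' @param snp_density_per_kb true SNP density (default 15).
#' @param n_perm permutations per chromosome (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return `list(fraction, n_chrom, n_sig, alpha)`.
#' @export
calibration_experiment <- function(n_chrom = 200, chrom_len = 2e6,
                                   lambda = 12, snp_density_per_kb = 15,
                                   n_perm = 1000, alpha = 0.05, seed = 1) {
  layout <- genome_layout("chr1", chrom_len)
  lines <- data.frame(line_id = "L1", group = "broiler",
                      n_individuals = 12, depth_lambda = lambda)
  sig <- logical(n_chrom)
  for (i in seq_len(n_chrom)) {
    cfg <- sim_config(seed = seed * 1000L + i, layout = layout,
                      lines = lines,
                      snp_density_per_kb = snp_density_per_kb)
    sim <- simulate_poolseq(cfg)
    sc <- site_counts(sim$calls$L1)
    th <- suppressMessages(
      permute_thresholds(sc, layout, n_perm = n_perm, alphas = alpha,
                         seed = seed * 2000L + i))
    fl <- significant_windows(hp_scan(sc, layout), th, alpha)
    sig[i] <- any(fl$significant, na.rm = TRUE)
  }
  list(fraction = mean(sig), n_chrom = n_chrom, n_sig = sum(sig),
       alpha = alpha)
}

#' Sweep recovery under an injected fixed interval
#'
#' Repeatedly simulates a group of lines with a fully fixed interval
#' injected into every line, runs the per-line scan plus permutation
#' thresholds, intersects the flagged windows across lines, merges them
#' into pSS regions, and checks whether a merged common region overlaps the
#' injected interval.
#'
#' @param n_reps replicates (default 50).
#' @param n_lines lines in the group (default 4).
#' @param chrom_len chromosome length (default 2 Mb).
#' @param sweep_start,sweep_end injected interval (defaults 1.0-1.2 Mb,
#'   i.e. 200 kb).
#' @param lambda mean depth (default 12).
#' @param n_perm permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return `list(recovery_rate, regions_le_windows (fraction of replicates
#'   with region count <= common-window count), replicates)` where
#'   `replicates` has one row per replicate: `recovered`, `n_common`,
#'   `n_regions`.
#' @export
sweep_recovery_experiment <- function(n_reps = 50, n_lines = 4,
                                      chrom_len = 2e6, sweep_start = 1e6,
                                      sweep_end = 1.2e6, lambda = 12,
                                      n_perm = 1000, alpha = 0.05,
                                      seed = 1) {
  layout <- genome_layout("chr1", chrom_len)
  lines <- data.frame(line_id = paste0("B", seq_len(n_lines)),
                      group = "broiler", n_individuals = 12,
                      depth_lambda = lambda)
  reps <- data.frame(recovered = logical(n_reps),
                     n_common = integer(n_reps),
                     n_regions = integer(n_reps))
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(seed = seed * 10000L + r, layout = layout,
                      lines = lines,
                      sweep_specs = data.frame(chrom = "chr1",
                                               start = sweep_start,
                                               end = sweep_end,
                                               lines = ""))
    sim <- simulate_poolseq(cfg)
    flagged <- list()
    for (i in seq_len(n_lines)) {
      sc <- site_counts(sim$calls[[i]])
      th <- suppressMessages(
        permute_thresholds(sc, layout, n_perm = n_perm, alphas = alpha,
                           seed = seed * 20000L + r * 10L + i))
      flagged[[lines$line_id[i]]] <-
        significant_windows(hp_scan(sc, layout), th, alpha)
    }
    common <- common_windows(flagged)
    regions <- merge_regions(common)
    reps$n_common[r] <- nrow(common)
    reps$n_regions[r] <- nrow(regions)
    reps$recovered[r] <- any(regions$start < sweep_end &
                               regions$end > sweep_start)
  }
  list(recovery_rate = mean(reps$recovered),
       regions_le_windows = mean(reps$n_regions <= reps$n_common),
       replicates = reps)
}

#' Frequency-spectrum fidelity experiment
#'
#' Simulates an annotated SNP set whose categories follow a realistic
#' genome-wide mix, with amino-acid-altering and splicing variants held at
#' low frequencies by purifying selection and MCE/ncRNA/structure
#' non-coding pfVars enriched at high frequencies (hitchhiking to
#' fixation), then summarizes it: category proportions, and the
#' non-coding/coding pfVar ratio trend across frequency bins.
#'
#' @param seed integer seed.
#' @param chrom_len total simulated length (default 4 Mb).
#' @param n_lines lines (default 4).
#' @param lambda mean depth (default 12).
#' @return `list(summary, proportions_gof_p (chi-square goodness of fit of
#'   generated category counts against the requested mix), ratio,
#'   spearman_rho, spearman_p, annotation, mix)`.
#' @export
spectrum_experiment <- function(seed = 1, chrom_len = 4e6, n_lines = 4,
                                lambda = 12) {
  layout <- genome_layout("chr1", chrom_len)
  lines <- data.frame(line_id = paste0("L", seq_len(n_lines)),
                      group = "broiler", n_individuals = 12,
                      depth_lambda = lambda)
  cfg <- sim_config(
    seed = seed, layout = layout, lines = lines,
    p_mce_noncoding = 0.035,
    coding_aaf_law = function(n) 0.05 + 0.95 * rbeta(n, 1.2, 3),
    noncoding_pfvar_aaf_law = function(n) 0.05 + 0.95 * rbeta(n, 3, 1.2))
  sim <- simulate_poolseq(cfg)
  mix <- cfg$category_mix
  counts <- table(factor(sim$truth$sites$category, levels = names(mix)))
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = mix))
  rt <- noncoding_coding_ratio(sim$annotation)
  ok <- !is.na(rt$ratio)
  ct <- cor.test(rt$bin_lo[ok], rt$ratio[ok], method = "spearman",
                 alternative = "greater", exact = FALSE)
  list(summary = table1_summary(sim$annotation),
       proportions_gof_p = gof$p.value,
       ratio = rt,
       spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value,
       annotation = sim$annotation,
       mix = mix)
}
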
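## Default annotation-category mix, proportioned after the genome-wide
## composition of a filtered chicken Pool-seq SNP set (intergenic and
## intronic dominate; coding classes are rare).
.DEFAULT_CATEGORY_MIX <- c(
  intergenic = 0.5022, updownstream = 0.0283, intronic = 0.4335,
  nonsyn_intol = 0.0058, nonsyn_tol = 0.0061, stopgain_loss = 0.0001,
  synonymous = 0.0099, splicing = 0.0009, utr = 0.0134, ncrna = 0.0002)

#' Configuration for the Pool-seq simulator
#'
#' The generator emulates pooled resequencing of 10-15 diploid individuals
#' per line at modest coverage (8-17X): per site and line, read depth is
#' Poisson, alternative reads are binomial in the site's true line AAF, and
#' each alt read lands on a strand by a fair coin. Sequencing-error false
#' positives appear at a per-base rate with weak, strand-biased support and
#' low-shifted quality scores; sweep intervals drive the specified lines'
#' true AAF to 1. Read sampling is binomial, ignoring the finite pool of 2n
#' chromosomes (no hypergeometric double-sampling) — adequate for testing
#' the pipeline's logic.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param layout [genome_layout()].
#' @param lines `data.frame` with `line_id`, `group`, `n_individuals`,
#'   `depth_lambda` (mean coverage).
#' @param snp_density_per_kb expected true SNPs per kb (default 15,
#'   uniformly placed).
#' @param aaf_law function(n) drawing true per-line AAFs (default uniform
#'   on `[0.05, 1]`).
#' @param sweep_specs optional `data.frame` `chrom`, `start`, `end`
#'   (0-based half-open), `lines` (comma-separated line ids, empty = all):
#'   true AAF inside is set to 1 for those lines.
#' @param fp_rate per-base probability of an error site (true AAF 0
#'   everywhere).
#' @param category_mix named category proportions (must sum to 1).
#' @param p_rna_struct,p_mce_noncoding probability of the RNA-structure
#'   flag (any category) and of the MCE flag for non-coding categories.
#' @param coding_aaf_law,noncoding_pfvar_aaf_law optional functions(n)
#'   drawing AAFs for coding pfVars (AA-altering/splicing) and for
#'   MCE/ncRNA/structure-altering non-coding variants, overriding
#'   `aaf_law`; used to inject the purifying-vs-hitchhiking contrast in
#'   which non-coding variants reach high frequency more often.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, layout, lines,
                       snp_density_per_kb = 15,
                       aaf_law = function(n) runif(n, 0.05, 1),
                       sweep_specs = NULL,
                       fp_rate = 0,
                       category_mix = .DEFAULT_CATEGORY_MIX,
                       p_rna_struct = 0.003,
                       p_mce_noncoding = 0.035,
                       coding_aaf_law = NULL,
                       noncoding_pfvar_aaf_law = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stopifnot(all(c("line_id", "group", "n_individuals", "depth_lambda")
                %in% names(lines)))
  if (any(lines$n_individuals < 1)) stop("pool size must be >= 1")
  if (fp_rate < 0 || fp_rate > 1) stop("fp_rate must be in [0,1]")
  if (abs(sum(category_mix) - 1) > 1e-6)
    category_mix <- category_mix / sum(category_mix)
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% .CATEGORIES))
    stop("category_mix must be named with known categories")
  if (!is.null(sweep_specs)) {
    for (i in seq_len(nrow(sweep_specs))) {
      len <- layout$length[match(sweep_specs$chrom[i], layout$chrom)]
      if (is.na(len) || sweep_specs$start[i] < 0 ||
          sweep_specs$end[i] > len || sweep_specs$start[i] >= sweep_specs$end[i])
        stop("sweep interval outside its chromosome")
    }
  }
  structure(list(seed = seed, layout = layout, lines = lines,
                 snp_density_per_kb = snp_density_per_kb,
                 aaf_law = aaf_law, sweep_specs = sweep_specs,
                 fp_rate = fp_rate, category_mix = category_mix,
                 p_rna_struct = p_rna_struct,
                 p_mce_noncoding = p_mce_noncoding,
                 coding_aaf_law = coding_aaf_law,
                 noncoding_pfvar_aaf_law = noncoding_pfvar_aaf_law),
            class = "sim_config")
}

#' Simulate Pool-seq inputs for the whole pipeline
#'
#' Generates per-line call sets, an annotation table built from the
#' estimated per-line AAFs of detected true sites, the ground truth, and a
#' gold-standard fixture of short covered intervals carrying the simulated
#' truth. Deterministic under a fixed seed; when `out_dir` is given, one
#' VCF per line plus the annotation/gold TSV-BED files are also written.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory for on-disk outputs.
#' @param gold_n_intervals,gold_interval_range number and length range
#'   (bases) of gold-standard covered intervals (defaults 25 intervals of
#'   150-500 bases, drawn on the first chromosome).
#' @return `list(calls, annotation, truth, gold, files)` where `calls` is a
#'   named list of [snp_calls()] tables (unfiltered, i.e. before
#'   [apply_filters()]), `truth` holds the true AAF matrix (`sites` x
#'   `lines`), the site table with categories, the sweep intervals and the
#'   error-site indices, and `gold` is a [gold_standard()] built from the
#'   truth restricted to the covered intervals.
#' @export
simulate_poolseq <- function(config, out_dir = NULL,
                             gold_n_intervals = 25,
                             gold_interval_range = c(150, 500)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- config$layout
  lines <- config$lines
  n_lines <- nrow(lines)

  ## --- true site placement ---------------------------------------------
  site_list <- lapply(seq_len(nrow(layout)), function(i) {
    n_true <- rpois(1, layout$length[i] / 1000 * config$snp_density_per_kb)
    n_err <- rbinom(1, layout$length[i], config$fp_rate)
    pos <- sample.int(layout$length[i], min(n_true + n_err,
                                            layout$length[i]))
    is_err <- rep(c(FALSE, TRUE), c(min(n_true, length(pos)),
                                    max(0, length(pos) - n_true)))
    o <- order(pos)
    data.frame(chrom = layout$chrom[i], pos = pos[o], is_error = is_err[o],
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  n_sites <- nrow(sites)

  ## --- annotation categories and pfVar flags ---------------------------
  sites$category <- sample(names(config$category_mix), n_sites,
                           replace = TRUE, prob = config$category_mix)
  noncoding <- c("intergenic", "intronic", "utr", "updownstream")
  sites$in_mce <- runif(n_sites) <
    ifelse(sites$category %in% noncoding, config$p_mce_noncoding, 0)
  sites$rna_struct <- runif(n_sites) < config$p_rna_struct

  ## --- true AAFs per line ----------------------------------------------
  aaf_true <- matrix(0, n_sites, n_lines,
                     dimnames = list(NULL, lines$line_id))
  ok <- which(!sites$is_error)
  aaf_true[ok, ] <- config$aaf_law(length(ok) * n_lines)
  coding_pf <- sites$category %in% c("nonsyn_intol", "nonsyn_tol",
                                     "stopgain_loss", "splicing")
  nc_pf <- !coding_pf &
    ((sites$category %in% noncoding & sites$in_mce) |
       sites$category == "ncrna" | sites$rna_struct)
  if (!is.null(config$coding_aaf_law)) {
    idx <- which(coding_pf & !sites$is_error)
    aaf_true[idx, ] <- config$coding_aaf_law(length(idx) * n_lines)
  }
  if (!is.null(config$noncoding_pfvar_aaf_law)) {
    idx <- which(nc_pf & !sites$is_error)
    aaf_true[idx, ] <- config$noncoding_pfvar_aaf_law(length(idx) * n_lines)
  }
  if (!is.null(config$sweep_specs)) {
    for (i in seq_len(nrow(config$sweep_specs))) {
      sw <- config$sweep_specs[i, ]
      in_sw <- sites$chrom == sw$chrom & sites$pos - 1 >= sw$start &
        sites$pos - 1 < sw$end & !sites$is_error
      sw_lines <- if (is.null(sw$lines) || !nzchar(sw$lines)) lines$line_id
                  else strsplit(sw$lines, ",", fixed = TRUE)[[1]]
      aaf_true[in_sw, sw_lines] <- 1
    }
  }

  ## --- read sampling per line ------------------------------------------
  bases <- c("A", "C", "G", "T")
  ref_idx <- sample.int(4, n_sites, replace = TRUE)
  ref <- bases[ref_idx]
  alt <- bases[((ref_idx - 1 + sample.int(3, n_sites, replace = TRUE)) %% 4) + 1]
  calls <- setNames(vector("list", n_lines), lines$line_id)
  for (j in seq_len(n_lines)) {
    lambda <- lines$depth_lambda[j]
    depth <- rpois(n_sites, lambda)
    true_aaf <- aaf_true[, j]
    alt_reads <- rbinom(n_sites, depth, true_aaf)
    err <- sites$is_error
    ## error sites: 1-3 artefactual alt reads, all on one strand half the
    ## time, to exercise the strand filter's discrimination
    if (any(err)) {
      alt_reads[err] <- pmin(depth[err], 1 + rpois(sum(err), 0.5))
      one_strand <- runif(sum(err)) < 0.5
    }
    alt_fwd <- rbinom(n_sites, alt_reads, 0.5)
    if (any(err)) {
      ef <- which(err)[one_strand]
      alt_fwd[ef] <- ifelse(runif(length(ef)) < 0.5, alt_reads[ef], 0L)
    }
    snpq <- ifelse(err, round(rexp(n_sites, 1 / 15)),
                   round(40 + rexp(n_sites, 1 / 60)))
    emit <- depth > 0 & alt_reads > 0
    calls[[j]] <- snp_calls(
      line_id = lines$line_id[j], chrom = sites$chrom[emit],
      pos = sites$pos[emit], ref = ref[emit], alt = alt[emit],
      snpq = snpq[emit], depth = depth[emit],
      alt_fwd = alt_fwd[emit],
      alt_rev = alt_reads[emit] - alt_fwd[emit])
  }

  ## --- annotation table from estimated AAFs of detected sites ----------
  ann_df <- sites[, c("chrom", "pos", "category", "in_mce", "rna_struct")]
  for (j in seq_len(n_lines)) {
    a <- rep(NA_real_, n_sites)
    cl <- calls[[j]]
    idx <- match(paste(cl$chrom, cl$pos), paste(sites$chrom, sites$pos))
    a[idx] <- estimate_aaf(cl)
    ann_df[[lines$line_id[j]]] <- a
  }
  detected_any <- rowSums(!is.na(as.matrix(
    ann_df[, lines$line_id, drop = FALSE]))) > 0
  annotation <- annotated_snps(ann_df[detected_any, , drop = FALSE],
                               lines$line_id)

  ## --- gold-standard fixture on the first chromosome -------------------
  ch1 <- layout$chrom[1]
  len1 <- layout$length[1]
  iv_len <- sample(seq(gold_interval_range[1], gold_interval_range[2]),
                   gold_n_intervals, replace = TRUE)
  anchors <- sort(sample.int(max(1, len1 - max(iv_len)), gold_n_intervals))
  covered <- data.frame(chrom = ch1, start = anchors - 1,
                        end = anchors - 1 + iv_len)
  ## drop overlaps, keep first of each overlapping pair
  keep <- rep(TRUE, nrow(covered))
  for (k in seq_len(nrow(covered))[-1])
    if (covered$start[k] < max(covered$end[seq_len(k - 1)][keep[seq_len(k - 1)]]))
      keep[k] <- FALSE
  covered <- covered[keep, , drop = FALSE]
  truth_in <- sites[!sites$is_error &
                      .in_intervals(sites$chrom, sites$pos, covered),
                    c("chrom", "pos")]
  gold <- gold_standard(truth_in, covered)

  truth <- list(sites = sites, aaf = aaf_true,
                sweep_specs = config$sweep_specs,
                error_idx = which(sites$is_error))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (l in names(calls)) {
      f <- file.path(out_dir, paste0(l, ".vcf"))
      write_pool_vcf(calls[[l]], f, layout)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "annotation.tsv")
    write_annotation_table(annotation, f)
    files <- c(files, f)
    f <- file.path(out_dir, "truth_snps.tsv")
    write.table(truth_in, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "covered.bed")
    write_bed(cbind(covered, name = paste0("iv", seq_len(nrow(covered))),
                    score = 0), f)
    files <- c(files, f)
    f <- file.path(out_dir, "chrom_sizes.tsv")
    writeLines(sprintf("%s\t%d", layout$chrom, as.integer(layout$length)),
               f)
    files <- c(files, f)
  }
  list(calls = calls, annotation = annotation, truth = truth, gold = gold,
       files = files)
}

#' Write a per-line call set as a minimal VCF
#'
#' Sites-only VCF 4.2 with `DP` and `DP4` INFO fields (reference strand
#' depths are split evenly), readable by [read_pool_vcf()].
#'
#' @param calls [snp_calls()] table for one line.
#' @param path output path.
#' @param layout optional [genome_layout()] for contig header lines.
#' @export
write_pool_vcf <- function(calls, path, layout = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=poolsweep-simulator",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
               "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref-forward, ref-reverse, alt-forward, alt-reverse read counts\">"),
             con)
  if (!is.null(layout))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                       as.integer(layout$length)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(calls) > 0) {
    ref_tot <- calls$depth - calls$alt_fwd - calls$alt_rev
    ref_fwd <- ref_tot %/% 2
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%g\t.\tDP=%d;DP4=%d,%d,%d,%d",
                       calls$chrom, calls$pos, calls$ref, calls$alt,
                       calls$snpq, calls$depth, ref_fwd, ref_tot - ref_fwd,
                       calls$alt_fwd, calls$alt_rev), con)
  }
  invisible(path)
}

#' Fraction of truth sites lost to the detection rules
#'
#' Runs the generator and reports the fraction of (site, line) truth pairs
#' with true AAF at most `aaf_max` that fail detection under the minimum
#' alt-read and strand rules (a pair is detected when a call is emitted and
#' passes [filter_strand_support()]; optionally also the depth floor).
#' Quantifies the simulator's analogue of the low-frequency variant loss
#' that pooled sequencing at modest coverage is known to suffer.
#'
#' @param config a [sim_config()].
#' @param aaf_max restrict to truth pairs with true AAF <= this (1 = all).
#' @param min_alt_reads,require_both_strands,min_depth detection rules.
#' @return `list(loss = fraction lost, n = truth pairs assessed)`.
#' @export
expected_detection_loss <- function(config, aaf_max = 1,
                                    min_alt_reads = 2,
                                    require_both_strands = TRUE,
                                    min_depth = 0) {
  sim <- simulate_poolseq(config)
  sites <- sim$truth$sites
  lines <- config$lines$line_id
  lost <- 0L
  n <- 0L
  key_sites <- paste(sites$chrom, sites$pos)
  for (l in lines) {
    truth_sel <- !sites$is_error & sim$truth$aaf[, l] <= aaf_max
    cl <- sim$calls[[l]]
    pass <- cl$alt_fwd + cl$alt_rev >= min_alt_reads & cl$depth >= min_depth
    if (require_both_strands)
      pass <- pass & cl$alt_fwd >= 1 & cl$alt_rev >= 1
    detected <- key_sites[truth_sel] %in% paste(cl$chrom[pass], cl$pos[pass])
    lost <- lost + sum(!detected)
    n <- n + sum(truth_sel)
  }
  list(loss = if (n == 0) NA_real_ else lost / n, n = n)
}
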
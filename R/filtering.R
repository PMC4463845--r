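#' Filtration thresholds for pooled SNP calls
#'
#' Defaults reproduce the post-calling cascade used genome-wide: SNPQ >= 40;
#' coverage >= 5 and <= mean line coverage + 3 SD; alternative allele
#' supported by at least two reads, one per strand; adjacent markers more
#' than 1 base apart; and exclusion of regions denser than 10 SNPs per 50
#' bases.
#'
#' @param min_snpq minimum Phred-scaled SNP quality (inclusive).
#' @param min_depth minimum coverage at the SNP position (inclusive).
#' @param max_depth_sd multiplier on the line coverage SD for the upper
#'   coverage bound (depth <= mean_cov + max_depth_sd * sd_cov).
#' @param min_alt_reads minimum reads supporting the alternative allele.
#' @param require_both_strands require at least one alt read per strand.
#' @param min_gap minimum distance (bases) between adjacent retained
#'   markers; the default 2 keeps only pairs more than 1 base apart.
#' @param dense_window,dense_max_snps any `dense_window`-base span holding
#'   more than `dense_max_snps` calls is masked entirely.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_snpq = 40, min_depth = 5, max_depth_sd = 3,
                          min_alt_reads = 2, require_both_strands = TRUE,
                          min_gap = 2, dense_window = 50,
                          dense_max_snps = 10) {
  cfg <- list(min_snpq = min_snpq, min_depth = min_depth,
              max_depth_sd = max_depth_sd, min_alt_reads = min_alt_reads,
              require_both_strands = isTRUE(require_both_strands),
              min_gap = min_gap, dense_window = dense_window,
              dense_max_snps = dense_max_snps)
  num <- unlist(cfg[c("min_snpq", "min_depth", "max_depth_sd",
                      "min_alt_reads", "min_gap", "dense_window",
                      "dense_max_snps")])
  if (any(num < 0)) stop("filter thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' SNP quality filter
#'
#' @param calls [snp_calls()] table from one line.
#' @param config [filter_config()].
#' @return Calls with `snpq >= min_snpq` (inclusive).
#' @export
filter_snpq <- function(calls, config = filter_config()) {
  calls[calls$snpq >= config$min_snpq, , drop = FALSE]
}

#' Coverage filter
#'
#' Keeps calls with depth at least `min_depth` and at most
#' `mean_cov + max_depth_sd * sd_cov` for the line. The explicit floor
#' subsumes the lower side of the mean +/- k SD band, which would usually
#' fall below it anyway.
#'
#' @param calls calls from one line.
#' @param stats one [line_stats()] row for that line.
#' @param config [filter_config()].
#' @return Retained calls.
#' @export
filter_coverage <- function(calls, stats, config = filter_config()) {
  if (nrow(stats) != 1) stop("stats must contain exactly one line")
  if (is.na(stats$sd_cov)) stop("sd_cov is missing for line ", stats$line_id)
  upper <- stats$mean_cov + config$max_depth_sd * stats$sd_cov
  calls[calls$depth >= config$min_depth & calls$depth <= upper, ,
        drop = FALSE]
}

#' Strand-support filter
#'
#' Requires the alternative allele to be supported by at least
#' `min_alt_reads` reads and, when `require_both_strands`, by at least one
#' read on each strand.
#'
#' @inheritParams filter_snpq
#' @return Retained calls.
#' @export
filter_strand_support <- function(calls, config = filter_config()) {
  total <- calls$alt_fwd + calls$alt_rev
  ok <- total >= config$min_alt_reads
  if (config$require_both_strands)
    ok <- ok & calls$alt_fwd >= 1 & calls$alt_rev >= 1
  calls[ok, , drop = FALSE]
}

#' Marker-spacing filter
#'
#' Removes BOTH members of every pair of same-chromosome calls closer than
#' `min_gap` bases (default: adjacent markers must be more than 1 base
#' apart). Input must be sorted by (chrom, pos).
#'
#' @inheritParams filter_snpq
#' @return Retained calls.
#' @export
filter_spacing <- function(calls, config = filter_config()) {
  if (nrow(calls) < 2) return(calls)
  o <- order(calls$chrom, calls$pos)
  if (any(o != seq_len(nrow(calls))))
    stop("calls must be sorted by (chrom, pos)")
  same_next <- calls$chrom[-nrow(calls)] == calls$chrom[-1]
  gap <- diff(calls$pos)
  too_close <- same_next & gap < config$min_gap
  drop <- c(too_close, FALSE) | c(FALSE, too_close)
  calls[!drop, , drop = FALSE]
}

#' High-density region mask
#'
#' Scans every possible `dense_window`-base span (sliding by one base, not
#' tiled bins, so straddling clusters are caught); if a span holds more than
#' `dense_max_snps` calls, every call in that span is removed.
#'
#' @inheritParams filter_snpq
#' @return Retained calls.
#' @export
mask_dense_regions <- function(calls, config = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  o <- order(calls$chrom, calls$pos)
  calls <- calls[o, , drop = FALSE]
  drop <- logical(nrow(calls))
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    pos <- calls$pos[i]
    n <- length(i)
    ## every maximal span has its left-most SNP at the span start, so spans
    ## anchored at each SNP position suffice
    right <- findInterval(pos + config$dense_window - 1, pos)
    for (k in seq_len(n)) {
      if (right[k] - k + 1 > config$dense_max_snps)
        drop[i[k:right[k]]] <- TRUE
    }
  }
  calls[!drop, , drop = FALSE]
}

#' Apply the full filtration cascade
#'
#' Stages run in the fixed order SNPQ, coverage, strand support, spacing,
#' density; spacing and density therefore act on the quality-filtered set.
#' Filters are per line: a SNP removed in one line may survive in another.
#'
#' @param calls calls from one line, sorted by (chrom, pos).
#' @param stats [line_stats()] row for the line.
#' @param config [filter_config()].
#' @return `list(calls = retained calls, report = per-stage attrition)`;
#'   the report has counts `input`, `fail_snpq`, `fail_coverage`,
#'   `fail_strand`, `fail_spacing`, `fail_density`, `retained`, with
#'   `retained = input - sum(failures)`.
#' @export
apply_filters <- function(calls, stats, config = filter_config()) {
  n0 <- nrow(calls)
  s1 <- filter_snpq(calls, config)
  s2 <- filter_coverage(s1, stats, config)
  s3 <- filter_strand_support(s2, config)
  s4 <- filter_spacing(s3, config)
  s5 <- mask_dense_regions(s4, config)
  report <- c(input = n0,
              fail_snpq = n0 - nrow(s1),
              fail_coverage = nrow(s1) - nrow(s2),
              fail_strand = nrow(s2) - nrow(s3),
              fail_spacing = nrow(s3) - nrow(s4),
              fail_density = nrow(s4) - nrow(s5),
              retained = nrow(s5))
  list(calls = s5, report = report)
}
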
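#' Construct a gold standard for false-discovery evaluation
#'
#' The truth set is a table of SNP positions confirmed by an independent
#' method (e.g. Sanger resequencing of short regions); the covered intervals
#' delimit where that method produced good-quality sequence, so evaluation
#' is restricted to them and true negatives are counted per covered base.
#'
#' @param truth `data.frame` with columns `chrom`, `pos` (1-based).
#' @param covered `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), non-overlapping.
#' @return A list of class `gold_standard` with `truth`, `covered` and
#'   `covered_bases`.
#' @export
gold_standard <- function(truth, covered) {
  stopifnot(all(c("chrom", "pos") %in% names(truth)),
            all(c("chrom", "start", "end") %in% names(covered)))
  if (nrow(covered) > 0 && any(covered$end <= covered$start))
    stop("covered intervals must satisfy start < end")
  ir <- split(IRanges::IRanges(covered$start + 1L, covered$end),
              covered$chrom)
  if (any(vapply(ir, function(x) any(IRanges::countOverlaps(x, x) > 1),
                 logical(1))))
    stop("covered intervals must be non-overlapping")
  if (!all(.in_intervals(truth$chrom, truth$pos, covered)))
    stop("every truth SNP must lie inside a covered interval")
  structure(list(truth = truth, covered = covered,
                 covered_bases = sum(covered$end - covered$start)),
            class = "gold_standard")
}

## positions are 1-based; intervals 0-based half-open: inside iff
## start < pos <= end on the same chromosome
.in_intervals <- function(chrom, pos, intervals) {
  if (length(pos) == 0) return(logical(0))
  inside <- logical(length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!any(sel)) next
    p <- pos[sel]
    hit <- rep(FALSE, length(p))
    for (k in seq_len(nrow(iv)))
      hit <- hit | (p > iv$start[k] & p <= iv$end[k])
    inside[sel] <- hit
  }
  inside
}

#' Evaluate a call set against a gold standard
#'
#' A site is a true positive when called by both methods, a false positive
#' when called only by the sequencing pipeline, a false negative when called
#' only by the gold standard, and every other covered base is a true
#' negative. Matching is on (chrom, pos) only; allele agreement is not
#' required. Calls outside the covered intervals are dropped (with a logged
#' count) before counting.
#'
#' @param ngs_calls `data.frame` with columns `chrom`, `pos` (duplicate
#'   positions count once).
#' @param gold a [gold_standard()].
#' @return One-row `data.frame`: `tp`, `fp`, `fn`, `tn`, `sensitivity`
#'   (TPR), `specificity`, `fpr`, `fnr`, and `fp_proportion` = FP / retained
#'   calls (NA when no calls are retained).
#' @export
evaluate_calls <- function(ngs_calls, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  if (gold$covered_bases == 0) stop("gold standard covers zero bases")
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  calls <- unique(key(ngs_calls$chrom, ngs_calls$pos))
  inside <- .in_intervals(sub(":.*", "", calls),
                          as.integer(sub(".*:", "", calls)), gold$covered)
  n_outside <- sum(!inside)
  if (n_outside > 0)
    message("evaluate_calls: dropped ", n_outside,
            " call(s) outside covered intervals")
  calls <- calls[inside]
  truth <- unique(key(gold$truth$chrom, gold$truth$pos))
  tp <- sum(calls %in% truth)
  fp <- length(calls) - tp
  fn <- length(truth) - tp
  tn <- gold$covered_bases - tp - fp - fn
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = sens, specificity = spec,
             fpr = 1 - spec, fnr = 1 - sens,
             fp_proportion = if (tp + fp == 0) NA_real_ else fp / (tp + fp))
}

#' Sweep the SNPQ threshold and tabulate error statistics
#'
#' Method 1 filters on SNP quality alone; Method 2 additionally requires
#' alternative-allele support by at least one read on each strand (via
#' [filter_strand_support()]) before counting, which can only remove calls
#' and hence never increases the false-positive count at a given threshold.
#'
#' @param ngs_calls a [snp_calls()] table (Method 2 needs `alt_fwd`,
#'   `alt_rev`).
#' @param gold a [gold_standard()].
#' @param snpq_grid thresholds to evaluate.
#' @param method 1 or 2.
#' @param config [filter_config()] supplying the Method-2 strand rule.
#' @return `data.frame` with one row per threshold: `threshold`, `method`,
#'   the [evaluate_calls()] columns, and `tpr` duplicating sensitivity for
#'   ROC plotting.
#' @export
threshold_sweep <- function(ngs_calls, gold, snpq_grid, method = 1,
                            config = filter_config()) {
  stopifnot(method %in% c(1, 2))
  if (method == 2)
    ngs_calls <- filter_strand_support(ngs_calls, config)
  rows <- lapply(snpq_grid, function(q) {
    res <- evaluate_calls(ngs_calls[ngs_calls$snpq >= q, , drop = FALSE],
                          gold)
    cbind(data.frame(threshold = q, method = method), res)
  })
  out <- do.call(rbind, rows)
  out$tpr <- out$sensitivity
  out
}

#' Truncated integer percentage
#'
#' Presentation helper for error rates quoted as whole percentages: the
#' fraction is scaled to percent and truncated toward zero (0.515 -> 51).
#'
#' @param x fraction in `[0,1]`.
#' @return Integer percentage.
#' @export
pct_truncate <- function(x) trunc(x * 100)
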
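#' Pooled alternative-allele frequency of a call
#'
#' The AAF is the proportion of good-quality reads supporting the
#' alternative allele; the depth emitted by the caller is trusted
#' (base-quality filtering happened upstream).
#'
#' @param calls [snp_calls()] table with `depth > 0`.
#' @return Numeric vector of frequencies in `[0,1]`, one per call.
#' @export
estimate_aaf <- function(calls) {
  if (any(calls$depth == 0)) stop("AAF undefined at zero depth")
  (calls$alt_fwd + calls$alt_rev) / calls$depth
}

#' Mean AAF over the lines where a SNP was detected
#'
#' @param ann annotation table ([annotated_snps()]).
#' @return Numeric vector: arithmetic mean of the per-line AAFs over
#'   detected lines only.
#' @export
mean_aaf <- function(ann) {
  aaf <- as.matrix(ann[, attr(ann, "line_ids"), drop = FALSE])
  if (nrow(aaf) > 0 && any(rowSums(!is.na(aaf)) == 0))
    stop("mean AAF undefined for a SNP detected in zero lines")
  rowMeans(aaf, na.rm = TRUE)
}

#' Fixation and privacy status of each SNP
#'
#' @param ann annotation table.
#' @param min_lines a SNP is "multi-line" when detected in more than this
#'   many lines (default 10, strict).
#' @param fix_threshold AAF above which an allele counts as fixed or nearly
#'   fixed (default 0.9, strict).
#' @return `data.frame` per SNP: `n_lines_detected`, `is_fixed_mean`
#'   (mean AAF > threshold), `is_private` (detected in exactly one line),
#'   `is_multi_line_fixed`, `is_all_lines_fixed`, `is_private_fixed`, and
#'   `n_lines_fixed` (lines with per-line AAF > threshold).
#' @export
classify_status <- function(ann, min_lines = 10, fix_threshold = 0.9) {
  line_ids <- attr(ann, "line_ids")
  aaf <- as.matrix(ann[, line_ids, drop = FALSE])
  n_det <- rowSums(!is.na(aaf))
  m_aaf <- rowMeans(aaf, na.rm = TRUE)
  fixed_mean <- m_aaf > fix_threshold
  data.frame(
    n_lines_detected = n_det,
    is_fixed_mean = fixed_mean,
    is_private = n_det == 1L,
    is_multi_line_fixed = n_det > min_lines & fixed_mean,
    is_all_lines_fixed = n_det == length(line_ids) & fixed_mean,
    is_private_fixed = n_det == 1L & fixed_mean,
    n_lines_fixed = rowSums(aaf > fix_threshold, na.rm = TRUE))
}

#' Allele-frequency bin labels
#'
#' Half-open `(lo, hi]` bins of the given width over (0, 1]; an AAF of
#' exactly 0 falls in the lowest bin.
#'
#' @param x frequencies in `[0,1]`.
#' @param bin_width bin width (default 0.05).
#' @return Ordered factor of bin labels.
#' @keywords internal
aaf_bins <- function(x, bin_width = 0.05) {
  breaks <- round(seq(0, 1, by = bin_width), 10)
  cut(x, breaks = breaks, include.lowest = TRUE, right = TRUE)
}

#' Per-category, per-group allele-frequency spectra
#'
#' Histograms of per-line AAF observations (each line where a SNP was
#' detected contributes one observation), normalized to percentages within
#' each category-group cell.
#'
#' @param ann annotation table.
#' @param groups `data.frame` with columns `line_id`, `group`.
#' @param bin_width histogram bin width (default 0.05).
#' @return Long `data.frame`: `group`, `category`, `bin` (label), `bin_lo`,
#'   `bin_hi`, `n`, `pct`; `pct` sums to 100 within each group-category.
#' @export
build_spectra <- function(ann, groups, bin_width = 0.05) {
  line_ids <- attr(ann, "line_ids")
  stopifnot(all(line_ids %in% groups$line_id))
  grp <- setNames(groups$group, groups$line_id)
  breaks <- round(seq(0, 1, by = bin_width), 10)
  obs <- do.call(rbind, lapply(line_ids, function(l) {
    a <- ann[[l]]
    keep <- !is.na(a)
    if (!any(keep)) return(NULL)
    data.frame(group = grp[[l]], category = ann$category[keep],
               aaf = a[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(obs)) return(NULL)
  obs$bin <- aaf_bins(obs$aaf, bin_width)
  tab <- as.data.frame(table(group = obs$group, category = obs$category,
                             bin = obs$bin), stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  cell_n <- stats::ave(tab$n, tab$group, tab$category, FUN = sum)
  tab <- tab[cell_n > 0, , drop = FALSE]
  tab$pct <- 100 * tab$n / stats::ave(tab$n, tab$group, tab$category,
                                      FUN = sum)
  idx <- match(tab$bin, levels(obs$bin))
  tab$bin_lo <- breaks[idx]
  tab$bin_hi <- breaks[idx + 1]
  tab[order(tab$group, tab$category, tab$bin_lo),
      c("group", "category", "bin", "bin_lo", "bin_hi", "n", "pct")]
}

#' Ratio of non-coding to coding putatively functional variants by bin
#'
#' Numerator: non-coding pfVars (intergenic, intronic, UTR or up/downstream
#' variants inside a most conserved element, ncRNA variants, and
#' RNA-structure-altering variants). Denominator: amino-acid-altering
#' (non-synonymous and stop-gain/loss) plus splicing variants. SNPs are
#' binned by their mean AAF; bins with a zero denominator are reported as
#' `NA`, not infinity.
#'
#' @param ann annotation table (typically restricted to sweep regions).
#' @param bin_width bin width (default 0.05).
#' @return `data.frame`: `bin`, `bin_lo`, `bin_hi`, `n_noncoding`,
#'   `n_coding`, `ratio`.
#' @export
noncoding_coding_ratio <- function(ann, bin_width = 0.05) {
  noncoding_cat <- c("intergenic", "intronic", "utr", "updownstream")
  is_noncoding <- (ann$category %in% noncoding_cat & ann$in_mce) |
    ann$category == "ncrna" | ann$rna_struct
  is_coding <- ann$category %in% c("nonsyn_intol", "nonsyn_tol",
                                   "stopgain_loss", "splicing")
  bins <- aaf_bins(ann$mean_aaf, bin_width)
  breaks <- round(seq(0, 1, by = bin_width), 10)
  num <- tapply(is_noncoding, bins, sum)
  den <- tapply(is_coding, bins, sum)
  num[is.na(num)] <- 0
  den[is.na(den)] <- 0
  data.frame(bin = levels(bins),
             bin_lo = breaks[-length(breaks)],
             bin_hi = breaks[-1],
             n_noncoding = as.integer(num),
             n_coding = as.integer(den),
             ratio = ifelse(den == 0, NA_real_, num / den))
}

#' Category-wise summary of SNP counts, frequencies and fixation
#'
#' One row per annotation category plus an overlay row `within_mce` for
#' SNPs inside most conserved elements (the overlay is excluded from the
#' category total, which partitions the input).
#'
#' @param ann annotation table.
#' @param min_lines,fix_threshold passed to [classify_status()].
#' @return `data.frame`: `category`, `n_snps`, `pct_of_total`, `mean_aaf`,
#'   `sd_aaf`, `n_multi_line_fixed` (detected in more than `min_lines`
#'   lines with mean AAF above the threshold), `n_all_lines_fixed`,
#'   `n_private_fixed`.
#' @export
table1_summary <- function(ann, min_lines = 10, fix_threshold = 0.9) {
  status <- classify_status(ann, min_lines, fix_threshold)
  total <- nrow(ann)
  one_row <- function(label, sel) {
    data.frame(category = label,
               n_snps = sum(sel),
               pct_of_total = 100 * sum(sel) / total,
               mean_aaf = if (any(sel)) mean(ann$mean_aaf[sel]) else NA_real_,
               sd_aaf = if (sum(sel) > 1) sd(ann$mean_aaf[sel]) else NA_real_,
               n_multi_line_fixed = sum(status$is_multi_line_fixed[sel]),
               n_all_lines_fixed = sum(status$is_all_lines_fixed[sel]),
               n_private_fixed = sum(status$is_private_fixed[sel]),
               stringsAsFactors = FALSE)
  }
  cats <- .CATEGORIES[.CATEGORIES %in% unique(ann$category)]
  rows <- lapply(cats, function(cc) one_row(cc, ann$category == cc))
  rows <- c(rows, list(one_row("within_mce", ann$in_mce)))
  do.call(rbind, rows)
}
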
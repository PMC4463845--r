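#' Windows significant in every line of a group
#'
#' Comparing fixation signals across the lines of a group suppresses false
#' signals from drift and demography: only windows flagged in all required
#' lines are kept. A window untested in a line (no threshold or too few
#' SNPs) does not count as flagged.
#'
#' @param flagged named list (by line) of [significant_windows()] tables,
#'   all on the identical window grid.
#' @param lines line ids to require (default: all list names).
#' @param drop_lines lines to exclude from the requirement (e.g. a line
#'   with aberrant critical values).
#' @return The common windows (`chrom`, `start`, `end`) with `n_snps` and
#'   per-line Hp columns `hp.<line>`.
#' @export
common_windows <- function(flagged, lines = names(flagged),
                           drop_lines = NULL) {
  lines <- setdiff(lines, drop_lines)
  if (length(lines) == 0) stop("no lines left to intersect")
  if (!all(lines %in% names(flagged)))
    stop("missing flagged windows for: ",
         paste(setdiff(lines, names(flagged)), collapse = ", "))
  ref <- flagged[[lines[1]]]
  key <- function(w) paste(w$chrom, w$start, w$end, sep = ":")
  for (l in lines[-1]) {
    if (!identical(key(flagged[[l]]), key(ref)))
      stop("window grids differ across lines; rebuild with one layout")
  }
  sig <- sapply(lines, function(l) {
    s <- flagged[[l]]$significant
    !is.na(s) & s
  })
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1)
  common <- rowSums(sig) == length(lines)
  out <- ref[common, c("chrom", "start", "end", "n_snps"), drop = FALSE]
  for (l in lines) out[[paste0("hp.", l)]] <- flagged[[l]]$hp[common]
  rownames(out) <- NULL
  out
}

#' Merge overlapping or abutting windows into discrete sweep regions
#'
#' Windows are sorted by (chrom, start) and merged transitively whenever
#' they overlap or abut (end of one equals start of the next on the 20 kb
#' grid); the resulting putative selective-sweep (pSS) regions are pairwise
#' disjoint with positive gaps between them. Merging is idempotent and
#' independent of input order.
#'
#' @param windows `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return `data.frame`: `region_id`, `chrom`, `start`, `end`, `n_windows`.
#' @export
merge_regions <- function(windows) {
  if (nrow(windows) == 0)
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start + 1,
                                                windows$end))
  red <- GenomicRanges::reduce(gr)  # merges overlapping and abutting
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = GenomicRanges::end(red),
                    n_windows = as.integer(
                      GenomicRanges::countOverlaps(red, gr)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  cbind(region_id = paste0("R", sprintf("%02d", seq_len(nrow(out)))), out,
        stringsAsFactors = FALSE)
}

#' Overlap sweep regions with QTL intervals
#'
#' Overlap means at least one shared base (half-open coordinates: a QTL
#' starting exactly at a region's end does not overlap).
#'
#' @param regions [merge_regions()] table.
#' @param qtl `data.frame` with `chrom`, `start`, `end` and optionally
#'   `name` (BED, 0-based half-open).
#' @return `list(regions = regions with 'qtl' (comma-separated names) and
#'   'n_qtl' columns, fraction_overlapping = share of regions hitting at
#'   least one QTL)`.
#' @export
qtl_overlap <- function(regions, qtl) {
  if (is.null(qtl$name)) qtl$name <- paste0("QTL", seq_len(nrow(qtl)))
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1,
                                                  regions$end))
  gr_q <- GenomicRanges::GRanges(qtl$chrom,
                                 IRanges::IRanges(qtl$start + 1, qtl$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_q)
  by_region <- split(qtl$name[S4Vectors::subjectHits(hits)],
                     factor(S4Vectors::queryHits(hits),
                            levels = seq_len(nrow(regions))))
  regions$qtl <- vapply(by_region, paste, character(1), collapse = ",")
  regions$n_qtl <- lengths(by_region)
  list(regions = regions,
       fraction_overlapping =
         if (nrow(regions) == 0) NA_real_
         else mean(regions$n_qtl > 0))
}

#' Prioritize fixed putatively functional variants within sweep regions
#'
#' For every pfVar inside a region, per-line fixation (AAF above the
#' threshold) is assessed and the variant is labelled:
#' \describe{
#'   \item{ubiquitous_fixed}{fixed in every line where detected, across
#'     more than one group — candidate old selection shared by the groups;}
#'   \item{group_specific}{fixed in every line of exactly one group while
#'     undetected or segregating in all other groups' lines — candidate
#'     driver of group-specific traits;}
#'   \item{group_fixed}{fixed in at least one whole group but not
#'     group-specific or ubiquitous;}
#'   \item{segregating}{none of the above.}
#' }
#'
#' @param regions [merge_regions()] table.
#' @param ann annotation table; only pfVars are reported.
#' @param groups `data.frame` with `line_id`, `group`.
#' @param fix_threshold per-line fixation threshold on AAF (default 0.9,
#'   strict).
#' @return `data.frame`: `region_id`, `chrom`, `pos`, `category`,
#'   `in_mce`, `rna_struct`, `n_lines_detected`, `n_lines_fixed`,
#'   `fixed_groups` (comma-separated), `status`.
#' @export
prioritize_pfvars <- function(regions, ann, groups, fix_threshold = 0.9) {
  line_ids <- attr(ann, "line_ids")
  stopifnot(all(line_ids %in% groups$line_id))
  grp_of <- setNames(groups$group, groups$line_id)
  pf <- ann[ann$pfvar, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(regions))) {
    sel <- pf$chrom == regions$chrom[r] &
      pf$pos - 1 >= regions$start[r] & pf$pos - 1 < regions$end[r]
    if (!any(sel)) next
    sub <- pf[sel, , drop = FALSE]
    aaf <- as.matrix(sub[, line_ids, drop = FALSE])
    detected <- !is.na(aaf)
    fixed <- detected & aaf > fix_threshold
    grp_levels <- unique(unname(grp_of[line_ids]))
    status <- character(nrow(sub))
    fixed_groups <- character(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      det_g <- fix_all_g <- other_clean_g <- logical(length(grp_levels))
      for (j in seq_along(grp_levels)) {
        l <- line_ids[grp_of[line_ids] == grp_levels[j]]
        det_g[j] <- any(detected[i, l])
        fix_all_g[j] <- all(fixed[i, l])  # whole group fixed (all detect)
        other_clean_g[j] <- !any(fixed[i, l])  # undetected or segregating
      }
      fixed_groups[i] <- paste(grp_levels[fix_all_g], collapse = ",")
      fixed_where_detected <- all(!detected[i, ] | fixed[i, ])
      if (fixed_where_detected && sum(det_g) > 1) {
        status[i] <- "ubiquitous_fixed"
      } else if (sum(fix_all_g) == 1 &&
                 all(other_clean_g[!fix_all_g])) {
        status[i] <- "group_specific"
      } else if (any(fix_all_g)) {
        status[i] <- "group_fixed"
      } else {
        status[i] <- "segregating"
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      region_id = regions$region_id[r],
      chrom = sub$chrom, pos = sub$pos, category = sub$category,
      in_mce = sub$in_mce, rna_struct = sub$rna_struct,
      n_lines_detected = rowSums(detected),
      n_lines_fixed = rowSums(fixed),
      fixed_groups = fixed_groups, status = status,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(region_id = character(), chrom = character(),
                      pos = integer(), category = character(),
                      in_mce = logical(), rna_struct = logical(),
                      n_lines_detected = integer(),
                      n_lines_fixed = integer(),
                      fixed_groups = character(), status = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
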
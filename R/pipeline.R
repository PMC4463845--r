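#' Run the full Pool-seq sweep pipeline
#'
#' Orchestrates the stages end to end on a simulated or loaded data set:
#' per-line filtration, optional gold-standard evaluation, allele-frequency
#' summaries, the per-line Hp scan with permutation thresholds, and
#' cross-line region calling with pfVar prioritization. Every stage is a
#' pure function of (inputs, parameters, seed); the run writes its outputs
#' plus a JSON manifest of per-stage record counts and file checksums, so a
#' rerun with the same configuration and seed is checksum-identical.
#'
#' @param sim a [simulate_poolseq()] result (or a list with the same
#'   `calls`/`annotation`/`gold` components built from files).
#' @param groups `data.frame` with `line_id`, `group`.
#' @param layout [genome_layout()].
#' @param out_dir output directory (created).
#' @param seed integer seed for the permutation stage.
#' @param filter_cfg [filter_config()].
#' @param window,step,min_snps Hp scan parameters.
#' @param n_perm permutations per chromosome.
#' @param alpha significance level for window flagging.
#' @param fix_threshold fixation threshold on AAF.
#' @param qtl optional QTL `data.frame` (`chrom`, `start`, `end`, `name`).
#' @param chrom_blocklist chromosomes to exclude from the scan (e.g. sex
#'   chromosomes).
#' @return Invisibly, `list(filtered, reports, eval, summary, windows,
#'   thresholds, flagged, common, regions, qtl, pfvars, manifest)`.
#' @export
run_pipeline <- function(sim, groups, layout, out_dir, seed,
                         filter_cfg = filter_config(),
                         window = 40000, step = 20000, min_snps = 10,
                         n_perm = 10000, alpha = 0.05,
                         fix_threshold = 0.9, qtl = NULL,
                         chrom_blocklist = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scan_layout <- layout[!(layout$chrom %in% chrom_blocklist), , drop = FALSE]
  stats <- do.call(rbind, lapply(names(sim$calls), function(l) {
    d <- sim$calls[[l]]$depth
    line_stats(l, groups$group[match(l, groups$line_id)],
               n_individuals = 12, mean_cov = mean(d), sd_cov = sd(d))
  }))

  ## filter
  filtered <- list()
  reports <- list()
  for (l in names(sim$calls)) {
    res <- apply_filters(sim$calls[[l]], stats[stats$line_id == l, ],
                         filter_cfg)
    filtered[[l]] <- res$calls
    reports[[l]] <- res$report
    message("filter [", l, "]: ", res$report["retained"], "/",
            res$report["input"], " calls retained")
  }

  ## gold-standard evaluation on the first line's unfiltered calls
  eval_res <- NULL
  if (!is.null(sim$gold))
    eval_res <- suppressMessages(
      evaluate_calls(sim$calls[[1]], sim$gold))

  ## allele-frequency summaries
  summary_tab <- table1_summary(sim$annotation,
                                fix_threshold = fix_threshold)
  spectra <- build_spectra(sim$annotation, groups)

  ## per-line scan + permutation thresholds
  windows <- list()
  thresholds <- list()
  flagged <- list()
  for (i in seq_along(filtered)) {
    l <- names(filtered)[i]
    sc <- site_counts(filtered[[l]][filtered[[l]]$chrom %in%
                                      scan_layout$chrom, , drop = FALSE])
    windows[[l]] <- hp_scan(sc, scan_layout, window, step, min_snps)
    thresholds[[l]] <- suppressMessages(
      permute_thresholds(sc, scan_layout, n_perm = n_perm,
                         alphas = unique(c(0.001, 0.01, alpha)),
                         seed = seed + i, window = window, step = step,
                         min_snps = min_snps))
    flagged[[l]] <- significant_windows(windows[[l]], thresholds[[l]],
                                        alpha)
    message("scan [", l, "]: ",
            sum(flagged[[l]]$significant, na.rm = TRUE),
            " significant window(s) at alpha=", alpha)
  }

  ## region calling
  common <- common_windows(flagged)
  regions <- merge_regions(common)
  message("regions: ", nrow(common), " common window(s) -> ",
          nrow(regions), " pSS region(s)")
  qtl_res <- if (!is.null(qtl)) qtl_overlap(regions, qtl) else NULL
  pfv <- prioritize_pfvars(regions, sim$annotation, groups, fix_threshold)

  ## outputs + manifest
  paths <- c(summary = "category_summary.tsv", spectra = "spectra.tsv",
             regions = "pss_regions.bed", pfvars = "pfvars.tsv")
  write.table(summary_tab, file.path(out_dir, paths["summary"]),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(spectra))
    write.table(spectra, file.path(out_dir, paths["spectra"]),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(regions) > 0)
    write_bed(data.frame(chrom = regions$chrom, start = regions$start,
                         end = regions$end, name = regions$region_id,
                         score = regions$n_windows),
              file.path(out_dir, paths["regions"]))
  write.table(pfv, file.path(out_dir, paths["pfvars"]), sep = "\t",
              quote = FALSE, row.names = FALSE)
  written <- file.path(out_dir, paths[file.exists(file.path(out_dir, paths))])
  manifest <- list(
    seed = seed,
    parameters = list(window = window, step = step, min_snps = min_snps,
                      n_perm = n_perm, alpha = alpha,
                      fix_threshold = fix_threshold,
                      filter = unclass(filter_cfg)),
    counts = list(
      input_calls = vapply(sim$calls, nrow, integer(1)),
      retained_calls = vapply(filtered, nrow, integer(1)),
      significant_windows = vapply(flagged, function(f)
        sum(f$significant, na.rm = TRUE), numeric(1)),
      common_windows = nrow(common),
      regions = nrow(regions),
      pfvars = nrow(pfv)),
    checksums = as.list(tools::md5sum(written)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(filtered = filtered, reports = reports, eval = eval_res,
                 summary = summary_tab, spectra = spectra,
                 windows = windows, thresholds = thresholds,
                 flagged = flagged, common = common, regions = regions,
                 qtl = qtl_res, pfvars = pfv, manifest = manifest))
}
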
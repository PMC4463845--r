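#' Per-site major/minor allele read counts
#'
#' The alternative-allele reads are `alt_fwd + alt_rev`; reference reads are
#' `depth` minus that. The larger of the two is the major count. At a tie
#' the assignment is irrelevant by symmetry of the Hp statistic.
#'
#' @param calls [snp_calls()] table with `depth > 0`.
#' @return `data.frame`: `chrom`, `pos`, `n_maj`, `n_min`.
#' @export
site_counts <- function(calls) {
  if (any(calls$depth == 0)) stop("allele counts undefined at zero depth")
  alt <- calls$alt_fwd + calls$alt_rev
  ref <- calls$depth - alt
  data.frame(chrom = calls$chrom, pos = calls$pos,
             n_maj = pmax(ref, alt), n_min = pmin(ref, alt),
             stringsAsFactors = FALSE)
}

#' Pooled heterozygosity of a set of sites
#'
#' `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2` where `S_maj` and `S_min`
#' are the sums of per-site major and minor allele read counts. Bounded in
#' `[0, 0.5]`, with 0.5 attained only when the two sums are equal and 0 at
#' complete local fixation.
#'
#' @param n_maj,n_min per-site major/minor allele read counts (at least one
#'   site).
#' @return Scalar Hp.
#' @export
hp <- function(n_maj, n_min) {
  if (length(n_maj) == 0) stop("Hp needs at least one site")
  s1 <- sum(n_maj)
  s2 <- sum(n_min)
  2 * s1 * s2 / (s1 + s2)^2
}

#' Sliding-window grid for one chromosome
#'
#' Windows of `window` bases every `step` bases, anchored at coordinate 0,
#' 0-based half-open. A terminal window is truncated at the chromosome end;
#' truncated windows shorter than half the window size are dropped, and of
#' several candidate windows ending at the chromosome end only the
#' left-most is kept (later ones are nested inside it).
#'
#' @param chrom_len chromosome length in bases.
#' @param window,step window and step sizes in bases.
#' @return `data.frame` with `start`, `end`.
#' @keywords internal
window_grid <- function(chrom_len, window = 40000, step = 20000) {
  starts <- seq(0, max(0, chrom_len - 1), by = step)
  ends <- pmin(starts + window, chrom_len)
  keep <- (ends - starts) >= window / 2
  at_end <- ends == chrom_len
  if (any(at_end)) keep <- keep & (!at_end | starts == min(starts[at_end]))
  data.frame(start = starts[keep], end = ends[keep])
}

#' Sliding-window Hp scan over a genome
#'
#' @param sites [site_counts()] table for one line.
#' @param layout [genome_layout()].
#' @param window,step window and step sizes in bases (defaults 40 kb /
#'   20 kb).
#' @param min_snps windows are analysable only when they hold strictly more
#'   than this many SNPs (default 10); others are emitted with `hp = NA`.
#' @return `data.frame`: `chrom`, `start`, `end` (0-based half-open),
#'   `n_snps`, `hp`.
#' @export
hp_scan <- function(sites, layout, window = 40000, step = 20000,
                    min_snps = 10) {
  bad <- !(sites$chrom %in% layout$chrom)
  if (any(bad))
    stop("site on unknown chromosome: ", sites$chrom[which(bad)[1]])
  out <- lapply(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    g <- window_grid(layout$length[i], window, step)
    s <- sites[sites$chrom == ch, , drop = FALSE]
    if (nrow(s) > 0 && any(s$pos > layout$length[i]))
      stop("site beyond chromosome length on ", ch)
    pos0 <- s$pos - 1L  # to 0-based for half-open window arithmetic
    res <- data.frame(chrom = ch, g, n_snps = 0L, hp = NA_real_)
    for (k in seq_len(nrow(g))) {
      in_w <- pos0 >= g$start[k] & pos0 < g$end[k]
      res$n_snps[k] <- sum(in_w)
      if (res$n_snps[k] > min_snps)
        res$hp[k] <- hp(s$n_maj[in_w], s$n_min[in_w])
    }
    res
  })
  do.call(rbind, out)
}

#' Chromosome-wise empirical Hp significance thresholds by permutation
#'
#' Within each chromosome the per-site (n_maj, n_min) count pairs are
#' shuffled among the SNP positions (positions stay fixed, so window SNP
#' counts and the set of analysable windows are permutation-invariant), the
#' windowed Hp scan is recomputed, and the minimum Hp over analysable
#' windows is recorded. The threshold at level `alpha` is the lower
#' empirical `alpha`-quantile of the permutation minima (the order statistic
#' at `ceiling(alpha * n_perm)`), giving chromosome-wise control of the
#' probability that any window falls below it. Permutations are Fisher-Yates
#' draws from R's RNG stream, so results are reproducible from `seed`.
#'
#' @param sites [site_counts()] table for one line.
#' @param layout [genome_layout()].
#' @param n_perm number of permutations (default 10000).
#' @param alphas significance levels.
#' @param seed integer seed (required).
#' @param window,step,min_snps as in [hp_scan()].
#' @param mode `"chromwise"` (default) returns thresholds from permutation
#'   minima; `"perwindow"` instead returns, per window, the empirical P
#'   value `mean(permuted Hp <= observed Hp)`.
#' @return For `"chromwise"`: `data.frame` `chrom`, `alpha`, `threshold`,
#'   `n_perm` (chromosomes with no analysable window are skipped with a
#'   message). For `"perwindow"`: the [hp_scan()] table with an added
#'   `p_value` column.
#' @export
permute_thresholds <- function(sites, layout, n_perm = 10000,
                               alphas = c(0.001, 0.01, 0.05), seed,
                               window = 40000, step = 20000, min_snps = 10,
                               mode = c("chromwise", "perwindow")) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(all(alphas > 0 & alphas < 1))
  set.seed(seed)
  obs <- hp_scan(sites, layout, window, step, min_snps)
  thr_rows <- list()
  if (mode == "perwindow") obs$p_value <- NA_real_
  for (ch in layout$chrom) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    w <- obs[obs$chrom == ch, , drop = FALSE]
    usable <- which(!is.na(w$hp))
    if (length(usable) == 0 || nrow(s) == 0) {
      message("permute_thresholds: no analysable window on ", ch)
      next
    }
    ## windows as index ranges [lo, hi) into the position-sorted sites
    pos0 <- s$pos - 1
    win_lo <- findInterval(w$start[usable] - 0.5, pos0)
    win_hi <- findInterval(w$end[usable] - 0.5, pos0)
    res <- perm_hp_stats(s$n_maj, s$n_min, win_lo, win_hi, n_perm,
                         w$hp[usable])
    if (mode == "chromwise") {
      minima <- sort(res$minima)
      for (a in alphas)
        thr_rows[[length(thr_rows) + 1L]] <-
          data.frame(chrom = ch, alpha = a,
                     threshold = minima[ceiling(a * n_perm)],
                     n_perm = n_perm)
    } else {
      pv <- obs$p_value[obs$chrom == ch]
      pv[usable] <- res$exceed / n_perm
      obs$p_value[obs$chrom == ch] <- pv
    }
  }
  if (mode == "perwindow") return(obs)
  if (length(thr_rows) == 0)
    return(data.frame(chrom = character(), alpha = numeric(),
                      threshold = numeric(), n_perm = integer()))
  do.call(rbind, thr_rows)
}

#' Flag windows below the permutation-derived critical Hp
#'
#' @param windows [hp_scan()] table.
#' @param thresholds [permute_thresholds()] table (chromwise mode),
#'   optionally carrying extra levels.
#' @param alpha significance level to use.
#' @return `windows` with logical `significant` (strictly `hp < threshold`;
#'   windows with undefined Hp or on chromosomes without a threshold are
#'   `NA` = untested) and the matched `threshold`.
#' @export
significant_windows <- function(windows, thresholds, alpha = 0.05) {
  th <- thresholds[thresholds$alpha == alpha, , drop = FALSE]
  m <- match(windows$chrom, th$chrom)
  windows$threshold <- th$threshold[m]
  windows$significant <- ifelse(is.na(windows$hp) | is.na(windows$threshold),
                                NA, windows$hp < windows$threshold)
  windows
}
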
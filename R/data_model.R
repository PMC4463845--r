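#' @useDynLib poolsweep, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rbinom rpois runif rbeta rexp sd setNames
#'   cor.test chisq.test
#' @importFrom utils read.delim write.table
NULL

## Closed vocabulary of functional annotation categories.  The first five
## entries of .PFVAR_CATEGORIES are putatively functional by category alone;
## any category becomes putatively functional inside a most conserved element
## (MCE) or when predicted to alter RNA secondary structure.
.CATEGORIES <- c("intergenic", "updownstream", "intronic", "nonsyn_intol",
                 "nonsyn_tol", "stopgain_loss", "synonymous", "splicing",
                 "utr", "ncrna")
.PFVAR_CATEGORIES <- c("nonsyn_intol", "nonsyn_tol", "stopgain_loss",
                       "splicing", "ncrna")

#' Construct a per-line pooled SNP call table
#'
#' One row per variant observation in one sequenced line/pool. Positions are
#' 1-based (VCF convention); all window and region arithmetic elsewhere in
#' the package is 0-based half-open, and the conversion happens exactly once,
#' at the window/interval boundary.
#'
#' @param line_id line identifier (recycled if length 1).
#' @param chrom chromosome identifier.
#' @param pos 1-based position.
#' @param ref,alt single-base reference and alternative alleles.
#' @param snpq Phred-scaled variant quality (SNPQ).
#' @param depth total good-quality reads covering the site.
#' @param alt_fwd,alt_rev reads supporting the alternative allele on the
#'   forward and reverse strand.
#' @return A `data.frame` with the nine columns above, validated.
#' @export
snp_calls <- function(line_id, chrom, pos, ref, alt, snpq, depth,
                      alt_fwd, alt_rev) {
  df <- data.frame(line_id = as.character(line_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   ref = as.character(ref),
                   alt = as.character(alt),
                   snpq = as.numeric(snpq),
                   depth = as.integer(depth),
                   alt_fwd = as.integer(alt_fwd),
                   alt_rev = as.integer(alt_rev),
                   stringsAsFactors = FALSE)
  validate_snp_calls(df)
  df
}

validate_snp_calls <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("line_id", "chrom", "pos", "ref", "alt", "snpq", "depth",
            "alt_fwd", "alt_rev")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("snp_calls is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$pos < 1)) stop("pos must be >= 1")
  if (any(df$depth < 0)) stop("depth must be >= 0")
  if (any(df$snpq < 0)) stop("snpq must be >= 0")
  if (any(df$alt_fwd < 0 | df$alt_rev < 0))
    stop("strand-wise alt read counts must be >= 0")
  if (any(df$alt_fwd + df$alt_rev > df$depth))
    stop("alt_fwd + alt_rev must not exceed depth")
  if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L))
    stop("ref and alt must be single bases (indels are not SNP calls)")
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  invisible(df)
}

#' Per-line pool metadata
#'
#' @param line_id line identifier.
#' @param group group label, one of broiler, BEL, WEL, inbred, other.
#' @param n_individuals number of diploid individuals in the pool.
#' @param mean_cov,sd_cov mean and standard deviation of the line's
#'   sequencing coverage, in reads.
#' @return A validated one-row-per-line `data.frame`.
#' @export
line_stats <- function(line_id, group, n_individuals, mean_cov, sd_cov) {
  group <- match.arg(as.character(group),
                     c("broiler", "BEL", "WEL", "inbred", "other"),
                     several.ok = TRUE)
  stopifnot(all(n_individuals >= 1), all(mean_cov >= 0), all(sd_cov >= 0))
  data.frame(line_id = as.character(line_id), group = group,
             n_individuals = as.integer(n_individuals),
             mean_cov = as.numeric(mean_cov), sd_cov = as.numeric(sd_cov),
             stringsAsFactors = FALSE)
}

#' Read a chromosome-sizes table
#'
#' @param path two-column tab-delimited file: chromosome, length in bases.
#' @return A genome layout: `data.frame` with columns `chrom`, `length`,
#'   chromosomes in file order.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

#' Construct a genome layout
#'
#' @param chrom chromosome identifiers (unique).
#' @param length chromosome lengths in bases (> 0).
#' @return `data.frame` with columns `chrom`, `length`.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome identifiers must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  data.frame(chrom = chrom, length = as.numeric(length),
             stringsAsFactors = FALSE)
}

#' Read one line's pooled variant calls from a VCF
#'
#' Keeps biallelic SNP records and splits multiallelic SNP records into one
#' call per alternative allele; indels and other non-SNP records are skipped
#' and counted. Total depth is taken from the `DP` INFO field and per-strand
#' alternative-allele support from `DP4` (ref-fwd, ref-rev, alt-fwd,
#' alt-rev). A multiallelic record's combined `DP4` alt counts are inherited
#' by each split allele (VCF does not carry per-allele strand depths).
#' Files without `DP` or `DP4` are rejected rather than guessed, because the
#' strand-support filter is meaningless without per-strand counts.
#'
#' @param path VCF 4.x file.
#' @param line_id identifier to stamp on every call.
#' @return A [snp_calls()] `data.frame`; the number of skipped non-SNP
#'   records is available as `attr(x, "n_skipped")`.
#' @export
read_pool_vcf <- function(path, line_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  dp4 <- vcfR::extract.info(vcf, "DP4")
  if (n > 0 && (all(is.na(dp)) || all(is.na(dp4))))
    stop("VCF lacks DP/DP4 INFO fields; per-strand alt depths are required")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- nchar(ref) == 1L &
    vapply(strsplit(alt, ",", fixed = TRUE),
           function(a) all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
           logical(1))
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    message("read_pool_vcf: skipped ", n_skipped, " non-SNP record(s)")
  keep <- which(is_snp)
  if (length(keep) == 0) {
    out <- snp_calls(character(), character(), integer(), character(),
                     character(), numeric(), integer(), integer(), integer())
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  bad <- keep[is.na(dp[keep]) | is.na(dp4[keep])]
  if (length(bad))
    stop("VCF record at ", fix[bad[1], "CHROM"], ":", fix[bad[1], "POS"],
         " lacks DP or DP4")
  alts <- strsplit(alt[keep], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(keep, n_alt)
  d4 <- do.call(rbind, strsplit(dp4[idx], ",", fixed = TRUE))
  storage.mode(d4) <- "integer"
  out <- snp_calls(line_id = line_id,
                   chrom = fix[idx, "CHROM"],
                   pos = as.integer(fix[idx, "POS"]),
                   ref = ref[idx],
                   alt = unlist(alts),
                   snpq = as.numeric(fix[idx, "QUAL"]),
                   depth = dp[idx],
                   alt_fwd = d4[, 3],
                   alt_rev = d4[, 4])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a SNP annotation table
#'
#' Tab-delimited with header `chrom`, `pos`, `category`, `in_mce`,
#' `rna_struct`, then one alternative-allele-frequency (AAF) column per line;
#' an empty cell means the SNP was not detected in that line. Adds the
#' derived columns `mean_aaf` (mean over lines where detected) and `pfvar`
#' (putatively functional: amino-acid-altering, splicing, ncRNA, inside an
#' MCE, or RNA-structure-altering).
#'
#' @param path file path.
#' @return `data.frame`; the line identifiers are in `attr(x, "line_ids")`.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = "", stringsAsFactors = FALSE)
  fixed <- c("chrom", "pos", "category", "in_mce", "rna_struct")
  miss <- setdiff(fixed, names(df))
  if (length(miss))
    stop("annotation table is missing columns: ", paste(miss, collapse = ", "))
  line_ids <- setdiff(names(df), fixed)
  df$chrom <- as.character(df$chrom)
  df$in_mce <- as.logical(df$in_mce)
  df$rna_struct <- as.logical(df$rna_struct)
  annotated_snps(df, line_ids)
}

#' Validate and finalize an annotation table
#'
#' @param df `data.frame` with columns `chrom`, `pos`, `category`, `in_mce`,
#'   `rna_struct`, and one numeric AAF column per line (`NA` = undetected).
#' @param line_ids names of the AAF columns.
#' @return The table with derived `mean_aaf` and `pfvar` columns and a
#'   `line_ids` attribute.
#' @export
annotated_snps <- function(df, line_ids) {
  df$pos <- as.integer(df$pos)
  bad_cat <- setdiff(unique(df$category), .CATEGORIES)
  if (length(bad_cat))
    stop("unknown annotation category: ", paste(bad_cat, collapse = ", "))
  aaf <- as.matrix(df[, line_ids, drop = FALSE])
  storage.mode(aaf) <- "double"
  out_of_range <- which(!is.na(aaf) & (aaf < 0 | aaf > 1), arr.ind = TRUE)
  if (nrow(out_of_range) > 0)
    stop("AAF outside [0,1] at row ", out_of_range[1, 1])
  if (nrow(df) > 0 && any(rowSums(!is.na(aaf)) == 0))
    stop("every SNP must be detected in at least one line")
  df[line_ids] <- as.data.frame(aaf)
  df$mean_aaf <- rowMeans(aaf, na.rm = TRUE)
  df$pfvar <- df$category %in% .PFVAR_CATEGORIES | df$in_mce | df$rna_struct
  attr(df, "line_ids") <- line_ids
  df
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]; undetected cells are written empty.
#' The derived `mean_aaf`/`pfvar` columns are not written (they are
#' recomputed on read).
#'
#' @param ann annotation table from [annotated_snps()].
#' @param path output path.
#' @export
write_annotation_table <- function(ann, path) {
  line_ids <- attr(ann, "line_ids")
  cols <- c("chrom", "pos", "category", "in_mce", "rna_struct", line_ids)
  out <- ann[, cols, drop = FALSE]
  out$in_mce <- ifelse(out$in_mce, "TRUE", "FALSE")
  out$rna_struct <- ifelse(out$rna_struct, "TRUE", "FALSE")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Write intervals as BED5
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `name`, `score`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score") %in%
                  names(intervals)))
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end))
    stop("BED intervals must satisfy start < end")
  write.table(intervals[, c("chrom", "start", "end", "name", "score")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first 3-5 columns)
#'
#' @param path BED file; 0-based half-open coordinates.
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score")[seq_len(ncol(df))]
  df$chrom <- as.character(df$chrom)
  df
}
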
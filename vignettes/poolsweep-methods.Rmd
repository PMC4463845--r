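---
title: "Pool-seq filtration, allele-frequency characterization and Hp sweep scans: methods"
author: "poolsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poolsweep methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
```

## The setting

`poolsweep` analyses pooled whole-genome resequencing (Pool-seq) of
structured populations — in the motivating design, commercial chicken
lines, each sequenced as a single pool of 10–15 diploid individuals at
8–17X coverage. Because individual genotypes are never observed, every
inference rests on read counts: the alternative-allele frequency (AAF) of a
SNP in a line is the proportion of good-quality reads supporting the
alternative allele, and diversity statistics are computed from per-site
major/minor allele read counts. The pipeline covers five stages:

1. **Filtration** of per-line SNP calls by quality, coverage, strand
   support, marker spacing and local density.
2. **False-discovery benchmarking** of call sets against an independently
   sequenced gold standard.
3. **Allele-frequency characterization** by functional annotation
   category: spectra, fixation, private variants.
4. **Selective-sweep scanning** with pooled heterozygosity (Hp) in sliding
   windows and chromosome-wise permutation thresholds.
5. **Region calling**: intersection of significant windows across the
   lines of a group, merging into discrete putative selective-sweep (pSS)
   regions, QTL overlap, and prioritization of fixed putatively functional
   variants (pfVars).

A seeded simulator (`simulate_poolseq()`) generates all inputs with the
statistical structure these stages assume, so the whole pipeline is
testable without any sequencing data.

## Filtration

`apply_filters()` runs five stages in a fixed order — quality, coverage,
strand support, spacing, density — with defaults SNPQ ≥ 40, depth ≥ 5 and
≤ mean line coverage + 3 SD, ≥ 2 alternative reads with at least one per
strand, inter-marker distance > 1 base, and exclusion of any 50-base span
holding more than 10 SNPs. Choices the definition leaves open, decided
here once:

* **Spacing removes both members** of a too-close pair. Nothing
  distinguishes the two calls, so keeping either would be arbitrary;
  removing both is conservative.
* **The coverage band uses only the upper limit** mean + 3 SD together
  with the explicit floor of 5 reads. A mean − 3 SD lower bound would
  usually fall below 5 at these coverages, so the floor subsumes it.
* **Density masking slides base by base** rather than over tiled 50-base
  bins: a cluster straddling a tile boundary is still a cluster.
* **Filters are per line.** A SNP removed in one line may legitimately
  survive in another; "detected in a line" downstream always means
  "survived that line's filters". The density rule is likewise applied per
  line, not on the merged SNP set.

Spacing and density are idempotent (tested by property), and the spacing
and density stages deliberately act on the quality-filtered set: a
low-quality call does not get to veto its well-supported neighbour.

## Gold-standard evaluation

`evaluate_calls()` restricts the call set to the gold standard's covered
intervals and counts a true positive when both methods call a site, a
false positive when only the pipeline does, a false negative when only the
gold standard does, and every remaining covered base as a true negative.
Matching is by position only; allele agreement is not required. Counting
true negatives per base makes specificity depend on the covered length and
therefore look very high — that is inherent to the definition being
reproduced, and the more informative figure is the FP proportion
FP / (retained calls). Error rates quoted as whole percentages use
truncation (`pct_truncate()`: 0.515 → 51), which is how such rates are
conventionally printed.

`threshold_sweep()` traces both filtration methods across a quality grid:
Method 1 filters on SNPQ alone, Method 2 additionally imposes the
both-strand rule. Since the strand rule only removes calls, Method 2's FP
count is never above Method 1's at the same threshold (asserted as an
invariant).

## Allele frequencies and spectra

Per-line AAFs come straight from read proportions (`estimate_aaf()`); the
caller-emitted depth is trusted because base- and mapping-quality
filtering happened upstream. The mean AAF of a SNP averages only the lines
where it was detected. Fixation uses a strict AAF > 0.9 ("fixed or nearly
fixed"); "multi-line" means detected in strictly more than 10 lines; a
private SNP is detected in exactly one line. Spectra
(`build_spectra()`) histogram **per-line observations** — each detected
line contributes one value — in half-open bins of width 0.05 over (0, 1];
the bin width matches the convention of quoting a "low-frequency bin
(≤ 0.05)", and an AAF of exactly 0 would fall in the lowest bin. Pooling
per-line observations rather than per-SNP means is a declared choice; the
alternative would smooth the spectra toward the centre.

With pools of 10–15 individuals sequenced at 8–17X and detection requiring
two alternative reads split across strands, frequencies at or below 0.05
are essentially undetectable — the lowest bin of the spectrum is expected
to be empty, and `expected_detection_loss()` quantifies exactly this loss
by comparing the simulator's truth to what survives the detection rules.
For a site with true AAF *p* in a line at depth λ, alt-forward and
alt-reverse reads are independent Poisson(λp/2) by thinning, so the
detection probability under the strand rule is (1 − e^(−λp/2))²; the
simulation agrees with this closed form (tested).

The non-coding/coding pfVar ratio (`noncoding_coding_ratio()`) divides,
within each mean-AAF bin, the count of non-coding pfVars (intergenic,
intronic, UTR or up/downstream variants inside a most conserved element,
ncRNA variants, RNA-structure-altering variants) by the count of
amino-acid-altering plus splicing variants, with stop-gain/loss counted as
amino-acid-altering. Bins with no coding variant report `NA`, not
infinity.

## The Hp scan

Pooled heterozygosity of a window is

Hp = 2 · ΣnMAJ · ΣnMIN / (ΣnMAJ + ΣnMIN)²,

with the sums of per-site major and minor allele read counts taken over
the window's SNPs. Hp lies in [0, 0.5], reaching 0.5 only when the two
sums tie and 0 under complete local fixation. Windows are 40 kb sliding by
20 kb, anchored at coordinate 0 (the anchor is a convention; no anchor is
canonical), and a window is analysable only with strictly more than 10
SNPs. A truncated terminal window is kept when it is at least half a
window long and not nested inside its predecessor — so a chromosome of
100 kb yields exactly [0,40k), [20k,60k), [40k,80k), [60k,100k).

### Permutation thresholds

Mean Hp varies between lines and, within a line, between chromosomes
(recombination-rate variation), so a single genome-wide cutoff would be
miscalibrated. Critical values are instead empirical and chromosome-wise:
the per-site (n_maj, n_min) pairs are shuffled among the chromosome's SNP
positions — positions stay fixed, so per-window SNP counts and the set of
analysable windows never change — and each shuffle records the minimum Hp
over the chromosome's analysable windows. The critical Hp at level α is
the lower empirical α-quantile of these minima, taken as the order
statistic at ⌈α · n_perm⌉ so results are bit-reproducible under a seed. A
window is significant when its observed Hp is **strictly below** the
critical value. Using minima controls the chromosome-wise probability that
any window falls below the threshold, which is the intended error rate for
"does this chromosome carry a sweep signal"; a per-window mode
(`mode = "perwindow"`) returning empirical P values per window is provided
as an alternative. Count **pairs** are shuffled, not the two alleles
independently, preserving each site's depth. Shuffled-data minima are
computed by a small C++ kernel, but every permutation is a Fisher–Yates
pass over R's own RNG stream, so a run is fully determined by `set.seed()`
and the test suite replays the identical shuffles in pure R.

The default of 10,000 permutations resolves α = 0.001; the packaged
experiments use 1,000 permutations, which resolves the α = 0.05 level they
test at while keeping a 200-chromosome calibration run in minutes. The
calibration experiment (`calibration_experiment()`) checks the design: on
neutral 2 Mb chromosomes at 15 SNPs/kb and 12X, the fraction of
chromosomes with any significant window at α = 0.05 should be ≈ 0.05
within binomial error.

## Region calling

Cross-population comparison suppresses drift and demography: only windows
significant in **every** line of a group (`common_windows()`; a
`drop_lines` argument re-runs the intersection excluding a named line, for
the case where one aberrant line — e.g. one with unusually low critical
values from high background fixation — masks otherwise shared signals) are
carried forward. Overlapping or abutting common windows are merged
transitively into discrete pSS regions (`merge_regions()`, backed by
`GenomicRanges::reduce`); "abutting" counts as joinable, which only
matters for windows meeting exactly on the grid since consecutive
significant windows already overlap when the step is half the window.
Merging is idempotent and order-independent, and the region count can only
be at most the window count. QTL overlap is any shared base under
half-open coordinates. Within each region, pfVars are classified per line
as fixed (AAF > 0.9) or segregating and then labelled ubiquitous-fixed
(fixed wherever detected, across more than one group), group-specific
(fixed in every line of exactly one group and undetected or segregating
everywhere else), group-fixed, or segregating. Sex chromosomes can be
excluded with a chromosome blocklist (default empty) when pool sex
composition differs between lines.

## The simulator

`simulate_poolseq()` emulates the study design rather than the sequencing
machinery: true SNPs are placed uniformly at 15 SNPs/kb; each line's true
AAF at a site is drawn from a uniform law on [0.05, 1] (a flat spectrum —
convenient for calibration because departures are visible); depth is
Poisson with mean λ (default matching the 8–17X design); alternative reads
are Binomial(depth, AAF); strands are fair coin flips. Error sites occur
at a per-base rate, carry true AAF 0 everywhere, get 1–3 artefactual
alternative reads that land on a single strand half the time (so the
strand filter has something to discriminate), and draw low-shifted quality
scores, while true sites draw SNPQ ≥ 40. Sweep intervals set the chosen
lines' true AAF to 1. Categories follow a configurable mix defaulting to
realistic genome-wide proportions in which intergenic and intronic
variants dominate and coding classes are rare; optional per-class AAF laws
let coding pfVars sit at low frequencies (purifying selection) and
MCE/ncRNA/structure non-coding pfVars reach high frequencies
(hitchhiking), which is what the spectrum experiment exercises.

What the simulator does **not** model, and what passing tests therefore do
not show about real data: read sampling is binomial, ignoring the finite
pool of 2n chromosomes (no double-sampling correction), so sampling
variance at high depth is mildly understated; there is no alignment error,
mapping bias, indel realignment or linkage disequilibrium — sites are
independent, so the permutation null is exactly true in the simulation,
whereas real background LD makes neighbouring windows correlated; and
annotation labels are assigned independently of position. Multiallelic
records are split one call per alternative allele on reading, with the
record-level DP4 alternative counts inherited by each split allele, since
VCF carries no per-allele strand depths.

## Numerical and degenerate-input conventions

* Coordinates: SNP positions are 1-based (VCF); all window and region
  arithmetic is 0-based half-open (BED); the conversion happens exactly
  once, at the window/interval boundary.
* Hp at a tie (n_maj = n_min) is label-invariant by symmetry; the
  assignment is irrelevant.
* Windows with ≤ 10 SNPs are emitted with `hp = NA` and never tested;
  chromosomes with no analysable window produce no threshold and their
  windows are reported untested, as are windows whose chromosome lacks a
  threshold at the requested level.
* A window exactly at its critical value is not significant (strict
  inequality).
* `fp_proportion` with an empty retained call set, and sensitivity with an
  empty truth set, are reported as missing rather than 0/0.
* Zero depth is a hard error for AAF and allele-count computation, never a
  silent 0.

## Problem sizes in the packaged experiments

The experiment functions default to the sizes used throughout the tests
and the acceptance script, chosen to make each experiment's sampling error
small relative to the effect it measures while keeping a laptop run short:
calibration uses 200 neutral chromosomes of 2 Mb at 15 SNPs/kb and 12X
with 1,000 permutations; sweep recovery uses 50 replicates of a 4-line
group with a 200 kb fixed interval on a 2 Mb chromosome; the spectrum
experiment uses 4 Mb × 4 lines (~60,000 sites). The genome-scale outputs
of the original design (tens of millions of SNPs, tens of thousands of
windows per line) are structural targets only — the same code paths at
smaller n — and are not re-derived here.
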
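---
title: "Methods: Pol I NET-seq occupancy analysis on a toy rDNA locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pol I NET-seq occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polinetseq)
```

## The measurement and the model

Native elongating transcript sequencing (NET-seq) captures nascent RNA
still associated with the polymerase. Each sequenced fragment ends at the
last incorporated nucleotide (LNT) of a nascent transcript, so the 5' end
of the aligned read marks the position of one polymerase at the moment of
harvest. Counting read 5' ends per template position therefore yields a
single-nucleotide occupancy profile: peaks are slowly transcribed
(pause-prone) positions, valleys are rapidly transcribed ones. Two
biological signals are of interest for RNA polymerase I on the 35S rDNA
unit:

* **Processivity.** If a fraction of polymerases terminates prematurely,
  occupancy becomes enriched toward the 5' end of the unit and depleted
  toward the 3' end. A per-nucleotide termination probability $\delta$
  produces survival $\propto (1-\delta)^x$ at transcription-direction
  position $x$.
* **Sequence-dependent pausing.** If dwell time depends on the template
  downstream of the active site, pause sites acquire a sequence signature.
  We couple dwell weight to the G fraction $g(x)$ of the 10 sense-strand
  positions downstream of $x$ through a coefficient $\beta$.

The synthetic generator draws LNT positions from
$$
P(x) \;\propto\; (1-\delta)^x \, e^{\beta g(x)},
$$
normalized over eligible positions. These two parameters are the ground
truth that the analysis stages must recover: $\delta_{mut} > \delta_{wt}$
must surface as a 5'-up/3'-down occupancy shift, and
$\beta_{mut} > \beta_{wt} = 0$ as downstream-G enrichment in the pause-site
difference logo.

## The toy locus and its geometry

`generate_template()` builds a small genome carrying **two identical
copies** of a 35S-like unit — ETS1, 18S, ITS1, 5.8S, ITS2, 25S, ETS2 in
transcription order (defaults 100, 180, 80, 60, 80, 340, 60 nt; 900 nt
total) — inside random flanks. Real rDNA repeats are several-fold longer;
the toy unit is scaled down so that full simulation-heavy checks run in
seconds while keeping all seven regions large enough for region-level
statistics.

The unit is deliberately placed on the genomic **minus strand**. A NET-seq
insert is the 3'-most stretch of the nascent transcript, i.e. the
transcribed sequence *ending* at the LNT. With a minus-strand gene, that
insert is, read left-to-right, a plus-strand genomic substring whose
**leftmost coordinate is the LNT**. Two consequences follow literally, with
no special cases:

* 5'-end genome coverage (the single-base `start+1` / `end` convention
  implemented in `count_5prime_ends()`) puts each read's count exactly on
  its LNT;
* every on-target read aligns to the plus strand, so normalizing by the
  plus-strand total is the natural library-size correction.

Transcription-direction coordinate $i \in 1..U$ maps to 1-based genomic
position $e - i + 1$ for a copy spanning $[s, e)$; the per-position
"nucleotide" column is the sense (RNA-like) strand, the complement of the
plus strand read backwards. Positions within one maximum fragment length of
the unit's 5' edge cannot yield a full insert and are excluded from the
sampling distribution (their truth probability is 0).

## Read structure and preprocessing

Each on-target read is `AG` + 8-nt UMI + `TG` + insert +
`CTGTAGGCACCAT` (3' linker). Preprocessing is three exact-match steps:

1. **Deduplication** collapses identical molecules. PCR duplicates are
   verbatim copies including the embedded UMI, so identical full sequence
   (or identical UMI + insert once the UMI has been split off) identifies a
   duplicate. No mismatch tolerance is applied anywhere in preprocessing:
   the simulator introduces no sequencing errors, and exact matching keeps
   every contract deterministic. This is a dialect choice; a real-data
   adapter trimmer typically tolerates mismatches.
2. **Format filtering** keeps reads of length ≥ 13 with `AG` at positions
   1–2 and `TG` at 11–12, records positions 3–10 as the UMI, and removes
   the 12-nt prefix.
3. **Linker trimming** truncates at the *first* occurrence of the linker;
   reads whose insert becomes empty are discarded.

Off-target reads (a configurable fraction) are random sequence constructed
to fail the format filter, emulating library contamination.

## Alignment, counting, and the per-position data frame

`align_exact()` is a minimal exact-substring aligner over the toy genome
(Biostrings `PDict`/`matchPDict` with a trusted-band prefix). Because the
two 35S copies are identical, every on-target insert matches both; each
read contributes one interval per matching location, and `build_track()`
sums the two copies per transcription-direction coordinate. Up to the
constant factor of two this reproduces a combine-the-copies step, and the
factor cancels in normalization. The reverse complement is searched only
for inserts without a plus-strand match; dual-strand exact matches would be
degenerate ambiguities the toy aligner does not attempt to resolve.
`normalize_track()` divides plus-strand counts by their total, so a
normalized track sums to 1; minus-strand counts are kept for QC only.

## Comparison statistics

* **Replicate concordance** is Spearman rank correlation of normalized
  tracks (average ranks for ties). Identical rankings return exactly 1,
  bypassing floating-point round-off in the product-moment formula. Note
  that concordance reflects *heterogeneity*: with a nearly uniform truth
  (small $\delta$, $\beta = 0$) replicates are dominated by counting noise
  and concordance is legitimately near 0.
* **Per-position test.** With three replicates per strain, each position
  gets a two-sided two-sample t-test on normalized values; positions with
  $p < \alpha$ are classed `increased`/`decreased` by the direction of the
  median difference. The default pools variances (`var.equal = TRUE`):
  direct simulation shows the Welch–Satterthwaite test at $n = 3$ per group
  is visibly conservative (type-I error near 0.035 at $\alpha = 0.05$
  even for Gaussian data, because the estimated degrees of freedom are
  noisy), while the pooled test comes much closer to its nominal size on
  Poisson-like counts. Even the pooled test retains a small intrinsic
  conservatism on count data: at ~12 reads per position its measured null
  size is ≈ 0.048 rather than 0.050, because with three replicates the
  variance estimate co-varies with the mean on right-skewed counts. This
  is shared by every test in the family (variance-stabilizing transforms
  and moderated-variance fits move it only to ≈ 0.0485) and vanishes as
  coverage grows. Welch remains available via `var_equal = FALSE`. No
  multiple-testing correction is applied: the per-position track is a
  display of raw local evidence, not a discovery list. Positions with no
  variation at all (e.g. all-zero counts near the ineligible 5' edge) are
  reported with `NA` p-values and class `none`; they carry no information
  about the test.
* **Moving averages** use full windows only (output length
  $n - w + 1$), avoiding invented edge values. Window sizes of 200 and
  2000 nt are the configuration defaults; windows larger than the analysed
  unit (the 2000-nt window on the 900-nt toy unit) are skipped with a
  message rather than padded.
* **K-S tests** compare the per-position median normalized values of the
  two strains as value samples — genome-wide, per smoothed profile, and per
  region — using the asymptotic two-sample statistic (ties make it mildly
  conservative, which is acceptable here).

## Pause sites and the difference logo

Pause sites are the positions at or above the $1 - f$ quantile
($f = 0.025$ by default) of the median normalized track, computed per
strain after excluding positions within one flank (30 nt) of the unit
edges. All positions tied at the threshold are kept: deterministic, at the
cost of occasionally exceeding $f$ exactly at ties. Windows cover labels
$-30..-1, +1..+30$ with the LNT base at label $-1$ and no label 0.

Position matrices are maximum-likelihood per-column base probabilities with
no pseudocounts ($0 \log 0 \equiv 0$ keeps the divergence finite). For each
column the difference-logo height is the Jensen–Shannon divergence (base
2, bounded by 1 bit, exactly 1 for disjoint point masses); the per-base
signed contribution is
$h \,(p_{mut}(b) - p_{wt}(b)) / \sum_{b'} |p_{mut}(b') - p_{wt}(b')|$,
positive toward the mutant, so absolute contributions sum to the height.
Significance is by permutation: the pooled base observations of the column
are reallocated to the two strains with group sizes preserved, and the
p-value is the fraction of shuffles whose divergence reaches the observed
one, with the $+1/(n+1)$ correction so p is never 0. This implements the
generic permutation description of difference-logo testing; the internal
height-partition rule of any particular plotting package is not
reverse-engineered.

## Numerical and design choices

* Weights are computed in log space and normalized after subtracting the
  maximum, so large $x \log(1-\delta)$ terms cannot underflow.
* All randomness flows through explicit integer seeds (a private RNG
  stream that never disturbs the caller's `.Random.seed`); fixed seed
  means byte-identical reads, truth tables, and manifest checksums.
* Tracks are written with 17 significant digits so TSV round trips are
  value-identical; every tabular output carries a header comment with the
  tool version, seed, and configuration hash.
* Default strain parameters used by the bundled pipeline:
  $\delta_{wt} = 5\times10^{-4}$, $\delta_{mut} = 2.5\times10^{-3}$
  (a five-fold processivity defect), $\beta_{wt} = 0$, $\beta_{mut} = 1$,
  10% PCR duplication, 5% off-target reads, inserts 20–40 nt, triplicate
  libraries of 20,000 reads. These give each position ~45 expected counts,
  enough for the per-position test to be well calibrated while the whole
  simulate-to-logo pipeline stays interactive.

## What the simulation does and does not show

The generator reproduces the statistical structure the analysis relies on:
multinomial sampling of LNTs from a smooth position distribution, verbatim
PCR duplicates, format-failing contamination, and two identical gene
copies. It does **not** model base-call errors or quality scores, rDNA
copy-number variation between strains, partial linkers, RNA secondary
structure, or any kinetic mechanism behind pausing — dwell weight is a
static function of downstream G content. Passing the recovery checks
therefore demonstrates that the analysis measures what it claims on data
satisfying its assumptions; it does not validate robustness to alignment
ambiguity or error-containing reads, which real libraries would add.

```{r example, eval = FALSE}
locus <- generate_template(c(100, 180, 80, 60, 80, 340, 60), seed = 7)
wt <- lapply(1:3, function(k) {
  sim <- simulate_reads(locus, strain_params(termination_prob = 5e-4),
                        20000, seed = k)
  occupancy_track(preprocess_reads(sim$reads)$reads, locus, "wt",
                  paste0("rep", k))
})
mut <- lapply(1:3, function(k) {
  sim <- simulate_reads(locus,
                        strain_params(termination_prob = 2.5e-3,
                                      pause_gc_weight = 1),
                        20000, seed = 10 + k)
  occupancy_track(preprocess_reads(sim$reads)$reads, locus, "mut",
                  paste0("rep", k))
})
cmp <- compare_strains(wt, mut, locus, analysis_config(windows = 200))
cmp
pl <- pause_logo_analysis(cmp$median_wt, cmp$median_mut, locus,
                          analysis_config(windows = 200))
pl$difflogo
```
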
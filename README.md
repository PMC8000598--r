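# polinetseq

Single-nucleotide occupancy analysis of RNA polymerase I NET-seq data on a
two-copy rDNA locus, with a synthetic-library generator providing known
ground truth for every stage.

## The problem

Native elongating transcript sequencing (NET-seq) sequences nascent RNA
still held by the polymerase; the 5' end of each read marks the 3' end of
the nascent transcript — the last incorporated nucleotide (LNT) — and
therefore the polymerase's position on the template. Counting read 5' ends
per position gives a single-nucleotide occupancy profile of Pol I across
the 35S rDNA transcription unit (ETS1, 18S, ITS1, 5.8S, ITS2, 25S, ETS2).
Comparing a wild-type strain against a mutant then asks two questions:

* **Processivity** — does the mutant lose polymerases along the way? A
  per-nucleotide premature-termination probability δ produces occupancy
  `∝ (1 − δ)^x` at transcription-direction position `x`: enrichment at the
  5' end, depletion at the 3' end when δ rises.
* **Sequence-dependent pausing** — do high-occupancy (pause) sites carry a
  sequence signature? Dwell weight `∝ exp(β·g(x))`, with `g(x)` the G
  fraction of the 10 template positions downstream of `x`, plants a
  downstream-G preference that a difference logo between the strains'
  pause-site position matrices should recover.

The package implements the whole path: FASTQ preprocessing (exact
PCR-duplicate removal, `AG`+UMI+`TG` 5'-format filtering, 3'-linker
trimming), exact-match alignment to a toy two-copy locus, 5'-end counting
with copy collapsing and plus-strand normalization, replicate Spearman
concordance, per-position strain tests with moving-average profiles and
Kolmogorov–Smirnov comparisons (genome-wide and per region), and
top-quantile pause-site calling with a permutation-tested
Jensen–Shannon difference logo. A simulator with explicit (δ, β) ground
truth drives calibration and recovery checks end to end.

## Worked example

```r
library(polinetseq)

locus <- generate_template(c(100, 180, 80, 60, 80, 340, 60), seed = 7)
wt <- lapply(1:3, function(k) {
  sim <- simulate_reads(locus, strain_params(termination_prob = 5e-4),
                        20000, seed = k)
  occupancy_track(preprocess_reads(sim$reads)$reads, locus, "wt",
                  paste0("rep", k))
})
mut <- lapply(1:3, function(k) {
  sim <- simulate_reads(locus,
                        strain_params(termination_prob = 2.5e-3,  # 5x delta
                                      pause_gc_weight = 1),
                        20000, seed = 10 + k)
  occupancy_track(preprocess_reads(sim$reads)$reads, locus, "mut",
                  paste0("rep", k))
})

cmp <- compare_strains(wt, mut, locus, analysis_config(windows = 200))
cmp
#> strain_comparison over 900 positions
#>   increased: 169  decreased: 244 (alpha = 0.05)
#>   genome-wide K-S: D = 0.3700, p = 0

pl <- pause_logo_analysis(cmp$median_wt, cmp$median_mut, locus,
                          analysis_config(windows = 200))
pl$difflogo
#> diff_logo_result: 60 columns, 2 significant at alpha = 0.05
#>   significant labels: -21 1
sum(pl$difflogo$contributions["G", pl$difflogo$columns$label %in% 1:10])
#> [1] 0.2088439
```

The five-fold δ increase in the mutant shows up as hundreds of
significantly changed positions (increased ones concentrated 5', decreased
ones 3') and a genome-wide K-S difference; the β = 1 pause weighting shows
up as a positive net G contribution on the mutant side of the difference
logo over labels +1..+10, with only a couple of individually significant
columns — per-column permutation tests at ~20 pause windows per strain have
limited power, so the trend across the downstream block is the readout.

A command-line front end over the same functions is installed at
`inst/cli/polinetseq.R` (subcommands `simulate`, `preprocess`, `occupancy`,
`compare`, `pauselogo`, `all`), and `run_pipeline()` orchestrates all
stages with a checksummed output manifest.

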
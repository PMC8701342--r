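# cnpipe

Copy-number inference from whole-genome sequencing coverage and qPCR in
haploid yeast.

Viable yeast strains carrying nonsense mutations in the essential
translation-termination factor genes (*SUP35*/eRF3, *SUP45*/eRF1) adapt by
amplifying the mutant allele: centromeric plasmids that normally sit at ~1
copy per cell rise to several copies, whole chromosomes become disomic, and
defined chromosomal segments duplicate. `cnpipe` implements the inference
chain that detects and quantifies these events from standard sequencing and
qPCR outputs, together with a synthetic-data generator with recorded ground
truth so every stage is testable without any external download.

## The statistics at the core

* **Plasmid copy number** (copies per haploid genome) is a depth ratio:

  `CN = mean depth over plasmid-specific bases / genome-wide mean depth`

  where "plasmid-specific" is the complement of the plasmid/genome shared
  sequence (markers, CEN/ARS, the cloned insert). A seeded bin-level
  bootstrap gives a 95% CI. A uniformity diagnostic checks that every
  backbone feature is elevated in concert (whole-plasmid amplification)
  rather than one region alone (intra-plasmid rearrangement).

* **Disomy** is called per chromosome from the median of normalized binned
  coverage (euploid < 1.25, disomic >= 1.75, ambiguous between).

* **Segmental duplications** come from recursive binary segmentation of
  log2 normalized coverage: max-t splits gated by a seeded permutation
  test (p < 0.01), adjacent segments merged below a 0.4 log2 contrast,
  boundaries refined by a negative-binomial likelihood-ratio locator, and
  gains reported at copy factor >= 1.5.

* **Variant recurrence**: per-sample VCF calls are aggregated by variant
  key across strains; a variant seen in more than two strains is recurrent.
  Heterozygous calls inside plasmid/genome shared sequence are flagged as
  mapping artifacts; engineered substitutions are flagged from a table.

* **qPCR**: relative quantity by delta-delta-Ct, `2^-((Ct_t - Ct_ref)_s -
  (Ct_t - Ct_ref)_cal)`; groups compared by exact two-sided Wilcoxon
  rank-sum; Benjamini-Hochberg adjustment.

* **Concordance**: Pearson r^2 and OLS fit between WGS- and qPCR-derived
  copy numbers paired by strain.

## Worked example

```r
library(cnpipe)

lay  <- yeast_layout()             # 16 chromosomes + excluded chrM
spec <- default_plasmid_spec()     # 8.5-kb centromeric plasmid geometry

# a strain with 7.5 plasmid copies, a chrII disomy and a 100-kb duplication
ev  <- event_set(plasmid_cn = 7.5, disomies = "chrII",
                 segments = data.frame(seqname = "chrIV", start = 600000L,
                                       end = 700000L, factor = 2))
sim <- simulate_depth(lay, ev, noise_model(mean_depth = 30, dispersion = 10,
                                           seed = 42))

gm  <- genome_mean_depth(sim$track, exclude = lay$excluded)
cv  <- call_cnv(normalize_track(sim$track, gm),
                exclude_sequences = "chrM", seed = 7)
cv$disomy[cv$disomy$status != "euploid", ]
#>   seqname   median  status
#> 2   chrII 1.823616 disomic
cv$segments
#>   seqname start_bin end_bin  start    end n_bins mean_norm copy_factor direction
#> 1   chrIV       599     700 599000 700000    101  1.835551    1.835551      gain

pl  <- simulate_plasmid_depth(spec, 7.5, gm, noise_model(30, 10, seed = 43))
estimate_plasmid_cn(pl, spec, gm, seed = 44)
#> plasmid copy number: 7.54 (95% CI 6.96-8.23, 3800 specific bases)
```

The genome mean (32.4x here, not 30x) is inflated by the planted disomy
and duplication themselves — the naive genome-wide mean is what anchors
the ratio, so a disomy pushes all normalized values down slightly; the
call thresholds are placed to absorb this (see the methods vignette).

## Layout

* `R/` — simulation (`simulate_*`), coverage I/O (`read_depth`,
  `bin_track`, `genome_mean_depth`, `normalize_track`), plasmid CN
  (`estimate_plasmid_cn`, `uniformity`), chromosome CNV (`call_disomy`,
  `segment`, `compare_boundaries`, `call_cnv`), variant recurrence
  (`read_calls`, `aggregate_calls`, `recurrent`), qPCR (`ddct`,
  `quantify_plate`, `compare_groups`, `adjust`), concordance (`concord`,
  `concordance_experiment`).
* `inst/cli/simulate.R` — config-file-driven simulation entry point.
* `vignettes/copy-number-methods.Rmd` — models, assumptions, parameter
  choices, limitations.
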
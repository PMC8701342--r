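---
title: "Copy-number inference from coverage and qPCR: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number inference from coverage and qPCR: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnpipe)
```

# The problem

Haploid yeast strains carrying nonsense mutations in the essential
release-factor genes survive by amplifying the mutant allele. The
amplification takes three forms, each leaving a distinct footprint in
whole-genome sequencing coverage:

1. **Plasmid copy-number gain.** A centromeric plasmid normally maintained
   at about one copy per cell rises to several copies; depth over the
   plasmid rises proportionally.
2. **Whole-chromosome disomy.** A second copy of an entire chromosome
   doubles that chromosome's coverage.
3. **Segmental duplication.** A sub-chromosomal region with defined
   boundaries sits at elevated coverage.

`cnpipe` turns binned or per-base depth, per-sample VCFs and qPCR plates
into calls for all three, and checks the internal consistency of the
evidence (plasmid uniformity, cross-strain variant recurrence, WGS/qPCR
concordance).

# Models and estimators

## Plasmid copy number

The estimator is the ratio of the mean per-base depth over
*plasmid-specific* sequence to the genome-wide mean depth. Sequence shared
between plasmid and genome (selection marker, CEN/ARS cassette, the cloned
insert gene) accumulates reads from the genomic locus *plus* every plasmid
copy — its expected depth is `genome_mean * (CN + 1)` — so it is excluded
outright rather than corrected. The shared set is an explicit input (a BED
mask); the package never derives it by self-alignment.

Uncertainty comes from a nonparametric percentile bootstrap over **bins**
of specific bases (default 1,000 resamples, seeded). Bins, not bases,
because depth is locally autocorrelated at the read-length scale; a
per-base bootstrap would understate the variance roughly by the factor of
the within-bin correlation.

The estimator is exactly blind to shared-region depth (tested as an
invariance) and unbiased across stochastic replicates (tested at 2%).

## Genome mean and normalization

The genome mean is the width-weighted mean of bin means over all nuclear
sequences, after removing excluded intervals (default: the mitochondrial
contig, whose copy number is unrelated to nuclear ploidy). Two deliberate
choices:

* **Disomic chromosomes are not excluded.** The ratio's denominator is the
  naive genome-wide mean. A disomy spanning a fraction *f* of the genome
  inflates the mean by *(1+f)*, deflating all normalized values by the
  same factor; for the largest realistic single-chromosome disomy
  (f ~ 0.13) a true disomy still sits at 2/1.13 = 1.77. The disomy
  threshold (1.75) is placed to absorb exactly this bias.
* **Zero-depth bins are kept.** They are evidence of loss, not missing
  data.

## Disomy calling

Per chromosome, the **median** normalized coverage is compared with fixed
thresholds: euploid below 1.25, disomic at or above 1.75, ambiguous
between. The median (not the mean) makes the call robust to focal
duplications on the same chromosome; the band midpoints guard both against
the genome-mean inflation above and against the right skew of
negative-binomial depth (the median of the per-bin distribution sits
slightly below its mean, which is the main cost of the robustness choice).
At the default simulation noise the decision margin is about four standard
errors of the chromosome median.

## Segmentation

Recursive binary segmentation on `log2(normalized coverage + eps)`, with
`eps = 1/30` (one read at the default 30x) so zero bins stay finite.

* **Split statistic:** the maximizing two-sample t statistic along the
  chromosome (pooled variance).
* **Split acceptance:** a seeded permutation test of the max-|t| statistic
  (default 1,000 permutations, p < 0.01). The permutation loop
  short-circuits as soon as the exceedance count makes p >= 0.01 certain;
  the accept/reject decision is identical to the full test and a flat
  chromosome costs only a few dozen permutations.
* **Contrast rule:** the minimum |delta log2| between segments (0.4 by
  default, about a 1.3-fold step) is enforced *between adjacent final
  segments*, merging the weakest boundary first — not between the two
  halves of the top-level split. Applied at the top level it would
  suppress every small interior event (a 100-bin duplication on a
  1,500-bin chromosome changes the half-chromosome means by only ~0.1
  log2), and it would contradict exact recovery of a noiseless planted
  step, which the merge-based formulation preserves.
* **Boundary refinement:** the global max-t split is a noisy boundary
  locator. Each final boundary is re-placed at the argmax of the
  cumulative log-likelihood ratio between the two flanking segment models,
  with negative-binomial likelihoods under a common moment-estimated
  dispersion. With a shared dispersion the per-bin NB log-likelihood ratio
  is *linear* in the counts, so the locator is insensitive to the heavy
  right tail of read-depth noise (a Gaussian LLR, by contrast, lets single
  outlier bins drag the cut). Refinement never moves a boundary closer
  than `min_bins` to a segment end.
* **Reporting:** segments with mean copy factor >= 1.5 are returned as
  gain calls. Sub-haploid segments (factor <= 1/1.5) are detected by the
  same machinery but only *reported* (in the `losses` attribute /
  component), never interpreted: the phenomena being modeled are gains.
* **Interplay with disomy:** segmentation runs only on chromosomes not
  called disomic, so a whole-chromosome gain is a disomy call and never a
  chromosome-spanning segment.

Boundary agreement between strains (`compare_boundaries`) uses a tolerance
of 2 bins on both ends.

### What boundary accuracy is achievable

At the default noise (30x, per-bin NB dispersion 10, i.e. per-bin CV of
about 36%, and a 2-fold step), the boundary-location problem has an
information limit: the maximum-likelihood changepoint estimator *with the
true segment means and dispersion known* places both boundaries of a
planted duplication within +-2 bins in only ~87% of replicates (measured
over 4,000 draws of the known-parameter estimator). The package's locator
performs at this oracle level (~90% observed), so any expectation of
+-2-bin accuracy in more than ~90% of noisy replicates at this noise is
not attainable by any method; the acceptance suite asserts the stricter
stated threshold anyway and documents the red outcome rather than
loosening it. The same bound propagates to boundary *identity* between two
independent noisy recoveries of the same event (tolerance 2 bins on both
ends): the oracle agreement rate is ~75%, so near-certain identity
judgments at this noise require either deeper coverage, finer dispersion,
or a wider tolerance.

## Variant recurrence

Per-sample VCFs are decomposed into one record per sample-allele,
multi-allelic sites split, indels parsimony-trimmed so the same event keys
identically across samples. A variant is *recurrent* when carried by three
or more strains ("more than two"). Flags:

* `shared_region_het_artifact` — heterozygous call inside plasmid/genome
  shared sequence. A haploid genome plus a multi-copy plasmid produces
  exactly this signature from mapping ambiguity; het calls *outside* the
  mask are surfaced but not auto-flagged (they stand in for manual
  curation).
* `introduced_allele` — key matches the table of engineered substitutions.
* `backbone_region` — key inside an optional plasmid-backbone annotation
  mask (origins, polylinker).

The unflagged-recurrent list is the screen's positive output; on simulated
cohorts it is exactly the planted truth (empty, unless true recurrent
variants are planted).

## qPCR quantification

Technical triplicates are averaged (a spread over 0.5 cycles raises a QC
flag). Relative quantity is plain delta-delta-Ct with amplification
efficiency fixed at 1 — `2^-((Ct_t - Ct_ref)_sample - (Ct_t -
Ct_ref)_calibrator)` — an efficiency parameter exists but defaults to
perfect doubling, matching how the assay was designed to be analyzed.
Biological replicates (not technical wells) are the exchangeable units:
one plate `sample` is one biological replicate, and the design table maps
samples to strain groups. Group differences use the two-sided Wilcoxon
rank-sum test, exact when both groups have <= 10 untied values, otherwise
the tie- and continuity-corrected normal approximation. The
"adjusted p-value" is Benjamini-Hochberg by default (the family is
whatever vector of p-values the caller assembles — it must be declared,
not guessed); Holm is available where strict family-wise control is
wanted.

## Concordance

WGS and qPCR estimates are paired by strain id; the result is the Pearson
correlation, r^2, and an ordinary least-squares fit with per-strain
residuals. OLS, not an errors-in-variables fit: both axes carry noise and
the slope is therefore attenuated toward zero, but the validation
statistic of interest is the plain correlation of the scatterplot, and
modeling the x-axis error would change the estimand. Strains missing from
either side are listed, never imputed.

# The synthetic-data generator

The generator emulates, with recorded truth: a 16-chromosome yeast-like
haploid genome (true chromosome lengths, ~12.1 Mb) plus an excluded
mitochondrial contig; an 8.5-kb centromeric plasmid whose shared mask
(marker, CEN/ARS, 2.5-kb insert) leaves 3,800 plasmid-specific bases;
whole-chromosome disomies and bin-aligned segmental duplications with
multiplying factors; plasmid copy numbers anywhere in the observed 1-12
range; recurrent heterozygous artifact calls confined to shared sequence;
and qPCR plates whose Ct values encode true quantities under the
perfect-efficiency model.

Stated-world defaults, chosen once: 30x haploid mean depth (a typical
small-genome resequencing depth; the source data's depth is not public),
per-bin negative-binomial dispersion 10 (per-bin CV ~36%, the overdispersed
end of short-read depth noise), 1-kb genome bins, 50-bp plasmid noise bins
(roughly the depth decorrelation scale; gives the plasmid-specific set 76
bootstrap bins), Ct noise 0.1 cycles, triplicate wells, 6 biological
replicates.

Noise is applied **per bin, not per base**, for speed — every downstream
statistic operates on bins, so per-base noise would be integrated out
anyway. Determinism is a first-class switch: `deterministic = TRUE`
disables noise entirely and every expectation is hit exactly, which is
what the exact-recovery tests use.

What the generator does **not** emulate: GC-content and mappability bias,
read-level artifacts (chimeras, duplicates), diploid genotypes, qPCR
efficiency drift, inter-plate effects. A green test therefore establishes
correctness of the *inference machinery* under the stated noise model, not
robustness to every systematic artifact of real sequencing.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; depth-TSV and VCF conversion
  to/from 1-based happens only at the I/O boundary.
* Cumulative-sum variance computation clamps ~1e-12 float residue to zero
  so that noiseless steps register infinite t (exact recovery).
* An all-zero chromosome yields no segment calls with a warning; an
  all-zero plasmid track yields CN 0 with a degenerate CI; a mask covering
  the whole plasmid is an error (the specific set must be non-empty).
* Readers tolerate CRLF, `#` headers and `track` lines; parse errors name
  the offending line.
* Identical seeds reproduce byte-identical outputs; all permutation and
  bootstrap procedures take explicit seeds and record them.

# Known limitations

* The genome-mean bias from including disomic chromosomes is documented
  and absorbed by thresholds, not corrected; genomes that are mostly
  aneuploid would need an iterative (ploidy-aware) mean.
* Boundary accuracy is information-limited as analyzed above; at the
  stated noise, +-2-bin agreement cannot exceed ~90% of replicates.
* The recurrence screen automates only the stated artifact rule
  (heterozygous inside shared homology); other curation rules remain
  manual.
* qPCR quantities assume perfect efficiency; the efficiency-corrected mode
  exists but is off by default and untested against standard curves.
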
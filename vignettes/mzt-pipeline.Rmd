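---
title: "Models and methods behind the mztseq pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mztseq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztseq)
```

`mztseq` packages the computational side of a single-embryo
maternal-to-zygotic transition (MZT) study: read-level filters and
multi-mapping, transposable-element quantification, gene-level
differential expression, wave-catalogue cross-tabulation, and confocal
image quantification. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The experimental setting being modeled

In mouse, the embryonic transcriptome is handed over in waves: maternal
transcripts deposited in the oocyte are degraded while zygotic
transcription starts — a minor wave at the one-cell stage (with a
transient subset), the major wave at the two-cell stage (again with a
transient subset), and mid-preimplantation gene activation (MGA)
afterwards. A maternal-effect mutation can leave maternal-side
transcripts abnormally high while the zygotic-side waves fail — the
signature the pipeline's wave-overlap stage is designed to expose.
Single-embryo RNA-seq libraries are shallow, oligo-dT-primed and noisy,
so the study design modeled here uses 8 control vs 8 mutant embryos at
the two-cell stage (5 per group for oocytes) with 49-bp single-end
reads.

## Read QC, rRNA filtering and multi-mapping

A read is discarded when any of four rules fires, reported in a fixed
order: (1) more than 50% of bases below Phred 5; (2) more than 5% N;
(3) A+T content above 80% (N bases excluded from numerator and
denominator — the simplest reading); (4) a continuous single-base run
of A or of T at least `max(15, ceiling(0.30 * read_length))` long. The
two printed anchors of rule 4 (15 bases, 30%) coincide at 49-bp reads;
the `max` reconciles them for other read lengths.

Ribosomal RNA is removed before repeat mapping: a read is dropped iff
it has a **unique best** ungapped alignment to an rRNA reference with at
most 2 mismatches in the seed. The seed is the first 28 bases — the
classical short-read-aligner default, adopted because nothing in the
protocol being modeled specifies it. Reads matching two rRNA loci
equally well are kept ("unique best" read literally).

The repeat mapper is an exhaustive exact-match scan: every zero-mismatch
occurrence of the read in the genome, both strands, reported up to a cap
of 10,000 locations. Reads above the cap are dropped, not truncated —
truncation would bias the family-concordance test that follows. Reads
are error-free in simulation (divergence between repeat copies is the
only source of mismatches), so zero-mismatch matching loses nothing;
this deliberately isolates the concordance logic under test. Coordinates
are 0-based half-open internally and in BED; SAM output converts to
1-based. Counting is unstranded (strand is recorded but not used),
since the modeled protocol is unstranded.

## Repeat family quantification

A hit is labeled with a repeat family only when its interval is wholly
contained in one annotated repeat. Overlapping annotation intervals are
rejected outright rather than disambiguated — this sidesteps the
ill-posed question of which repeat "owns" a hit that touches two.

A multi-mapped read is assigned to a family iff (a) every one of its
hits carries some family label and (b) the majority family's share
strictly exceeds 0.95. Both choices are deliberate: the assignment rule
speaks of *all* alignments being concordant, so one unlabeled hit
voids the read; and "more than 95%" is a strict inequality, so 19/20
(exactly 95%) is unassigned. Ties for the majority are unassigned
(they could only pass a threshold at or below 50% anyway).

Family counts are normalized to the per-sample total of repeat-assigned
reads, making each sample a composition (fractions summing to 1). The
per-family test is a Welch t-test on `log2(fraction + 1/total)` with BH
adjustment across families and a 0.05 adjusted-p threshold. The
pseudo-count `1/total` is each sample's smallest representable fraction
— scale-aware, and inert for families with counts well above 1. A
moderated linear model would pool variance across families; with a
handful of families and 8 samples per group the plain Welch test is
transparent and, as the permutation-null test shows, calibrated
(measured family-wise false-positive rate ≈ 5% across datasets).

Because the data are compositional, a planted fold change `f` on one
family appears in the normalized table as `f / (1 + s(f-1))` where `s`
is the family's control share. The recovery simulations therefore give
the boosted LINE family a 10% share: the expected recovered ratio for a
planted two-fold increase is 2/1.1 ≈ 1.82, and that is what the
pipeline should (and does) report. This is a property of
total-normalization itself, not an estimator error.

## Gene-level differential expression

Counts `K_ij` are normalized with median-of-ratios size factors,
`s_j = median_i K_ij / (prod_j K_ij)^{1/m}` over genes with positive
geometric mean, computed in log space (identical to the common
Bioconductor estimator; a cross-check test confirms agreement to 1e-8).
Filtering drops all-zero genes, then keeps the top
`ceiling(0.60 * G)` genes by mean normalized count — normalized, not
raw, so the filter is scale-free; ties break by gene id for
determinism.

The test is a simplified negative-binomial Wald test. Per gene, the
dispersion `alpha` in `Var = mu + alpha * mu^2` is estimated by method
of moments from the pooled within-group variance of normalized counts,
then shrunk 50/50 toward a parametric trend `alpha(mu) = a0 + a1/mu`
fitted across genes (coefficients clamped at zero). The effect is
`log2((mean_mut + 0.5)/(mean_ctrl + 0.5))` — the 0.5 keeps zero groups
finite — with a delta-method standard error and a t reference with
`n - 2` degrees of freedom, the standard small-sample choice. The
calibration suite measures type-I error ≈ 0.036 at nominal 0.05 on a
2,000-gene null (8+8 samples, dispersion 0.1) and power 1.0 for 4-fold
effects at mean 100; those two simulations are the test's validation,
not a tuning loop.

Classes combine an inclusive fold threshold with an FDR gate: *up* iff
`log2FC >= 1` and `padj < 0.05`, *down* iff `log2FC <= -1` and
`padj < 0.05`, else *similar*. The figure-legend convention in this
field defines the classes by fold change alone while the accompanying
text quotes an FDR; the conjunction is this package's resolution, and a
gene at `log2FC = -1.2` with `padj = 0.2` is deliberately *similar*.

Clustering uses `d = 1 - Spearman rho` between `log2(normalized + 1)`
profiles with Ward linkage (`ward.D2`, the Ward criterion on
distances); Spearman makes the distances invariant to monotone
per-sample transforms. PCA runs on the same log-transformed matrix,
genes centered. `log2(x + 1)` is a common variance-stabilizing default;
nothing stronger is claimed for it.

A caveat the tests encode explicitly: median-of-ratios needs a majority
of unchanged genes as an anchor. If *every* gene carries a planted
effect (half up, half down), the median ratio lands unstably between
the two blocks and fold changes are absorbed into the size factors.
The generator's default `affected_fraction = 0.5` keeps half of each
wave unchanged for this reason.

## Wave-overlap tables

Each catalogue gene lands in exactly one cell of its category's row:
its DE class, or `not_in_data` when the gene is absent from the
filtered DE result (the zero-count and top-60% filters are the usual
cause — "not in the data" is read as "not classified", the
interpretation that keeps row sums equal to catalogue sizes).
Percentages are `round(100 * cell / total)` with halves away from zero;
this convention reproduces the printed 37/39/38% of the three cleanly
parsed published rows and is applied uniformly (so 1818/3811 prints as
48%).

## Image quantification

Integrated nuclear intensity is the in-mask total divided by the
in-mask voxel count — a mean, computed over all z slices of a stack.
Group fold change is the ratio of group means with a Welch t-test.

Texture uses a gray-level co-occurrence matrix: in-mask intensities
min-max rescaled to 32 levels, distance-1 offsets in the four 2D
directions, pairs accumulated only when both pixels are in the mask,
symmetrized, pooled over offsets and normalized to sum 1. For z-stacks
the GLCM pools per-slice counts; offsets across the anisotropic z axis
are not used. Entropy is `-sum p log2 p` in bits (`0 log 0 = 0`),
bounded by `2 log2(32) = 10`. The 32-level/4-offset/symmetric choices
are the common Haralick defaults; the original analysis scripts in this
field are typically unpublished, so the defaults are stated here and
frozen. Group comparisons report a Shapiro–Wilk normality check per
group at 0.05 alongside the t-test; non-normal data raise a flag but
the test is still reported, leaving the judgement visible rather than
silent. Categorical phenotype proportions use plain Pearson chi-square
without continuity correction.

## The synthetic-data generators

**Counts.** Genes come in six equal wave categories. Baseline means are
log-uniform on [5, 500] — the range a shallow single-embryo library
plausibly spans after filtering — with NB dispersion 0.1, a typical
between-embryo value. A planted genotype effect of +2 log2 units on
maternal-side waves and −2 on zygotic-side waves, on half the genes per
category, emulates the direction (not the magnitude distribution) of a
maternal-factor-mutant transcriptome; the magnitudes are free
parameters of the generator, chosen once as clearly detectable at
8 + 8, not estimates of any real dataset.

**Repeat genomes.** Families of near-identical interspersed copies
(default 3 families × 20 copies × 300 bp in 100 kb, identity 1.0) are
planted in disjoint bins of a random background, plus four random rRNA
decoys standing in for the usual rRNA reference set. Reads are sampled
from copies proportional to family abundance (multinomial — Poisson
depth conditioned on the total, so exactly `n_reads` records are always
emitted and abundance ratios are preserved in expectation), with
optional injected QC failures that modify, never drop, reads. Phred+33
throughout.

**Images.** A disk nucleus on a flat background, Gaussian foci placed
uniformly within 80% of the nuclear radius, additive Gaussian noise.
The mutant's entire in-mask signal is scaled by
`mutant_intensity_ratio`, so the expected ratio of group mean
integrated intensities equals the planted ratio exactly and recovery is
a pure noise question. The planted per-nucleus scale factor travels in
the record metadata so tests never re-derive it.

What the generators do **not** emulate: sequencing errors, splicing,
the 3'-bias of oligo-dT priming, chromatin-domain structure, microscope
point-spread functions, or realistic repeat-family divergence
landscapes. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under its stated model, not that the model
captures every property of real single-embryo data.

## Problem sizes and determinism

The test and acceptance suites run at desk scale, chosen as the
smallest sizes at which the statistical assertions are stable: 2,000
genes for test calibration, 10,000 label sets for the concordance
oracle, 100 kb genomes for mapper equivalence, 16 libraries × 3,000
reads for repeat-fold recovery, 50 image pairs for intensity-ratio
recovery. Every generator is deterministic given its config and seed;
the pipeline derives per-stage seeds from one global seed and
re-running a config byte-identically reproduces all TSV outputs.

## Known limitations

- The multi-mapper is exact-match only; it replaces a seed-and-extend
  aligner for synthetic error-free reads and cannot process real
  mismatched data.
- The NB test is intentionally simpler than full empirical-Bayes
  machinery (no gene-wise shrinkage of fold changes, no outlier
  handling); it is calibrated at the simulated scale but will be less
  powerful than moderated tests at very small n or very high
  dispersion.
- Total-count normalization of repeat families is compositional;
  recovered ratios are systematically attenuated by the boosted
  family's share (quantified above), which is inherent to the method,
  not corrected for.
- Manual categorical scoring of staining strength is not reproduced;
  only threshold-based binning on integrated intensity is exposed.
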
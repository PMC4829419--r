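# mztseq

Desk-scale analysis toolkit for single-embryo studies of the
maternal-to-zygotic transition (MZT) in mouse. When a maternal chromatin
factor is depleted from the oocyte, the wave-like handover from
maternally deposited transcripts to zygotic transcription (minor ZGA at
the one-cell stage, major ZGA at the two-cell stage, MGA afterwards) can
derail; so can the silencing of transposable elements such as LINE-1.
`mztseq` implements the computational pipeline such a study needs, end to
end, against synthetic data with planted ground truth:

- **Read QC and multi-mapping** — the four FASTQ discard rules (more than
  50% of bases under Phred 5; more than 5% N; more than 80% A+T; a
  single-base A or T run covering 30% of the read), a ribosomal-RNA
  pre-filter that removes reads with a *unique best* seed alignment
  (seed = first 28 bases, up to 2 mismatches) to rRNA references, and an
  exhaustive zero-mismatch multi-mapper reporting up to 10,000 genomic
  locations per read on both strands.
- **Transposable-element quantification** — hits are assigned to a repeat
  family only when *fully contained* in an annotated interval; a read
  counts for a family only when *more than 95%* of its alignments agree
  on that family (so 19 of 20 is not enough); family counts are
  normalized by the per-sample total of repeat-assigned reads, and
  per-family differences are tested (Welch t on log2 fractions,
  Benjamini–Hochberg across families).
- **Differential expression** — median-of-ratios size factors
  `s_j = median_i K_ij / (prod_j K_ij)^{1/m}`, a zero-count filter and a
  top-60%-expressed filter, a simplified negative-binomial Wald test
  (variance `mu + alpha*mu^2`, moment dispersions shrunk to a trend), BH
  adjustment, and the three-way class rule: *up* iff `log2FC >= 1` and
  `padj < 0.05`, *down* iff `log2FC <= -1` and `padj < 0.05`, else
  *similar*. Spearman-distance/Ward clustering and PCA of samples, and
  geometric-mean housekeeping normalization for RT-qPCR-style data.
- **Wave-overlap tables** — cross-tabulation of DE classes against a
  six-wave catalogue (maternal, minor ZGA, 1C transient, major ZGA,
  2C transient, MGA), with integer percentages (half away from zero),
  coverage statistics and stage-overlap (Venn) counts.
- **Image quantification** — integrated nuclear intensity (in-mask total
  divided by in-mask voxels), group fold changes with Welch t-tests,
  gray-level co-occurrence matrices (32 levels, distance-1 offsets in 4
  directions, symmetric) with Haralick entropy
  `-sum p(i,j) log2 p(i,j)`, mean-vs-max intensity scatters,
  Shapiro–Wilk-gated group comparisons, and plain Pearson chi-square
  tests for categorical phenotype proportions.
- **Synthetic data generators** — wave-structured NB count matrices,
  repeat genomes with near-identical interspersed copies plus rRNA
  decoys, FASTQ read libraries with injected QC failures, and punctate
  nucleus images with a planted mutant/control intensity ratio.

## Worked example

Simulate a two-cell-embryo experiment (8 control vs 8 mutant embryos,
half the genes in each wave carrying a planted ±2 log2 effect), run the
DE stage and tabulate the classes against the wave catalogue:

```r
library(mztseq)

cfg <- count_sim_config(n_genes_per_category = 50, seed = 111,
                        n_samples_per_group = 8,
                        effect_log2fc_up = 2, effect_log2fc_down = -2,
                        affected_fraction = 0.5)
catalogue <- make_wave_catalogue(cfg)
sim <- simulate_embryo_counts(catalogue, cfg)
de  <- run_de(sim$counts, sim$metadata)
table(de$de_class)
#>      up    down similar
#>      57      35      88
category_percentages(build_overlap_table(de, catalogue))
#>       category pct_up pct_down pct_similar
#> 1     maternal     38        0          28
#> 2    minor_ZGA     42        0          20
#> 3 1C_transient     34        0          40
#> 4    major_ZGA      0       18          32
#> 5 2C_transient      0       28          28
#> 6          MGA      0       24          28
```

Maternal-side waves come out upregulated and zygotic-side waves
downregulated, mirroring the planted direction; genes removed by the
zero-count/top-60% filters land in the `not_in_data` column (not shown).
On the published three cleanly printed wave rows, the same functions
return 37/39/38% upregulated and a minimum category coverage of 96.8%:

```r
tab <- structure(data.frame(
  category = c("maternal", "minor_ZGA", "1C_transient"),
  up = c(360, 540, 34), down = c(63, 47, 4), similar = c(521, 750, 51),
  not_in_data = c(31, 40, 1), total = c(975, 1377, 90)),
  class = c("overlap_table", "data.frame"))
category_percentages(tab)$pct_up   # 37 39 38
coverage_stats(tab)$minimum        # 96.82051
```

A full synthetic run of every stage, with TSV outputs and a JSON report:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "mzt_run")
```

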
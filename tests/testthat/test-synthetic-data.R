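test_that("wave catalogue has the requested size and is deterministic", {
  cfg <- count_sim_config(n_genes_per_category = 10, seed = 4)
  cat10 <- make_wave_catalogue(cfg)
  expect_equal(nrow(cat10), 60)
  expect_equal(unname(table(cat10$category)), rep(10L, 6),
               ignore_attr = TRUE)
  expect_identical(cat10, make_wave_catalogue(cfg))

  cat163 <- make_wave_catalogue(count_sim_config(n_genes_per_category = 163))
  expect_equal(sum(cat163$category == "maternal"), 163)
  expect_error(count_sim_config(n_genes_per_category = 0))
})

test_that("null simulation draws control and mutant from one distribution", {
  cfg <- count_sim_config(n_genes_per_category = 40, effect_log2fc_up = 0,
                          effect_log2fc_down = 0, seed = 9)
  sim <- simulate_embryo_counts(make_wave_catalogue(cfg), cfg)
  expect_true(all(sim$truth$log2fc_true == 0))
  ctrl <- sim$metadata$genotype == "control"
  # group means should not differ systematically
  diffs <- rowMeans(sim$counts[, !ctrl]) - rowMeans(sim$counts[, ctrl])
  expect_lt(abs(mean(diffs / (1 + sim$truth$base_mean))), 0.1)
})

test_that("unaffected gene sample means match configured NB mean", {
  cfg <- count_sim_config(n_genes_per_category = 5, n_samples_per_group = 100,
                          affected_fraction = 0, nb_dispersion = 0.1,
                          seed = 2)
  sim <- simulate_embryo_counts(make_wave_catalogue(cfg), cfg)
  mu <- sim$truth$base_mean
  se <- sqrt((mu + 0.1 * mu^2) / 200)  # NB variance over all 200 samples
  expect_true(all(abs(rowMeans(sim$counts) - mu) < 3 * se + 1e-9))
})

test_that("planted up effects are recovered by the DE stage across seeds", {
  for (seed in 1:3) {
    cfg <- count_sim_config(n_genes_per_category = 40, effect_log2fc_up = 2,
                            effect_log2fc_down = -2, affected_fraction = 0.5,
                            n_samples_per_group = 8, seed = seed)
    sim <- simulate_embryo_counts(make_wave_catalogue(cfg), cfg)
    de <- run_de(sim$counts, sim$metadata)
    truth <- sim$truth[match(de$gene, sim$truth$gene_id), ]
    up_truth <- truth$log2fc_true > 0 & truth$category == "maternal"
    expect_gte(mean(de$de_class[up_truth] == "up"), 0.8)
  }
})

test_that("simulated repeat genome has the declared geometry", {
  cfg <- repeat_genome_config(n_families = 2, copies_per_family = 3,
                              copy_length = 120, genome_length = 5000,
                              intra_family_identity = 1, seed = 5)
  sim <- simulate_repeat_genome(cfg)
  ann <- sim$annotation
  expect_equal(length(ann), 6)
  expect_true(all(GenomicRanges::start(ann) >= 1))
  expect_true(all(GenomicRanges::end(ann) <= 5000))
  expect_equal(length(GenomicRanges::reduce(ann)), 6)  # non-overlapping

  # identity 1: a read taken from one copy occurs at exactly 3 locations,
  # confirmed by an exhaustive sliding-window scan
  genome <- as.character(sim$genome[["chr1"]])
  fam <- S4Vectors::mcols(ann)$family
  first <- which(fam == fam[1])[1]
  read <- substring(genome, GenomicRanges::start(ann)[first],
                    GenomicRanges::start(ann)[first] + 49)
  hits <- oracle_scan(read, genome)
  expect_equal(nrow(hits), 3)

  expect_error(repeat_genome_config(n_families = 10, copies_per_family = 10,
                                    copy_length = 200, genome_length = 5000),
               "overlap")
})

test_that("copies diverge from the consensus within the identity bound", {
  cfg <- repeat_genome_config(n_families = 2, copies_per_family = 4,
                              copy_length = 200, genome_length = 10000,
                              intra_family_identity = 0.95, seed = 8)
  sim <- simulate_repeat_genome(cfg)
  genome <- as.character(sim$genome[["chr1"]])
  ann <- sim$annotation
  max_subs <- floor(0.05 * 200)
  for (i in seq_along(ann)) {
    copy <- substring(genome, GenomicRanges::start(ann)[i],
                      GenomicRanges::end(ann)[i])
    cons <- as.character(sim$consensus[[S4Vectors::mcols(ann)$family[i]]])
    diff <- sum(strsplit(copy, "")[[1]] != strsplit(cons, "")[[1]])
    expect_lte(diff, max_subs)
  }
})

test_that("simulated reads conserve count and honour abundances and noise", {
  cfg <- repeat_genome_config(seed = 3, genome_length = 30000,
                              copies_per_family = 10, copy_length = 200)
  sim <- simulate_repeat_genome(cfg)
  fams <- sim$family_class$family
  ab <- setNames(c(1, 2, 1), fams)

  reads <- simulate_reads(sim, ab, n_reads = 800, seed = 1)
  expect_equal(nrow(reads), 800)
  qc <- qc_filter(reads)
  expect_true(all(qc$keep))  # zero noise: everything passes QC

  # doubling one family's abundance doubles its expected read share
  tab <- table(reads$source_family)
  expect_equal(unname(tab[fams[2]] / tab[fams[1]]), 2, tolerance = 0.25)

  # determinism
  reads2 <- simulate_reads(sim, ab, n_reads = 800, seed = 1)
  expect_identical(reads, reads2)

  expect_error(simulate_reads(sim, ab, read_length = 500),
               "transcript length")
  expect_error(simulate_reads(sim, setNames(c(0, 0, 0), fams)))
})

test_that("injected poly-A reads are discarded at the configured rate", {
  cfg <- repeat_genome_config(seed = 3, genome_length = 30000,
                              copies_per_family = 10, copy_length = 200)
  sim <- simulate_repeat_genome(cfg)
  ab <- setNames(c(1, 1, 1), sim$family_class$family)
  n <- 10000
  reads <- simulate_reads(sim, ab, n_reads = n,
                          qc_noise = list(p_polya = 0.2), seed = 6)
  qc <- qc_filter(reads)
  frac <- mean(!qc$keep)
  ci <- 3 * sqrt(0.2 * 0.8 / n)
  expect_gt(frac, 0.2 - ci - 0.01)
  expect_lt(frac, 0.2 + ci + 0.01)
  expect_true(all(qc$reason[!qc$keep] == "homopolymer"))
})

test_that("nucleus image simulation is deterministic with planted truth", {
  cfg <- image_sim_config(n_nuclei = 3, mutant_intensity_ratio = 2.2,
                          seed = 12)
  nuc <- simulate_nucleus_images(cfg)
  expect_length(nuc, 6)
  scales <- vapply(nuc, `[[`, numeric(1), "scale")
  genos <- vapply(nuc, `[[`, character(1), "genotype")
  expect_equal(scales[genos == "mutant"], rep(2.2, 3))
  expect_equal(scales[genos == "control"], rep(1, 3))
  nuc2 <- simulate_nucleus_images(cfg)
  expect_identical(nuc[[1]]$image, nuc2[[1]]$image)
})

test_that("unit intensity ratio gives equal group means within noise", {
  cfg <- image_sim_config(n_nuclei = 30, mutant_intensity_ratio = 1,
                          noise_sd = 5, seed = 13)
  nuc <- simulate_nucleus_images(cfg)
  genos <- vapply(nuc, `[[`, character(1), "genotype")
  ii <- vapply(nuc, function(r) integrated_intensity(r$image, r$mask),
               numeric(1))
  fc <- group_fold_change(ii[genos == "mutant"], ii[genos == "control"])
  expect_equal(fc$ratio, 1, tolerance = 0.05)
  expect_gt(fc$p, 0.01)
})

test_that("focus-free images have background-like texture entropy", {
  mk <- function(nf, seed) {
    cfg <- image_sim_config(n_nuclei = 8, n_foci = nf,
                            mutant_intensity_ratio = 1, noise_sd = 5,
                            seed = seed)
    nuc <- simulate_nucleus_images(cfg)
    genos <- vapply(nuc, `[[`, character(1), "genotype")
    vapply(nuc[genos == "control"], function(r)
      haralick_entropy(compute_glcm(r$image, r$mask)), numeric(1))
  }
  e_none <- mk(0, 31)
  # background-only reference: noise-only texture entropy
  e_bg <- mk(0, 32)
  e_foci <- mk(12, 33)
  expect_equal(mean(e_none), mean(e_bg), tolerance = 0.05)
  # punctate signal makes texture less noise-like than pure background
  expect_gt(abs(mean(e_foci) - mean(e_bg)), 3 * stats::sd(e_bg))
})
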
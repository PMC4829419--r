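#' Full pipeline configuration
#'
#' One object tying together the per-stage configurations and a single
#' global seed; stage-specific seeds are derived deterministically from
#' it. Can be built programmatically or loaded from YAML with
#' [read_pipeline_config()].
#'
#' @param seed global integer seed.
#' @param stages character subset of `c("counts", "repeats", "images")`.
#' @param count_sim a [count_sim_config()] (its `seed` is overridden).
#' @param de a [de_config()].
#' @param repeat_genome a [repeat_genome_config()].
#' @param qc a [qc_config()].
#' @param map a [map_config()] (rRNA references are filled in from the
#'   simulated genome).
#' @param repeats a [repeat_config()].
#' @param family_abundances named control-group family abundances; when
#'   `NULL`, sensible defaults over the simulated families are used.
#' @param repeat_fold named per-family mutant fold changes (default: first
#'   LINE family doubled).
#' @param n_reads_per_library reads simulated per repeat library.
#' @param n_repeat_libraries samples per genotype for the repeat stage.
#' @param image_sim an [image_sim_config()] (its `seed` is overridden).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("counts", "repeats", "images"),
                            count_sim = count_sim_config(),
                            de = de_config(),
                            repeat_genome = repeat_genome_config(),
                            qc = qc_config(),
                            map = map_config(),
                            repeats = repeat_config(),
                            family_abundances = NULL,
                            repeat_fold = NULL,
                            n_reads_per_library = 4000L,
                            n_repeat_libraries = 8L,
                            image_sim = image_sim_config()) {
  structure(list(seed = as.integer(seed), stages = stages,
                 count_sim = count_sim, de = de,
                 repeat_genome = repeat_genome, qc = qc, map = map,
                 repeats = repeats,
                 family_abundances = family_abundances,
                 repeat_fold = repeat_fold,
                 n_reads_per_library = as.integer(n_reads_per_library),
                 n_repeat_libraries = as.integer(n_repeat_libraries),
                 image_sim = image_sim),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems; empty iff the configuration is
#'   runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (!inherits(config, "pipeline_config")) {
    return("not a pipeline_config object")
  }
  bad <- setdiff(config$stages, c("counts", "repeats", "images"))
  if (length(bad)) add(paste("unknown stage:", paste(bad, collapse = ", ")))
  cs <- config$count_sim
  if (cs$n_samples_per_group < 2) add("need >= 2 samples per group")
  if (cs$nb_dispersion <= 0) add("nb_dispersion must be positive")
  if (cs$affected_fraction < 0 || cs$affected_fraction > 1)
    add("affected_fraction must lie in [0, 1]")
  if (config$de$alpha <= 0 || config$de$alpha >= 1)
    add("DE alpha must lie in (0, 1)")
  ct <- config$repeats$concordance_threshold
  if (ct <= 0 || ct > 1) add("concordance_threshold must lie in (0, 1]")
  if (config$n_reads_per_library < 1) add("n_reads_per_library must be >= 1")
  if (config$n_repeat_libraries < 2)
    add("need >= 2 repeat libraries per genotype")
  if (config$image_sim$mutant_intensity_ratio <= 0)
    add("mutant_intensity_ratio must be > 0")
  problems
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; per-stage
#' keys are passed to the corresponding `*_config()` constructor, so every
#' value is validated on load.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$stages)) args$stages <- y$stages
  ctor <- list(count_sim = count_sim_config, de = de_config,
               repeat_genome = repeat_genome_config, qc = qc_config,
               map = map_config, repeats = repeat_config,
               image_sim = image_sim_config)
  for (key in names(ctor))
    if (!is.null(y[[key]])) args[[key]] <- do.call(ctor[[key]], y[[key]])
  for (key in c("family_abundances", "repeat_fold", "n_reads_per_library",
                "n_repeat_libraries"))
    if (!is.null(y[[key]])) args[[key]] <- unlist(y[[key]])
  do.call(pipeline_config, args)
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + offset * 104729L) %% 2147483629L
}

run_counts_stage <- function(config, out_dir) {
  cs <- config$count_sim
  cs$seed <- derive_seed(config$seed, 1L)
  catalogue <- make_wave_catalogue(cs)
  sim <- simulate_embryo_counts(catalogue, cs)
  de <- run_de(sim$counts, sim$metadata, config$de)
  overlap <- build_overlap_table(de, catalogue)
  clust <- cluster_samples(filter_genes(sim$counts, config$de))
  pca <- pca_samples(filter_genes(sim$counts, config$de))

  write_counts(sim, file.path(out_dir, "counts.tsv"),
               file.path(out_dir, "samples.tsv"))
  write_catalogue(catalogue, file.path(out_dir, "wave_catalogue.tsv"))
  write.table(as.data.frame(de), file.path(out_dir, "de_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_overlap_table(overlap, file.path(out_dir, "wave_overlap.tsv"))
  write_tree_newick(clust$tree, file.path(out_dir, "sample_tree.nwk"))
  write.table(data.frame(sample_id = rownames(pca$coordinates),
                         pca$coordinates[, 1:min(4, ncol(pca$coordinates))]),
              file.path(out_dir, "pca_coordinates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  geno <- setNames(sim$metadata$genotype, sim$metadata$sample_id)
  split_ok <- length(unique(clust$labels[geno == "control"])) == 1 &&
    length(unique(clust$labels[geno == "mutant"])) == 1 &&
    clust$labels[which(geno == "control")[1]] !=
    clust$labels[which(geno == "mutant")[1]]
  list(de_class_counts = as.list(table(de$de_class)),
       genes_tested = nrow(de),
       overlap_percentages = category_percentages(overlap),
       coverage_minimum = coverage_stats(overlap)$minimum,
       cluster_split_matches_genotype = split_ok)
}

run_repeats_stage <- function(config, out_dir) {
  rg <- config$repeat_genome
  rg$seed <- derive_seed(config$seed, 2L)
  sim <- simulate_repeat_genome(rg)
  fams <- sim$family_class$family
  ab <- config$family_abundances
  if (is.null(ab)) {
    # LINE family a modest share so the compositional distortion of the
    # planted fold stays small
    ab <- setNames(rep(1, length(fams)), fams)
    line_fams <- fams[sim$family_class$class == "LINE"]
    if (length(line_fams)) ab[line_fams] <- 0.25
    ab <- ab / sum(ab)
  }
  fold <- config$repeat_fold
  if (is.null(fold)) {
    fold <- setNames(rep(1, length(fams)), fams)
    line_fams <- fams[sim$family_class$class == "LINE"]
    if (length(line_fams)) fold[line_fams[1]] <- 2
  }
  map_cfg <- config$map
  map_cfg$rrna_references <- sim$rrna

  n_lib <- config$n_repeat_libraries
  records <- list()
  tallies <- list()
  lib_id <- 0L
  genotype <- character(0)
  for (geno in c("control", "mutant")) {
    for (i in seq_len(n_lib)) {
      lib_id <- lib_id + 1L
      ab_lib <- if (geno == "mutant") ab * fold[names(ab)] else ab
      reads <- simulate_reads(sim, ab_lib,
                              n_reads = config$n_reads_per_library,
                              rrna_fraction = 0.02,
                              qc_noise = list(p_polya = 0.02),
                              seed = derive_seed(config$seed, 10L + lib_id))
      qc <- qc_filter(reads, config$qc)
      kept <- qc[qc$keep, , drop = FALSE]
      rr <- filter_rrna(kept, map_cfg)
      mm <- map_multi(rr$kept, sim$genome, map_cfg)
      name <- sprintf("%s_%02d", substr(geno, 1, 4), i)
      records[[name]] <- mm$alignments
      genotype <- c(genotype, geno)
      tallies[[name]] <- c(input = nrow(reads),
                           qc_discarded = sum(!qc$keep),
                           rrna_discarded = rr$n_discarded,
                           mm$tally)
    }
  }
  table <- build_count_table(records, sim$annotation, config$repeats)
  comp <- class_composition(table)
  tests <- test_families(table, genotype, config$repeats)

  write_repeat_annotation(sim$annotation, file.path(out_dir, "repeats.bed"),
                          file.path(out_dir, "repeat_classes.tsv"))
  write_repeat_table(table, file.path(out_dir, "repeat_counts.tsv"), tests)
  tally_df <- cbind(sample = names(tallies),
                    as.data.frame(do.call(rbind, tallies)))
  write.table(tally_df, file.path(out_dir, "read_tallies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # conservation check: every input read is accounted for
  stopifnot(all(tally_df$input == tally_df$qc_discarded +
                  tally_df$rrna_discarded + tally_df$mapped +
                  tally_df$unmapped + tally_df$over_cap))

  list(families_tested = nrow(tests),
       significant_families = tests$family[tests$significant],
       class_composition_control =
         as.list(rowMeans(comp[, genotype == "control", drop = FALSE])),
       read_tallies = tally_df)
}

run_images_stage <- function(config, out_dir) {
  im <- config$image_sim
  im$seed <- derive_seed(config$seed, 3L)
  nuclei <- simulate_nucleus_images(im)
  geno <- vapply(nuclei, `[[`, character(1), "genotype")
  ii <- vapply(nuclei, function(r) integrated_intensity(r$image, r$mask),
               numeric(1))
  fc <- group_fold_change(ii[geno == "mutant"], ii[geno == "control"])
  scatter <- intensity_scatter(nuclei)
  entropy <- vapply(nuclei, function(r)
    haralick_entropy(compute_glcm(r$image, r$mask)), numeric(1))
  cmp <- compare_groups(entropy[geno == "mutant"],
                        entropy[geno == "control"])
  per_nucleus <- cbind(scatter, integrated_intensity = ii,
                       entropy = entropy)
  write.table(per_nucleus, file.path(out_dir, "image_quant.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(intensity_ratio = fc$ratio, intensity_p = fc$p,
       planted_ratio = im$mutant_intensity_ratio,
       entropy_t_p = cmp$p, entropy_normality_flag = cmp$normality_flag)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the enabled stages — count simulation with differential
#' expression and wave overlap; repeat-genome simulation with read QC,
#' rRNA filtering, multi-mapping and family testing; nucleus-image
#' simulation with intensity and texture quantification — writing
#' per-stage TSV outputs and a JSON report of every numeric decision
#' (seed, thresholds, tallies, headline statistics) to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 stages = config$stages,
                 parameters = list(
                   de_alpha = config$de$alpha,
                   log2fc_thresholds = c(config$de$log2fc_down,
                                         config$de$log2fc_up),
                   top_expressed_fraction = config$de$top_expressed_fraction,
                   concordance_threshold = config$repeats$concordance_threshold,
                   repeat_alpha = config$repeats$alpha,
                   max_locations = config$map$max_locations,
                   rrna_seed_mismatch_limit = config$map$rrna_seed_mismatch_limit))
  for (stage in config$stages) {
    report[[stage]] <- switch(stage,
      counts = run_counts_stage(config, out_dir),
      repeats = run_repeats_stage(config, out_dir),
      images = run_images_stage(config, out_dir))
  }
  if (!is.null(report$repeats)) report$repeats$read_tallies <- NULL
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
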
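#' Configuration for the single-embryo count simulation
#'
#' Defaults reflect the study design this generator emulates: single-embryo
#' libraries at the two-cell stage with 8 control and 8 mutant samples,
#' negative-binomial counts, and a planted genotype effect whose direction
#' depends on the transcription wave — maternal-side waves (maternal, minor
#' ZGA, 1C transient) go up in the mutant, zygotic-side waves (major ZGA,
#' 2C transient, MGA) go down.
#'
#' @param n_genes_per_category genes simulated per wave category.
#' @param n_samples_per_group embryos per genotype group (>= 2).
#' @param nb_mean_range length-2 positive range; baseline means are drawn
#'   log-uniformly from it.
#' @param nb_dispersion negative-binomial dispersion alpha, so that
#'   `Var = mu + alpha * mu^2`.
#' @param effect_log2fc_up planted mutant log2 fold change for maternal-side
#'   waves.
#' @param effect_log2fc_down planted mutant log2 fold change for
#'   zygotic-side waves (conventionally negative).
#' @param affected_fraction fraction of genes per category carrying the
#'   planted effect.
#' @param seed integer seed making the simulation reproducible.
#' @return an object of class `count_sim_config` (a validated list).
#' @export
count_sim_config <- function(n_genes_per_category = 200L,
                             n_samples_per_group = 8L,
                             nb_mean_range = c(5, 500),
                             nb_dispersion = 0.1,
                             effect_log2fc_up = 2,
                             effect_log2fc_down = -2,
                             affected_fraction = 0.5,
                             seed = 1L) {
  stopifnot(length(n_genes_per_category) == 1, n_genes_per_category >= 1)
  stopifnot(length(n_samples_per_group) == 1, n_samples_per_group >= 2)
  stopifnot(length(nb_mean_range) == 2, all(nb_mean_range > 0),
            nb_mean_range[1] <= nb_mean_range[2])
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop("nb_dispersion must be a positive real")
  if (affected_fraction < 0 || affected_fraction > 1)
    stop("affected_fraction must lie in [0, 1]")
  structure(list(n_genes_per_category = as.integer(n_genes_per_category),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 nb_mean_range = as.numeric(nb_mean_range),
                 nb_dispersion = as.numeric(nb_dispersion),
                 effect_log2fc_up = as.numeric(effect_log2fc_up),
                 effect_log2fc_down = as.numeric(effect_log2fc_down),
                 affected_fraction = as.numeric(affected_fraction),
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Build a wave catalogue with equal category sizes
#'
#' Generates a gene -> transcription-wave catalogue covering the six waves
#' of the maternal-to-zygotic transition (maternal, minor ZGA, 1C transient,
#' major ZGA, 2C transient, MGA), `n_genes_per_category` genes each.
#'
#' @param config a [count_sim_config()].
#' @return a `wave_catalogue`: data.frame with columns `gene_id`,
#'   `category` (factor over the six waves).
#' @export
#' @examples
#' cat6 <- make_wave_catalogue(count_sim_config(n_genes_per_category = 10))
#' table(cat6$category)
make_wave_catalogue <- function(config) {
  if (!inherits(config, "count_sim_config"))
    config <- do.call(count_sim_config, config)
  n <- config$n_genes_per_category
  if (n < 1) stop("n_genes_per_category must be >= 1")
  ids <- unlist(lapply(WAVE_CATEGORIES, function(cat)
    sprintf("gene_%s_%04d", cat, seq_len(n))))
  out <- data.frame(gene_id = ids,
                    category = factor(rep(WAVE_CATEGORIES, each = n),
                                      levels = WAVE_CATEGORIES),
                    stringsAsFactors = FALSE)
  class(out) <- c("wave_catalogue", "data.frame")
  validate_wave_catalogue(out)
}

validate_wave_catalogue <- function(cat) {
  if (anyDuplicated(cat$gene_id))
    stop("duplicate gene_id in wave catalogue")
  if (!all(as.character(cat$category) %in% WAVE_CATEGORIES))
    stop("unknown wave category label")
  cat
}

#' Simulate single-embryo RNA-seq counts with planted wave effects
#'
#' Draws per-gene negative-binomial counts (`Var = mu + alpha * mu^2`) for
#' control and mutant embryos. An `affected_fraction` of genes in each wave
#' category carries a genotype effect on the mutant mean: maternal-side
#' waves shift by `effect_log2fc_up`, zygotic-side waves by
#' `effect_log2fc_down`. The planted truth is returned alongside the counts
#' so recovery can be asserted without re-deriving it.
#'
#' @param catalogue a `wave_catalogue` from [make_wave_catalogue()].
#' @param config a [count_sim_config()].
#' @param stage embryonic stage recorded in the sample metadata.
#' @return list of class `embryo_sim` with elements `counts` (gene x sample
#'   integer matrix), `metadata` (sample_id, genotype, stage), and `truth`
#'   (gene_id, category, base_mean, affected, log2fc_true).
#' @export
simulate_embryo_counts <- function(catalogue, config,
                                   stage = c("two_cell", "oocyte")) {
  stage <- match.arg(stage)
  validate_wave_catalogue(catalogue)
  if (nrow(catalogue) == 0) stop("empty wave catalogue")
  set.seed(config$seed)
  g <- nrow(catalogue)
  n <- config$n_samples_per_group
  mu <- exp(runif(g, log(config$nb_mean_range[1]),
                  log(config$nb_mean_range[2])))
  affected <- runif(g) < config$affected_fraction
  lfc <- ifelse(as.character(catalogue$category) %in% WAVES_UP,
                config$effect_log2fc_up, config$effect_log2fc_down)
  lfc[!affected] <- 0
  mu_mut <- mu * 2^lfc
  size <- 1 / config$nb_dispersion
  counts_ctrl <- matrix(rnbinom(g * n, mu = rep(mu, n), size = size), g, n)
  counts_mut <- matrix(rnbinom(g * n, mu = rep(mu_mut, n), size = size), g, n)
  counts <- cbind(counts_ctrl, counts_mut)
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(n)),
                  sprintf("mut_%02d", seq_len(n)))
  dimnames(counts) <- list(catalogue$gene_id, sample_ids)
  metadata <- data.frame(sample_id = sample_ids,
                         genotype = rep(c("control", "mutant"), each = n),
                         stage = stage,
                         stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = catalogue$gene_id,
                      category = catalogue$category,
                      base_mean = mu,
                      affected = affected,
                      log2fc_true = lfc,
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, metadata = metadata, truth = truth),
            class = "embryo_sim")
}

#' Write / read a wave catalogue as TSV
#'
#' @param catalogue a `wave_catalogue`.
#' @param path file path.
#' @return `write_catalogue` returns `path` invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  write.table(as.data.frame(catalogue)[, c("gene_id", "category")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix and its sample metadata as TSV
#'
#' @param sim an `embryo_sim`, or a list with `counts` and `metadata`.
#' @param counts_path,metadata_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(sim, counts_path, metadata_path) {
  df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' Read a gene x sample count matrix and sample metadata from TSV
#'
#' @param counts_path TSV with a `gene_id` column then one column per sample.
#' @param metadata_path TSV with columns `sample_id`, `genotype`, `stage`.
#' @return list with `counts` (integer matrix) and `metadata` (data.frame).
#' @export
read_counts <- function(counts_path, metadata_path) {
  df <- read.delim(counts_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  metadata <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(colnames(counts) %in% metadata$sample_id))
    stop("metadata is missing samples present in the count matrix")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  list(counts = counts, metadata = metadata)
}
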
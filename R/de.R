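#' Differential expression configuration
#'
#' @param alpha adjusted-p threshold below which a gene passes the FDR
#'   gate.
#' @param log2fc_up inclusive upper log2 fold-change threshold for the
#'   "up" class.
#' @param log2fc_down inclusive lower threshold for "down".
#' @param top_expressed_fraction fraction of (non-all-zero) genes kept by
#'   expression rank before testing.
#' @return an object of class `de_config`.
#' @export
de_config <- function(alpha = 0.05, log2fc_up = 1, log2fc_down = -1,
                      top_expressed_fraction = 0.60) {
  if (!(log2fc_down < 0 && 0 < log2fc_up))
    stop("need log2fc_down < 0 < log2fc_up")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (top_expressed_fraction <= 0 || top_expressed_fraction > 1)
    stop("top_expressed_fraction must lie in (0, 1]")
  structure(list(alpha = alpha, log2fc_up = log2fc_up,
                 log2fc_down = log2fc_down,
                 top_expressed_fraction = top_expressed_fraction),
            class = "de_config")
}

#' Median-of-ratios size factors
#'
#' For sample j, `s_j = median_i K_ij / (prod_j K_ij)^(1/m)`, the median
#' taken over genes whose geometric mean across samples is positive.
#'
#' @param counts gene x sample non-negative integer matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
#' @examples
#' k <- matrix(c(10, 20, 20, 40), 2, dimnames = list(NULL, c("a", "b")))
#' size_factors(k)  # second factor is twice the first
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene has positive counts in all samples")
  sf <- apply(counts, 2, function(k)
    exp(median((log(k) - log_geo)[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor; check for samples with too many zeros")
  sf
}

#' Remove all-zero genes and keep the top expressed fraction
#'
#' All-zero genes are dropped first; the remaining genes are ranked by
#' mean size-factor-normalized count (ties broken by gene id), and the
#' top `ceiling(fraction * G)` are retained.
#'
#' @param counts gene x sample count matrix with row names.
#' @param config a [de_config()].
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, config = de_config()) {
  counts <- as.matrix(counts)
  nz <- rowSums(counts) > 0
  if (!any(nz)) stop("all genes have zero counts")
  counts <- counts[nz, , drop = FALSE]
  sf <- size_factors(counts)
  means <- rowMeans(sweep(counts, 2, sf, "/"))
  ord <- order(-means, rownames(counts))
  n_keep <- ceiling(config$top_expressed_fraction * nrow(counts))
  keep <- sort(ord[seq_len(n_keep)])
  counts[keep, , drop = FALSE]
}

# Parametric mean-dispersion trend alpha(mu) = a0 + a1/mu fitted to
# method-of-moments estimates; coefficients clamped at zero.
fit_dispersion_trend <- function(mu, alpha_mom) {
  use <- alpha_mom > 0 & mu > 0
  if (sum(use) < 10) return(function(m) rep(max(mean(alpha_mom), 1e-8),
                                            length(m)))
  fit <- tryCatch(lm(alpha_mom[use] ~ I(1 / mu[use])), error = function(e) NULL)
  if (is.null(fit)) return(function(m) rep(max(mean(alpha_mom), 1e-8),
                                           length(m)))
  a0 <- max(coef(fit)[1], 0)
  a1 <- max(coef(fit)[2], 0)
  function(m) a0 + a1 / pmax(m, 1e-8)
}

#' Simplified negative-binomial Wald test
#'
#' Counts are normalized by median-of-ratios size factors; per-gene
#' dispersions are method-of-moments estimates shrunk 50/50 toward a
#' parametric mean-dispersion trend `alpha(mu) = a0 + a1/mu`. The Wald
#' statistic tests `log2((mean_mut + 0.5) / (mean_ctrl + 0.5))` against
#' zero with a delta-method standard error from the NB variance
#' `mu + alpha * mu^2`, referred to a t distribution with `n - 2` degrees
#' of freedom.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors from [size_factors()] (computed if `NULL`).
#' @param genotype character vector over samples, "control" / "mutant".
#' @return data.frame: gene, base_mean, log2fc (mutant vs control), p.
#' @export
nb_test <- function(counts, genotype, sf = NULL) {
  counts <- as.matrix(counts)
  genotype <- as.character(genotype)
  stopifnot(length(genotype) == ncol(counts))
  if (!all(genotype %in% c("control", "mutant")))
    stop("genotype must be 'control' or 'mutant'")
  n_ctrl <- sum(genotype == "control"); n_mut <- sum(genotype == "mutant")
  if (n_ctrl < 2 || n_mut < 2) stop("need >= 2 samples per genotype")
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  ctrl <- genotype == "control"

  base_mean <- rowMeans(q)
  mu_c <- rowMeans(q[, ctrl, drop = FALSE])
  mu_m <- rowMeans(q[, !ctrl, drop = FALSE])

  # pooled within-group variance of normalized counts
  ss <- rowSums((q[, ctrl, drop = FALSE] - mu_c)^2) +
    rowSums((q[, !ctrl, drop = FALSE] - mu_m)^2)
  v_within <- ss / (n_ctrl + n_mut - 2)
  # E Var(K/s) = mu * mean(1/s) + alpha * mu^2 under NB on the raw scale
  xi <- mean(1 / sf)
  alpha_mom <- pmax((v_within - xi * base_mean) / base_mean^2, 0)
  trend <- fit_dispersion_trend(base_mean, alpha_mom)
  alpha <- pmax(0.5 * alpha_mom + 0.5 * trend(base_mean), 1e-8)

  var_mean <- function(mu, idx, n) {
    mu <- pmax(mu, 1e-8)
    (mu * sum(1 / sf[idx]) + n * alpha * mu^2) / n^2
  }
  v_c <- var_mean(mu_c, which(ctrl), n_ctrl)
  v_m <- var_mean(mu_m, which(!ctrl), n_mut)

  lfc <- log2((mu_m + 0.5) / (mu_c + 0.5))
  se2 <- v_c / ((mu_c + 0.5) * log(2))^2 + v_m / ((mu_m + 0.5) * log(2))^2
  stat <- lfc / sqrt(se2)
  p <- 2 * pt(-abs(stat), df = n_ctrl + n_mut - 2)
  p[lfc == 0] <- 1
  data.frame(gene = rownames(counts), base_mean = base_mean,
             log2fc = lfc, p = pmin(p, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (a thin wrapper over [stats::p.adjust()] kept as
#' the pipeline's single adjustment point).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values, elementwise >= `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify genes as up / down / similar
#'
#' `up` iff `log2fc >= log2fc_up` and `padj < alpha`; `down` iff
#' `log2fc <= log2fc_down` and `padj < alpha`; everything else (including
#' genes failing the FDR gate at any fold change) is `similar`. The
#' partition is exhaustive and exclusive.
#'
#' @param log2fc,padj numeric vectors.
#' @param config a [de_config()].
#' @return factor with levels up, down, similar.
#' @export
classify_de <- function(log2fc, padj, config = de_config()) {
  stopifnot(length(log2fc) == length(padj))
  cls <- rep("similar", length(log2fc))
  sig <- padj < config$alpha
  cls[sig & log2fc >= config$log2fc_up] <- "up"
  cls[sig & log2fc <= config$log2fc_down] <- "down"
  factor(cls, levels = c("up", "down", "similar"))
}

#' Full gene-level differential expression
#'
#' Convenience wrapper chaining [filter_genes()], [size_factors()],
#' [nb_test()], [bh_adjust()] and [classify_de()].
#'
#' @param counts gene x sample count matrix.
#' @param metadata data.frame with `sample_id` and `genotype` matching the
#'   columns of `counts`.
#' @param config a [de_config()].
#' @return object of class `de_result`: data.frame gene, base_mean,
#'   log2fc, p, padj, de_class.
#' @export
run_de <- function(counts, metadata, config = de_config()) {
  stopifnot(all(colnames(counts) %in% metadata$sample_id))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  filtered <- filter_genes(counts, config)
  res <- nb_test(filtered, metadata$genotype)
  res$padj <- bh_adjust(res$p)
  res$de_class <- classify_de(res$log2fc, res$padj, config)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Hierarchical clustering of samples on Spearman correlation distance
#'
#' Samples are clustered on `d = 1 - Spearman rho` between
#' `log2(normalized count + 1)` profiles with Ward linkage, and cut into
#' two flat clusters.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors (computed if `NULL`).
#' @return list with `tree` (an [stats::hclust]) and `labels` (named
#'   2-cluster assignment).
#' @export
cluster_samples <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3) stop("need >= 3 samples to cluster")
  if (is.null(sf)) sf <- size_factors(counts)
  x <- log2(sweep(counts, 2, sf, "/") + 1)
  rho <- cor(x, method = "spearman")
  d <- stats::as.dist(1 - rho)
  tree <- hclust(d, method = "ward.D2")
  list(tree = tree, labels = cutree(tree, k = 2))
}

#' Export an hclust tree as Newick
#'
#' @param tree an [stats::hclust].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Principal component analysis of sample expression profiles
#'
#' PCA of `log2(normalized count + 1)`, genes centered; returns per-sample
#' coordinates and the fraction of variance explained per component.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors (computed if `NULL`).
#' @return list with `coordinates` (sample x PC matrix) and
#'   `variance_explained` (non-increasing fractions summing to <= 1).
#' @export
pca_samples <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3) stop("need >= 3 samples for PCA")
  if (is.null(sf)) sf <- size_factors(counts)
  x <- log2(sweep(counts, 2, sf, "/") + 1)
  pr <- prcomp(t(x), center = TRUE, scale. = FALSE)
  list(coordinates = pr$x,
       variance_explained = pr$sdev^2 / sum(pr$sdev^2))
}

#' Normalize expression to housekeeping genes
#'
#' Divides each sample's values by the per-sample geometric mean of the
#' housekeeping genes (e.g. Hprt, Gapdh, Ppia), the standard RT-qPCR
#' normalization; any per-sample scale factor cancels exactly.
#'
#' @param expression gene x sample positive numeric matrix.
#' @param housekeeping_ids row names of the housekeeping genes.
#' @return matrix of the same shape, housekeeping-normalized.
#' @export
normalize_to_housekeeping <- function(expression, housekeeping_ids) {
  expression <- as.matrix(expression)
  if (!all(housekeeping_ids %in% rownames(expression)))
    stop("housekeeping genes missing from expression matrix")
  hk <- expression[housekeeping_ids, , drop = FALSE]
  if (any(hk <= 0)) stop("housekeeping values must be positive")
  geo <- exp(colMeans(log(hk)))
  sweep(expression, 2, geo, "/")
}
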
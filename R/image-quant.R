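#' Integrated nuclear intensity
#'
#' Total in-mask fluorescence divided by the number of in-mask voxels —
#' i.e. the mean intensity over the nuclear area, computed over all z
#' slices for a stack.
#'
#' @param image numeric 2D/3D array.
#' @param mask logical array of the same shape; must select at least one
#'   voxel.
#' @return a single numeric value (arbitrary units per voxel).
#' @export
integrated_intensity <- function(image, mask) {
  stopifnot(identical(dim(image), dim(mask)))
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  sum(image[mask]) / n
}

#' Group fold change of a per-nucleus statistic
#'
#' Ratio of group means (mutant over control) with a two-sided Welch
#' t-test on the raw values. Degenerate zero-variance identical groups
#' yield p = 1.
#'
#' @param values_mutant,values_control numeric vectors, >= 2 values each.
#' @return list with `ratio`, `t`, `p`.
#' @export
group_fold_change <- function(values_mutant, values_control) {
  stopifnot(length(values_mutant) >= 2, length(values_control) >= 2)
  ratio <- mean(values_mutant) / mean(values_control)
  if (var(values_mutant) + var(values_control) == 0) {
    eq <- isTRUE(all.equal(mean(values_mutant), mean(values_control)))
    return(list(ratio = ratio, t = 0, p = if (eq) 1 else 0))
  }
  tt <- t.test(values_mutant, values_control)
  list(ratio = ratio, t = unname(tt$statistic), p = tt$p.value)
}

quantize_levels <- function(values, levels) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  g <- floor((values - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  pmin(g, levels)
}

glcm_offsets_2d <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

glcm_slice <- function(g, mask, levels, offsets) {
  m <- matrix(0, levels, levels)
  nr <- nrow(g); nc <- ncol(g)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- g[r1, c1, drop = FALSE]
    b <- g[r1 + dr, c1 + dc, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    counts <- matrix(tabulate((a[ok] - 1L) * levels + b[ok],
                              nbins = levels * levels),
                     levels, levels, byrow = TRUE)
    m <- m + counts + t(counts)  # symmetric accumulation
  }
  m
}

#' Gray-level co-occurrence matrix of a masked nucleus
#'
#' In-mask intensities are min-max rescaled to `levels` gray levels;
#' co-occurring pairs at distance-1 offsets in four directions (2D) are
#' accumulated over pairs whose both pixels are in the mask, symmetrized,
#' summed over offsets and normalized to sum 1. For a 3D stack the GLCM is
#' accumulated per slice and pooled (offsets across anisotropic z are not
#' used).
#'
#' @param image numeric 2D/3D array.
#' @param mask logical array of the same shape.
#' @param levels number of gray levels (>= 2).
#' @param offsets list of integer offset pairs `c(dr, dc)`.
#' @return object of class `glcm`: list with `levels` and `matrix` (an
#'   `levels x levels` matrix summing to 1).
#' @export
compute_glcm <- function(image, mask = NULL, levels = 32L,
                         offsets = glcm_offsets_2d) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(image))
  stopifnot(identical(dim(image), dim(mask)), levels >= 2)
  g <- array(0L, dim = dim(image))
  g[mask] <- quantize_levels(image[mask], levels)
  g[!mask] <- 1L  # placeholder; masked out of pair accumulation anyway
  if (length(dim(image)) == 3L) {
    m <- matrix(0, levels, levels)
    for (z in seq_len(dim(image)[3]))
      m <- m + glcm_slice(g[, , z], mask[, , z], levels, offsets)
  } else {
    m <- glcm_slice(g, mask, levels, offsets)
  }
  tot <- sum(m)
  if (tot == 0) stop("mask has fewer than 2 neighboring in-mask pixels")
  structure(list(levels = as.integer(levels), matrix = m / tot),
            class = "glcm")
}

#' Haralick entropy of a GLCM
#'
#' `-sum p(i,j) * log2 p(i,j)` over the normalized co-occurrence matrix,
#' with `0 * log 0 = 0`; in bits, bounded by `2 * log2(levels)`.
#'
#' @param glcm a `glcm` from [compute_glcm()].
#' @return entropy in bits (>= 0).
#' @export
haralick_entropy <- function(glcm) {
  p <- glcm$matrix
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Core Haralick descriptors of a GLCM
#'
#' Entropy, contrast `sum p (i-j)^2`, homogeneity `sum p / (1 + |i-j|)`,
#' and energy `sum p^2`.
#'
#' @param glcm a `glcm`.
#' @return named numeric vector.
#' @export
haralick_features <- function(glcm) {
  p <- glcm$matrix
  i <- row(p); j <- col(p)
  c(entropy = haralick_entropy(glcm),
    contrast = sum(p * (i - j)^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    energy = sum(p^2))
}

#' Per-nucleus mean and maximum intensity
#'
#' The mean-vs-max scatter used to compare fluorescence distributions of
#' nuclear foci between genotypes.
#'
#' @param nuclei a `nucleus_image_set` (list of records with `image`,
#'   `mask`, and optionally `genotype`, `nucleus_id`).
#' @return data.frame: nucleus_id, genotype, mean, max.
#' @export
intensity_scatter <- function(nuclei) {
  stopifnot(length(nuclei) >= 1)
  do.call(rbind, lapply(seq_along(nuclei), function(i) {
    rec <- nuclei[[i]]
    v <- rec$image[rec$mask]
    data.frame(nucleus_id = if (!is.null(rec$nucleus_id)) rec$nucleus_id
               else sprintf("nuc_%03d", i),
               genotype = if (!is.null(rec$genotype)) rec$genotype
               else NA_character_,
               mean = mean(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
}

#' Compare two groups with a normality-gated t-test
#'
#' Shapiro-Wilk normality is tested per group at alpha = 0.05 and reported
#' alongside a two-sided Welch t-test; non-normal data raise a flag but
#' the t-test is still reported.
#'
#' @param values_a,values_b numeric vectors, >= 3 values each.
#' @return list with `normal_a`, `normal_b`, `shapiro_p_a`, `shapiro_p_b`,
#'   `normality_flag` (TRUE when either group fails), `t`, `p`.
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 3, length(values_b) >= 3)
  shap <- function(x) {
    if (length(unique(x)) == 1) return(NA_real_)
    shapiro.test(x)$p.value
  }
  pa <- shap(values_a); pb <- shap(values_b)
  norm_a <- is.na(pa) || pa >= 0.05
  norm_b <- is.na(pb) || pb >= 0.05
  if (var(values_a) + var(values_b) == 0) {
    eq <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    tt <- list(statistic = c(t = 0), p.value = if (eq) 1 else 0)
  } else {
    tt <- t.test(values_a, values_b)
  }
  list(normal_a = norm_a, normal_b = norm_b,
       shapiro_p_a = pa, shapiro_p_b = pb,
       normality_flag = !(norm_a && norm_b),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square without continuity correction, for comparing
#' categorical phenotype proportions between genotypes.
#'
#' @param table matrix of non-negative counts with positive margins.
#' @return list with `statistic` and `p`.
#' @export
proportion_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Rounded percentage of successes
#'
#' `round(100 * successes / trials)`, halves away from zero — the
#' convention used for printed embryo proportions (e.g. 39 of 206
#' recovered = 19%).
#'
#' @param successes,trials non-negative counts, `successes <= trials`,
#'   `trials > 0`.
#' @return integer percent.
#' @export
summarize_proportion <- function(successes, trials) {
  stopifnot(trials > 0, successes >= 0, successes <= trials)
  round_half_away(100 * successes / trials)
}
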
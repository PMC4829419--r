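# TIFF I/O for nucleus images. Intensities are arbitrary-unit doubles;
# TIFF stores [0,1], so each image is written scaled by its own maximum
# and the factor is recorded in a sidecar TSV next to the files.

#' Write a nucleus image set as TIFF files with masks
#'
#' Each record becomes `<id>_<genotype>.tif` (intensity, one page per z
#' slice, scaled to \[0,1\]) and `<id>_<genotype>_mask.tif`; per-file scale
#' factors and metadata go to `images.tsv` in the same directory.
#'
#' @param nuclei a `nucleus_image_set`.
#' @param dir output directory (created if needed).
#' @return path of the metadata TSV, invisibly.
#' @export
write_nucleus_images <- function(nuclei, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(seq_along(nuclei), function(i) {
    rec <- nuclei[[i]]
    base <- sprintf("%s_%s", rec$nucleus_id, rec$genotype)
    img <- rec$image
    lo <- min(img); hi <- max(img)
    scale <- if (hi > lo) hi - lo else 1
    to_pages <- function(a) {
      if (length(dim(a)) == 3L)
        lapply(seq_len(dim(a)[3]), function(z) a[, , z])
      else list(a)
    }
    tiff::writeTIFF(to_pages((img - lo) / scale),
                    file.path(dir, paste0(base, ".tif")),
                    bits.per.sample = 16L)
    tiff::writeTIFF(to_pages(rec$mask * 1),
                    file.path(dir, paste0(base, "_mask.tif")),
                    bits.per.sample = 8L)
    data.frame(nucleus_id = rec$nucleus_id, genotype = rec$genotype,
               file = paste0(base, ".tif"),
               mask_file = paste0(base, "_mask.tif"),
               offset = lo, scale = scale,
               stringsAsFactors = FALSE)
  }))
  path <- file.path(dir, "images.tsv")
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

list_to_array <- function(pages) {
  if (length(pages) == 1L) return(pages[[1]])
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  arr
}

#' Read a nucleus image set written by [write_nucleus_images()]
#'
#' When a record has no mask file, a mask is derived by Otsu thresholding
#' of the intensity image (fallback is reported with a message).
#'
#' @param dir directory holding the TIFFs and `images.tsv`.
#' @return a `nucleus_image_set`.
#' @export
read_nucleus_images <- function(dir) {
  meta <- read.delim(file.path(dir, "images.tsv"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    img <- list_to_array(tiff::readTIFF(file.path(dir, m$file), all = TRUE))
    img <- img * m$scale + m$offset
    mask_path <- file.path(dir, m$mask_file)
    if (!is.na(m$mask_file) && nzchar(m$mask_file) && file.exists(mask_path)) {
      mask <- list_to_array(tiff::readTIFF(mask_path, all = TRUE)) > 0.5
    } else {
      mask <- otsu_mask(img)
      message("no mask for ", m$file, "; using Otsu threshold fallback")
    }
    list(image = img, mask = mask, genotype = m$genotype,
         nucleus_id = m$nucleus_id, scale = NA_real_)
  })
  structure(out, class = "nucleus_image_set")
}

# Otsu threshold fallback when no mask file is provided; uses EBImage when
# available, otherwise an exhaustive between-class-variance search over a
# 256-bin histogram.
otsu_mask <- function(image) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) return(array(TRUE, dim = dim(image)))
  if (requireNamespace("EBImage", quietly = TRUE)) {
    scaled <- (image - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    return(array(scaled > thr, dim = dim(image)))
  }
  h <- tabulate(cut(v, breaks = 256, labels = FALSE), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  k <- which.max(replace(sigma_b, !is.finite(sigma_b), -Inf))
  thr <- rng[1] + (k / 256) * (rng[2] - rng[1])
  array(image > thr, dim = dim(image))
}
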
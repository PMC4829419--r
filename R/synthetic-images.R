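#' Configuration for synthetic nucleus images
#'
#' Describes punctate nuclear fluorescence images of the kind produced by
#' RNA FISH or immunofluorescence of two-cell embryos: a disk-shaped
#' nucleus on a darker background, Gaussian foci of nascent-transcript
#' signal inside the nucleus, and additive Gaussian noise. Mutant images
#' have the whole in-nucleus signal scaled by `mutant_intensity_ratio`,
#' which is the planted ground truth that the quantification stage should
#' recover.
#'
#' @param image_shape integer vector, `c(rows, cols)` or
#'   `c(rows, cols, slices)` for a z-stack.
#' @param n_nuclei image pairs (one control + one mutant each).
#' @param nucleus_radius radius of the disk mask in pixels.
#' @param n_foci number of Gaussian foci per nucleus (0 for none).
#' @param focus_intensity peak focus amplitude, arbitrary units.
#' @param focus_sigma focus width (s.d. of the Gaussian profile) in pixels.
#' @param background_mean mean intensity, arbitrary units, both inside and
#'   outside the nucleus before focus signal is added.
#' @param noise_sd s.d. of additive Gaussian noise.
#' @param mutant_intensity_ratio positive scale factor applied to in-mask
#'   mutant signal.
#' @param seed integer seed.
#' @return an object of class `image_sim_config`.
#' @export
image_sim_config <- function(image_shape = c(64L, 64L),
                             n_nuclei = 50L,
                             nucleus_radius = 20L,
                             n_foci = 12L,
                             focus_intensity = 200,
                             focus_sigma = 2,
                             background_mean = 100,
                             noise_sd = 10,
                             mutant_intensity_ratio = 2.2,
                             seed = 1L) {
  stopifnot(length(image_shape) %in% c(2L, 3L), all(image_shape >= 8L))
  if (mutant_intensity_ratio <= 0) stop("mutant_intensity_ratio must be > 0")
  if (n_foci < 0) stop("n_foci must be >= 0")
  if (nucleus_radius >= min(image_shape[1:2]) / 2)
    stop("nucleus does not fit in the image")
  structure(list(image_shape = as.integer(image_shape),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = as.numeric(nucleus_radius),
                 n_foci = as.integer(n_foci),
                 focus_intensity = as.numeric(focus_intensity),
                 focus_sigma = as.numeric(focus_sigma),
                 background_mean = as.numeric(background_mean),
                 noise_sd = as.numeric(noise_sd),
                 mutant_intensity_ratio = as.numeric(mutant_intensity_ratio),
                 seed = as.integer(seed)),
            class = "image_sim_config")
}

disk_mask <- function(shape, radius) {
  ctr <- (shape[1:2] + 1) / 2
  r <- outer((seq_len(shape[1]) - ctr[1])^2,
             (seq_len(shape[2]) - ctr[2])^2, "+")
  m <- r <= radius^2
  if (length(shape) == 3L) m <- array(rep(m, shape[3]), dim = shape)
  m
}

simulate_one_nucleus <- function(config, scale) {
  shape <- config$image_shape
  is3d <- length(shape) == 3L
  mask2d <- disk_mask(shape[1:2], config$nucleus_radius)
  ctr <- (shape[1:2] + 1) / 2

  signal2d <- matrix(0, shape[1], shape[2])
  if (config$n_foci > 0) {
    # foci placed uniformly within 80% of the nucleus radius
    rr <- config$nucleus_radius * 0.8 * sqrt(runif(config$n_foci))
    th <- runif(config$n_foci, 0, 2 * pi)
    fx <- ctr[1] + rr * cos(th)
    fy <- ctr[2] + rr * sin(th)
    xs <- seq_len(shape[1]); ys <- seq_len(shape[2])
    for (i in seq_len(config$n_foci)) {
      g <- outer(exp(-(xs - fx[i])^2 / (2 * config$focus_sigma^2)),
                 exp(-(ys - fy[i])^2 / (2 * config$focus_sigma^2)))
      signal2d <- signal2d + config$focus_intensity * g
    }
  }

  build_slice <- function() {
    img <- matrix(config$background_mean, shape[1], shape[2])
    img[mask2d] <- scale * (config$background_mean + signal2d[mask2d])
    img + matrix(rnorm(prod(shape[1:2]), 0, config$noise_sd),
                 shape[1], shape[2])
  }
  if (is3d) {
    img <- array(0, dim = shape)
    for (z in seq_len(shape[3])) img[, , z] <- build_slice()
    mask <- array(rep(mask2d, shape[3]), dim = shape)
  } else {
    img <- build_slice()
    mask <- mask2d
  }
  list(image = img, mask = mask)
}

#' Simulate paired control/mutant nucleus images
#'
#' Generates `n_nuclei` control/mutant image pairs. The in-mask signal of
#' each mutant nucleus is the control-model signal multiplied by
#' `mutant_intensity_ratio`, so the expected ratio of group mean integrated
#' intensities equals the configured ratio; noise is additive with the
#' stated s.d. The planted per-nucleus scale factor is kept in each
#' record's metadata.
#'
#' @param config an [image_sim_config()].
#' @return list of class `nucleus_image_set`; each element is a list with
#'   `image`, `mask`, `genotype` ("control"/"mutant"), `nucleus_id`, and
#'   `scale` (the planted factor).
#' @export
simulate_nucleus_images <- function(config) {
  set.seed(config$seed)
  out <- vector("list", 2L * config$n_nuclei)
  k <- 0L
  for (i in seq_len(config$n_nuclei)) {
    for (geno in c("control", "mutant")) {
      scale <- if (geno == "mutant") config$mutant_intensity_ratio else 1
      rec <- simulate_one_nucleus(config, scale)
      rec$genotype <- geno
      rec$nucleus_id <- sprintf("nuc_%03d", i)
      rec$scale <- scale
      k <- k + 1L
      out[[k]] <- rec
    }
  }
  structure(out, class = "nucleus_image_set")
}
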
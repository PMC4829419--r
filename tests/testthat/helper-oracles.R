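# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# All exact occurrences of `read` in `genome` (character scalar), both
# strands, by comparing every sliding window.
oracle_scan <- function(read, genome, ref = "chr1") {
  w <- nchar(read)
  L <- nchar(genome)
  if (w > L) return(NULL)
  windows <- substring(genome, 1:(L - w + 1), w:L)
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  fwd <- which(windows == read)
  rev <- which(windows == rc(read))
  out <- rbind(
    if (length(fwd)) data.frame(reference = ref, start = fwd - 1L,
                                end = fwd - 1L + w, strand = "+"),
    if (length(rev)) data.frame(reference = ref, start = rev - 1L,
                                end = rev - 1L + w, strand = "-"))
  if (is.null(out)) return(NULL)
  out[order(out$reference, out$start, out$strand), , drop = FALSE]
}

# Majority-family concordance by explicit fraction computation.
oracle_concordance <- function(labels, threshold = 0.95) {
  if (any(is.na(labels))) return(NA_character_)
  counts <- sapply(unique(labels), function(f) sum(labels == f))
  best <- max(counts)
  winners <- names(counts)[counts == best]
  if (length(winners) > 1) return(NA_character_)
  if (best / length(labels) > threshold) winners else NA_character_
}

# GLCM of a 2D matrix by explicit pair enumeration.
oracle_glcm <- function(img, mask, levels,
                        offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  v <- img[mask]
  rng <- range(v)
  q <- matrix(0L, nrow(img), ncol(img))
  if (rng[1] == rng[2]) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(floor((img[mask] - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
                    levels)
  }
  m <- matrix(0, levels, levels)
  for (off in offsets) {
    for (r in seq_len(nrow(img))) {
      for (cc in seq_len(ncol(img))) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
        if (!mask[r, cc] || !mask[r2, c2]) next
        m[q[r, cc], q[r2, c2]] <- m[q[r, cc], q[r2, c2]] + 1
        m[q[r2, c2], q[r, cc]] <- m[q[r2, c2], q[r, cc]] + 1
      }
    }
  }
  m / sum(m)
}

# Median-of-ratios size factors straight from the definition.
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(k) prod(k)^(1 / length(k)))
  apply(counts, 2, function(k) median((k / geo)[geo > 0]))
}

# Benjamini-Hochberg by the explicit step-up construction.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

random_read_df <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = quals, stringsAsFactors = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mean silhouette width for a 2-group split on euclidean distances.
silhouette_mean <- function(coords, groups) {
  d <- as.matrix(dist(coords))
  vapply(seq_len(nrow(d)), function(i) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}
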
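#' Configuration for the synthetic repeat genome
#'
#' Describes a small genome carrying interspersed repeat families whose
#' copies are near-identical, so that short reads from them multi-map, plus
#' ribosomal-RNA decoy references for the rRNA pre-filter. Intra-family
#' identity must exceed 0.9 so multi-mapping actually arises.
#'
#' @param n_families number of repeat families.
#' @param copies_per_family interspersed copies per family.
#' @param copy_length length of each copy in bases.
#' @param intra_family_identity fraction in (0.9, 1]; each copy differs from
#'   the family consensus by at most `(1 - identity) * copy_length`
#'   substitutions.
#' @param genome_length total genome length in bases; must accommodate all
#'   copies without overlap.
#' @param family_classes repeat class per family, recycled over
#'   LINE/SINE/LTR by default.
#' @param rrna_lengths named integer vector of rRNA decoy lengths.
#' @param seed integer seed.
#' @return an object of class `repeat_genome_config`.
#' @export
repeat_genome_config <- function(n_families = 3L,
                                 copies_per_family = 20L,
                                 copy_length = 300L,
                                 intra_family_identity = 1.0,
                                 genome_length = 100000L,
                                 family_classes = NULL,
                                 rrna_lengths = c(rRNA_18S = 400L,
                                                  rRNA_28S = 500L,
                                                  rRNA_5S = 120L,
                                                  rRNA_5.8S = 150L),
                                 seed = 1L) {
  stopifnot(n_families >= 1, copies_per_family >= 1, copy_length >= 1)
  if (intra_family_identity <= 0.9 || intra_family_identity > 1)
    stop("intra_family_identity must lie in (0.9, 1]")
  n_copies <- n_families * copies_per_family
  if (n_copies * copy_length > genome_length)
    stop("repeat copies cannot be placed in the genome without overlap")
  if (is.null(family_classes))
    family_classes <- rep_len(c("LINE", "SINE", "LTR"), n_families)
  stopifnot(length(family_classes) == n_families,
            all(family_classes %in% REPEAT_CLASSES))
  structure(list(n_families = as.integer(n_families),
                 copies_per_family = as.integer(copies_per_family),
                 copy_length = as.integer(copy_length),
                 intra_family_identity = as.numeric(intra_family_identity),
                 genome_length = as.integer(genome_length),
                 family_classes = family_classes,
                 rrna_lengths = rrna_lengths,
                 seed = as.integer(seed)),
            class = "repeat_genome_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a repeat-rich genome with rRNA decoys
#'
#' Builds a random background genome, plants `n_families` repeat families
#' of near-identical interspersed copies (each copy is the family consensus
#' with at most `(1 - identity) * copy_length` substitutions), and
#' generates separate ribosomal-RNA decoy references. Copies are placed in
#' disjoint evenly spaced bins so annotation intervals never overlap.
#'
#' @param config a [repeat_genome_config()].
#' @return list of class `repeat_genome` with elements `genome`
#'   (a [Biostrings::DNAStringSet] holding `chr1`), `annotation`
#'   (a [GenomicRanges::GRanges] with `family` and `class` metadata,
#'   0-based half-open when exported to BED), `rrna` (DNAStringSet of
#'   decoys), `consensus` (DNAStringSet per family), and `family_class`
#'   (data.frame family -> class).
#' @export
simulate_repeat_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  k <- config$copy_length
  n_cop <- config$n_families * config$copies_per_family
  genome <- random_dna(L)

  consensus <- vapply(seq_len(config$n_families), function(i) random_dna(k),
                      character(1))
  fam_names <- sprintf("%s_fam%d", config$family_classes,
                       seq_len(config$n_families))
  names(consensus) <- fam_names

  bin <- L %/% n_cop
  if (bin < k) stop("repeat copies cannot be placed without overlap")
  # one copy per bin, random offset; guarantees non-overlapping placement
  starts0 <- (seq_len(n_cop) - 1L) * bin +
    sample.int(bin - k + 1L, n_cop, replace = TRUE) - 1L
  fam_of_copy <- rep(fam_names, each = config$copies_per_family)

  max_subs <- floor((1 - config$intra_family_identity) * k)
  copy_seqs <- vapply(seq_len(n_cop), function(i) {
    s <- consensus[[fam_of_copy[i]]]
    if (max_subs > 0) {
      n_subs <- sample.int(max_subs + 1L, 1L) - 1L
      if (n_subs > 0) {
        pos <- sample.int(k, n_subs)
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        s <- paste(ch, collapse = "")
      }
    }
    s
  }, character(1))

  gch <- strsplit(genome, "")[[1]]
  for (i in seq_len(n_cop)) {
    idx <- (starts0[i] + 1L):(starts0[i] + k)
    gch[idx] <- strsplit(copy_seqs[i], "")[[1]]
  }
  genome <- paste(gch, collapse = "")

  class_of_fam <- setNames(config$family_classes, fam_names)
  annotation <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = starts0 + 1L, width = k),
    family = fam_of_copy,
    class = unname(class_of_fam[fam_of_copy]))
  annotation <- GenomicRanges::sort(annotation)

  rrna <- Biostrings::DNAStringSet(vapply(config$rrna_lengths, random_dna,
                                          character(1)))
  names(rrna) <- names(config$rrna_lengths)

  structure(list(
    genome = Biostrings::DNAStringSet(c(chr1 = genome)),
    annotation = annotation,
    rrna = rrna,
    consensus = Biostrings::DNAStringSet(consensus),
    family_class = data.frame(family = fam_names,
                              class = unname(class_of_fam[fam_names]),
                              stringsAsFactors = FALSE)),
    class = "repeat_genome")
}

#' Simulate a read library from a repeat genome
#'
#' Samples `n_reads` error-free reads from the repeat copies (each copy
#' treated as one transcript), with per-family abundances; the number of
#' reads per transcript is multinomial, i.e. Poisson depth conditioned on
#' the total, so abundance ratios are preserved in expectation. Optionally a
#' fraction of reads originates from the rRNA decoys, and QC failures
#' (low-quality runs, N bases, poly-A tails) are injected at configured
#' rates by modifying — never dropping — reads, so exactly `n_reads`
#' records are always returned.
#'
#' @param sim a `repeat_genome` from [simulate_repeat_genome()].
#' @param family_abundances named non-negative numeric, one per family;
#'   need not sum to one.
#' @param read_length read length in bases (<= copy length).
#' @param n_reads number of reads to emit.
#' @param qc_noise list with elements `p_low_quality`, `p_n_bases`,
#'   `p_polya` (injection probabilities, mutually exclusive per read).
#' @param rrna_fraction fraction of reads drawn from rRNA decoys.
#' @param seed integer seed.
#' @return data.frame of class `read_set` with columns `id`, `sequence`,
#'   `quality`, plus truth columns `source_family` (NA for rRNA/none) and
#'   `qc_flag` (none/low_quality/n_bases/polya).
#' @export
simulate_reads <- function(sim, family_abundances, read_length = 49L,
                           n_reads = 1000L,
                           qc_noise = list(p_low_quality = 0, p_n_bases = 0,
                                           p_polya = 0),
                           rrna_fraction = 0, seed = 1L) {
  stopifnot(inherits(sim, "repeat_genome"))
  if (any(family_abundances < 0) || all(family_abundances == 0))
    stop("family abundances must be non-negative and not all zero")
  if (read_length > min(GenomicRanges::width(sim$annotation)))
    stop("read_length exceeds transcript length")
  qc <- modifyList(list(p_low_quality = 0, p_n_bases = 0, p_polya = 0),
                   qc_noise)
  set.seed(seed)

  ann <- sim$annotation
  fam <- S4Vectors::mcols(ann)$family
  copies_per_fam <- table(fam)
  w <- family_abundances[fam] / as.numeric(copies_per_fam[fam])
  n_rrna <- rbinom(1L, n_reads, rrna_fraction)
  n_rep <- n_reads - n_rrna

  src <- sample.int(length(ann), n_rep, replace = TRUE, prob = w)
  offs <- vapply(src, function(i)
    sample.int(GenomicRanges::width(ann)[i] - read_length + 1L, 1L),
    integer(1))
  starts <- GenomicRanges::start(ann)[src] + offs - 1L
  chr <- as.character(sim$genome[["chr1"]])
  seqs <- substring(chr, starts, starts + read_length - 1L)
  fams <- fam[src]

  if (n_rrna > 0) {
    ridx <- sample.int(length(sim$rrna), n_rrna, replace = TRUE)
    rseq <- as.character(sim$rrna)
    roff <- vapply(ridx, function(i)
      sample.int(nchar(rseq[i]) - read_length + 1L, 1L), integer(1))
    seqs <- c(seqs, substring(rseq[ridx], roff, roff + read_length - 1L))
    fams <- c(fams, rep(NA_character_, n_rrna))
  }

  ord <- sample.int(n_reads)
  seqs <- seqs[ord]
  fams <- fams[ord]
  quals <- strrep("I", read_length)  # Phred+33, Q40
  quals <- rep(quals, n_reads)

  p <- c(qc$p_low_quality, qc$p_n_bases, qc$p_polya)
  if (any(p < 0) || sum(p) > 1) stop("invalid qc_noise probabilities")
  flag <- sample(c("low_quality", "n_bases", "polya", "none"), n_reads,
                 replace = TRUE, prob = c(p, 1 - sum(p)))

  lq <- which(flag == "low_quality")
  if (length(lq)) {
    # 60% of bases pushed below Phred 5 ('#' is Phred 2)
    n_low <- ceiling(0.6 * read_length)
    quals[lq] <- paste0(strrep("#", n_low), strrep("I", read_length - n_low))
  }
  nb <- which(flag == "n_bases")
  if (length(nb)) {
    n_n <- ceiling(0.10 * read_length)
    seqs[nb] <- vapply(seqs[nb], function(s) {
      pos <- sample.int(read_length, n_n)
      ch <- strsplit(s, "")[[1]]; ch[pos] <- "N"
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  pa <- which(flag == "polya")
  if (length(pa)) {
    run <- max(15L, ceiling(0.30 * read_length))
    seqs[pa] <- paste0(substring(seqs[pa], 1L, read_length - run),
                       strrep("A", run))
  }

  out <- data.frame(id = sprintf("read_%06d", seq_len(n_reads)),
                    sequence = seqs,
                    quality = quals,
                    source_family = fams,
                    qc_flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads a data.frame with `id`, `sequence`, `quality`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTQ file into a read data.frame
#'
#' @param path FASTQ path (Phred+33 qualities).
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write repeat annotation as 6-column BED plus a family-class TSV
#'
#' BED uses the 0-based half-open convention; `name` carries the repeat
#' family and `score` is 0.
#'
#' @param annotation a `GRanges` with `family` and `class` metadata.
#' @param bed_path,class_path output paths.
#' @return invisibly, the two paths.
#' @export
write_repeat_annotation <- function(annotation, bed_path, class_path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(annotation)),
                   start = GenomicRanges::start(annotation) - 1L,
                   end = GenomicRanges::end(annotation),
                   name = S4Vectors::mcols(annotation)$family,
                   score = 0L,
                   strand = "+")
  write.table(df, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fc <- unique(data.frame(family = S4Vectors::mcols(annotation)$family,
                          class = S4Vectors::mcols(annotation)$class,
                          stringsAsFactors = FALSE))
  write.table(fc, class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed_path, class_path))
}

#' Read repeat annotation from BED + family-class TSV
#'
#' @param bed_path 6-column BED (0-based half-open; name = family).
#' @param class_path TSV with columns `family`, `class`.
#' @return a `GRanges` with `family` and `class` metadata columns;
#'   overlapping intervals on the same reference are rejected.
#' @export
read_repeat_annotation <- function(bed_path, class_path) {
  bed <- read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)[, 1:4]
  names(bed) <- c("chrom", "start", "end", "family")
  fc <- read.delim(class_path, stringsAsFactors = FALSE)
  cl <- setNames(fc$class, fc$family)
  if (anyNA(cl[bed$family])) stop("family missing from class table")
  gr <- GenomicRanges::GRanges(bed$chrom,
                               IRanges::IRanges(bed$start + 1L, bed$end),
                               family = bed$family,
                               class = unname(cl[bed$family]))
  validate_annotation(gr)
}

validate_annotation <- function(annotation) {
  if (length(annotation)) {
    hits <- GenomicRanges::findOverlaps(annotation, drop.self = TRUE)
    if (length(hits) > 0)
      stop("overlapping repeat annotation intervals are not allowed")
    fc <- unique(data.frame(f = S4Vectors::mcols(annotation)$family,
                            c = S4Vectors::mcols(annotation)$class))
    if (anyDuplicated(fc$f))
      stop("a repeat family must map to exactly one class")
  }
  annotation
}
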
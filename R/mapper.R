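#' Multi-mapping configuration
#'
#' Parameters of the exhaustive best-hit mapper and the ribosomal-RNA
#' pre-filter: reads are removed when they have a unique best ungapped
#' alignment to an rRNA reference with at most `rrna_seed_mismatch_limit`
#' mismatches in the seed (the first `rrna_seed_length` bases); surviving
#' reads are mapped exhaustively at zero mismatches, reporting up to
#' `max_locations` genomic locations on either strand, and dropped when
#' more exist.
#'
#' @param max_locations cap on reported locations per read.
#' @param max_mismatches_repeat mismatches allowed in the genomic mapping;
#'   only 0 (exact matching) is supported.
#' @param rrna_seed_mismatch_limit maximum seed mismatches for the rRNA
#'   filter (2, i.e. "fewer than 3").
#' @param rrna_seed_length seed length in bases.
#' @param rrna_references rRNA decoy sequences
#'   (a [Biostrings::DNAStringSet] or named character vector); may be
#'   `NULL` when the rRNA filter is not used.
#' @return an object of class `map_config`.
#' @export
map_config <- function(max_locations = 10000L,
                       max_mismatches_repeat = 0L,
                       rrna_seed_mismatch_limit = 2L,
                       rrna_seed_length = 28L,
                       rrna_references = NULL) {
  stopifnot(max_locations >= 1, rrna_seed_mismatch_limit >= 0,
            rrna_seed_length >= 1)
  if (max_mismatches_repeat != 0L)
    stop("only exact (0-mismatch) genomic matching is supported")
  if (!is.null(rrna_references) && !methods::is(rrna_references, "DNAStringSet"))
    rrna_references <- Biostrings::DNAStringSet(rrna_references)
  structure(list(max_locations = as.integer(max_locations),
                 max_mismatches_repeat = 0L,
                 rrna_seed_mismatch_limit = as.integer(rrna_seed_mismatch_limit),
                 rrna_seed_length = as.integer(rrna_seed_length),
                 rrna_references = rrna_references),
            class = "map_config")
}

# Concatenate references and their reverse complements into one subject,
# N-spacer-separated so no placement can straddle a boundary (N never
# matches with fixed = TRUE). Placement counts on this subject equal the
# summed both-strand counts over the references.
concat_references <- function(refs, spacer_width) {
  spacer <- strrep("N", spacer_width)
  both <- c(as.character(refs),
            as.character(Biostrings::reverseComplement(refs)))
  Biostrings::DNAString(paste(both, collapse = spacer))
}

#' Filter reads matching ribosomal RNA
#'
#' A read is discarded iff it has a unique best ungapped alignment to an
#' rRNA reference with at most `rrna_seed_mismatch_limit` mismatches in the
#' seed region (the first `rrna_seed_length` bases of the read). Reads
#' matching several rRNA locations equally well (non-unique best) are kept.
#' Both strands are searched.
#'
#' @param reads data.frame with `id`, `sequence` columns.
#' @param config a [map_config()] with non-empty `rrna_references`.
#' @return list with `kept` (surviving reads data.frame) and `n_discarded`.
#' @export
filter_rrna <- function(reads, config) {
  if (is.null(config$rrna_references) || length(config$rrna_references) == 0)
    stop("rRNA reference set is empty")
  if (nrow(reads) == 0) return(list(kept = reads, n_discarded = 0L))
  lim <- config$rrna_seed_mismatch_limit
  subj <- concat_references(config$rrna_references,
                            config$rrna_seed_length + 2L)
  seeds <- substring(reads$sequence, 1L,
                     pmin(nchar(reads$sequence), config$rrna_seed_length))
  discard <- vapply(seeds, function(sd) {
    if (grepl("[^ACGT]", sd)) return(FALSE)
    p <- Biostrings::DNAString(sd)
    n_lim <- Biostrings::countPattern(p, subj, max.mismatch = lim,
                                      fixed = TRUE)
    if (n_lim == 0) return(FALSE)
    counts <- c(vapply(seq_len(lim) - 1L, function(k)
      Biostrings::countPattern(p, subj, max.mismatch = k, fixed = TRUE),
      integer(1)), n_lim)
    hit_k <- which(counts > 0)
    k_best <- hit_k[1]
    n_best <- if (k_best == 1) counts[1] else counts[k_best] - counts[k_best - 1]
    n_best == 1  # unique best alignment
  }, logical(1), USE.NAMES = FALSE)
  list(kept = reads[!discard, , drop = FALSE],
       n_discarded = sum(discard))
}

#' Exhaustive zero-mismatch multi-mapper
#'
#' Finds every exact occurrence of each read in the genome, on both
#' strands. A read with more than `max_locations` occurrences is dropped
#' and tallied (`over_cap`), as is a read with none (`unmapped`).
#' Coordinates are 0-based half-open; hits are unstranded for counting but
#' the strand is recorded.
#'
#' @param reads data.frame with `id`, `sequence` (QC- and rRNA-filtered).
#' @param genome a [Biostrings::DNAStringSet] or named character vector of
#'   reference sequences.
#' @param config a [map_config()].
#' @return list of class `alignment_set` with `alignments` (data.frame:
#'   `read_id`, `reference`, `start` 0-based, `end` half-open, `strand`,
#'   `n_mismatches`, `n_hits`) sorted by read then coordinate, and `tally`
#'   (named counts: mapped, unmapped, over_cap).
#' @export
map_multi <- function(reads, genome, config = map_config()) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("ref", seq_along(genome))
  if (min(Biostrings::width(genome)) < 1) stop("empty genome sequence")
  if (nrow(reads) > 0 && max(nchar(reads$sequence)) >
      max(Biostrings::width(genome)))
    stop("genome shorter than the longest read")

  clean <- !grepl("[^ACGT]", reads$sequence)
  chunks <- list()

  idx_clean <- which(clean)
  if (length(idx_clean)) {
    widths <- nchar(reads$sequence[idx_clean])
    for (w in unique(widths)) {
      sel <- idx_clean[widths == w]
      pats <- Biostrings::DNAStringSet(reads$sequence[sel])
      pd_f <- Biostrings::PDict(pats)
      pd_r <- Biostrings::PDict(Biostrings::reverseComplement(pats))
      for (ref in names(genome)) {
        subj <- genome[[ref]]
        for (strand in c("+", "-")) {
          pd <- if (strand == "+") pd_f else pd_r
          m <- Biostrings::matchPDict(pd, subj)
          starts <- Biostrings::startIndex(m)
          lens <- vapply(starts, length, integer(1))
          if (sum(lens) == 0) next
          st <- unlist(starts[lens > 0], use.names = FALSE)
          chunks[[length(chunks) + 1L]] <- data.frame(
            idx = rep(sel, lens), reference = ref,
            start = st - 1L, end = st - 1L + w, strand = strand,
            n_mismatches = 0L, stringsAsFactors = FALSE)
        }
      }
    }
  }

  n_hits <- integer(nrow(reads))
  if (length(chunks)) {
    hits <- do.call(rbind, chunks)
    tab <- tabulate(hits$idx, nbins = nrow(reads))
    n_hits <- tab
  } else {
    hits <- NULL
  }
  over <- n_hits > config$max_locations
  mapped <- n_hits >= 1L & !over

  if (!is.null(hits) && any(mapped)) {
    hits <- hits[mapped[hits$idx], , drop = FALSE]
    aln <- data.frame(read_id = reads$id[hits$idx],
                      hits[c("reference", "start", "end", "strand",
                             "n_mismatches")],
                      n_hits = n_hits[hits$idx],
                      stringsAsFactors = FALSE)
    aln <- aln[order(aln$read_id, aln$reference, aln$start, aln$strand), ,
               drop = FALSE]
    rownames(aln) <- NULL
  } else {
    aln <- data.frame(read_id = character(0), reference = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_mismatches = integer(0),
                      n_hits = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(alignments = aln,
                 tally = c(mapped = sum(mapped),
                           unmapped = sum(n_hits == 0L),
                           over_cap = sum(over))),
            class = "alignment_set")
}

#' Write alignment records as minimal SAM
#'
#' Emits `@HD`/`@SQ` headers and one line per hit: POS is 1-based on
#' write, MAPQ is 0 for multi-hit reads and 255 for unique ones, CIGAR is
#' full-length match, and the mismatch count goes in the `NM` tag.
#'
#' @param alignments the `alignments` data.frame of an `alignment_set`.
#' @param reference_lengths named integer vector of reference lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ref in names(reference_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref,
                       as.integer(reference_lengths[[ref]])), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    mapq <- ifelse(alignments$n_hits > 1L, 0L, 255L)
    cigar <- sprintf("%dM", alignments$end - alignments$start)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNM:i:%d",
                       alignments$read_id, flag, alignments$reference,
                       alignments$start + 1L, mapq, cigar,
                       alignments$n_mismatches), con)
  }
  invisible(path)
}

#' Read minimal SAM back into an alignment data.frame
#'
#' @param path SAM path written by [write_sam()] (or compatible ungapped
#'   single-segment SAM with full-match CIGARs and NM tags).
#' @return data.frame with the same columns as [map_multi()] alignments.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(read_id = character(0), reference = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_mismatches = integer(0),
                      n_hits = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  read_id <- vapply(f, `[[`, character(1), 1L)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  ref <- vapply(f, `[[`, character(1), 3L)
  pos <- as.integer(vapply(f, `[[`, character(1), 4L))
  cigar <- vapply(f, `[[`, character(1), 6L)
  width <- as.integer(sub("M$", "", cigar))
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x, value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else 0L
  }, integer(1))
  out <- data.frame(read_id = read_id, reference = ref,
                    start = pos - 1L, end = pos - 1L + width,
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    n_mismatches = nm, stringsAsFactors = FALSE)
  nh <- table(out$read_id)
  out$n_hits <- as.integer(nh[out$read_id])
  out[order(out$read_id, out$reference, out$start), , drop = FALSE]
}
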
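#' Read quality-control configuration
#'
#' The four discard rules applied to raw single-embryo reads, in order:
#' more than 50% of bases below Phred 5; more than 5% N bases; more than
#' 80% A+T content; a continuous run of a single base A or T covering at
#' least 30% of the read (15 bases at the 49-bp read length these defaults
#' were written for — the effective run threshold is
#' `max(min_homopolymer_run, ceiling(0.30 * read_length))`).
#'
#' @param low_quality_phred_threshold bases strictly below this Phred score
#'   count as low quality.
#' @param max_low_quality_fraction discard when the low-quality fraction
#'   exceeds this.
#' @param max_n_fraction discard when the N fraction exceeds this.
#' @param max_at_fraction discard when (A+T)/(non-N length) exceeds this.
#' @param min_homopolymer_run minimum A-run or T-run length that triggers
#'   the homopolymer rule.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(low_quality_phred_threshold = 5L,
                      max_low_quality_fraction = 0.50,
                      max_n_fraction = 0.05,
                      max_at_fraction = 0.80,
                      min_homopolymer_run = 15L) {
  fr <- c(max_low_quality_fraction, max_n_fraction, max_at_fraction)
  if (any(fr < 0 | fr > 1)) stop("QC fractions must lie in [0, 1]")
  structure(list(low_quality_phred_threshold = as.integer(low_quality_phred_threshold),
                 max_low_quality_fraction = max_low_quality_fraction,
                 max_n_fraction = max_n_fraction,
                 max_at_fraction = max_at_fraction,
                 min_homopolymer_run = as.integer(min_homopolymer_run)),
            class = "qc_config")
}

#' Apply read quality-control filters
#'
#' A read is discarded as soon as any rule fires; `reason` reports the
#' first firing rule in the order low_quality, n_bases, at_rich,
#' homopolymer (or `pass`). The A/T content rule excludes N bases from
#' both numerator and denominator.
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`
#'   (Phred+33), e.g. from [read_fastq()] or [simulate_reads()].
#' @param config a [qc_config()].
#' @return the input data.frame with added logical `keep` and factor
#'   `reason` columns.
#' @export
#' @examples
#' r <- data.frame(id = "r1", sequence = strrep("ACGG", 12),
#'                 quality = strrep("I", 48))
#' qc_filter(r)$reason
qc_filter <- function(reads, config = qc_config()) {
  if (nrow(reads) == 0) {
    reads$keep <- logical(0)
    reads$reason <- factor(character(0), levels = QC_REASONS)
    return(reads)
  }
  len <- nchar(reads$sequence)
  if (any(len == 0)) stop("empty read sequence")
  if (any(nchar(reads$quality) != len))
    stop("sequence and quality lengths differ")

  phred <- lapply(reads$quality, function(q) utf8ToInt(q) - 33L)
  frac_low <- vapply(phred, function(p)
    mean(p < config$low_quality_phred_threshold), numeric(1))

  n_N <- vapply(gregexpr("N", reads$sequence, fixed = TRUE), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1))
  frac_N <- n_N / len

  n_AT <- vapply(gregexpr("[AT]", reads$sequence), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1))
  denom <- len - n_N
  frac_AT <- ifelse(denom > 0, n_AT / denom, 0)

  run_thr <- pmax(config$min_homopolymer_run, ceiling(0.30 * len))
  has_run <- vapply(seq_len(nrow(reads)), function(i)
    grepl(sprintf("A{%d,}|T{%d,}", run_thr[i], run_thr[i]),
          reads$sequence[i]), logical(1))

  reason <- rep("pass", nrow(reads))
  reason[has_run] <- "homopolymer"
  reason[frac_AT > config$max_at_fraction] <- "at_rich"
  reason[frac_N > config$max_n_fraction] <- "n_bases"
  reason[frac_low > config$max_low_quality_fraction] <- "low_quality"

  reads$keep <- reason == "pass"
  reads$reason <- factor(reason, levels = QC_REASONS)
  reads
}

QC_REASONS <- c("low_quality", "n_bases", "at_rich", "homopolymer", "pass")

#' Tally QC discard reasons
#'
#' @param qc result of [qc_filter()].
#' @return named integer vector over the discard reasons plus `pass`.
#' @export
qc_tally <- function(qc) {
  table(qc$reason)
}
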
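#' Repeat quantification configuration
#'
#' @param concordance_threshold strict lower bound on the fraction of a
#'   read's alignments that must agree on one repeat family before the
#'   read is counted for that family ("more than 95%": 19/20 agreeing hits
#'   do NOT pass at the default 0.95).
#' @param alpha adjusted-p significance threshold for the per-family test.
#' @return an object of class `repeat_config`.
#' @export
repeat_config <- function(concordance_threshold = 0.95, alpha = 0.05) {
  if (concordance_threshold <= 0 || concordance_threshold > 1)
    stop("concordance_threshold must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(concordance_threshold = concordance_threshold,
                 alpha = alpha),
            class = "repeat_config")
}

#' Label alignment hits with the repeat family they fall in
#'
#' A hit is labeled with a family iff its interval is entirely contained
#' within a single annotated repeat interval ("full overlap"); hits
#' straddling a repeat boundary or on unannotated sequence get `NA`.
#'
#' @param alignments alignment data.frame from [map_multi()] (0-based
#'   half-open coordinates).
#' @param annotation a `GRanges` repeat annotation with `family` metadata;
#'   overlapping intervals are rejected.
#' @return character vector of families, `NA` where a hit is not fully
#'   contained in any repeat.
#' @export
annotate_hits <- function(alignments, annotation) {
  validate_annotation(annotation)
  if (nrow(alignments) == 0) return(character(0))
  q <- GenomicRanges::GRanges(alignments$reference,
                              IRanges::IRanges(alignments$start + 1L,
                                               alignments$end))
  ov <- GenomicRanges::findOverlaps(q, annotation, type = "within")
  fam <- rep(NA_character_, nrow(alignments))
  fam[S4Vectors::queryHits(ov)] <-
    S4Vectors::mcols(annotation)$family[S4Vectors::subjectHits(ov)]
  fam
}

#' Assign a multi-mapped read to a family by concordance
#'
#' A read is assigned to its majority family iff every hit carries some
#' family label and the majority fraction strictly exceeds
#' `concordance_threshold`; otherwise it is unassigned (`NA`). A tie for
#' the majority family is unassigned.
#'
#' @param labels character vector of per-hit family labels (`NA` = no
#'   repeat).
#' @param config a [repeat_config()].
#' @return a single family name or `NA_character_`.
#' @export
#' @examples
#' concordance_assign(rep("L1", 20))                  # "L1"
#' concordance_assign(c(rep("L1", 19), "B1"))         # NA: 95% is not > 95%
concordance_assign <- function(labels, config = repeat_config()) {
  if (length(labels) == 0) stop("empty label list")
  if (anyNA(labels)) return(NA_character_)
  tab <- table(labels)
  top <- max(tab)
  if (sum(tab == top) > 1L) return(NA_character_)
  if (top / length(labels) > config$concordance_threshold)
    names(tab)[which.max(tab)]
  else NA_character_
}

#' Build the repeat family count table
#'
#' Runs [annotate_hits()] and [concordance_assign()] over each sample's
#' alignment records; every assigned read increments its family count by
#' exactly one. Normalized values are raw counts divided by the per-sample
#' total of repeat-assigned reads.
#'
#' @param records named list (one element per sample) of alignment
#'   data.frames from [map_multi()].
#' @param annotation repeat annotation `GRanges` with `family` and `class`.
#' @param config a [repeat_config()].
#' @return object of class `repeat_count_table`: list with `raw` and
#'   `normalized` family x sample matrices, `totals` (per-sample assigned
#'   read counts), and `family_class` (data.frame).
#' @export
build_count_table <- function(records, annotation, config = repeat_config()) {
  validate_annotation(annotation)
  stopifnot(is.list(records), length(records) >= 1,
            !is.null(names(records)))
  families <- sort(unique(S4Vectors::mcols(annotation)$family))
  fc <- unique(data.frame(family = S4Vectors::mcols(annotation)$family,
                          class = S4Vectors::mcols(annotation)$class,
                          stringsAsFactors = FALSE))
  raw <- matrix(0L, length(families), length(records),
                dimnames = list(families, names(records)))
  for (s in names(records)) {
    aln <- records[[s]]
    if (nrow(aln) == 0) next
    fam <- annotate_hits(aln, annotation)
    assigned <- vapply(split(fam, aln$read_id), concordance_assign,
                       character(1), config = config)
    assigned <- assigned[!is.na(assigned)]
    if (length(assigned)) {
      tab <- table(assigned)
      raw[names(tab), s] <- raw[names(tab), s] + as.integer(tab)
    }
  }
  totals <- colSums(raw)
  if (all(totals == 0)) warning("no reads were assigned to any repeat family")
  normalized <- sweep(raw, 2, totals, "/")
  if (any(totals == 0)) {
    warning("sample(s) with zero repeat-mapped reads: ",
            paste(names(totals)[totals == 0], collapse = ", "))
    normalized[, totals == 0] <- NA_real_
  }
  structure(list(raw = raw, normalized = normalized, totals = totals,
                 family_class = fc[order(fc$family), , drop = FALSE]),
            class = "repeat_count_table")
}

#' Per-sample repeat class composition
#'
#' Fraction of repeat-assigned reads per repeat class (LINE/SINE/LTR/...)
#' and sample, i.e. class sums of the normalized family fractions.
#'
#' @param table a `repeat_count_table`.
#' @return class x sample matrix of fractions summing to 1 per sample.
#' @export
class_composition <- function(table) {
  if (any(table$totals == 0)) stop("sample with zero repeat-mapped reads")
  cl <- setNames(table$family_class$class, table$family_class$family)
  rowsum(table$normalized, group = cl[rownames(table$normalized)])
}

#' Per-family differential expression test
#'
#' Welch two-sample t-test on `log2(normalized fraction + 1/total)` per
#' family, mutant vs control, with Benjamini-Hochberg adjustment across
#' families. The pseudo-count `1/total` is each sample's smallest
#' representable fraction, keeping zero fractions on scale. The reported
#' `log2fc` is the difference of group means on that log scale.
#'
#' @param table a `repeat_count_table`.
#' @param genotype character vector over samples, values "control" /
#'   "mutant", aligned with the table's columns.
#' @param config a [repeat_config()].
#' @return data.frame: family, class, log2fc, p, padj, significant.
#' @export
test_families <- function(table, genotype, config = repeat_config()) {
  stopifnot(length(genotype) == ncol(table$raw))
  genotype <- as.character(genotype)
  if (!all(genotype %in% c("control", "mutant")))
    stop("genotype must be 'control' or 'mutant'")
  if (min(table(genotype)) < 2) stop("need >= 2 samples per group")
  if (any(table$totals == 0)) stop("sample with zero repeat-mapped reads")
  pseudo <- 1 / table$totals
  lf <- log2(sweep(table$normalized, 2, pseudo, "+"))
  ctrl <- genotype == "control"
  res <- t(apply(lf, 1, function(x) {
    a <- x[!ctrl]; b <- x[ctrl]
    lfc <- mean(a) - mean(b)
    if (var(a) + var(b) == 0) {
      p <- if (lfc == 0) 1 else 0
    } else {
      p <- t.test(a, b)$p.value
    }
    c(log2fc = lfc, p = p)
  }))
  padj <- p.adjust(res[, "p"], method = "BH")
  cl <- setNames(table$family_class$class, table$family_class$family)
  data.frame(family = rownames(lf),
             class = unname(cl[rownames(lf)]),
             log2fc = res[, "log2fc"],
             p = res[, "p"],
             padj = padj,
             significant = padj < config$alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a repeat count table and test results as TSV
#'
#' @param table a `repeat_count_table`.
#' @param tests optional result of [test_families()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(table, path, tests = NULL) {
  df <- data.frame(family = rownames(table$raw),
                   class = setNames(table$family_class$class,
                                    table$family_class$family)[rownames(table$raw)],
                   table$raw,
                   check.names = FALSE, stringsAsFactors = FALSE)
  norm <- table$normalized
  colnames(norm) <- paste0("norm_", colnames(norm))
  df <- cbind(df, norm)
  if (!is.null(tests))
    df <- cbind(df, tests[match(df$family, tests$family),
                          c("log2fc", "p", "padj", "significant")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
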
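#' Read a wave catalogue from TSV
#'
#' @param path TSV with columns `gene_id`, `category`; categories must be
#'   drawn from the six-wave vocabulary (maternal, minor_ZGA,
#'   1C_transient, major_ZGA, 2C_transient, MGA). Duplicate gene ids are
#'   an error; an empty file yields an empty catalogue with a warning.
#' @return a `wave_catalogue` data.frame.
#' @export
read_catalogue <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(df)))
    stop("catalogue must have columns gene_id, category")
  if (nrow(df) == 0) warning("empty wave catalogue")
  bad <- setdiff(unique(df$category), WAVE_CATEGORIES)
  if (length(bad))
    stop("unknown wave category: ", paste(bad, collapse = ", "))
  out <- data.frame(gene_id = df$gene_id,
                    category = factor(df$category, levels = WAVE_CATEGORIES),
                    stringsAsFactors = FALSE)
  class(out) <- c("wave_catalogue", "data.frame")
  validate_wave_catalogue(out)
}

#' Cross-tabulate DE classes against wave categories
#'
#' Each catalogue gene lands in exactly one cell: its DE class (up / down /
#' similar) when present in the differential expression result, or
#' `not_in_data` when absent (e.g. removed by the zero-count or top-60%
#' filters). Row sums equal the catalogue category sizes by construction.
#'
#' @param de a `de_result` from [run_de()] (or any data.frame with `gene`
#'   and `de_class`).
#' @param catalogue a `wave_catalogue`.
#' @return object of class `overlap_table`: data.frame with one row per
#'   category and columns up, down, similar, not_in_data, total.
#' @export
build_overlap_table <- function(de, catalogue) {
  validate_wave_catalogue(catalogue)
  cls <- as.character(de$de_class)[match(catalogue$gene_id, de$gene)]
  cls[is.na(cls)] <- "not_in_data"
  cls <- factor(cls, levels = c("up", "down", "similar", "not_in_data"))
  tab <- table(catalogue$category, cls)
  out <- as.data.frame.matrix(tab)
  out <- cbind(category = rownames(out), out, total = rowSums(out))
  rownames(out) <- NULL
  class(out) <- c("overlap_table", "data.frame")
  out
}

#' Percent of each category in each DE class
#'
#' `round(100 * cell / total)` with halves away from zero, matching the
#' printed integer percentages of wave-overlap tables (e.g. 360 of 975
#' maternal genes up = 37%).
#'
#' @param table an `overlap_table`.
#' @return data.frame: category, pct_up, pct_down, pct_similar.
#' @export
category_percentages <- function(table) {
  if (any(table$total <= 0)) stop("category with non-positive total")
  data.frame(category = table$category,
             pct_up = round_half_away(100 * table$up / table$total),
             pct_down = round_half_away(100 * table$down / table$total),
             pct_similar = round_half_away(100 * table$similar / table$total),
             stringsAsFactors = FALSE)
}

#' Catalogue coverage of the dataset
#'
#' Percent of each category's genes present in the DE result,
#' `(total - not_in_data) / total * 100`, and the minimum over categories.
#'
#' @param table an `overlap_table`.
#' @return list with `per_category` (named percents) and `minimum`.
#' @export
coverage_stats <- function(table) {
  if (any(table$total <= 0)) stop("category with non-positive total")
  pct <- 100 * (table$total - table$not_in_data) / table$total
  names(pct) <- as.character(table$category)
  list(per_category = pct, minimum = min(pct))
}

#' Summarize an overlap table
#'
#' @param table an `overlap_table`.
#' @return list with `changed` (up + down over all categories),
#'   `considered` (genes present in the data), and `percent_changed`
#'   (rounded integer percent of considered genes that changed).
#' @export
overlap_summary <- function(table) {
  changed <- sum(table$up) + sum(table$down)
  considered <- sum(table$total) - sum(table$not_in_data)
  list(changed = changed, considered = considered,
       percent_changed = round_half_away(100 * changed / considered))
}

#' Stage overlap of up- and downregulated gene sets
#'
#' Venn-style counts of genes called up (resp. down) in both stages or in
#' one stage only, e.g. oocyte vs two-cell embryo.
#'
#' @param de_a,de_b two `de_result` objects sharing a gene id namespace.
#' @return data.frame with rows `up`, `down` and columns `both`, `a_only`,
#'   `b_only`.
#' @export
stage_overlap <- function(de_a, de_b) {
  sets <- function(de, what) de$gene[as.character(de$de_class) == what]
  row <- function(what) {
    a <- sets(de_a, what); b <- sets(de_b, what)
    c(both = length(intersect(a, b)),
      a_only = length(setdiff(a, b)),
      b_only = length(setdiff(b, a)))
  }
  out <- as.data.frame(rbind(up = row("up"), down = row("down")))
  out
}

#' Write an overlap table as TSV
#'
#' Columns follow the conventional order Up, Down, Similar, Not in our
#' data, Total.
#'
#' @param table an `overlap_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap_table <- function(table, path) {
  df <- data.frame(category = table$category, up = table$up,
                   down = table$down, similar = table$similar,
                   not_in_data = table$not_in_data, total = table$total)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
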
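make_49mer <- function() {
  # 49 bases, balanced composition, no A/T runs
  paste(rep("ACGGTCGG", 7), collapse = "") |> substr(1, 49)
}

test_that("QC discards reads by the four rules in order", {
  base <- make_49mer()
  q_hi <- strrep("I", 49)
  # 25 of 49 bases (51%) below Phred 5 ('#' is Phred 2)
  q_low <- paste0(strrep("#", 25), strrep("I", 24))
  seq_n <- paste0(strrep("N", 3), substr(base, 4, 49))          # 6.1% N
  seq_at <- paste(rep("ATTA", 13), collapse = "") |> substr(1, 49) # AT-rich
  seq_run <- paste0(strrep("A", 15), substr(base, 16, 49))      # 15-base run

  reads <- random_read_df(c(base, base, seq_n, seq_at, seq_run),
                          c(q_hi, q_low, q_hi, q_hi, q_hi))
  qc <- qc_filter(reads)
  expect_equal(as.character(qc$reason),
               c("pass", "low_quality", "n_bases", "at_rich", "homopolymer"))
  expect_equal(qc$keep, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("QC reports the first firing rule when several apply", {
  # all-A read with bad quality: low_quality precedes at_rich/homopolymer
  reads <- random_read_df(strrep("A", 49),
                          paste0(strrep("#", 26), strrep("I", 23)))
  expect_equal(as.character(qc_filter(reads)$reason), "low_quality")
  # all-A read with good quality: at_rich precedes homopolymer... unless
  # the rule order says n_bases/at_rich first; homopolymer fires last
  reads2 <- random_read_df(strrep("A", 49))
  expect_equal(as.character(qc_filter(reads2)$reason), "at_rich")
})

test_that("QC boundary cases: exactly-at-threshold reads are kept", {
  base <- make_49mer()
  # exactly 50% low quality bases of 48 -> not more than 50%
  reads <- random_read_df(substr(base, 1, 48),
                          paste0(strrep("#", 24), strrep("I", 24)))
  expect_true(qc_filter(reads)$keep)
  # 14-base A run in 49 bases: below both 15 and ceil(0.3 * 49)
  r2 <- random_read_df(paste0(strrep("A", 14), "C", strrep("G", 17),
                              substr(base, 33, 49)))
  expect_true(qc_filter(r2)$keep)
})

test_that("QC is idempotent and N bases are excluded from the AT rate", {
  set.seed(7)
  seqs <- vapply(1:60, function(i) random_dna_str(49), character(1))
  qc1 <- qc_filter(random_read_df(seqs))
  survivors <- qc1[qc1$keep, c("id", "sequence", "quality")]
  qc2 <- qc_filter(survivors)
  expect_true(all(qc2$keep))

  # 10 A + 2 C + 37 N: AT rate = 10/12 = 83% of non-N bases
  r <- random_read_df(paste0(strrep("A", 10), "CC", strrep("N", 37)))
  expect_equal(as.character(qc_filter(r)$reason), "n_bases")
  r2 <- qc_filter(r, qc_config(max_n_fraction = 1))
  expect_equal(as.character(r2$reason), "at_rich")

  expect_error(qc_filter(random_read_df("")), "empty")
})

test_that("rRNA filter removes unique best seed matches only", {
  set.seed(11)
  decoy1 <- random_dna_str(300)
  decoy2 <- random_dna_str(300)
  refs <- Biostrings::DNAStringSet(c(rRNA_a = decoy1, rRNA_b = decoy2))
  cfg <- map_config(rrna_references = refs)

  exact <- substr(decoy1, 50, 98)          # verbatim from a decoy
  nowhere <- random_dna_str(49)            # random, no similarity
  # seed present identically in both decoys -> two equal best alignments
  shared_seed <- substr(decoy1, 10, 37)
  refs_shared <- Biostrings::DNAStringSet(c(
    rRNA_a = decoy1,
    rRNA_b = paste0(shared_seed, substr(decoy2, 29, 300))))
  cfg_shared <- map_config(rrna_references = refs_shared)
  ambiguous <- paste0(shared_seed, substr(random_dna_str(21), 1, 21))

  out <- filter_rrna(random_read_df(c(exact, nowhere)), cfg)
  expect_equal(out$n_discarded, 1)
  expect_equal(out$kept$sequence, nowhere)

  out2 <- filter_rrna(random_read_df(ambiguous), cfg_shared)
  expect_equal(out2$n_discarded, 0)  # non-unique best is kept

  expect_error(filter_rrna(random_read_df(exact), map_config()),
               "empty")
})

test_that("rRNA filter tolerates up to the seed mismatch limit", {
  set.seed(12)
  decoy <- random_dna_str(300)
  cfg <- map_config(rrna_references = c(rRNA_a = decoy))
  read <- substr(decoy, 21, 69)
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- chartr("ACGT", "GTAC", ch[pos])
    paste(ch, collapse = "")
  }
  two_mm <- mutate_at(read, c(3, 17))    # 2 seed mismatches: discarded
  three_mm <- mutate_at(read, c(3, 17, 25))  # 3: kept
  out <- filter_rrna(random_read_df(c(two_mm, three_mm)), cfg)
  expect_equal(out$n_discarded, 1)
  expect_equal(out$kept$sequence, three_mm)
})

test_that("multi-mapper reports all exact locations on both strands", {
  cfg <- repeat_genome_config(n_families = 1, copies_per_family = 3,
                              copy_length = 120, genome_length = 4000,
                              intra_family_identity = 1, seed = 21)
  sim <- simulate_repeat_genome(cfg)
  genome <- as.character(sim$genome[["chr1"]])
  st <- GenomicRanges::start(sim$annotation)[1]
  read <- substring(genome, st, st + 48)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(read, "")[[1]]), collapse = ""))
  absent <- strrep("ACGT", 13) |> substr(1, 49)

  mm <- map_multi(random_read_df(c(read, rc, absent)), sim$genome)
  expect_equal(unname(mm$tally),
               c(2L, 1L, 0L), ignore_attr = TRUE)  # mapped, unmapped, over_cap
  by_read <- split(mm$alignments, mm$alignments$read_id)
  expect_equal(nrow(by_read[[1]]), 3)
  # the reverse-complement read hits the same 3 loci on the minus strand
  expect_equal(by_read[[2]]$start, by_read[[1]]$start)
  expect_equal(unique(by_read[[2]]$strand), "-")
})

test_that("location cap drops reads with too many hits", {
  cfg <- repeat_genome_config(n_families = 1, copies_per_family = 6,
                              copy_length = 120, genome_length = 4000,
                              intra_family_identity = 1, seed = 22)
  sim <- simulate_repeat_genome(cfg)
  genome <- as.character(sim$genome[["chr1"]])
  st <- GenomicRanges::start(sim$annotation)[1]
  read <- substring(genome, st, st + 48)
  mm5 <- map_multi(random_read_df(read), sim$genome,
                   map_config(max_locations = 5))
  expect_equal(unname(mm5$tally["over_cap"]), 1L)
  expect_equal(nrow(mm5$alignments), 0)
  mm6 <- map_multi(random_read_df(read), sim$genome,
                   map_config(max_locations = 6))
  expect_equal(nrow(mm6$alignments), 6)
})

test_that("multi-mapper equals the sliding-window oracle on random reads", {
  set.seed(23)
  cfg <- repeat_genome_config(n_families = 2, copies_per_family = 5,
                              copy_length = 150, genome_length = 20000,
                              intra_family_identity = 1, seed = 23)
  sim <- simulate_repeat_genome(cfg)
  genome <- as.character(sim$genome[["chr1"]])
  pos <- sample(nchar(genome) - 49, 25)
  seqs <- c(substring(genome, pos, pos + 48),
            vapply(1:5, function(i) random_dna_str(49), character(1)))
  reads <- random_read_df(seqs)
  mm <- map_multi(reads, sim$genome)
  for (i in seq_len(nrow(reads))) {
    expected <- oracle_scan(reads$sequence[i], genome)
    got <- mm$alignments[mm$alignments$read_id == reads$id[i],
                         c("reference", "start", "end", "strand")]
    rownames(got) <- NULL
    if (is.null(expected)) {
      expect_equal(nrow(got), 0)
    } else {
      rownames(expected) <- NULL
      expect_equal(got, expected)
    }
  }
})

test_that("mapper output is independent of read order", {
  set.seed(24)
  cfg <- repeat_genome_config(n_families = 1, copies_per_family = 4,
                              copy_length = 120, genome_length = 8000,
                              intra_family_identity = 1, seed = 24)
  sim <- simulate_repeat_genome(cfg)
  genome <- as.character(sim$genome[["chr1"]])
  pos <- sample(nchar(genome) - 49, 10)
  reads <- random_read_df(substring(genome, pos, pos + 48))
  fwd <- map_multi(reads, sim$genome)
  shuf <- map_multi(reads[sample(nrow(reads)), ], sim$genome)
  expect_equal(fwd$alignments, shuf$alignments)
  expect_equal(fwd$tally, shuf$tally)
})

test_that("FASTQ and SAM round-trips preserve records", {
  set.seed(25)
  reads <- random_read_df(vapply(1:5, function(i) random_dna_str(49),
                                 character(1)))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, reads[, c("id", "sequence", "quality")])

  cfg <- repeat_genome_config(n_families = 1, copies_per_family = 3,
                              copy_length = 120, genome_length = 4000,
                              intra_family_identity = 1, seed = 26)
  sim <- simulate_repeat_genome(cfg)
  genome <- as.character(sim$genome[["chr1"]])
  st <- GenomicRanges::start(sim$annotation)[1:2]
  mm <- map_multi(random_read_df(substring(genome, st, st + 48)), sim$genome)
  sam <- tempfile(fileext = ".sam")
  write_sam(mm$alignments, c(chr1 = nchar(genome)), sam)
  back_aln <- read_sam(sam)
  rownames(back_aln) <- NULL
  expect_equal(back_aln, mm$alignments)
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ\tSN:chr1", lines)))
})
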
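test_that("bismark CX lines are parsed with 1-based to 0-based conversion", {
  f <- write_bismark_cx("chr1\t101\t+\t3\t7\tCG\tCGG")
  tbl <- read_cytosine_report(f, "bismark_cx")
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$chrom, "chr1")
  expect_equal(tbl$pos, 100L)
  expect_equal(tbl$strand, "+")
  expect_equal(tbl$context, "CpG")
  expect_equal(tbl$motif, "CGG")
  expect_equal(tbl$m, 3L)
  expect_equal(tbl$n, 10L)

  # CHG/CHH both collapse to CpH; m = n boundary is accepted
  f2 <- write_bismark_cx(c("chr1\t5\t-\t5\t0\tCHH\tCAC",
                           "chr2\t9\t+\t0\t4\tCHG\tCAG"))
  tbl2 <- read_cytosine_report(f2, "bismark_cx")
  expect_equal(tbl2$context, c("CpH", "CpH"))
  expect_equal(tbl2$m, c(5L, 0L))
  expect_equal(tbl2$n, c(5L, 4L))
})

test_that("empty and malformed reports are handled", {
  f <- write_bismark_cx(character(0))
  expect_equal(nrow(read_cytosine_report(f, "bismark_cx")), 0)

  f2 <- write_bismark_cx(c("chr1\t10\t+\t1\t2\tCG\tCGA",
                           "chr1\tnotanumber\t+\t1\t2\tCG\tCGA"))
  suppressWarnings(expect_error(read_cytosine_report(f2, "bismark_cx"), "line 2"))
})

test_that("generic TSV round-trips through write_tracks", {
  set.seed(4)
  n <- sample(1:30, 100, replace = TRUE)
  tbl <- mk_methylome(pos = seq(0, 990, 10), m = rbinom(100, n, 0.3), n = n,
                      context = sample(c("CpG", "CpH"), 100, replace = TRUE),
                      motif = "CAC")
  f <- tempfile(fileext = ".tsv")
  write_tracks(tbl, f, "tsv")
  back <- read_cytosine_report(f, "generic_tsv")
  expect_equal(as.data.frame(back), as.data.frame(tbl), ignore_attr = TRUE)
})

test_that("mapper consensus keeps sites covered > min_reads in >= min_mappers", {
  site <- function(mapper, n_reads) {
    mk_methylome(pos = 100, mapper = mapper, m = 1, n = n_reads)
  }
  # n = 6 in 2 of 3 mappers: retained with both counts entries
  merged <- merge_mapper_reports(list(site("a", 6), site("b", 6)))
  expect_equal(nrow(merged), 2)
  expect_equal(sort(merged$mapper), c("a", "b"))

  # n = 6 in only 1 mapper: dropped
  expect_equal(nrow(merge_mapper_reports(list(site("a", 6)))), 0)

  # n = 5 in 3 mappers: 5 is not strictly more than 5, dropped
  expect_equal(nrow(merge_mapper_reports(list(site("a", 5), site("b", 5), site("c", 5)))), 0)

  # min_mappers = 1 admits single-source data
  expect_equal(nrow(merge_mapper_reports(list(site("a", 6)), min_mappers = 1)), 1)
})

test_that("mapper merge is order-insensitive in its retained site set", {
  set.seed(9)
  mk <- function(mapper) {
    pos <- sort(sample(0:500, 60))
    n <- sample(0:12, 60, replace = TRUE)
    mk_methylome(pos = pos, mapper = mapper, m = pmin(n, 1), n = n)
  }
  tabs <- list(mk("a"), mk("b"), mk("c"))
  m1 <- merge_mapper_reports(tabs)
  m2 <- merge_mapper_reports(rev(tabs))
  k1 <- unique(m1[c("chrom", "pos", "strand")])
  k2 <- unique(m2[c("chrom", "pos", "strand")])
  expect_equal(k1, k2)
})

test_that("inconsistent annotation across mappers is rejected", {
  a <- mk_methylome(pos = 10, context = "CpG", mapper = "a", m = 1, n = 9)
  b <- mk_methylome(pos = 10, context = "CpH", mapper = "b", m = 1, n = 9)
  expect_error(merge_mapper_reports(list(a, b)), "inconsistent context")
})

test_that("context annotation recomputes motif and context from sequence", {
  # positions:       0123456789
  genome <- Biostrings::DNAStringSet(c(toy = "ACACGTCCGA"))
  tbl <- mk_methylome(chrom = "toy", pos = c(1, 3, 8), strand = c("+", "+", "-"),
                      context = "CpH", m = 0, n = 5)
  ann <- annotate_context(tbl, genome)
  # pos 1 '+': C A C -> CpH, motif CAC
  expect_equal(ann$motif[ann$pos == 1], "CAC")
  expect_equal(ann$context[ann$pos == 1], "CpH")
  # pos 3 '+': C G T -> CpG
  expect_equal(ann$context[ann$pos == 3], "CpG")
  expect_equal(ann$motif[ann$pos == 3], "CGT")
  # pos 8 '-': plus-strand G at 8; plus triplet 6..8 = CCG -> revcomp CGG, CpG
  expect_equal(ann$motif[ann$pos == 8], "CGG")
  expect_equal(ann$context[ann$pos == 8], "CpG")
})

test_that("ambiguous or non-C reference sites are dropped; bounds checked", {
  genome <- Biostrings::DNAStringSet(c(toy = "ACNCGTAC"))
  # pos 1 '+': next base is N -> dropped as ambiguous
  tbl <- mk_methylome(chrom = "toy", pos = 1, m = 0, n = 5)
  expect_message(ann <- annotate_context(tbl, genome), "dropped 1")
  expect_equal(nrow(ann), 0)
  # pos 0 is 'A', not a cytosine -> dropped
  tbl2 <- mk_methylome(chrom = "toy", pos = 0, m = 0, n = 5)
  expect_message(ann2 <- annotate_context(tbl2, genome), "dropped 1")
  expect_equal(nrow(ann2), 0)
  # beyond chromosome end -> bounds error
  tbl3 <- mk_methylome(chrom = "toy", pos = 99, m = 0, n = 5)
  expect_error(annotate_context(tbl3, genome), "beyond")
})

test_that("annotated context is CpG iff the strand-local dinucleotide is CG", {
  set.seed(21)
  for (rep in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(seq, "r"))
    chars <- strsplit(seq, "")[[1]]
    # all plus-strand cytosines away from the edges
    pos_p <- setdiff(which(chars == "C") - 1L, c(0:1, 57:59))
    pos_m <- setdiff(which(chars == "G") - 1L, c(0:1, 57:59))
    tbl <- mk_methylome(chrom = "r", pos = c(pos_p, pos_m),
                        strand = rep(c("+", "-"), c(length(pos_p), length(pos_m))),
                        m = 0, n = 3)
    ann <- suppressMessages(annotate_context(tbl, genome))
    # string-scan oracle
    for (i in seq_len(nrow(ann))) {
      p <- ann$pos[i]
      din <- if (ann$strand[i] == "+") paste0(chars[p + 1], chars[p + 2])
             else paste0(chartr("ACGT", "TGCA", chars[p + 1]),
                         chartr("ACGT", "TGCA", chars[p]))
      expect_equal(ann$context[i] == "CpG", din == "CG")
      expect_equal(substr(ann$motif[i], 1, 1), "C")
    }
  }
})

test_that("sex chromosomes are removed by default", {
  tbl <- mk_methylome(chrom = c("chr1", "chrX", "chrY"), pos = c(1, 2, 3),
                      m = 0, n = 5)
  expect_message(out <- filter_chromosomes(tbl), "removed 2")
  expect_equal(out$chrom, "chr1")
  # empty exclusion is the identity
  expect_equal(nrow(filter_chromosomes(tbl, exclude = character(0))), 3)
  # all sites removed: empty table with a warning
  tblx <- mk_methylome(chrom = "chrX", pos = 1, m = 0, n = 5)
  expect_warning(suppressMessages(out2 <- filter_chromosomes(tblx)), "no sites")
  expect_equal(nrow(out2), 0)
})

test_that("BED output is 0-based half-open with state as name", {
  dmr <- tibble::tibble(chrom = "chr1", start = 1800L, end = 2520L, state = "N")
  f <- tempfile(fileext = ".bed")
  write_tracks(dmr, f, "bed")
  expect_equal(readLines(f), "chr1\t1800\t2520\tN")
  # empty set gives an empty file
  write_tracks(dmr[0, ], f, "bed")
  expect_equal(length(readLines(f)), 0)
  back <- read_bed(write_tracks(dmr, f, "bed"))
  expect_equal(back$start, 1800L)
  expect_equal(back$end, 2520L)
})

test_that("count validation rejects m > n", {
  expect_error(mk_methylome(pos = 1, m = 6, n = 5), "0 <= m <= n")
})
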
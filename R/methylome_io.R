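#' Per-cytosine methylome tables
#'
#' A methylome is an ordinary tibble with one row per cytosine site and
#' per source mapper, using 0-based positions throughout:
#'
#' * `chrom`   -- chromosome name
#' * `pos`     -- 0-based position of the cytosine
#' * `strand`  -- `"+"` or `"-"`
#' * `context` -- `"CpG"` or `"CpH"` (CHG/CHH are both CpH)
#' * `motif`   -- trinucleotide read 5'->3' on the cytosine's own strand
#'   (always starts with `C`), or `NA` when unknown
#' * `mapper`  -- identifier of the read source the counts came from
#' * `m`, `n`  -- methylated (unconverted) and total read counts
#'
#' Sample-level metadata (sample id, bisulfite non-conversion rate) travels
#' as the tibble attributes `sample_id` and `nonconversion_rate`; functions
#' that need the non-conversion rate also accept it explicitly.
#'
#' @name methylome
NULL

.methylome_cols <- c("chrom", "pos", "strand", "context", "motif", "mapper", "m", "n")

new_methylome <- function(df, sample_id = NA_character_, nonconversion_rate = NA_real_) {
  df <- as_tibble(df)
  for (col in .methylome_cols) {
    if (!col %in% names(df)) {
      df[[col]] <- switch(col, motif = NA_character_, mapper = "default",
                          stop("missing methylome column: ", col))
    }
  }
  df <- df[.methylome_cols]
  validate_methylome(df)
  attr(df, "sample_id") <- sample_id
  attr(df, "nonconversion_rate") <- nonconversion_rate
  df
}

validate_methylome <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$m > df$n | df$m < 0)
  if (length(bad) > 0) {
    stop("invalid counts (need 0 <= m <= n) at row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(df$context %in% c("CpG", "CpH"))) stop("context must be 'CpG' or 'CpH'")
  if (anyDuplicated(df[c("chrom", "pos", "strand", "mapper")]) > 0) {
    stop("duplicate (chrom, pos, strand, mapper) keys in methylome table")
  }
  invisible(df)
}

#' Read a per-cytosine bisulfite report
#'
#' Reads either a Bismark cytosine/CX report (tab-separated, no header:
#' chromosome, 1-based position, strand, methylated count, unmethylated
#' count, context `CG`/`CHG`/`CHH`, trinucleotide) or a generic TSV with a
#' header and columns `chrom, pos, strand, context, m, n` (plus optional
#' `motif`, `mapper`), where `pos` is already 0-based. Bismark positions are
#' converted to 0-based on read; `CHG`/`CHH` contexts are collapsed to
#' `CpH`.
#'
#' @param path Path to the report file.
#' @param dialect `"bismark_cx"` or `"generic_tsv"`.
#' @param sample_id Sample identifier stored as a table attribute.
#' @param mapper Read-source label for the counts (e.g. the mapper name).
#' @param nonconversion_rate Optional bisulfite non-conversion rate `R`,
#'   stored as a table attribute.
#' @return A [methylome] tibble with one row per (chrom, pos, strand).
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t101\t+\t3\t7\tCG\tCGG", f)
#' read_cytosine_report(f, "bismark_cx")
#' @export
read_cytosine_report <- function(path, dialect = c("bismark_cx", "generic_tsv"),
                                 sample_id = NA_character_, mapper = "mapper1",
                                 nonconversion_rate = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bismark_cx") {
    df <- readr::read_tsv(path, col_names = c("chrom", "pos1", "strand",
                                              "count_m", "count_u", "ctx", "tri"),
                          col_types = "cicddcc", progress = FALSE,
                          na = character())
    .check_parse(df, path)
    if (nrow(df) > 0 && (any(df$count_m != floor(df$count_m)) ||
                         any(df$count_u != floor(df$count_u)))) {
      bad <- which(df$count_m != floor(df$count_m) | df$count_u != floor(df$count_u))[1]
      stop("malformed line ", bad, " in ", path, ": non-integer counts")
    }
    out <- tibble(chrom = df$chrom, pos = df$pos1 - 1L, strand = df$strand,
                  context = ifelse(df$ctx == "CG", "CpG", "CpH"),
                  motif = df$tri, mapper = mapper,
                  m = as.integer(df$count_m),
                  n = as.integer(df$count_m + df$count_u))
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      strand = readr::col_character(), context = readr::col_character(),
      m = readr::col_integer(), n = readr::col_integer(),
      .default = readr::col_character()), progress = FALSE)
    .check_parse(df, path)
    out <- tibble(chrom = df$chrom, pos = df$pos, strand = df$strand,
                  context = df$context,
                  motif = if ("motif" %in% names(df)) df$motif else NA_character_,
                  mapper = if ("mapper" %in% names(df)) df$mapper else mapper,
                  m = df$m, n = df$n)
  }
  new_methylome(out, sample_id = sample_id, nonconversion_rate = nonconversion_rate)
}

.check_parse <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    stop("malformed line ", pr$row[1], " in ", path, ": ", pr$expected[1],
         " but got '", pr$actual[1], "'")
  }
}

#' Merge per-mapper methylomes with consensus site filtering
#'
#' Combines one methylome table per read mapper into a single table,
#' retaining only sites supported by sufficiently many mappers: a site is
#' kept when at least `min_mappers` of the source tables cover it with more
#' than `min_reads` reads (strictly more). All available counts rows of a
#' retained site are kept, in the order the tables are given.
#'
#' @param tables List of [methylome] tibbles for one sample.
#' @param min_reads Coverage a mapper must exceed (strict `>`) to support a
#'   site. Default 5.
#' @param min_mappers Minimum number of supporting mappers. Default 2; set
#'   to 1 for single-source data such as simulator output.
#' @return A [methylome] tibble with the retained sites.
#' @export
merge_mapper_reports <- function(tables, min_reads = 5, min_mappers = 2) {
  stopifnot(is.list(tables), length(tables) >= 1)
  sids <- unique(unlist(lapply(tables, attr, "sample_id")))
  sids <- sids[!is.na(sids)]
  if (length(sids) > 1) stop("tables belong to different samples: ", paste(sids, collapse = ", "))
  rs <- unique(unlist(lapply(tables, attr, "nonconversion_rate")))
  rs <- rs[!is.na(rs)]

  tagged <- purrr::imap(tables, function(t, i) {
    t <- as_tibble(t)
    t$.src <- i
    t
  })
  all <- dplyr::bind_rows(tagged)
  key <- c("chrom", "pos", "strand")

  ann <- dplyr::distinct(all, .data$chrom, .data$pos, .data$strand,
                         .data$context, .data$motif)
  dup <- ann %>%
    dplyr::count(.data$chrom, .data$pos, .data$strand) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("inconsistent context/motif across mappers at ", dup$chrom[1], ":", dup$pos[1])
  }

  keep <- all %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) %>%
    dplyr::summarise(n_support = sum(.data$n > min_reads), .groups = "drop") %>%
    dplyr::filter(.data$n_support >= min_mappers) %>%
    dplyr::select(-"n_support")

  out <- dplyr::inner_join(all, keep, by = key) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$strand, .data$.src) %>%
    dplyr::select(-".src")
  new_methylome(out,
                sample_id = if (length(sids) == 1) sids else NA_character_,
                nonconversion_rate = if (length(rs) == 1) rs else NA_real_)
}

#' Recompute context and motif from a genome sequence
#'
#' Looks up each cytosine in the genome and re-derives its trinucleotide
#' motif and CpG/CpH context on the cytosine's own strand (minus-strand
#' motifs are reverse-complemented so that every motif reads 5'->3' and
#' starts with `C`). Sites whose reference base is not a cytosine on the
#' recorded strand, or whose context/motif involves an `N` or runs off the
#' chromosome end, are dropped with a message reporting how many.
#'
#' @param table A [methylome] tibble.
#' @param genome_fasta Path to a FASTA file containing every chromosome in
#'   `table`, or a [Biostrings::DNAStringSet].
#' @return The table with `context` and `motif` recomputed.
#' @export
annotate_context <- function(table, genome_fasta) {
  genome <- if (inherits(genome_fasta, "DNAStringSet")) genome_fasta
            else Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(table$chrom), names(genome))
  if (length(missing_chr) > 0) stop("chromosome(s) not in FASTA: ", paste(missing_chr, collapse = ", "))

  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(table$pos >= lens[table$chrom] | table$pos < 0)) {
    stop("site position beyond chromosome end")
  }

  ctx <- motif <- rep(NA_character_, nrow(table))
  keep <- rep(TRUE, nrow(table))
  for (ch in unique(table$chrom)) {
    idx <- which(table$chrom == ch)
    seq <- as.character(genome[[ch]])
    len <- lens[[ch]]
    pos <- table$pos[idx]
    plus <- table$strand[idx] == "+"

    base <- substring(seq, pos + 1, pos + 1)
    ok_ref <- ifelse(plus, base == "C", base == "G")

    nxt <- ifelse(plus,
                  ifelse(pos + 1 < len, substring(seq, pos + 2, pos + 2), "N"),
                  ifelse(pos - 1 >= 0, substring(seq, pos, pos), "N"))
    # next base on the cytosine's strand; minus strand reads the complement
    nxt_local <- ifelse(plus, nxt, chartr("ACGT", "TGCA", nxt))
    ok_ctx <- nxt_local %in% c("A", "C", "G", "T")

    tri_plus <- ifelse(plus & pos + 2 < len, substring(seq, pos + 1, pos + 3), NA)
    tri_minus_src <- ifelse(!plus & pos - 2 >= 0, substring(seq, pos - 1, pos + 1), NA)
    tri <- ifelse(plus, tri_plus, .revcomp(tri_minus_src))
    ok_tri <- !is.na(tri) & !grepl("[^ACGT]", tri)

    keep[idx] <- ok_ref & ok_ctx & ok_tri
    ctx[idx] <- ifelse(nxt_local == "G", "CpG", "CpH")
    motif[idx] <- tri
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) message("annotate_context: dropped ", n_drop,
                          " site(s) with non-C reference or ambiguous context")
  out <- table
  out$context <- ctx
  out$motif <- motif
  out <- out[keep, , drop = FALSE]
  new_methylome(out, sample_id = attr(table, "sample_id"),
                nonconversion_rate = attr(table, "nonconversion_rate"))
}

.revcomp <- function(x) {
  out <- vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1))
  unname(out)
}

#' Remove sites on excluded chromosomes
#'
#' Drops every site on the excluded chromosomes (by default the sex
#' chromosomes, to avoid sex-driven methylation bias) and reports how many
#' sites were removed.
#'
#' @param table A [methylome] tibble.
#' @param exclude Chromosome names to drop. Default `chrX/chrY/X/Y`.
#' @return The filtered [methylome] tibble (possibly empty).
#' @export
filter_chromosomes <- function(table, exclude = c("chrX", "chrY", "X", "Y")) {
  drop <- table$chrom %in% exclude
  if (any(drop)) message("filter_chromosomes: removed ", sum(drop), " site(s) on ",
                         paste(intersect(unique(table$chrom), exclude), collapse = ", "))
  out <- table[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("no sites remain after chromosome filtering")
  new_methylome(out, sample_id = attr(table, "sample_id"),
                nonconversion_rate = attr(table, "nonconversion_rate"))
}

#' Pool read counts across mappers
#'
#' Collapses a multi-mapper methylome to one row per site with counts
#' summed over mappers; methylation statistics are invariant to how reads
#' are split across mappers at fixed pooled counts.
#'
#' @param table A [methylome] tibble.
#' @return A tibble with one row per (chrom, pos, strand) and pooled `m`, `n`.
#' @export
pool_counts <- function(table) {
  df <- as_tibble(table)
  if (anyDuplicated(df[c("chrom", "pos", "strand")]) == 0) {
    # already one row per site: nothing to pool
    out <- dplyr::arrange(df[c("chrom", "pos", "strand", "context", "motif", "m", "n")],
                          .data$chrom, .data$pos, .data$strand)
  } else {
    out <- df %>%
      dplyr::group_by(.data$chrom, .data$pos, .data$strand, .data$context, .data$motif) %>%
      dplyr::summarise(m = sum(.data$m), n = sum(.data$n), .groups = "drop") %>%
      dplyr::arrange(.data$chrom, .data$pos, .data$strand)
  }
  attr(out, "sample_id") <- attr(table, "sample_id")
  attr(out, "nonconversion_rate") <- attr(table, "nonconversion_rate")
  out
}

#' Write genomic tables as BED, bedGraph, or TSV
#'
#' BED output is 0-based half-open. For `format = "tsv"` a methylome table
#' round-trips exactly through [read_cytosine_report()] with the
#' `generic_tsv` dialect.
#'
#' @param x A tibble: a [methylome], a segment/DMR table with
#'   `chrom/start/end` (+ optional `name` or `state` used as the BED name
#'   and optional `score`), or, for bedGraph, a table with
#'   `chrom/start/end/value`.
#' @param path Output file.
#' @param format `"tsv"`, `"bed"`, or `"bedgraph"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(x, path, format = c("tsv", "bed", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(x), path, progress = FALSE)
  } else if (format == "bed") {
    name <- if ("name" %in% names(x)) x$name else if ("state" %in% names(x)) as.character(x$state) else "."
    df <- tibble(chrom = x$chrom, start = x$start, end = x$end, name = name)
    if ("score" %in% names(x)) df$score <- x$score
    if ("strand" %in% names(x)) {
      if (!"score" %in% names(df)) df$score <- 0
      df$strand <- x$strand
    }
    readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  } else {
    stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
    readr::write_tsv(x[c("chrom", "start", "end", "value")], path,
                     col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' @param path BED3+ file (0-based half-open).
#' @param name Optional annotation-set name attached as a `name` column when
#'   the file has no fourth column.
#' @return Tibble with `chrom`, `start`, `end`, and `name` when available.
#' @export
read_bed <- function(path, name = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        comment = "#")
  if (nrow(df) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  out <- tibble(chrom = df$X1, start = as.integer(df$X2), end = as.integer(df$X3))
  if (ncol(df) >= 4) out$name <- df$X4 else if (!is.null(name)) out$name <- name
  if (ncol(df) >= 6) out$strand <- df$X6
  if (any(out$start >= out$end)) stop("invalid BED interval (start >= end)")
  out
}
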
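#' Classify DMRs as hyper- or hypo-mCpH by fold change
#'
#' Each DMR's mCpH level is compared with the genome-wide mCpH level:
#' fold change > 2 makes a hyper-mCpH DMR, fold change < 0.5 a hypo-mCpH
#' DMR (both strict), anything else `neither`. A pseudo-level of 0.0001 is
#' added to both numerator and denominator when the genome level is zero
#' or missing, the same guard used when log fold changes are displayed.
#'
#' @param dmrs Tibble of DMRs with an `mcph_level` column (e.g.
#'   [extract_dmrs()] output annotated by [region_methylation()]).
#' @param genome_level Genome-wide mCpH level (see [genome_mcph_level()]).
#' @param pseudo_level Guard against a zero denominator. Default 1e-4.
#' @return `dmrs` with `fold_change` and `klass` (`hyper`/`hypo`/`neither`)
#'   appended.
#' @export
classify_dmrs <- function(dmrs, genome_level, pseudo_level = 1e-4) {
  stopifnot("mcph_level" %in% names(dmrs))
  out <- as_tibble(dmrs)
  if (is.na(genome_level) || genome_level <= 0) {
    fc <- (out$mcph_level + pseudo_level) / (max(genome_level, 0, na.rm = TRUE) + pseudo_level)
  } else {
    fc <- out$mcph_level / genome_level
  }
  out$fold_change <- fc
  out$klass <- dplyr::case_when(fc > 2 ~ "hyper", fc < 0.5 ~ "hypo",
                                TRUE ~ "neither")
  out$klass[is.na(fc)] <- NA_character_
  out
}

.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' All pairwise overlaps between two interval sets
#'
#' Returns every pair of intervals (one from each set) sharing at least
#' 1 bp, with the overlap in 0-based half-open coordinates. Inputs need
#' not be sorted.
#'
#' @param set_a,set_b Tibbles with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Tibble with `chrom`, `a_idx`, `b_idx` (row indices into the
#'   inputs), `overlap_start`, `overlap_end`, `overlap_bp`.
#' @export
intersect_intervals <- function(set_a, set_b) {
  empty <- tibble(chrom = character(), a_idx = integer(), b_idx = integer(),
                  overlap_start = integer(), overlap_end = integer(),
                  overlap_bp = integer())
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)
  stopifnot(all(set_a$start < set_a$end), all(set_b$start < set_b$end))
  ga <- .as_granges(set_a)
  gb <- .as_granges(set_b)
  ov <- GenomicRanges::findOverlaps(ga, gb)
  if (length(ov) == 0) return(empty)
  ai <- S4Vectors::queryHits(ov)
  bi <- S4Vectors::subjectHits(ov)
  os <- pmax(set_a$start[ai], set_b$start[bi])
  oe <- pmin(set_a$end[ai], set_b$end[bi])
  tibble(chrom = set_a$chrom[ai], a_idx = ai, b_idx = bi,
         overlap_start = os, overlap_end = oe, overlap_bp = oe - os) %>%
    dplyr::arrange(.data$chrom, .data$overlap_start, .data$a_idx, .data$b_idx)
}

.merged_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(IRanges::width(GenomicRanges::reduce(.as_granges(df))))
}

.merged_overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  sum(IRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(.as_granges(a)), GenomicRanges::reduce(.as_granges(b)))))
}

#' Fractions of annotations (and of the genome) covered by DMRs
#'
#' For each named annotation set, computes the merged base pairs covered
#' by the DMR set, the fraction of the annotation covered, and the
#' fraction of the DMR set falling in the annotation; overlapping
#' intervals are merged first so no base is double-counted. A
#' `whole_genome` row reports total merged DMR bp / `genome_size`.
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end`).
#' @param annotations Tibble with `chrom`, `start`, `end`, `name` (one
#'   annotation set per distinct `name`).
#' @param genome_size Total genome length in bp.
#' @return Tibble with one row per annotation plus `whole_genome`:
#'   `annotation_name`, `bp_overlap`, `fraction_of_annotation`,
#'   `fraction_of_dmr_set`.
#' @export
overlap_fraction_table <- function(dmrs, annotations, genome_size) {
  stopifnot("name" %in% names(annotations), genome_size > 0)
  dmr_bp <- .merged_bp(dmrs)
  rows <- lapply(unique(annotations$name), function(nm) {
    ann <- annotations[annotations$name == nm, , drop = FALSE]
    ann_bp <- .merged_bp(ann)
    ov <- .merged_overlap_bp(dmrs, ann)
    tibble(annotation_name = nm, bp_overlap = ov,
           fraction_of_annotation = if (ann_bp > 0) ov / ann_bp else NA_real_,
           fraction_of_dmr_set = if (dmr_bp > 0) ov / dmr_bp else NA_real_)
  })
  dplyr::bind_rows(
    tibble(annotation_name = "whole_genome", bp_overlap = dmr_bp,
           fraction_of_annotation = dmr_bp / genome_size,
           fraction_of_dmr_set = if (dmr_bp > 0) 1 else NA_real_),
    dplyr::bind_rows(rows))
}

#' Methylated-motif composition of CpHs inside DMRs
#'
#' Tallies, per trinucleotide motif, the methylated and total CpH sites
#' falling inside the DMR set (e.g. to show CAC-dominated methylation in
#' brain DMRs).
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end`).
#' @param calls Per-site call table with `motif` annotated.
#' @return Tibble with `motif`, `n_mcph`, `n_cph`, `ratio`, sorted by
#'   descending methylated count.
#' @export
motif_methylation_summary <- function(dmrs, calls) {
  if (nrow(dmrs) == 0) {
    return(tibble(motif = character(), n_mcph = integer(), n_cph = integer(),
                  ratio = numeric()))
  }
  hits <- .site_interval_hits(dplyr::filter(calls, .data$context == "CpH"), dmrs)
  hits %>%
    dplyr::distinct(.data$chrom, .data$pos, .data$strand, .keep_all = TRUE) %>%
    dplyr::group_by(.data$motif) %>%
    dplyr::summarise(n_mcph = sum(.data$is_methylated), n_cph = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::mutate(ratio = .data$n_mcph / .data$n_cph) %>%
    dplyr::arrange(dplyr::desc(.data$n_mcph))
}

#' Methylation level profile around (un)methylated CpGs
#'
#' For every center CpG -- methylated CpGs, or unmethylated ones
#' (`Me < 0.05`) -- accumulates the methylation levels of same-strand CpH
#' sites within `flank` bp, by position relative to the center in the
#' center's 5'->3' orientation (minus-strand centers are mirrored). Each
#' reported offset is the mean level over a centered `window`-bp sliding
#' window (offsets `o - window/2 ... o + window/2 - 1`); offsets with no
#' observations are `NA`.
#'
#' @param calls Per-site call table from [call_sites()] (both contexts).
#' @param center_kind `"mcpg"` (methylated CpGs) or `"unmethylated_cpg"`
#'   (`Me < 0.05`).
#' @param flank Half-width of the profile in bp. Default 1000.
#' @param window Sliding-window width in bp. Default 50.
#' @param target_context Context of the profiled sites. Default `"CpH"`.
#' @return Tibble of class `cphmm_profile` with `offset`
#'   (-flank ... flank), `value` (mean level in the window), `n_obs`
#'   (site observations in the window), and attribute `n_centers`.
#' @export
proximity_profile <- function(calls, center_kind = c("mcpg", "unmethylated_cpg"),
                              flank = 1000, window = 50, target_context = "CpH") {
  center_kind <- match.arg(center_kind)
  cpg <- dplyr::filter(calls, .data$context == "CpG")
  centers <- if (center_kind == "mcpg") dplyr::filter(cpg, .data$is_methylated)
             else dplyr::filter(cpg, .data$me < 0.05)
  if (nrow(centers) == 0) stop("no center CpGs of the requested kind")
  targets <- dplyr::filter(calls, .data$context == target_context)

  half <- window %/% 2
  sums <- counts <- numeric(2 * flank + 1)  # offsets -flank..flank
  for (ch in intersect(unique(centers$chrom), unique(targets$chrom))) {
    for (sd_ in c("+", "-")) {
      cen <- centers[centers$chrom == ch & centers$strand == sd_, , drop = FALSE]
      tar <- targets[targets$chrom == ch & targets$strand == sd_, , drop = FALSE]
      if (nrow(cen) == 0 || nrow(tar) == 0) next
      q <- IRanges::IRanges(start = pmax(cen$pos - flank, 0) + 1L,
                            end = cen$pos + flank + 1L)
      s <- IRanges::IRanges(start = tar$pos + 1L, width = 1L)
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      ci <- S4Vectors::queryHits(ov)
      ti <- S4Vectors::subjectHits(ov)
      off <- tar$pos[ti] - cen$pos[ci]
      if (sd_ == "-") off <- -off  # orient 5'->3' on the center's strand
      keep <- abs(off) <= flank & off != 0L
      t2 <- tapply(tar$me[ti[keep]], off[keep] + flank + 1L, sum)
      c2 <- tapply(rep(1, sum(keep)), off[keep] + flank + 1L, sum)
      ix <- as.integer(names(t2))
      sums[ix] <- sums[ix] + t2
      counts[ix] <- counts[ix] + c2
    }
  }
  # centered sliding window: value(o) = sum over o-half .. o+half-1
  csum <- c(0, cumsum(sums)); ccnt <- c(0, cumsum(counts))
  n_off <- 2 * flank + 1
  lo <- pmax(seq_len(n_off) - half, 1)
  hi <- pmin(seq_len(n_off) + half - 1, n_off)
  wsum <- csum[hi + 1] - csum[lo]
  wcnt <- ccnt[hi + 1] - ccnt[lo]
  out <- tibble(offset = seq(-flank, flank),
                value = ifelse(wcnt > 0, wsum / wcnt, NA_real_),
                n_obs = as.integer(wcnt))
  attr(out, "n_centers") <- nrow(centers)
  attr(out, "center_kind") <- center_kind
  attr(out, "window") <- window
  class(out) <- c("cphmm_profile", class(out))
  out
}
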
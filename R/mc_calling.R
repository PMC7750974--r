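#' Per-site methylation level with non-conversion correction
#'
#' The methylation level of a cytosine is the pooled methylated-read
#' fraction minus the bisulfite non-conversion rate `R`, clamped to
#' \[0, 1\]: `Me = sum(m) / sum(n) - R`. Pooling is over mappers, so the
#' result is invariant to how reads are split across sources.
#'
#' @param m,n Methylated and total read counts. Vectors are summed
#'   (single-site, multi-mapper) unless `pooled = TRUE`, in which case
#'   `m`/`n` are parallel per-site vectors and a vector of levels is
#'   returned.
#' @param R Non-conversion rate in `[0, 1)`.
#' @param pooled Treat `m`/`n` as already-pooled per-site vectors.
#' @return Methylation level(s) in \[0, 1\].
#' @examples
#' methylation_level(c(8, 7), c(10, 10), R = 0.005)  # 15/20 - 0.005
#' @export
methylation_level <- function(m, n, R, pooled = FALSE) {
  stopifnot(R >= 0, R < 1)
  if (!pooled) {
    m <- sum(m); n <- sum(n)
  }
  if (any(n == 0)) stop("methylation level undefined: total read count is zero")
  pmin(pmax(m / n - R, 0), 1)
}

#' Call methylated CpGs by level threshold
#'
#' A CpG is called methylated when its corrected level strictly exceeds the
#' threshold: `Me > 0.8` by default, or `Me > 0.5` in `low_meth` mode for
#' samples with globally depressed CpG methylation (e.g. DNMT-rescue
#' lines).
#'
#' @param table A [methylome] tibble (its CpG rows are used; counts are
#'   pooled across mappers per site).
#' @param R Non-conversion rate; defaults to the table's
#'   `nonconversion_rate` attribute.
#' @param mcpg_me_min Level threshold (strict `>`). Default 0.8.
#' @param low_meth Use the 0.5 threshold for low-methylation samples.
#' @return Tibble of CpG sites with `me` and `is_methylated` (no p-value:
#'   CpG calls are threshold-based).
#' @export
call_mcpg <- function(table, R = attr(table, "nonconversion_rate"),
                      mcpg_me_min = 0.8, low_meth = FALSE) {
  stopifnot(is.numeric(R), !is.na(R))
  cut <- if (low_meth) 0.5 else mcpg_me_min
  pooled <- pool_counts(table) %>% dplyr::filter(.data$context == "CpG")
  pooled$me <- methylation_level(pooled$m, pooled$n, R, pooled = TRUE)
  pooled$pvalue <- NA_real_
  pooled$is_methylated <- pooled$me > cut
  pooled
}

#' Binomial p-value for CpH methylation
#'
#' Upper-tail probability `P(X >= m)` for `X ~ Binomial(n, R)`: the
#' probability of observing at least `m` unconverted reads if the site is
#' truly unmethylated and unconverted reads arise only from bisulfite
#' conversion failure at rate `R`. The tail is computed exactly (no normal
#' approximation).
#'
#' @param m,n Methylated and total read counts (vectorised).
#' @param R Non-conversion rate.
#' @return P-value(s) in (0, 1\]; with `R = 0` and `m > 0` the value is 0
#'   by convention (with a warning).
#' @examples
#' cph_pvalue(3, 10, 0.005)
#' @export
cph_pvalue <- function(m, n, R) {
  stopifnot(all(m >= 0), all(m <= n), all(n > 0), R >= 0, R < 1)
  if (R == 0) {
    if (any(m > 0)) warning("R = 0: sites with m > 0 get p-value 0 by convention")
    return(ifelse(m > 0, 0, 1))
  }
  pbinom(m - 1, n, R, lower.tail = FALSE)
}

#' Call methylated CpHs by binomial test
#'
#' A CpH is called methylated when its binomial p-value (see
#' [cph_pvalue()]) is strictly below `cph_pvalue_max`. The default cutoff
#' 1e-5 is the one the empirical FDR calibration ([calibrate_fdr()])
#' selects on typical data.
#'
#' @inheritParams call_mcpg
#' @param cph_pvalue_max P-value cutoff (strict `<`). Default 1e-5.
#' @return Tibble of CpH sites with `me`, `pvalue`, and `is_methylated`.
#' @export
call_mcph <- function(table, R = attr(table, "nonconversion_rate"),
                      cph_pvalue_max = 1e-5) {
  stopifnot(is.numeric(R), !is.na(R))
  pooled <- pool_counts(table) %>% dplyr::filter(.data$context == "CpH")
  pooled$me <- methylation_level(pooled$m, pooled$n, R, pooled = TRUE)
  pooled$pvalue <- cph_pvalue(pooled$m, pooled$n, R)
  pooled$is_methylated <- pooled$pvalue < cph_pvalue_max
  pooled
}

#' Call all sites (CpG by threshold, CpH by binomial test)
#'
#' Convenience wrapper combining [call_mcpg()] and [call_mcph()] into one
#' per-site call table.
#'
#' @inheritParams call_mcpg
#' @inheritParams call_mcph
#' @return Tibble of all sites with `me`, `pvalue` (`NA` for CpGs), and
#'   `is_methylated`, sorted by position.
#' @export
call_sites <- function(table, R = attr(table, "nonconversion_rate"),
                       mcpg_me_min = 0.8, low_meth = FALSE,
                       cph_pvalue_max = 1e-5) {
  dplyr::bind_rows(
    call_mcpg(table, R = R, mcpg_me_min = mcpg_me_min, low_meth = low_meth),
    call_mcph(table, R = R, cph_pvalue_max = cph_pvalue_max)
  ) %>% dplyr::arrange(.data$chrom, .data$pos, .data$strand)
}

#' Calibrate the CpH p-value cutoff by empirical FDR
#'
#' For a grid of p-value cutoffs, counts methylated-CpH calls on the real
#' data and on a matched null data set in which each site's methylated
#' reads are redrawn as `Binomial(n, R)` (pure conversion error), and
#' reports the empirical false discovery rate `null calls / real calls` at
#' each cutoff. The recommended cutoff is the loosest (largest) one with
#' FDR < `fdr_max`.
#'
#' @param table A [methylome] tibble with CpH sites.
#' @param R Non-conversion rate.
#' @param grid Descending p-value cutoffs. Default `1e-2 ... 1e-6`.
#' @param seed Integer seed for the null draw (recorded in the result).
#' @param fdr_max FDR target. Default 0.01.
#' @return A tibble of class `cphmm_fdr` with columns `cutoff`,
#'   `real_calls`, `null_calls`, `fdr`, and attributes
#'   `recommended_cutoff` and `seed`. `0/0` is reported as FDR 0 (no
#'   discoveries implies no false discoveries).
#' @export
calibrate_fdr <- function(table, R = attr(table, "nonconversion_rate"),
                          grid = 10^-(2:6), seed = 1L, fdr_max = 0.01) {
  stopifnot(is.numeric(R), !is.na(R), R > 0)
  grid <- sort(grid, decreasing = TRUE)
  pooled <- pool_counts(table) %>% dplyr::filter(.data$context == "CpH")
  if (nrow(pooled) == 0) stop("no CpH sites to calibrate on")

  p_real <- cph_pvalue(pooled$m, pooled$n, R)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m_null <- rbinom(nrow(pooled), pooled$n, R)
  p_null <- cph_pvalue(m_null, pooled$n, R)

  real_calls <- vapply(grid, function(a) sum(p_real < a), integer(1))
  null_calls <- vapply(grid, function(a) sum(p_null < a), integer(1))
  fdr <- ifelse(real_calls == 0, 0, null_calls / real_calls)

  out <- tibble(cutoff = grid, real_calls = real_calls,
                null_calls = null_calls, fdr = fdr)
  ok <- which(fdr < fdr_max & real_calls > 0)
  rec <- if (length(ok) > 0) grid[ok[1]] else NA_real_
  if (is.na(rec)) warning("no cutoff in the grid achieves FDR < ", fdr_max)
  attr(out, "recommended_cutoff") <- rec
  attr(out, "seed") <- seed
  class(out) <- c("cphmm_fdr", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Region-level methylation summaries
#'
#' For each interval, the mCpG level is the mean corrected level `Me` over
#' CpG sites in the region (both strands), and the mCpH level is the number
#' of methylated CpHs divided by the number of CpHs in the region. Regions
#' with no sites of a context get `NA` (not 0) for that level.
#'
#' @param calls Per-site call table from [call_sites()] (or a row-bind of
#'   [call_mcpg()] and [call_mcph()] output).
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based
#'   half-open); one output row per input row.
#' @return `intervals` with `mcpg_level`, `mcph_level`, `n_cpg`, `n_cph`,
#'   `n_mcph` appended.
#' @export
region_methylation <- function(calls, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(intervals$start < intervals$end))
  hits <- .site_interval_hits(calls, intervals)
  per <- hits %>%
    dplyr::group_by(.data$interval_idx) %>%
    dplyr::summarise(
      mcpg_level = if (any(.data$context == "CpG"))
        mean(.data$me[.data$context == "CpG"]) else NA_real_,
      n_cpg = sum(.data$context == "CpG"),
      n_cph = sum(.data$context == "CpH"),
      n_mcph = sum(.data$context == "CpH" & .data$is_methylated),
      .groups = "drop") %>%
    dplyr::mutate(mcph_level = ifelse(.data$n_cph > 0, .data$n_mcph / .data$n_cph, NA_real_))
  out <- as_tibble(intervals)
  out$interval_idx <- seq_len(nrow(out))
  out <- dplyr::left_join(out, per, by = "interval_idx") %>%
    dplyr::select(-"interval_idx") %>%
    dplyr::mutate(n_cpg = dplyr::coalesce(.data$n_cpg, 0L),
                  n_cph = dplyr::coalesce(.data$n_cph, 0L),
                  n_mcph = dplyr::coalesce(.data$n_mcph, 0L))
  out
}

# site-in-interval lookup via IRanges; returns calls rows with interval_idx
.site_interval_hits <- function(calls, intervals) {
  res <- vector("list", 0)
  for (ch in intersect(unique(intervals$chrom), unique(calls$chrom))) {
    ci <- which(calls$chrom == ch)
    ii <- which(intervals$chrom == ch)
    q <- IRanges::IRanges(start = calls$pos[ci] + 1L, width = 1L)
    s <- IRanges::IRanges(start = intervals$start[ii] + 1L,
                          end = intervals$end[ii])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    rows <- calls[ci[S4Vectors::queryHits(ov)], , drop = FALSE]
    rows$interval_idx <- ii[S4Vectors::subjectHits(ov)]
    res[[length(res) + 1]] <- rows
  }
  if (length(res) == 0) {
    out <- as_tibble(calls)[0, , drop = FALSE]
    out$interval_idx <- integer()
    return(out)
  }
  dplyr::bind_rows(res)
}

#' Genome-wide mCpH level
#'
#' Number of methylated CpHs divided by the number of CpHs over the whole
#' call table; used as the fold-change denominator when classifying DMRs.
#'
#' @param calls Per-site call table including CpH rows.
#' @return A single level in \[0, 1\] (`NA` if there are no CpHs).
#' @export
genome_mcph_level <- function(calls) {
  cph <- calls$context == "CpH"
  if (!any(cph)) return(NA_real_)
  sum(calls$is_methylated[cph]) / sum(cph)
}
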
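#' Tile the genome into fixed-width bins and pool read counts
#'
#' Each chromosome is tiled with `bin_size`-bp bins from position 0; read
#' counts are pooled separately over CpG and CpH sites falling in each bin.
#' A bin is *detected* when its read counts at both CpGs and CpHs strictly
#' exceed `min_bin_reads`; only detected bins carry informative emissions.
#'
#' @param table A [methylome] tibble (multi-mapper counts are pooled).
#' @param bin_size Bin width in bp. Default 180, matching the periodicity
#'   with which de novo methyltransferases track the nucleosome repeat.
#' @param min_bin_reads Detection threshold (strict `>`) on both the CpG
#'   and the CpH read totals. Default 10.
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   omitted, each chromosome is tiled up to the bin containing its last
#'   observed site. The final bin is truncated at the chromosome end.
#' @return Tibble with one row per bin: `chrom`, `bin` (0-based ordinal),
#'   `start`, `end`, `cpg_m`, `cpg_n`, `cph_m`, `cph_n`, `mg` (= cpg_m /
#'   cpg_n), `mh` (= cph_m / cph_n), `detected`.
#' @export
make_bins <- function(table, bin_size = 180, min_bin_reads = 10, chrom_sizes = NULL) {
  pooled <- pool_counts(table)
  if (nrow(pooled) == 0) stop("empty methylome table")
  chroms <- if (!is.null(chrom_sizes)) names(chrom_sizes) else unique(pooled$chrom)

  per_chrom <- lapply(chroms, function(ch) {
    sites <- pooled[pooled$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_sizes)) chrom_sizes[[ch]]
           else (max(sites$pos) %/% bin_size + 1) * bin_size
    n_bins <- as.integer(ceiling(len / bin_size))
    idx <- sites$pos %/% bin_size
    cpg <- sites$context == "CpG"
    agg <- function(v, sel) {
      out <- numeric(n_bins)
      if (any(sel)) {
        t <- tapply(v[sel], idx[sel], sum)
        out[as.integer(names(t)) + 1L] <- t
      }
      out
    }
    tibble(chrom = ch, bin = seq_len(n_bins) - 1L,
           start = (seq_len(n_bins) - 1L) * bin_size,
           end = pmin(seq_len(n_bins) * bin_size, len),
           cpg_m = agg(sites$m, cpg), cpg_n = agg(sites$n, cpg),
           cph_m = agg(sites$m, !cpg), cph_n = agg(sites$n, !cpg))
  })
  bins <- dplyr::bind_rows(per_chrom) %>%
    dplyr::mutate(mg = ifelse(.data$cpg_n > 0, .data$cpg_m / .data$cpg_n, NA_real_),
                  mh = ifelse(.data$cph_n > 0, .data$cph_m / .data$cph_n, NA_real_),
                  detected = .data$cpg_n > min_bin_reads & .data$cph_n > min_bin_reads)
  attr(bins, "bin_size") <- bin_size
  bins
}

#' Genome-wide methylation statistics over detected bins
#'
#' Summaries that anchor the per-bin emission priors: the genome-wide CpH
#' read ratio (the uncorrelated state's emission parameter), the median
#' and standard deviation of per-bin CpG read ratios `mG`, and the
#' standard deviation of per-bin CpH read ratios. All are computed over
#' detected bins only; sample (n-1) standard deviations are used.
#'
#' @param bins Bin table from [make_bins()].
#' @return List of class `cphmm_genome_stats` with `theta_u`, `med_mg`,
#'   `sd_mg`, `sd_mh`, `n_detected`.
#' @export
genome_stats <- function(bins) {
  det <- bins[bins$detected, , drop = FALSE]
  if (nrow(det) < 2) stop("need at least 2 detected bins")
  theta_u <- sum(det$cph_m) / sum(det$cph_n)
  sd_mg <- sd(det$mg)
  sd_mh <- sd(det$mh)
  if (!is.finite(sd_mg) || sd_mg == 0 || !is.finite(sd_mh) || sd_mh == 0) {
    stop("degenerate genome: per-bin methylation ratios have zero spread; ",
         "regenerate the data with variable methylation levels")
  }
  structure(list(theta_u = theta_u, med_mg = median(det$mg),
                 sd_mg = sd_mg, sd_mh = sd_mh, n_detected = nrow(det)),
            class = "cphmm_genome_stats")
}

#' @export
print.cphmm_genome_stats <- function(x, ...) {
  cat("Genome methylation stats over", x$n_detected, "detected bins\n")
  cat(sprintf("  theta_u (CpH read ratio): %.5f\n", x$theta_u))
  cat(sprintf("  mG median %.4f, sd %.4f; mH sd %.4f\n", x$med_mg, x$sd_mg, x$sd_mh))
  invisible(x)
}

.THETA_EPS <- 1e-6

#' Prior mean of the CpH methylation rate for the P or N state
#'
#' The beta-prior mean for a bin is the genome-wide CpH rate shifted up
#' (P, positively correlated) or down (N, negatively correlated) by the
#' bin's CpG methylation z-score scaled to CpH units:
#' `M = theta_u +/- sd_mh * (mG - med_mg) / sd_mg`, clamped to
#' `[1e-6, 1 - 1e-6]` so it remains a valid binomial rate.
#'
#' @param bins Bin table (detected bins; `mg` must be non-`NA`).
#' @param stats [genome_stats()] result.
#' @param state `"P"` or `"N"`.
#' @return Numeric vector of prior means, one per bin row.
#' @export
prior_mean <- function(bins, stats, state = c("P", "N")) {
  state <- match.arg(state)
  z <- (bins$mg - stats$med_mg) / stats$sd_mg
  raw <- if (state == "P") stats$theta_u + stats$sd_mh * z
         else stats$theta_u - stats$sd_mh * z
  pmin(pmax(raw, .THETA_EPS), 1 - .THETA_EPS)
}

#' Posterior mean CpH rate from counts and a beta prior
#'
#' The prior is a beta distribution with pseudo-counts `alpha = cpg_n * M`
#' and `beta = cpg_n - alpha` (so the prior carries as much weight as the
#' bin's CpG reads); the posterior mean given the bin's CpH counts is
#' `(cph_m + alpha) / (cph_n + cpg_n)`, clamped away from 0 and 1.
#'
#' @param cph_m,cph_n Pooled CpH methylated/total reads in the bin.
#' @param cpg_n Pooled total reads at CpGs in the bin (prior weight).
#' @param M Prior mean from [prior_mean()].
#' @return Posterior mean rate(s) in (0, 1).
#' @export
posterior_theta <- function(cph_m, cph_n, cpg_n, M) {
  alpha <- cpg_n * M
  theta <- (cph_m + alpha) / (cph_n + cpg_n)
  pmin(pmax(theta, .THETA_EPS), 1 - .THETA_EPS)
}

#' Per-bin log emission probabilities for the three states
#'
#' For each detected bin the emission of state j is the binomial
#' probability of the observed CpH methylated-read count at the state's
#' rate: the bin-specific posterior mean for P and N, the genome-wide CpH
#' rate for U. Undetected bins get log-emission 0 (probability 1) for all
#' states, i.e. they are uninformative and influence decoding only through
#' the transition structure.
#'
#' @param bins Bin table from [make_bins()].
#' @param stats [genome_stats()] result.
#' @return `bins` with `m_p`, `m_n` (prior means), `theta_p`, `theta_n`,
#'   `theta_u`, and `log_e_p`, `log_e_n`, `log_e_u` appended.
#' @export
emission_matrix <- function(bins, stats) {
  out <- as_tibble(bins)
  det <- out$detected
  out$m_p <- out$m_n <- out$theta_p <- out$theta_n <- NA_real_
  out$theta_u <- ifelse(det, pmin(pmax(stats$theta_u, .THETA_EPS), 1 - .THETA_EPS), NA_real_)
  out$m_p[det] <- prior_mean(out[det, ], stats, "P")
  out$m_n[det] <- prior_mean(out[det, ], stats, "N")
  out$theta_p[det] <- posterior_theta(out$cph_m[det], out$cph_n[det], out$cpg_n[det], out$m_p[det])
  out$theta_n[det] <- posterior_theta(out$cph_m[det], out$cph_n[det], out$cpg_n[det], out$m_n[det])
  out$log_e_p <- out$log_e_n <- out$log_e_u <- 0
  out$log_e_p[det] <- dbinom(out$cph_m[det], out$cph_n[det], out$theta_p[det], log = TRUE)
  out$log_e_n[det] <- dbinom(out$cph_m[det], out$cph_n[det], out$theta_n[det], log = TRUE)
  out$log_e_u[det] <- dbinom(out$cph_m[det], out$cph_n[det], out$theta_u[det], log = TRUE)
  attr(out, "bin_size") <- attr(bins, "bin_size")
  out
}

#' Split the bin sequence into HMM chains at long undetected gaps
#'
#' The Markov chain is broken wherever a run of consecutive undetected
#' bins spans more than `max_gap_bp` (strictly), and at every chromosome
#' boundary. Leading and trailing undetected bins of each chromosome are
#' trimmed (no chain). Undetected bins inside a chain are retained with
#' uninformative emissions so that bin distance equals genomic distance.
#'
#' @param bins Bin table (typically from [emission_matrix()]).
#' @param max_gap_bp Maximum tolerated undetected span in bp. Default
#'   100,000.
#' @return `bins` with an integer `chain` column (`NA` outside chains).
#' @export
split_chains <- function(bins, max_gap_bp = 1e5) {
  out <- as_tibble(bins)
  out$chain <- NA_integer_
  next_id <- 1L
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    idx <- idx[order(out$bin[idx])]
    det <- out$detected[idx]
    if (!any(det)) next
    r <- rle(det)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    det_runs <- which(r$values)
    # group detected runs separated by undetected spans <= max_gap_bp
    grp <- integer(length(det_runs))
    g <- 1L
    for (k in seq_along(det_runs)) {
      if (k > 1) {
        gap_runs <- (det_runs[k - 1] + 1):(det_runs[k] - 1)
        gap_bp <- sum(out$end[idx[unlist(lapply(gap_runs, function(q) starts[q]:ends[q]))]] -
                      out$start[idx[unlist(lapply(gap_runs, function(q) starts[q]:ends[q]))]])
        if (gap_bp > max_gap_bp) g <- g + 1L
      }
      grp[k] <- g
    }
    for (gg in unique(grp)) {
      runs <- det_runs[grp == gg]
      first_bin <- starts[runs[1]]
      last_bin <- ends[runs[length(runs)]]
      out$chain[idx[first_bin:last_bin]] <- next_id
      next_id <- next_id + 1L
    }
  }
  attr(out, "bin_size") <- attr(bins, "bin_size")
  out
}
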
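#' Configuration for the synthetic-methylome generator
#'
#' Bundles the generator's parameters. Defaults mirror the validation
#' construction: 180-bp bins, average read depth 10, planted N-state
#' region lengths uniform on 1-100 bins, CpH levels at one tenth of the
#' CpG scale, and genome-average site densities (about 2 CpG and 21 CpH
#' sites per 180-bp bin).
#'
#' @param genome_length Genome length in bp.
#' @param bin_size Bin width in bp. Default 180.
#' @param mean_depth Mean per-site read depth (Poisson). Default 10.
#' @param n_regions Number of planted N-state regions.
#' @param region_len_range Planted region length range in bins. Default
#'   `c(1, 100)`.
#' @param cpg_per_bin_mean,cph_per_bin_mean Mean site counts per bin
#'   (Poisson). Defaults 2 and 21.
#' @param nonconversion_rate Bisulfite non-conversion rate `R` used when
#'   noise is simulated. Default 0.005.
#' @param mcph_scale CpH-to-CpG methylation scale. Default 0.1.
#' @param fixed_depth Use exactly `mean_depth` reads per site instead of
#'   Poisson depths (useful for exact tests). Default `FALSE`.
#' @param chrom Chromosome name for the synthetic genome.
#' @param seed Integer seed; every generator is bit-reproducible from it.
#' @return A list of class `cphmm_sim_config`.
#' @export
sim_config <- function(genome_length = 9e6, bin_size = 180, mean_depth = 10,
                       n_regions = 50, region_len_range = c(1, 100),
                       cpg_per_bin_mean = 2, cph_per_bin_mean = 21,
                       nonconversion_rate = 0.005, mcph_scale = 0.1,
                       fixed_depth = FALSE, chrom = "chrS", seed = 1L) {
  cfg <- list(genome_length = genome_length, bin_size = bin_size,
              mean_depth = mean_depth, n_regions = n_regions,
              region_len_range = region_len_range,
              cpg_per_bin_mean = cpg_per_bin_mean,
              cph_per_bin_mean = cph_per_bin_mean,
              nonconversion_rate = nonconversion_rate,
              mcph_scale = mcph_scale, fixed_depth = fixed_depth,
              chrom = chrom, seed = as.integer(seed))
  stopifnot(genome_length > 0, bin_size > 0, mean_depth > 0,
            n_regions >= 0, region_len_range[1] >= 1,
            region_len_range[2] >= region_len_range[1],
            nonconversion_rate >= 0, nonconversion_rate < 1, mcph_scale > 0)
  cfg$n_bins <- as.integer(ceiling(genome_length / bin_size))
  if (cfg$n_regions > 0 && region_len_range[2] > cfg$n_bins) {
    stop("region_len_range exceeds the number of genome bins")
  }
  class(cfg) <- "cphmm_sim_config"
  cfg
}

#' Plant ground-truth N-state regions on a synthetic genome
#'
#' Places `n_regions` non-overlapping N-state regions at uniform random
#' positions with lengths uniform on `region_len_range`; every other bin
#' is P-state. Each bin receives a CpG methylation level drawn uniformly
#' on (0, 1). Reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `cphmm_truth`: list with `bins` (tibble `bin`,
#'   `state`, `me_cpg`), `regions` (tibble of planted intervals in bin and
#'   bp coordinates), and `config`.
#' @export
plant_truth <- function(config) {
  stopifnot(inherits(config, "cphmm_sim_config"))
  n_bins <- config$n_bins
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  lens <- if (config$n_regions > 0)
    sample(config$region_len_range[1]:config$region_len_range[2],
           config$n_regions, replace = TRUE) else integer(0)
  if (sum(lens) > 0.8 * n_bins) {
    stop("infeasible packing: planted regions would cover > 80% of bins")
  }
  occupied <- logical(n_bins)
  starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    repeat {
      s <- sample.int(n_bins - lens[i] + 1L, 1L) - 1L
      span <- (s + 1):(s + lens[i])
      if (!any(occupied[span])) { occupied[span] <- TRUE; starts[i] <- s; break }
    }
  }
  state <- ifelse(occupied, "N", "P")
  bins <- tibble(bin = seq_len(n_bins) - 1L, state = state,
                 me_cpg = runif(n_bins))
  regions <- tibble(start_bin = starts, end_bin = starts + lens,
                    start = starts * config$bin_size,
                    end = pmin((starts + lens) * config$bin_size, config$genome_length)) %>%
    dplyr::arrange(.data$start_bin)
  structure(list(bins = bins, regions = regions, config = config),
            class = "cphmm_truth")
}

#' Ground truth from a known Markov chain over P/N/U
#'
#' Alternative truth generator that draws the per-bin state sequence from
#' a known transition matrix, for parameter-recovery experiments on the
#' transition estimator.
#'
#' @param config A [sim_config()] (`n_regions` is ignored).
#' @param transition Row-stochastic 3x3 matrix in (P, N, U) state order.
#' @param initial Initial distribution. Default uniform.
#' @return A `cphmm_truth` whose `regions` are the realized N runs and
#'   which carries `transition` as an attribute.
#' @export
plant_markov_truth <- function(config, transition, initial = rep(1 / 3, 3)) {
  stopifnot(inherits(config, "cphmm_sim_config"),
            all(abs(rowSums(transition) - 1) < 1e-8))
  n_bins <- config$n_bins
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  state <- integer(n_bins)
  state[1] <- sample.int(3L, 1L, prob = initial)
  for (t in 2:n_bins) state[t] <- sample.int(3L, 1L, prob = transition[state[t - 1], ])
  st <- .STATES[state]
  bins <- tibble(bin = seq_len(n_bins) - 1L, state = st, me_cpg = runif(n_bins))
  r <- rle(st == "N")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  nruns <- which(r$values)
  regions <- tibble(start_bin = starts[nruns] - 1L, end_bin = ends[nruns],
                    start = (starts[nruns] - 1L) * config$bin_size,
                    end = pmin(ends[nruns] * config$bin_size, config$genome_length))
  out <- structure(list(bins = bins, regions = regions, config = config),
                   class = "cphmm_truth")
  attr(out, "transition") <- transition
  out
}

.CPH_MOTIFS <- c(CAC = 0.30, CAG = 0.15, CAT = 0.15, CTC = 0.12,
                 CCT = 0.08, CTT = 0.08, CCA = 0.07, CCC = 0.05)
.CPG_MOTIFS <- c(CGA = 0.25, CGC = 0.25, CGG = 0.25, CGT = 0.25)

#' Simulate a bisulfite methylome from a planted truth
#'
#' Generates per-site read counts: site counts per bin are Poisson with
#' the configured CpG/CpH densities and uniform positions within the bin;
#' per-site depth is Poisson(`mean_depth`) (or fixed); methylated reads
#' are binomial at the site's modeled level. CpG sites methylate at the
#' bin's `me_cpg`; CpH sites at `mcph_scale * me_cpg` in P-state bins and
#' `mcph_scale * (1 - me_cpg)` in N-state bins (the anticorrelation being
#' the planted signal), and at `mcph_scale * 0.5` in U-state bins
#' (uncorrelated with the bin's CpG level). Optional bisulfite
#' conversion-failure noise adds `Binomial(n - m, R)` false-methylated
#' reads.
#'
#' @param truth A `cphmm_truth` from [plant_truth()] or
#'   [plant_markov_truth()].
#' @param config The [sim_config()] used for the truth (defaults to the
#'   one stored in it).
#' @param noise Add non-conversion noise at rate
#'   `config$nonconversion_rate`. Default `FALSE`.
#' @param strict_complement_mode If `TRUE`, draws *unmethylated* reads as
#'   `Binomial(n, Me)` so the realized methylation level is `1 - Me`;
#'   provided only to explore that alternative parameterisation. Default
#'   `FALSE` (methylated reads are `Binomial(n, Me)`).
#' @return A [methylome] tibble (single source `"sim"`, all sites on the
#'   plus strand; zero-depth sites are dropped as unobserved).
#' @export
simulate_methylome <- function(truth, config = truth$config, noise = FALSE,
                               strict_complement_mode = FALSE) {
  stopifnot(inherits(truth, "cphmm_truth"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)

  n_bins <- config$n_bins
  k_cpg <- rpois(n_bins, config$cpg_per_bin_mean)
  k_cph <- rpois(n_bins, config$cph_per_bin_mean)

  mk_sites <- function(k, context) {
    bin_idx <- rep.int(seq_len(n_bins) - 1L, k)
    off <- floor(runif(length(bin_idx)) * config$bin_size)
    pos <- bin_idx * config$bin_size + as.integer(off)
    tibble(bin = bin_idx, pos = pos, context = context)
  }
  sites <- dplyr::bind_rows(mk_sites(k_cpg, "CpG"), mk_sites(k_cph, "CpH"))
  sites <- sites[sites$pos < config$genome_length, , drop = FALSE]
  # collisions across draws are removed so (chrom, pos, strand) stays unique
  sites <- sites[!duplicated(sites$pos), , drop = FALSE]

  st <- truth$bins$state[sites$bin + 1L]
  me_cpg <- truth$bins$me_cpg[sites$bin + 1L]
  me <- ifelse(sites$context == "CpG", me_cpg,
        ifelse(st == "P", config$mcph_scale * me_cpg,
        ifelse(st == "N", config$mcph_scale * (1 - me_cpg),
               config$mcph_scale * 0.5)))

  n <- if (config$fixed_depth) rep.int(as.integer(config$mean_depth), nrow(sites))
       else rpois(nrow(sites), config$mean_depth)
  keep <- n > 0
  sites <- sites[keep, , drop = FALSE]; me <- me[keep]; n <- n[keep]

  m <- if (strict_complement_mode) n - rbinom(length(n), n, me)
       else rbinom(length(n), n, me)
  if (noise && config$nonconversion_rate > 0) {
    m <- m + rbinom(length(n), n - m, config$nonconversion_rate)
  }

  is_cpg <- sites$context == "CpG"
  motif <- character(nrow(sites))
  motif[is_cpg] <- sample(names(.CPG_MOTIFS), sum(is_cpg), TRUE, .CPG_MOTIFS)
  motif[!is_cpg] <- sample(names(.CPH_MOTIFS), sum(!is_cpg), TRUE, .CPH_MOTIFS)

  out <- tibble(chrom = config$chrom, pos = sites$pos, strand = "+",
                context = sites$context, motif = motif, mapper = "sim",
                m = as.integer(m), n = as.integer(n)) %>%
    dplyr::arrange(.data$pos)
  new_methylome(out, sample_id = "simulated",
                nonconversion_rate = if (noise) config$nonconversion_rate else 0)
}

#' Synthetic CpH table for FDR calibration
#'
#' Generates a CpH-only methylome in which a fraction of sites is truly
#' methylated at `true_level` and the rest carry only bisulfite
#' conversion-failure signal at rate `R`; the input the empirical FDR
#' calibration of the CpH p-value cutoff is evaluated on.
#'
#' @param n_sites Number of CpH sites. Default 200,000.
#' @param depth_mean Mean per-site depth (Poisson; zero depths are
#'   redrawn so every site is observed). Default 10.
#' @param R Non-conversion rate. Default 0.005.
#' @param frac_methylated Fraction of truly methylated sites in `[0, 1)`.
#'   Default 0.05.
#' @param true_level Methylation level of the truly methylated sites.
#'   Default 0.3.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return A [methylome] tibble of CpH sites with `nonconversion_rate = R`
#'   attached.
#' @export
make_null_calibration_input <- function(n_sites = 200000, depth_mean = 10,
                                        R = 0.005, frac_methylated = 0.05,
                                        true_level = 0.3, seed = 1L,
                                        chrom = "chrS") {
  stopifnot(frac_methylated >= 0, frac_methylated < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- rpois(n_sites, depth_mean)
  while (any(n == 0)) n[n == 0] <- rpois(sum(n == 0), depth_mean)
  meth <- runif(n_sites) < frac_methylated
  p <- ifelse(meth, true_level, R)
  m <- rbinom(n_sites, n, p)
  out <- tibble(chrom = chrom, pos = (seq_len(n_sites) - 1L) * 2L, strand = "+",
                context = "CpH", motif = "CAC", mapper = "sim",
                m = m, n = n)
  new_methylome(out, sample_id = "calibration", nonconversion_rate = R)
}

#' Bin-level precision and recall of N-state detection
#'
#' Counts true/false positives and false negatives of N-state membership
#' bin by bin: `TP` are bins N in both prediction and truth, `FP`
#' predicted-N only, `FN` truth-N only. Unassigned (`NA`) predictions
#' count as not-N. `0/0` ratios are reported as `NA`.
#'
#' @param predicted Per-bin predicted states: a vector, or a bin table
#'   with a `state` column, ordered by bin.
#' @param truth A `cphmm_truth` or a per-bin state vector of equal length.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
evaluate_precision_recall <- function(predicted, truth) {
  pred <- if (is.data.frame(predicted)) as.character(predicted$state)
          else as.character(predicted)
  tr <- if (inherits(truth, "cphmm_truth")) truth$bins$state else as.character(truth)
  if (length(pred) != length(tr)) {
    stop("predicted (", length(pred), ") and truth (", length(tr),
         ") cover different numbers of bins")
  }
  pn <- !is.na(pred) & pred == "N"
  tn <- tr == "N"
  tp <- sum(pn & tn); fp <- sum(pn & !tn); fn <- sum(!pn & tn)
  tibble(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

.pipeline_states <- function(tbl, config, tol = 5e-4, max_iter = 500) {
  sizes <- setNames(config$genome_length, config$chrom)
  bins <- make_bins(tbl, bin_size = config$bin_size, chrom_sizes = sizes)
  stats <- genome_stats(bins)
  bins <- emission_matrix(bins, stats)
  bins <- split_chains(bins)
  model <- fit_transitions(bins, tol = tol, max_iter = max_iter)
  list(viterbi = viterbi_decode(bins, model),
       emission_only = emission_argmax_states(bins),
       model = model)
}

#' Benchmark N-state detection: emission-only vs. full HMM decoding
#'
#' Generates replicate synthetic methylomes with planted N regions, runs
#' the full segmentation pipeline on each, and scores bin-level precision
#' and recall of N-state detection both for the memoryless
#' highest-emission baseline and for transition learning plus Viterbi
#' decoding.
#'
#' @param config A [sim_config()]; its `seed` acts as the master seed from
#'   which per-replicate seeds are spawned.
#' @param n_sets Number of replicate genomes. Default 30.
#' @param tol,max_iter EM settings passed to [fit_transitions()].
#' @return Tibble with one row per (set, caller): `set`, `seed`, `caller`
#'   (`emission_only` / `viterbi`), `tp`, `fp`, `fn`, `precision`,
#'   `recall`.
#' @export
run_benchmark <- function(config, n_sets = 30, tol = 5e-4, max_iter = 500) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_sets)
  rows <- purrr::map(seq_len(n_sets), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    truth <- plant_truth(cfg)
    tbl <- simulate_methylome(truth, cfg)
    st <- .pipeline_states(tbl, cfg, tol = tol, max_iter = max_iter)
    dplyr::bind_rows(
      dplyr::mutate(evaluate_precision_recall(st$emission_only, truth),
                    set = i, seed = seeds[i], caller = "emission_only"),
      dplyr::mutate(evaluate_precision_recall(st$viterbi, truth),
                    set = i, seed = seeds[i], caller = "viterbi"))
  })
  dplyr::bind_rows(rows) %>%
    dplyr::select("set", "seed", "caller", "tp", "fp", "fn", "precision", "recall")
}
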
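.chain_emission_matrices <- function(bins) {
  stopifnot(all(c("chain", "log_e_p", "log_e_n", "log_e_u") %in% names(bins)))
  ids <- sort(unique(bins$chain[!is.na(bins$chain)]))
  if (length(ids) == 0) stop("no chains: run split_chains() on bins with detected sites")
  lapply(ids, function(id) {
    b <- bins[!is.na(bins$chain) & bins$chain == id, , drop = FALSE]
    b <- b[order(b$bin), , drop = FALSE]
    cbind(b$log_e_p, b$log_e_n, b$log_e_u)
  })
}

#' Train HMM transition probabilities by expectation-maximization
#'
#' Baum-Welch restricted to the transition matrix (and optionally the
#' initial distribution): the bin-specific emissions are fixed and only
#' the transition structure is re-estimated, with the forward-backward
#' recursions run in log domain and expected transition counts pooled
#' across all chains. Iteration stops when the largest absolute change of
#' any transition probability falls below `tol`, or at `max_iter`.
#'
#' @param bins Bin table from [split_chains()] (emissions and chain ids).
#' @param tol Convergence tolerance on `max |a_jk(t) - a_jk(t-1)|`.
#'   Default 5e-4.
#' @param max_iter Iteration cap. Default 500 (a message is emitted if hit).
#' @param transition_init,initial_init Starting values. The transition
#'   matrix defaults to a diagonal-dominant start (0.9 on the diagonal,
#'   0.05 off it), encoding the positional-continuity assumption that
#'   motivates the HMM; from a uniform start EM tends to a degenerate
#'   optimum in which no state can sustain a run. The initial
#'   distribution defaults to uniform. Pass `matrix(1/3, 3, 3)` for a
#'   fully uninformative start.
#' @param update_initial Also re-estimate the initial distribution.
#'   Default `TRUE`.
#' @return Object of class `cphmm_hmm`: list with `states`, `transition`
#'   (3x3 row-stochastic, P/N/U order), `initial`, `em_history` (tibble
#'   of per-iteration log-likelihood and transition change), `n_iter`,
#'   `converged`, `tol`. The log-likelihood sequence is non-decreasing.
#' @export
fit_transitions <- function(bins, tol = 5e-4, max_iter = 500,
                            transition_init = NULL, initial_init = NULL,
                            update_initial = TRUE) {
  mats <- .chain_emission_matrices(bins)
  K <- 3L
  A0 <- if (is.null(transition_init)) {
    0.85 * diag(K) + 0.05
  } else transition_init
  p0 <- if (is.null(initial_init)) rep(1 / K, K) else initial_init
  stopifnot(all(abs(rowSums(A0) - 1) < 1e-8), abs(sum(p0) - 1) < 1e-8)
  if (!any(vapply(mats, nrow, integer(1)) >= 2)) {
    warning("no chain has >= 2 bins; transition matrix remains at initialization")
  }
  fit <- .em_fit_cpp(mats, A0, p0, tol, as.integer(max_iter), update_initial)
  if (!fit$converged) message("fit_transitions: max_iter = ", max_iter,
                              " reached before convergence")
  dimnames(fit$transition) <- list(.STATES, .STATES)
  names(fit$initial) <- .STATES
  structure(list(states = .STATES,
                 transition = fit$transition,
                 initial = fit$initial,
                 em_history = tibble(iteration = seq_len(fit$n_iter),
                                     loglik = fit$loglik,
                                     delta = fit$delta),
                 n_iter = fit$n_iter, converged = fit$converged, tol = tol),
            class = "cphmm_hmm")
}

#' @export
print.cphmm_hmm <- function(x, ...) {
  cat("Three-state (P/N/U) HMM:", x$n_iter, "EM iteration(s),",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(tol %.1e)\n", x$tol))
  cat("Transition matrix:\n")
  print(round(x$transition, 4))
  cat("Initial distribution:", paste(sprintf("%s=%.3f", names(x$initial), x$initial),
                                     collapse = " "), "\n")
  invisible(x)
}

#' @describeIn fit_transitions Tidy the fitted transition matrix into a
#'   long tibble with columns `from`, `to`, `probability`.
#' @param x A `cphmm_hmm` object.
#' @param ... Unused.
#' @export
tidy.cphmm_hmm <- function(x, ...) {
  tidyr::expand_grid(from = x$states, to = x$states) %>%
    dplyr::mutate(probability = as.vector(t(x$transition)))
}

#' @describeIn fit_transitions One-row model summary (iterations, final
#'   log-likelihood, convergence).
#' @export
glance.cphmm_hmm <- function(x, ...) {
  tibble(n_iter = x$n_iter,
         loglik = tail(x$em_history$loglik, 1),
         delta = tail(x$em_history$delta, 1),
         converged = x$converged)
}

#' Decode the most probable state path with the Viterbi algorithm
#'
#' Per chain, computes the exact maximum-probability P/N/U path in log
#' domain. Ties are broken deterministically toward the earlier state in
#' (P, N, U) order. Bins outside any chain get `NA`.
#'
#' @param bins Bin table from [split_chains()].
#' @param model Fitted `cphmm_hmm` from [fit_transitions()].
#' @return `bins` with a `state` factor column (levels P, N, U).
#' @export
viterbi_decode <- function(bins, model) {
  stopifnot(inherits(model, "cphmm_hmm"),
            all(abs(rowSums(model$transition) - 1) < 1e-8))
  out <- as_tibble(bins)
  out$state <- factor(NA_character_, levels = .STATES)
  logA <- log(model$transition)
  logPi <- log(model$initial)
  for (id in sort(unique(out$chain[!is.na(out$chain)]))) {
    sel <- which(!is.na(out$chain) & out$chain == id)
    sel <- sel[order(out$bin[sel])]
    logE <- cbind(out$log_e_p[sel], out$log_e_n[sel], out$log_e_u[sel])
    path <- .viterbi_cpp(logE, logA, logPi)
    out$state[sel] <- .STATES[path]
  }
  attr(out, "bin_size") <- attr(bins, "bin_size")
  out
}

#' Assign states by highest emission probability only
#'
#' The memoryless baseline: each detected bin gets the state whose
#' emission probability is largest, ignoring transitions. Exact ties go to
#' the earlier state in (P, N, U) order. Undetected bins get `NA`.
#'
#' @param bins Bin table from [emission_matrix()] (chains not required).
#' @return `bins` with a `state` factor column.
#' @export
emission_argmax_states <- function(bins) {
  out <- as_tibble(bins)
  E <- cbind(out$log_e_p, out$log_e_n, out$log_e_u)
  idx <- max.col(E, ties.method = "first")
  out$state <- factor(ifelse(out$detected, .STATES[idx], NA_character_),
                      levels = .STATES)
  attr(out, "bin_size") <- attr(bins, "bin_size")
  out
}

#' Link same-state runs across short interruptions and extract segments
#'
#' Consecutive bins in the same state are merged into segments; two runs
#' of the same state are linked when separated by fewer than
#' `max_gap_bins` bins (i.e. a gap of at most `max_gap_bins - 1` bins of
#' other or unassigned state, 540 bp at the defaults). Linking is a single
#' left-to-right pass, so segments never overlap: an interruption absorbed
#' into a segment cannot seed a segment of its own. Absorbed gap bins are
#' counted but keep their own per-bin state for any level computation.
#'
#' @param states Bin table with a `state` column ([viterbi_decode()] or
#'   [emission_argmax_states()] output).
#' @param max_gap_bins Strict upper bound on the linkable gap, in bins.
#'   Default 3 (gaps of 1 or 2 bins are absorbed).
#' @return Tibble of segments: `chrom`, `start`, `end`, `state`, `n_bins`
#'   (same-state bins), `n_gap_bins_absorbed`.
#' @export
link_segments <- function(states, max_gap_bins = 3) {
  stopifnot("state" %in% names(states))
  segs <- list()
  for (ch in unique(states$chrom)) {
    b <- states[states$chrom == ch, , drop = FALSE]
    b <- b[order(b$bin), , drop = FALSE]
    s <- as.character(b$state)
    s[is.na(s)] <- "."
    r <- rle(s)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    nr <- length(r$values)
    i <- 1L
    while (i <= nr) {
      if (r$values[i] == ".") { i <- i + 1L; next }
      st <- r$values[i]
      first <- run_start[i]; last <- run_end[i]
      n_bins <- r$lengths[i]; gaps <- 0L
      j <- i + 1L
      while (j <= nr) {
        # accumulate a candidate gap of non-matching runs
        gap_len <- 0L; k <- j
        while (k <= nr && r$values[k] != st) {
          gap_len <- gap_len + r$lengths[k]
          if (gap_len >= max_gap_bins) break
          k <- k + 1L
        }
        if (k <= nr && r$values[k] == st && gap_len < max_gap_bins) {
          gaps <- gaps + gap_len
          n_bins <- n_bins + r$lengths[k]
          last <- run_end[k]
          j <- k + 1L
        } else break
      }
      segs[[length(segs) + 1]] <- tibble(
        chrom = ch, start = b$start[first], end = b$end[last], state = st,
        n_bins = n_bins, n_gap_bins_absorbed = gaps)
      i <- j
    }
  }
  if (length(segs) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  state = character(), n_bins = integer(),
                  n_gap_bins_absorbed = integer()))
  }
  dplyr::bind_rows(segs) %>% dplyr::arrange(.data$chrom, .data$start)
}

#' Extract N-state segments as CpG-CpH DMRs
#'
#' @param segments Segment table from [link_segments()].
#' @return The N-state rows: regions where CpG and CpH methylation are
#'   negatively correlated.
#' @export
extract_dmrs <- function(segments) {
  dplyr::filter(segments, .data$state == "N")
}

#' @rdname link_segments
#' @export
link_and_extract_dmrs <- function(states, max_gap_bins = 3) {
  segments <- link_segments(states, max_gap_bins = max_gap_bins)
  list(segments = segments, dmrs = extract_dmrs(segments))
}

#' Segment a methylome with the three-state HMM
#'
#' End-to-end pipeline: tile the genome into bins ([make_bins()]), compute
#' genome statistics and per-bin emissions ([genome_stats()],
#' [emission_matrix()]), split into chains at long undetected gaps
#' ([split_chains()]), train transitions by EM ([fit_transitions()]),
#' decode with Viterbi ([viterbi_decode()]), and link same-state runs into
#' segments, of which the N-state ones are the CpG-CpH DMRs.
#'
#' @inheritParams make_bins
#' @inheritParams fit_transitions
#' @param link_gap_bins Strict gap bound for segment linking. Default 3.
#' @param max_gap_bp Chain-splitting gap. Default 100,000.
#' @return Object of class `cphmm_segmentation`: list with `bins` (with
#'   emissions, chain, Viterbi `state` and `state_emission` columns),
#'   `stats`, `model`, `segments`, `dmrs`, `params`.
#' @export
segment_methylome <- function(table, bin_size = 180, min_bin_reads = 10,
                              max_gap_bp = 1e5, link_gap_bins = 3,
                              tol = 5e-4, max_iter = 500, chrom_sizes = NULL) {
  bins <- make_bins(table, bin_size = bin_size, min_bin_reads = min_bin_reads,
                    chrom_sizes = chrom_sizes)
  stats <- genome_stats(bins)
  bins <- emission_matrix(bins, stats)
  bins <- split_chains(bins, max_gap_bp = max_gap_bp)
  model <- fit_transitions(bins, tol = tol, max_iter = max_iter)
  decoded <- viterbi_decode(bins, model)
  decoded$state_emission <- emission_argmax_states(bins)$state
  segments <- link_segments(decoded, max_gap_bins = link_gap_bins)
  structure(list(bins = decoded, stats = stats, model = model,
                 segments = segments, dmrs = extract_dmrs(segments),
                 params = list(bin_size = bin_size, min_bin_reads = min_bin_reads,
                               max_gap_bp = max_gap_bp, link_gap_bins = link_gap_bins,
                               tol = tol, max_iter = max_iter)),
            class = "cphmm_segmentation")
}

#' @export
print.cphmm_segmentation <- function(x, ...) {
  frac <- prop.table(table(factor(x$bins$state, levels = .STATES)))
  cat("CpG-CpH HMM segmentation:", nrow(x$bins), "bins,",
      sum(x$bins$detected), "detected\n")
  cat(sprintf("  state fractions (of assigned bins): P %.3f  N %.3f  U %.3f\n",
              frac["P"], frac["N"], frac["U"]))
  cat("  segments:", nrow(x$segments), " DMRs (N-state):", nrow(x$dmrs), "\n")
  invisible(x)
}

#' @describeIn segment_methylome Tidy method: the segment table.
#' @param x A `cphmm_segmentation` object.
#' @param ... Unused.
#' @export
tidy.cphmm_segmentation <- function(x, ...) x$segments

#' @describeIn segment_methylome One-row summary: bin counts, state
#'   fractions, DMR count, genome-wide CpH rate, EM iterations.
#' @export
glance.cphmm_segmentation <- function(x, ...) {
  st <- table(factor(x$bins$state, levels = .STATES))
  n_assigned <- sum(st)
  tibble(n_bins = nrow(x$bins), n_detected = sum(x$bins$detected),
         frac_p = st[["P"]] / n_assigned, frac_n = st[["N"]] / n_assigned,
         frac_u = st[["U"]] / n_assigned,
         n_dmrs = nrow(x$dmrs), theta_u = x$stats$theta_u,
         em_iterations = x$model$n_iter, converged = x$model$converged)
}
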
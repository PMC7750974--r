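test_that("bins tile each chromosome and pool counts half-open", {
  tbl <- mk_methylome(pos = c(0, 179, 180, 500), context = "CpG", m = 1, n = 5)
  bins <- make_bins(tbl, chrom_sizes = c(chr1 = 540))
  expect_equal(nrow(bins), 3)
  expect_equal(bins$start, c(0, 180, 360))
  expect_equal(bins$end, c(180, 360, 540))
  # site at 179 goes to bin 0, site at 180 to bin 1
  expect_equal(bins$cpg_n, c(10, 5, 5))
  expect_equal(bins$cpg_m, c(2, 1, 1))
})

test_that("bin detection needs more than 10 reads at both contexts", {
  mk_bin_tbl <- function(cpg_n, cph_n) {
    dplyr::bind_rows(
      mk_methylome(pos = 0, context = "CpG", m = 0, n = cpg_n),
      mk_methylome(pos = 1, context = "CpH", m = 0, n = cph_n))
  }
  expect_true(make_bins(mk_bin_tbl(11, 11))$detected)
  expect_false(make_bins(mk_bin_tbl(10, 11))$detected)
  expect_false(make_bins(mk_bin_tbl(11, 10))$detected)
})

test_that("genome statistics summarise detected bins", {
  bins <- tibble::tibble(
    chrom = "chr1", bin = 0:2, start = 0:2 * 180L, end = 1:3 * 180L,
    cpg_m = c(2, 8, 15), cpg_n = c(20, 40, 50),
    cph_m = c(1, 3, 2), cph_n = c(100, 100, 100),
    mg = c(0.1, 0.2, 0.3), mh = c(0.01, 0.03, 0.02), detected = TRUE)
  st <- genome_stats(bins)
  expect_equal(st$med_mg, 0.2)
  expect_equal(st$theta_u, 6 / 300)
  expect_equal(st$sd_mg, sd(c(0.1, 0.2, 0.3)))
  # theta_u over the detected subset only
  bins2 <- bins
  bins2$detected[3] <- FALSE
  expect_equal(genome_stats(bins2)$theta_u, 4 / 200)
  # identical bins have zero spread: degenerate
  bins3 <- bins
  bins3$mg <- 0.2
  expect_error(genome_stats(bins3), "degenerate")
})

test_that("prior means shift symmetrically from the genome CpH rate and clamp", {
  stats <- structure(list(theta_u = 0.01, med_mg = 0.5, sd_mg = 0.2, sd_mh = 0.02),
                     class = "cphmm_genome_stats")
  at_med <- tibble::tibble(mg = 0.5)
  expect_equal(prior_mean(at_med, stats, "P"), 0.01)
  expect_equal(prior_mean(at_med, stats, "N"), 0.01)
  one_sd <- tibble::tibble(mg = 0.7)  # z = 1
  expect_equal(prior_mean(one_sd, stats, "P"), 0.03)
  expect_equal(prior_mean(one_sd, stats, "N"), 1e-6)  # raw -0.01, clamped
  below <- tibble::tibble(mg = 0.3)   # z = -1
  expect_lt(prior_mean(below, stats, "P"), stats$theta_u)
  expect_gt(prior_mean(below, stats, "N"), stats$theta_u)
})

test_that("posterior theta blends counts with CpG-weighted pseudo-counts", {
  expect_equal(posterior_theta(3, 20, 30, 0.1), 0.12)  # (3 + 3) / (20 + 30)
  # no CpH data: pure prior
  expect_equal(posterior_theta(0, 0, 30, 0.1), 0.1)
  # no prior weight: pure likelihood
  expect_equal(posterior_theta(5, 50, 0, 0.1), 0.1)
  # clamped inside (0, 1)
  expect_gt(posterior_theta(0, 100, 0, 0.5), 0)
  expect_lt(posterior_theta(100, 100, 0, 0.5), 1)
})

test_that("emissions are exact binomial probabilities; undetected bins are flat", {
  bins <- tibble::tibble(
    chrom = "chr1", bin = 0:1, start = c(0L, 180L), end = c(180L, 360L),
    cpg_m = c(5, 0), cpg_n = c(50, 0), cph_m = c(2, 0), cph_n = c(10, 0),
    mg = c(0.1, NA), mh = c(0.2, NA), detected = c(TRUE, FALSE))
  stats <- structure(list(theta_u = 0.1, med_mg = 0.1, sd_mg = 0.05, sd_mh = 0.01),
                     class = "cphmm_genome_stats")
  em <- emission_matrix(bins, stats)
  # detected bin at the median: both priors equal theta_u = 0.1,
  # theta = (2 + 5) / (10 + 50) = 7/60 for P and N; U keeps 0.1
  expect_equal(em$theta_p[1], 7 / 60)
  expect_equal(em$log_e_u[1], dbinom(2, 10, 0.1, log = TRUE))
  expect_equal(exp(em$log_e_u[1]), 0.1937102445, tolerance = 1e-9)
  # undetected bin: probability 1 for every state
  expect_equal(c(em$log_e_p[2], em$log_e_n[2], em$log_e_u[2]), c(0, 0, 0))
})

test_that("emission PMF sums to one over outcomes", {
  for (n in c(1, 10, 137)) {
    for (theta in c(1e-6, 0.02, 0.5, 1 - 1e-6)) {
      expect_equal(sum(dbinom(0:n, n, theta)), 1, tolerance = 1e-10)
    }
  }
  # and the state whose theta is nearest m/n has the largest emission
  stats <- structure(list(theta_u = 0.5, med_mg = 0.5, sd_mg = 0.1, sd_mh = 0.3),
                     class = "cphmm_genome_stats")
  bins <- tibble::tibble(chrom = "c", bin = 0L, start = 0L, end = 180L,
                         cpg_m = 9, cpg_n = 11, cph_m = 90, cph_n = 100,
                         mg = 9 / 11, mh = 0.9, detected = TRUE)
  em <- emission_matrix(bins, stats)
  # m/n = 0.9; theta_p is the largest of the three
  expect_true(em$theta_p > em$theta_u && em$theta_p > em$theta_n)
  expect_true(em$log_e_p > em$log_e_u && em$log_e_p > em$log_e_n)
})

test_that("chains split at undetected runs longer than 100 kb and trim edges", {
  mk_run_bins <- function(det) {
    L <- length(det)
    tibble::tibble(chrom = "chr1", bin = seq_len(L) - 1L,
                   start = (seq_len(L) - 1L) * 180L, end = seq_len(L) * 180L,
                   cpg_m = 0, cpg_n = 0, cph_m = 0, cph_n = 0,
                   mg = NA_real_, mh = NA_real_, detected = det,
                   log_e_p = 0, log_e_n = 0, log_e_u = 0)
  }
  # 600 undetected bins = 108,000 bp > 100,000: split into two chains
  b <- split_chains(mk_run_bins(c(rep(TRUE, 5), rep(FALSE, 600), rep(TRUE, 5))))
  expect_equal(length(unique(na.omit(b$chain))), 2)
  expect_true(all(is.na(b$chain[6:605])))
  # 500 undetected bins = 90,000 bp: one chain, gap retained inside it
  b2 <- split_chains(mk_run_bins(c(rep(TRUE, 5), rep(FALSE, 500), rep(TRUE, 5))))
  expect_equal(length(unique(na.omit(b2$chain))), 1)
  expect_true(all(!is.na(b2$chain)[6:505]))
  # leading/trailing undetected bins belong to no chain
  b3 <- split_chains(mk_run_bins(c(FALSE, FALSE, TRUE, TRUE, FALSE)))
  expect_equal(is.na(b3$chain), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  # chromosomes never share a chain
  two <- dplyr::bind_rows(mk_run_bins(rep(TRUE, 3)),
                          dplyr::mutate(mk_run_bins(rep(TRUE, 3)), chrom = "chr2"))
  b4 <- split_chains(two)
  expect_equal(length(unique(b4$chain)), 2)
})

test_that("EM keeps rows stochastic, increases the likelihood, and stops at tol", {
  set.seed(5)
  logE <- matrix(log(runif(300)), ncol = 3)
  bins <- mk_emission_bins(logE)
  fit <- fit_transitions(bins, tol = 5e-4)
  expect_equal(rowSums(fit$transition), c(P = 1, N = 1, U = 1), tolerance = 1e-12)
  expect_equal(sum(fit$initial), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$em_history$loglik) >= -1e-8))
  expect_true(fit$converged)
  expect_lt(tail(fit$em_history$delta, 1), 5e-4)
})

test_that("one-bin chains leave the transition matrix at its initialization", {
  bins <- mk_emission_bins(matrix(log(c(0.5, 0.3, 0.2)), 1))
  A0 <- matrix(1 / 3, 3, 3)
  expect_warning(fit <- fit_transitions(bins, transition_init = A0), "remains at init")
  expect_equal(unname(fit$transition), A0)
})

test_that("Viterbi matches exhaustive enumeration on short random chains", {
  set.seed(12)
  for (i in 1:30) {
    L <- sample(2:10, 1)
    logE <- matrix(log(runif(3 * L)), ncol = 3)
    A <- matrix(runif(9), 3)
    A <- A / rowSums(A)
    pi0 <- runif(3)
    pi0 <- pi0 / sum(pi0)
    got <- cphmm:::.viterbi_cpp(logE, log(A), log(pi0))
    want <- viterbi_bruteforce(logE, log(A), log(pi0))
    expect_equal(got, want)
  }
})

test_that("Viterbi reduces to per-bin argmax under uniform transitions", {
  set.seed(3)
  logE <- matrix(log(runif(150)), ncol = 3)
  bins <- mk_emission_bins(logE)
  model <- structure(list(states = c("P", "N", "U"),
                          transition = matrix(1 / 3, 3, 3,
                                              dimnames = list(c("P","N","U"), c("P","N","U"))),
                          initial = setNames(rep(1 / 3, 3), c("P","N","U"))),
                     class = "cphmm_hmm")
  dec <- viterbi_decode(bins, model)
  expect_equal(as.character(dec$state),
               c("P", "N", "U")[max.col(logE, ties.method = "first")])
})

test_that("the decoded path beats random paths and ignores emission rescaling", {
  set.seed(8)
  L <- 60
  logE <- matrix(log(runif(3 * L)), ncol = 3)
  A <- matrix(c(.8, .1, .1, .1, .8, .1, .2, .2, .6), 3, byrow = TRUE)
  pi0 <- rep(1 / 3, 3)
  path <- cphmm:::.viterbi_cpp(logE, log(A), log(pi0))
  best <- cphmm:::.path_loglik_cpp(logE, log(A), log(pi0), path)
  for (i in 1:200) {
    rnd <- sample(1:3, L, replace = TRUE)
    expect_gte(best, cphmm:::.path_loglik_cpp(logE, log(A), log(pi0), rnd))
  }
  # per-bin rescaling of all emissions leaves the path unchanged
  logE2 <- logE + rnorm(L)  # same constant added to the three states of a bin
  expect_equal(cphmm:::.viterbi_cpp(logE2, log(A), log(pi0)), path)
})

test_that("emission argmax assigns detected bins with ties toward P", {
  bins <- tibble::tibble(
    chrom = "c", bin = 0:2, start = 0:2 * 180L, end = 1:3 * 180L,
    cpg_m = 0, cpg_n = 20, cph_m = 0, cph_n = 20, mg = 0, mh = 0,
    detected = c(TRUE, TRUE, FALSE),
    log_e_p = log(c(0.2, 0.4, 1)), log_e_n = log(c(0.5, 0.4, 1)),
    log_e_u = log(c(0.3, 0.2, 1)))
  st <- emission_argmax_states(bins)
  expect_equal(as.character(st$state), c("N", "P", NA))
})

test_that("same-state runs link across gaps of fewer than three bins", {
  # N N P N N: the 1-bin interruption is absorbed
  segs <- link_segments(mk_state_bins("NNPNN"))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, "N")
  expect_equal(c(segs$start, segs$end), c(0, 900))
  expect_equal(segs$n_bins, 4)
  expect_equal(segs$n_gap_bins_absorbed, 1)

  # N N P P P N N: a 3-bin gap is not linked
  segs2 <- link_segments(mk_state_bins("NNPPPNN"))
  expect_equal(segs2$state, c("N", "P", "N"))
  expect_equal(nrow(extract_dmrs(segs2)), 2)

  # two-bin gap (540 bp would be reached at three) still links
  segs3 <- link_segments(mk_state_bins("NNPPNN"))
  expect_equal(extract_dmrs(segs3)$n_gap_bins_absorbed, 2)

  # all P: no DMRs at all
  expect_equal(nrow(extract_dmrs(link_segments(mk_state_bins("PPPPP")))), 0)

  # unassigned bins count toward the gap
  segs4 <- link_segments(mk_state_bins("NN..NN"))
  expect_equal(nrow(dplyr::filter(segs4, state == "N")), 1)

  # segments never overlap: an absorbed interruption seeds no segment
  segs5 <- link_segments(mk_state_bins("NNPNPPP"))
  expect_equal(segs5$state, c("N", "P"))
  expect_lte(segs5$end[1], segs5$start[2])
})

test_that("tidy and glance summarise a fitted model", {
  set.seed(5)
  bins <- mk_emission_bins(matrix(log(runif(90)), ncol = 3))
  fit <- fit_transitions(bins)
  td <- tidy(fit)
  expect_equal(nrow(td), 9)
  expect_equal(sum(td$probability), 3, tolerance = 1e-12)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_iter, fit$n_iter)
})
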
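# In-code fixtures shared across test files.

# minimal methylome tibble from parallel vectors
mk_methylome <- function(chrom = "chr1", pos, strand = "+", context = "CpH",
                         motif = NA_character_, mapper = "m1", m, n,
                         R = NA_real_, sample_id = "s1") {
  df <- tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                       context = context, motif = motif, mapper = mapper,
                       m = as.integer(m), n = as.integer(n))
  cphmm:::new_methylome(df, sample_id = sample_id, nonconversion_rate = R)
}

# write a bismark CX report from a data frame of columns
write_bismark_cx <- function(lines, path = tempfile(fileext = ".cx")) {
  writeLines(lines, path)
  path
}

# independent binomial upper-tail oracle: plain sum of choose() terms
tail_sum_oracle <- function(m, n, R) {
  if (m == 0) return(1)
  sum(vapply(m:n, function(k) choose(n, k) * R^k * (1 - R)^(n - k), numeric(1)))
}

# brute-force Viterbi: enumerate all 3^L paths, first-best tie-break in
# lexicographic path order (state order P < N < U)
viterbi_bruteforce <- function(logE, logA, logPi) {
  L <- nrow(logE)
  K <- ncol(logE)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), L))[, L:1, drop = FALSE])
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    p <- as.integer(unname(grid[r, ]))
    ll <- logPi[p[1]] + logE[1, p[1]]
    if (L > 1) for (t in 2:L) ll <- ll + logA[p[t - 1], p[t]] + logE[t, p[t]]
    if (ll > best + 1e-12) { best <- ll; best_path <- p }
  }
  best_path
}

# small bin table with emissions, for decoding tests
mk_emission_bins <- function(log_e, chrom = "chr1", bin_size = 180) {
  L <- nrow(log_e)
  tibble::tibble(
    chrom = chrom, bin = seq_len(L) - 1L,
    start = (seq_len(L) - 1L) * bin_size, end = seq_len(L) * bin_size,
    cpg_m = 0, cpg_n = 20, cph_m = 0, cph_n = 20,
    mg = 0, mh = 0, detected = TRUE, chain = 1L,
    log_e_p = log_e[, 1], log_e_n = log_e[, 2], log_e_u = log_e[, 3])
}

# state table for linking tests: one bin per state symbol ('.' = NA)
mk_state_bins <- function(states, chrom = "chr1", bin_size = 180) {
  s <- strsplit(states, "")[[1]]
  tibble::tibble(
    chrom = chrom, bin = seq_along(s) - 1L,
    start = (seq_along(s) - 1L) * bin_size, end = seq_along(s) * bin_size,
    state = factor(ifelse(s == ".", NA_character_, s), levels = c("P", "N", "U")))
}
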
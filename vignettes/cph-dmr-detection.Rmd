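---
title: "Detecting CpG–CpH differentially methylated regions with a three-state HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CpG-CpH differentially methylated regions with a three-state HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cphmm)
library(dplyr)
```

## The problem

In mammalian genomes, methylation outside the CpG context (mCpH, with
H = A, C, or T) is abundant in pluripotent stem cells and in neurons. In
stem cells mCpH tracks mCpG closely — the same de novo
methyltransferases deposit both marks as they move along the DNA — but
in brain tissue there are many loci where CpH methylation is high
precisely where CpG methylation is low, and vice versa. `cphmm` detects
such loci: genomic regions in which CpG and CpH methylation are
*negatively* correlated, called CpG–CpH DMRs.

The pipeline takes per-cytosine bisulfite read counts (Bismark-style
cytosine/CX reports, or any TSV of `chrom, pos, strand, context, m, n`),
calls methylated cytosines, segments the genome with a three-state
hidden Markov model, and classifies the resulting DMRs. A simulator
generates complete synthetic inputs with known ground truth, so every
stage can be validated without any external data.

## Methylation calling

For a cytosine with pooled methylated reads $m$ and total reads $n$
across mappers, the methylation level is

$$Me = \frac{\sum_j m_j}{\sum_j n_j} - R,$$

where $R$ is the bisulfite non-conversion rate measured from spiked-in
unmethylated lambda DNA. $R$-subtraction can make small negatives, so
the level is clamped to $[0,1]$. CpGs are called methylated when
$Me > 0.8$ (strict), or $Me > 0.5$ in a low-methylation mode meant for
samples with globally depressed CpG methylation such as DNMT-rescue
lines.

CpH levels are far lower, so a threshold on $Me$ would be dominated by
conversion error. Instead each CpH gets an exact binomial test of the
null "all methylated reads are conversion failures":
$p = P(X \ge m)$ with $X \sim \mathrm{Bin}(n, R)$. The point
probability alone is not a p-value; the upper tail is what measures
enrichment of unconverted reads. The default cutoff $p < 10^{-5}$ is
validated empirically: `calibrate_fdr()` redraws every site's
methylated reads as $\mathrm{Bin}(n, R)$ (a matched null methylome),
counts calls on real and null data across the cutoff grid
$10^{-2} \dots 10^{-6}$, and reports the ratio as an empirical FDR.
On the packaged calibration construction (200,000 CpH sites, depth
$\sim$Poisson(10), $R = 0.005$, 5% of sites truly methylated at level
0.3) the FDR at $10^{-5}$ is well below 0.01. We define $0/0 = 0$: no
discoveries imply no false discoveries. The null is drawn once with a
recorded seed, mirroring a single null data set; run with several seeds
if a variance estimate is wanted (on the packaged construction the FDR
moves by well under 0.005 between seeds).

Sites are admitted to the methylome when more than 5 reads were aligned
by at least 2 independent mappers (`merge_mapper_reports()`; both
bounds read strictly/inclusively as written). The rule is applied to
each mapper's own coverage, not the pooled total, because it expresses
mapper consensus. Single-source data — including the simulator's — use
`min_mappers = 1`. Sex chromosomes are removed by default to avoid
sex-composition artefacts.

## The three-state HMM

The genome is tiled into 180-bp bins — the periodicity with which de
novo DNMTs methylate DNA around nucleosomes, visible as a 180-bp
oscillation of mCpH around mCpG. Each bin pools reads over its CpG
sites ($mG_i$ = methylated fraction, weight $n_{i,\mathrm{CpG}}$) and
its CpH sites ($m_i$, $n_i$). A bin is *detected* when both read totals
strictly exceed 10.

Each bin belongs to one of three states describing how its CpH
methylation relates to its CpG methylation:

* **P** — positively correlated: CpH rate shifted up with the bin's CpG
  z-score;
* **N** — negatively correlated: shifted down (these are the DMRs);
* **U** — uncorrelated: CpH rate at the genome-wide level
  $\hat\theta_w = \sum m_i / \sum n_i$.

The state-specific CpH rate is a beta-posterior mean. The prior mean
for state P (N) in bin $i$ is

$$M_{i,P/N} = \hat\theta_w \pm SD_{mH}\,\frac{mG_i - MED_{mG}}{SD_{mG}},$$

i.e. the genome-wide CpH rate moved up or down by the bin's CpG
methylation z-score rescaled to CpH units. The prior carries pseudo-counts
$\alpha_i = n_{i,\mathrm{CpG}} M_{i,j}$ and
$\beta_i = n_{i,\mathrm{CpG}} - \alpha_i$ — as much weight as the bin's
CpG reads — giving the posterior mean

$$\hat\theta_{i,j} = \frac{m_i + \alpha_i}{n_i + n_{i,\mathrm{CpG}}}.$$

The emission probability of state $j$ in bin $i$ is the binomial
likelihood $\mathrm{Bin}(m_i \mid n_i, \hat\theta_{i,j})$. Undetected
bins get emission 1 for every state: they are uninformative but are
retained inside chains so that bin distance equals genomic distance,
which keeps the 540-bp linking rule and the 100-kb splitting rule in
one coordinate system. Note the two read totals play different roles:
the CpH total drives the likelihood, the CpG total the prior weight.
With genome-typical densities (roughly 2 CpG vs 21 CpH sites per bin)
the prior weight is about a tenth of the data weight, so single-bin
emissions separate P from N only weakly — by design, the transition
structure is what accumulates this weak evidence along a region.

Numerical choices: prior means and posterior rates are clamped to
$[10^{-6}, 1-10^{-6}]$ (the linear prior formula can leave $[0,1]$, and
a binomial rate must be interior); $SD$s are sample (n−1) standard
deviations over detected bins; all chain computations are in log space
(products over $10^5$ bins underflow otherwise); all ties break
deterministically toward the earlier state in (P, N, U) order.

### Training and decoding

Chains are built per chromosome and split wherever a run of undetected
bins spans more than 100,000 bp (strict, measured in bp); leading and
trailing undetected bins are trimmed. One transition matrix is trained
per sample on all chains pooled, by Baum–Welch restricted to the
transition matrix and initial distribution — the emissions are fixed,
bin-specific binomials and are never re-estimated. Iteration stops when
no transition probability moves by more than $5\times10^{-4}$
(`tol`), with a 500-iteration cap; the per-iteration log-likelihood is
recorded and is non-decreasing.

EM initialization was a genuinely open choice. From a uniform start
(all entries 1/3) the algorithm reliably converges, on data of this
shape, to a degenerate optimum in which the N state has a
near-zero self-transition — it gets used as an isolated "noise" state
and no contiguous N region can survive decoding. The package therefore
starts from a diagonal-dominant matrix (0.9 on the diagonal), which
encodes the same positional-continuity assumption that motivates using
an HMM at all; a uniform start remains available via
`transition_init`. The fitted matrices are insensitive to the exact
diagonal value.

Decoding is exact Viterbi in log domain. `emission_argmax_states()`
provides the memoryless baseline (each detected bin takes its
highest-emission state). After decoding, same-state runs separated by
fewer than 3 bins (540 bp) are linked; linking is a single
left-to-right pass so segments never overlap, absorbed gap bins are
counted but keep their own per-bin state for level computations, and
the N-state segments are reported as CpG–CpH DMRs.

## DMR classification and annotation

Each DMR's mCpH level (methylated CpHs / CpHs in the region) is
compared against the genome-wide level: fold change $>2$ defines a
hyper-mCpH DMR, $<0.5$ a hypo-mCpH DMR (both strict). A pseudo-level of
$10^{-4}$ guards the zero-denominator case, the same guard used when
displaying log fold changes. Annotation overlap
(`overlap_fraction_table()`) merges intervals before counting, so
fractions are true base-pair fractions and never exceed 1.
`proximity_profile()` reproduces the mCpG-centered mCpH metaplot: for
every methylated (or unmethylated, $Me < 0.05$) CpG, same-strand CpH
levels within ±1 kb are binned by signed offset in the center's 5'→3'
orientation (minus-strand centers mirrored) and smoothed with a
50-bp sliding window. The window steps by 1 bp — the finest choice
consistent with "50-bp sliding" — and covers offsets
$[o-25, o+24]$.

## The simulator

`plant_truth()` + `simulate_methylome()` generate the validation
construction: a synthetic chromosome with a configurable number of
non-overlapping N-state regions (lengths uniform on 1–100 bins) planted
in a P-state background. Per bin, the CpG level $Me$ is uniform on
(0, 1); CpH sites methylate at $0.1\,Me$ in P bins and $0.1\,(1-Me)$ in
N bins — the planted anticorrelation — and at $0.1 \times 0.5$ in U
bins (used only by the Markov-chain truth generator). Site counts per
bin are Poisson (defaults 2 CpG and 21 CpH sites per 180-bp bin,
matching genome-average dinucleotide frequencies), positions are
uniform within the bin (the rare position collisions are dropped so
site keys stay unique), and per-site depth is Poisson(10); a fixed-depth
mode aids exact tests. The construction as written draws the
*methylated* reads with probability $Me$; a `strict_complement_mode`
flag flips to the complementary convention for comparison.

What the simulator does *not* emulate: spatial autocorrelation of CpG
methylation (real methylomes are bimodal and regionally coherent; here
$Me$ is i.i.d. per bin), CpG islands and other density heterogeneity,
mapper-specific biases (one read source), and sequence context beyond
sampled trinucleotide labels. Passing benchmarks therefore demonstrate
the estimator's correctness under the stated generative model, not
performance on real tissue.

## Validation results and problem sizes

The test suite validates each layer at these scales (chosen so the
whole suite runs comfortably on a laptop):

* binomial tail and emission normalization: exhaustive for all
  $m \le n \le 50$, tolerance $10^{-12}$ / $10^{-10}$;
* Viterbi: 100 random chains of up to 10 bins against full $3^L$
  enumeration;
* FDR calibration: the 200,000-site construction above;
* transition recovery: a known sticky transition matrix
  (0.9 diagonal) on 20,000 bins, recovered within 0.05 elementwise.
  This experiment uses an emission-informative configuration (10 CpG
  and 10 CpH sites per bin, depth 30) because it tests the estimator,
  not the model's per-bin discriminative power — under genome-typical
  densities the P/N emissions are deliberately weak per bin and no
  estimator could pin transitions that tightly;
* end-to-end benchmark: 30 replicate genomes of 50,000 bins with 50
  planted regions, comparing emission-only against full decoding.

On the benchmark, full decoding raises mean bin-level precision from
about 0.25 to about 0.98. Mean bin-level recall, however, is lower
than the emission-only baseline (about 0.46 vs 0.58 at this region
density): with 50 regions in 50,000 bins the prior odds of entering an
N run are low, and the maximum-a-posteriori path only calls regions
whose accumulated evidence overcomes that entry cost, whereas the
memoryless baseline scatters N calls widely (four out of five of which
are false) and hits many true bins by volume. At higher planted-region
densities, or counting whole regions rather than bins, the comparison
shifts in Viterbi's favour; the package reports both callers so users
can weigh the trade-off on their own data.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(genome_length = 5000 * 180, n_regions = 10, seed = 42)
truth <- plant_truth(cfg)
methylome <- simulate_methylome(truth, cfg)

seg <- segment_methylome(methylome)
glance(seg)
calls <- call_sites(methylome, R = 0)
dmrs <- region_methylation(calls, seg$dmrs) |>
  classify_dmrs(genome_mcph_level(calls))
dplyr::count(dmrs, klass)
evaluate_precision_recall(seg$bins, truth)
```

## Limitations

* The non-conversion rate is a required input, not estimated from
  spiked-in reads.
* No posterior-marginal decoding; the decoded path is the single MAP
  path.
* One transition matrix per sample (no per-chromosome matrices).
* The empirical-FDR grid is the only multiple-testing treatment for
  CpH calls.
* Bin-level evaluation only; no region-matching criterion for
  precision/recall.
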
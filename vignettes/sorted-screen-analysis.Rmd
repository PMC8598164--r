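---
title: "Analysing FACS-sorted CRISPR knockout screens with sortscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing FACS-sorted CRISPR knockout screens with sortscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscreen)
```

## The experimental design being modelled

A pooled CRISPR knockout library (four sgRNAs per protein-coding gene plus
1,000 non-targeting control guides) is introduced into cells, the cells are
stimulated, and fluorescence-activated cell sorting splits the population
into marker-**high** and marker-**low** bins for each of several inducible
surface markers — here MHCII, CD40 and PD-L1 after IFN&gamma; stimulation,
each screened in duplicate. Guides are PCR-amplified and sequenced from each
sorted bin and from the unsorted input library. A knockout that blunts the
response leaves its guides depleted from the high bin and enriched in the
low bin; a knockout that exaggerates the response does the opposite.

`sortscreen` takes the guide count tables as its input boundary (read
trimming and alignment are upstream concerns) and carries the analysis from
counts to a single ranked gene list, gene-set enrichment, and
protein-complex-level statistics. A fully seeded simulator generates screens
of the same shape with known ground truth, so every stage of the pipeline is
testable at desk scale.

## Normalization and the guide-level null

Sequencing depth varies per sample, so counts are scaled by
median-of-ratios size factors: each sample's factor is the median, over
guides detected in every sample, of the ratio between its count and the
guide's geometric mean across samples. After scaling, the median ratio of
every sample to that reference is exactly 1. Re-normalizing a normalized
matrix can change it only by one global constant (the median/geometric-mean
commutator, within a couple of percent of 1 on count data) — never the
relative structure the downstream model consumes.

Per-guide enrichment is `log2((high + c) / (low + c))` on normalized counts
with pseudocount `c = 1` by default; the pseudocount bounds the fold change
of dropout guides and is exposed because the analogous choice upstream of
published fold-change figures is rarely stated. Gene-level significance at
this stage standardizes the mean of a gene's guides against the empirical
NTC distribution. The z-score divides by `sd_NTC / sqrt(n_guides)` — the
standard error of a mean of `n` null guides — rather than by the raw NTC
spread; with the raw spread the statistic would be conservative by a factor
of `sqrt(n)` and its null false-positive rate would sit near zero instead
of the nominal level. Under the simulator's null the empirical
false-positive rate at &alpha; = 0.05 lands within 0.03–0.07 (tested).
Benjamini–Hochberg adjustment is applied across genes.

## The selection-coefficient model

The core estimate is a gene-level selection coefficient &beta; on the log2
scale, fitted by negative-binomial maximum likelihood. For guide *i* of a
gene in sample *j*:

$$ y_{ij} \sim \mathrm{NB}(\mu_{ij},\ \alpha_i), \qquad
   \mu_{ij} = s_j \, \mu_i \, 2^{\sum_k d_{jk} \beta_k} $$

with size factors $s_j$, per-guide baseline abundances $\mu_i$ (nuisance),
per-guide dispersion $\alpha_i$, and a design matrix $d$ whose rows are the
samples and whose columns are the modelled conditions; input-library
samples have all-zero rows and act as the baseline. Positive &beta; means
enrichment relative to the input. Two designs mirror the two published
analyses:

* **marker-blind** — two conditions (all low bins, all high bins), pooling
  the three markers so each sorted selection acts as a replicate; used for
  the combined analysis.
* **marker-aware, bin-specific** — one condition per marker within one bin,
  used to find marker-specific regulators.

Dispersions are method-of-moments per guide,
$\hat\alpha = \max(10^{-4}, (s^2 - m)/m^2)$ on normalized counts, shrunk
halfway (log scale) toward a least-squares trend on log mean. The trend
borrows strength across the library; the floor keeps the model defined for
guides without excess variance. Because the per-guide variance is taken
across all samples, genes under real selection receive somewhat inflated
dispersions — a conservative choice that barely moves $\hat\beta$ (the NB
mean estimate is robust to $\alpha$) but widens its confidence band.

The joint likelihood in $(\log\mu, \beta)$ is maximized by Newton
iterations with step-halving and an active-set treatment of the box
constraint $\beta \in [-8, 8]$ (outward-pointing bound coordinates are
frozen out of each Newton system). The bound exists because the unpenalized
MLE diverges whenever a condition's counts are all zero — common for strong
hits in a small sorted bin. Convergence requires both a log-likelihood
change below 1e-8 and a parameter change below 1e-6, within 200 iterations;
the rare non-converged gene falls back to profiled coordinate grid search
and is flagged. On random single-guide instances the fit agrees with an
exhaustive profiled grid search over $\beta$ (step 0.001) to better than
0.01 (tested, 100 instances).

Wald z-scores come from the observed information (Schur complement of the
nuisance block), giving a one-sided p pair that partitions the unit
interval, a two-sided p, and per-condition BH FDR across genes. Because
Wald calibration is imperfect for counts near zero, an empirical null is
fitted alongside: the NTC guides are partitioned (seeded) into pseudo-genes
of four guides, fitted identically, and each real gene's |z| is ranked
against the pseudo-gene distribution (`ntc_p`, `ntc_fdr`). The calibration
test uses this NTC-based FDR.

Two properties the model deliberately does **not** have: exact
scale-equivariance (multiplying one sample's integer counts by *c* changes
the information content, not just the scale, so $\hat\beta$ can drift by a
few hundredths even though the size factors absorb *c* exactly), and
guide-outlier rejection (no EM-style guide removal; every guide of a gene
informs its &beta;).

## Cross-screen integration and ranking

Per-condition results are combined per gene: `beta_sum` is the plain sum of
condition &beta; values, `z_sum` is Stouffer's equal-weight combination
$\sum z_i / \sqrt{k}$, `p_sum` its two-sided normal p-value (the published
description does not state sidedness; one-sided is a flag, and the
combination mode is recorded in the output attributes), and the gene score
is

$$ \mathrm{score} = \log_{10}(p_{\mathrm{sum}}) \times \beta_{\mathrm{sum}}. $$

Genes are ranked by descending score, ties broken by larger
$|\beta_{\mathrm{sum}}|$ then gene name, so the ranking is a deterministic
permutation of its input. A positive regulator of the response is depleted
from the high bins (strongly negative &beta; there, since a shifted latent
distribution empties the far gate super-exponentially) and enriched in the
low bins (moderately positive &beta;), so its `beta_sum` is negative, its
score positive, and it rises to the top of the list.

**Known limitation.** For *weak* effects the high- and low-bin z-scores are
of comparable magnitude and opposite sign, and plain summation partially
cancels them; the combined statistic is then inefficient, and the combined
rank of a weakly selected shared regulator is only about as good as — not
reliably better than — the best of its three single-screen ranks. At the
effect sizes the screens were designed around (several latent standard
deviations) the asymmetry between gates makes the combination decisive: the
planted-regulator recovery test places at least 8 of 10 shared regulators
in the top 20 of roughly 2,000 genes in every tested seed.

The most selected genes — the union over screens of each screen's 5% most
enriched or depleted by &beta; (2.5% per tail) — are clustered with
k-means (k = 8, 25 seeded restarts, best inertia kept) on their per-screen
&beta; vectors, separating shared from marker-specific regulators.

## Gene-set enrichment

Preranked GSEA on the descending gene-score list uses the weighted
running-sum statistic (hits increment by $|s|^p/\sum_{\mathrm{hits}}|s|^p$
with p = 1, misses decrement by $1/(N - N_{\mathrm{hits}})$; the ES is the
signed maximum deviation, exact ties resolving positive). The null is a
seeded gene-label permutation (random same-size sets), the natural choice
for a preranked list. Normalization is sign-matched mean division
("meandiv"): NES = ES over the mean |null ES| of the same sign; the nominal
p comes from the same-sign null tail and the FDR q from the standard pooled
normalized-null ratio, clamped to [0, 1]. Sets are filtered to 10–500 genes
after intersection with the list. The implementation is checked against
brute-force evaluation of the running sum on short lists and against an
independent implementation (`fgsea::calcGseaStat`) to machine precision,
and a set planted as the top 20 of 1,000 genes reaches NES > 2 with
q < 0.025 at 1,000 permutations — the conventional reporting bar.

## Complex-level statistics

Two bespoke statistics address protein complexes such as respiratory-chain
complex I:

* **Binomial depletion/enrichment.** For a gene's *n* guides (or a module's
  pooled member guides), *x* counts how many fall beyond the library-wide
  null median of the guide statistic in the tested direction; the one-sided
  p is the upper binomial tail at $p_0 = 0.5$. Guides exactly at the median
  count as not-beyond. The published description ("the expected median
  probability") is read as a median split; $p_0$, the statistic, and a
  rank-based alternative are exposed rather than silently chosen. With four
  guides the smallest attainable p is $1/16$, so the test is conservative
  at &alpha; = 0.05 by construction; p-values match exhaustive enumeration
  of all $2^n$ outcomes exactly (tested to n = 12). Per-unit p-values are
  reported unadjusted, matching threshold-star reporting; BH is a flag.
* **N-module stability score.** From a subunit-KO proteomics matrix of
  median log2 abundance ratios, the score of a knockout is the sum over the
  nine N-module members minus the knocked-out subunit's own term (which
  reflects the deletion, not module stability). The score is correlated
  (Pearson, Fisher-z 95% CI, two-sided t on n − 2 df) with each subunit's
  screen &beta;, excluding listed genes — the use case being an essential
  subunit whose surviving guides must have spared function. The external
  proteomics processing is out of scope: the matrix is an input, and the
  package ships a clearly labelled synthetic generator
  (`simulate_subunit_proteomics()`) in its place.

## The simulator: what it emulates, and what it does not

`simulate_screen()` draws log-normal baseline guide abundances
(`sdlog = 0.3`), assigns cells to guides multinomially at 250 cells per
guide, gives each cell a latent marker value
`efficiency * delta(gene, marker) * sigma + Normal(0, sigma)`, sorts by
population-quantile gates (15% high, 15% low — gates in the screens were
likewise set on control populations, and quantile gates keep bin occupancy
exactly at the configured fraction), and multinomially subsamples each bin
and the pre-sort input pool to 400 reads per guide. Guide efficiencies are
Beta(5, 1.5): most guides cut well, a tail is weak, reproducing the
observation that sibling guides of one gene differ in effect. Default
effects are ten shared positive regulators at &delta; = −4&sigma;; shared
negative, marker-specific, and arbitrary per-gene (`custom_deltas`) effects
are configurable. Sample sizes above are the package defaults used
throughout the tests and the acceptance script.

Deliberately not modelled: lentiviral multiplicity of infection, growth
between transduction and sort, PCR jackpotting, copy-number effects, and
guide off-targets. Passing tests on this generator therefore demonstrate
the statistical machinery — calibration, ranking, recovery — under clean
sampling assumptions, not robustness to those artefacts in real screens.

## Numerical and design choices, collected

* Delimiters are auto-detected (tab preferred, comma fallback); GMT is
  tab-only. Gene symbols compare case-sensitively (mouse symbols are
  case-meaningful). Guides missing from a count table are zero-filled with
  a warning — dropout is signal in a pooled screen, not missingness.
* Pseudocount 1.0 after normalization; &beta; bounds ±8; dispersion floor
  1e-4; NTC pseudo-gene partition seed defaults to 1 and is recorded in the
  result attributes.
* Wald inference replaces permutation p-values for determinism and speed at
  desk scale; the NTC pseudo-gene empirical null is the robustness backstop.
* Guide-level gene tests use the NTC standard error of the mean (above);
  the published per-figure Tukey comparison against 1,000 NTCs is
  under-specified for reimplementation and was not reproduced.
* k-means restarts: 25; identical-row degeneracy collapses to the number of
  distinct rows and is flagged rather than erroring.
* `stouffer()` combines across all supplied conditions with equal weights;
  composition mode and sidedness are recorded in output metadata because
  the published description is ambiguous between combining two bin-level
  z's and combining across more conditions.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run simulated screens of 2,000
genes (9,000 guides, 14 samples) for calibration and recovery — 20
independent seeds for the recovery check — plus smaller screens (30–300
genes) for structural properties, 100 random instances for the grid-search
oracle, and 1,000-permutation GSEA on 1,000-gene lists. These sizes were
chosen so the whole battery completes in minutes on one CPU while keeping
every statistical bar meaningful (2,000 null genes bound the false-positive
rate estimates' noise well below the tested margins).
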
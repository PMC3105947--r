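---
title: "Methods: expression QTL mapping on recombinant inbred panels"
author: "rieqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression QTL mapping on recombinant inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rieqtl)
```

# The setting

Recombinant inbred (RI) panels such as the BXD family are fixed homozygous
mosaics of two parental genomes (C57BL/6J, "B", and DBA/2J, "D"). Because each
strain's genome is a permanent, fully genotyped patchwork, transcript
abundances measured across the panel become mappable quantitative traits:
variation in a transcript that co-segregates with the genotype at some locus
identifies an expression QTL (eQTL). An eQTL on the transcript's own
chromosome within 10 Mb of the gene is called *cis*; anything else is
*trans*. The same strain-mean expression matrix supports a second kind of
analysis: transcripts that co-vary across strains — because they share a
regulator or are expressed in the same cell type — form correlation networks
and cell-type signatures.

`rieqtl` implements this whole chain as composable, deterministic functions,
and ships a synthetic panel generator with planted ground truth so that every
stage has a recovery test that does not depend on external data.

# Normalization

`normalize_panel()` applies, in order:

1. add an offset of 1 to each raw intensity (all logs positive),
2. log2,
3. quantile normalization across the full set of arrays,
4. per-array Z scores,
5. rescale as $2Z + 8$.

After step 5 every array has mean 8 and population standard deviation 2
(asserted to $10^{-9}$ in the tests), and one unit corresponds approximately
to a two-fold expression difference. Two choices here were genuinely open:

* **Z per array, not pooled.** Z scores could be computed per array (across
  probes) or over the pooled value matrix. We compute them per array, which
  makes the mean-8/SD-2 contract exact per array; after quantile
  normalization the two choices almost coincide anyway, because all arrays
  share a sorted value vector.
* **Population SD.** The Z denominator uses the $n$-denominator standard
  deviation so the contract is exact rather than exact-up-to-$n/(n-1)$.
* **Quantile ties.** Tied values within an array all receive the mean of the
  rank-mean reference values over the ranks the tie occupies, making the
  result invariant to tie ordering. On tie-free data the step agrees with
  `limma::normalizeQuantiles` to $10^{-12}$ (checked in the tests, where
  limma serves as an independent oracle, not as the implementation).

A side effect of the per-array Z step worth knowing about: any component
shared by a *large fraction* of the probes on an array (for example a
co-expression module that dominates a small synthetic panel) shifts that
array's mean and SD and is therefore partially absorbed by the
standardization. On realistic panels (tens of thousands of probes, modules of
tens of genes) the effect is negligible; on toy panels where a module is 10%
of all probes it visibly attenuates correlations. Synthetic-panel tests of
network recovery therefore keep modules at a few percent of the probe set.

# Heritability

`anova_heritability()` implements the one-way ANOVA estimator with mouse
strain as the single factor:

$$ h^2 = \frac{MS_{between}}{MS_{between} + MS_{within}} $$

on mean squares (unbalanced designs use $\sum_i (n_i - 1)$ within-strain
degrees of freedom). This estimator is implemented verbatim and deliberately
not replaced by REML or a variance-component ratio. Users should know its
sampling behaviour: with $n$ replicates per strain its expectation is
$(\sigma_e^2 + n\sigma_b^2)/(2\sigma_e^2 + n\sigma_b^2)$, which is an upward-
biased transform of the intraclass correlation
$\sigma_b^2/(\sigma_b^2+\sigma_e^2)$ and tends to 1, not to the ICC, as
replication grows. It is monotone in $\sigma_b^2/\sigma_e^2$, so rankings of
transcripts by heritability are unaffected. The synthetic truth table records
both the planted ICC and the analytic expectation of this estimator at the
panel's replicate count (`h2_expected`), and the tests check estimates
against the latter — the correct oracle for the estimator as defined.

# Interval mapping

## Pseudomarker grid

`expected_dosage()` builds a scan grid at 1 cM steps (marker positions always
included). Genetic distance is converted to an RI-scale recombination
fraction in two steps: Haldane's map function $r = (1 - e^{-2d/100})/2$, then
the Haldane–Waterman map expansion for sib-mated RI lines,

$$ R = \frac{4r}{1 + 6r}, $$

which is the probability that two loci are discordant in a fixed RI genome.
The package validates this operator against a forward pedigree simulation of
sib mating to fixation (an independent oracle in the test suite). At each
pseudomarker the expected dosage $P(D) - P(B) \in [-1, 1]$ is computed per
strain by conditioning on the nearest non-missing flanking markers under a
Markov model with RI-scale transition probabilities; a deliberately simpler
scheme than a full multipoint HMM, adequate at the low missingness of dense
RI genotype files and documented as a limitation for sparse data. The X
chromosome is scanned like the autosomes on dosage codes; Y and the
mitochondrial genome are never generated or scanned.

## Haley–Knott regression

`hk_scan()` regresses the per-strain trait (one value per strain; replicate
arrays are averaged and F1 arrays excluded by `summarize_by_strain()`) on the
expected dosage at each position and reports

$$ \mathrm{LRS} = n \ln \frac{RSS_0}{RSS_1}, \qquad
   \mathrm{LOD} = \mathrm{LRS} / (2 \ln 10), $$

plus the additive coefficient (slope), signed so that positive means the D
allele increases the trait. With complete dosage data this is computed
through the simple-regression identity $RSS_1 = RSS_0 (1 - \rho^2)$,
vectorized as one matrix product over all positions (and, for transcriptome
scans and permutations, all traits at once); positions with missing dosage
fall back to a per-position fit with pairwise strain dropping. Near-perfect
fits ($RSS_1 < 10^{-12} RSS_0$) are capped at $n \ln 10^{12}$ and flagged
`saturated`. The tests verify exact agreement ($\le 10^{-9}$) with a
brute-force `lm()`-based oracle at observed markers.

## Permutation significance

`permutation_null()` permutes trait values over strain labels, keeping
dosages fixed, rescans the genome per permutation and records the genome-wide
maximum LRS; `empirical_p()` applies the plus-one estimator
$p = (\#\{ \text{null} \ge \text{obs} \} + 1)/(N + 1)$, which cannot return
zero. On a synthetic panel at the emulated study's scale — 57 strains, 19
autosomes plus X of ~80 cM each carrying ~3,800 markers, scanned at 1 cM —
the 95th percentile of 1,000 permutation maxima lands at LRS ≈ 16.5–17.5
across seeds, consistent with the conventional genome-wide significance level
of LRS 18 (LOD ≈ 3.9) used for such panels. (That level is sometimes printed
with a genome-wide *p* of "< 0.5"; the package treats the 0.05 quantile as
the significance contract, reading the 0.5 as a typo.)

# eQTL cataloguing

`transcriptome_scan()` records each transcript's peak position (ties broken
by lowest chromosome, then lowest position), classifies it with
`classify_eqtl()` — *cis* iff same chromosome and $|\Delta| \le 10$ Mb,
boundary inclusive, distance measured from the probe's annotated point
position — and reports LRS, LOD, additive coefficient and the grand mean
expression. `threshold_counts()` tabulates cis/trans counts over the LRS
ladder 12/16/20/30/50, and `cis_candidates_in_interval()` shortlists
cis-regulated transcripts inside a phenotype QTL support interval, the
standard candidate-gene step. Per-probe genome-wide empirical p-values are
optional because their cost is `n_perm` full scans per probe.

# Correlation networks and signatures

`correlation_pairs()` lists unordered probe pairs whose Pearson or Spearman
correlation across strain means clears a threshold (both statistics are
always reported). `correlation_test()` converts $r$ to a two-sided p-value
through the exact-under-normality transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$; the same transform applied to Spearman's
$\rho$ is a documented approximation. `pc_signature()` extracts a cell-type
style signature: PC1 of a strain-standardized seed-gene submatrix
(correlation-matrix PCA; sign fixed so the mean seed loading is positive,
making results invariant to per-seed sign and scale), then all probes whose
correlation with the PC1 scores clears either an $|r|$ threshold (default
0.8) or a p-value threshold — both gating modes exist because both are used
in practice.

# The synthetic panel generator

`simulate_ri_genotypes()` draws each strain as an independent Markov mosaic:
the first marker of a chromosome is B or D with probability 1/2 and each
inter-marker transition flips parental origin with probability $R$ of the
spacing. Residual heterozygosity is not modelled (real RI strains are
homozygous at almost every locus; the simplification is deliberate).
`simulate_expression_panel()` generates log2-scale values

$$ y = \text{baseline} + a\,g + \lambda z + s_{sex} + u_{strain} +
   \varepsilon_{array} $$

and exponentiates (`2^y`) so the raw files carry realistic skew into the
normalization chain. Planted structure — cis effects (annotated within 2 Mb
of their marker), trans effects (marker on another chromosome), Mendelian
bimodal transcripts at their cognate locus, sex-specific transcripts, and
latent module drivers standing in for immune-cell-proportion variation — is
recorded in a truth table for recovery testing.

Default conditions emulate the study scale: 57 strains, 20 chromosomes of
80 cM at 0.42 cM marker spacing (~3,820 markers), 2 Mb per cM, two replicate
arrays per strain. Within-strain (replicate-array) noise is a free parameter:
the emulated design pooled RNA from several animals per strain, so its true
within-strain variance is unknowable; the default SD of 0.5 log2 units gives
within-strain scatter modest relative to typical strain effects (0.3–1.0),
which is the regime pooled designs are built to reach. Planted effect sizes
default to 1.5 log2 units per allele for cis effects (strong, as cis effects
empirically are) and 1.0 for trans. Module drivers are standard normal
per-strain scores; member loadings are expressed as the driver's share of the
strain-mean SD (default 0.9), with the total strain-mean SD normalized to 1.

What the generator does *not* emulate — and therefore what passing recovery
tests do not show about real data: probe-level hybridization artifacts,
batch/array-date structure, linkage between planted trans loci and real
regulatory networks, non-normal expression distributions beyond the log-scale
skew, and genuine cell-composition differences (modules are linear latent
factors). Recovery rates on this generator are best-case figures for the
statistical machinery, not predictions of biological discovery rates.

# Numerical and design notes

* All stochastic functions take an explicit integer seed and are bit-
  reproducible; `run_pipeline()` fans a single seed out to per-stage child
  seeds by stable hashing so stages can be re-run independently.
* Genotype codes are fixed as B = −1, D = +1, so a positive additive
  coefficient always means the D allele increases the trait.
* Peak ties (exactly equal LRS) break to the lowest chromosome, then lowest
  position; grid order follows the marker map's chromosome order.
* Degenerate inputs fail loudly: constant traits, zero-variance arrays after
  quantile normalization, seeds absent from the panel and malformed intervals
  are errors naming the offending object; constant probes in scans and
  non-bimodal probes in the strain-identity check are skipped with warnings.
* QC calls use deterministic 2-means splits (centers seeded at the range
  extremes) rather than fixed cutoffs; the strain-identity check gates probes
  on a 1-D silhouette of the split (default 0.65, separating unimodal from
  genotype-driven bimodal distributions with margin on both sides).
* Test and example problem sizes are chosen so the whole suite runs in a few
  minutes on one CPU: thresholds and null calibration use 1,000 and 199
  permutations respectively, recovery suites use 100–200 probes. These sizes
  are stated in the tests themselves.

# Known limitations

* Missing-genotype handling conditions on the nearest informative flanks
  only; a full multipoint HMM would use the entire chromosome.
* No kinship or polygenic-background correction: the scan assumes
  exchangeable strains under the null, as the permutation scheme does.
* The heritability estimator is the mean-square ratio described above, with
  its known bias; it is kept because it is the estimator this analysis
  tradition reports.
* Spearman p-values reuse the t transform rather than exact rank-permutation
  tails.
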
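---
title: "Methods: summary-statistic X-WAS, colocalization, and chemical gene-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistic X-WAS, colocalization, and chemical gene-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xwas)
```

This vignette is the package's own account of the statistics it implements:
the models, the assumptions they rest on, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical decisions taken where a formula alone
does not pin down an implementation.

## 1. The association model

A proteome- or transcriptome-wide association scan asks, gene by gene,
whether genetically predicted molecular abundance covaries with a trait.
Three inputs meet at each gene:

* a cis-SNP **weight vector** `W` predicting the gene's abundance from
  standardized dosages,
* GWAS summary **Z-scores** `Z` at those SNPs, and
* the SNP-correlation (**LD**) matrix `S` from a reference panel.

The gene-level statistic is `z = W'Z / sqrt(W'SW)`. Its null distribution
is standard normal when the GWAS Z-scores are jointly normal with
covariance `S` — the standard summary-statistic model, exact for linear
association on a common sample and a good approximation for large
meta-analyses. `z` is invariant to rescaling `W` and to coherent allele
flips, and reduces to the single SNP's Z when `W` is an indicator vector;
all three properties are enforced by tests.

**Permutation P.** The asymptotic P ignores that weights were themselves
selected on a reference cohort and that a locus may carry GWAS signal not
mediated by this gene's abundance. The empirical P conditions on the
observed local GWAS signal and LD by permuting the weight-to-SNP assignment
within the locus and recomputing `z`; with add-one counting,
`p_perm = (1 + #{|z_perm| >= |z_obs|})/(n_perm + 1)`, never zero and never
below `1/(n_perm + 1)`. Two-sided exceedance (`|z|`) is used because the
scan reports signed Z with unsigned significance. A sign-flip variant
(random ±1 on each weight) is available for sensitivity analysis. The
default `n_perm` is 5000; tests and the bundled pipeline configurations use
smaller values, which only coarsens the attainable P granularity.

One consequence worth knowing: if a weight vector is 1-sparse (the top-SNP
model), a fraction ~1/m of permutations recreates the observed statistic
exactly, so `p_perm` cannot fall below about `1/m` no matter how strong the
signal. Realistic cis loci (tens to hundreds of SNPs) and denser weight
models both relieve this; it is the main reason the pipeline defaults use
30-SNP cis blocks and several weight estimators.

## 2. Weight training and the heritability screen

Weights are trained per gene on standardized cis dosages and a standardized
molecular trait, with k-fold cross-validation (default 5 folds, seeded fold
assignment) scoring each of four estimators by out-of-sample
`R2 = 1 - SSE/SST` (clamped to [-1, 1]); the best model is kept, with fixed
tie-break precedence spike_slab > elastic_net > ridge_blup > top1.

* **top1** — the single SNP with the largest marginal |correlation|.
* **ridge_blup** — `(X'X + kappa I)^{-1} X'y` with
  `kappa = m (1 - h2)/h2`, the BLUP ratio for m exchangeable cis effects;
  `h2` is the gene's Haseman-Elston estimate clamped to [0.01, 0.99].
* **elastic_net** — glmnet at alpha = 0.5; the penalty is chosen once per
  gene by internal cross-validation on the full data and held fixed across
  the outer folds (a deliberate economy: the outer CV then measures the
  fitting procedure at a fixed penalty, at a small optimistic bias in the
  penalty choice itself).
* **spike_slab** — a Gibbs sampler for `b_j ~ pi N(0, sb2) + (1-pi) d0`
  with Beta prior on `pi` and inverse-gamma variance updates, returning the
  posterior mean of `b`. This is a compact stand-in for the sparse Bayesian
  linear mixed models ordinarily used to train such weight panels: it keeps
  the qualitative behaviour (adaptive sparsity, dense posterior-mean
  weights) without a full mixed-model MCMC. 600 iterations with 200
  burn-in are enough at cis-locus scale; the sampler is compiled and uses
  R's RNG, so it is reproducible under a seed.

Genes whose best cross-validated R2 is not positive are flagged
non-predictive and excluded from scans by default.

**Heritability screen.** "Significantly heritable" genes are retained
before association. Cis h2 is estimated by Haseman-Elston regression of
off-diagonal trait cross-products on the cis genetic-relatedness entries;
the estimate is the slope, clipped to [0, 1] with the raw value kept. For
the P value, the plain normal approximation to the slope proved too
light-tailed at realistic locus sizes: the slope is a quadratic form in the
trait with only ~m effective degrees of freedom, and its null kurtosis is
far above 3. The package therefore computes the P from the score statistic
`T = y'Ky - tr(K)` with the Liu-Tang-Zhang moment-matched chi-square tail
(the approximation used throughout the variance-component testing
literature), which restored uniform null P values in calibration tests.
The screening threshold `alpha_h2` defaults to 0.01; the source panels the
design emulates do not publish their criterion, so the threshold is exposed
as a parameter.

## 3. Colocalization

For genes passing the association screen (asymptotic P < 0.05 by default —
the conventional screening gate; the permutation P can be selected
instead), the package computes Wakefield log approximate Bayes factors per
SNP for both the GWAS trait and the molecular trait,
`log ABF = 0.5 log(1-r) + r z^2/2`, `r = prior_var/(prior_var + v)`, where
`v` is the squared standard error (taken from the QTL summary, or derived
as `1/(2 f (1-f) n)` when only Z, allele frequency, and sample size are
available). The five-hypothesis posterior follows the standard
single-causal-variant sums: H1 and H2 from each trait's ABF sum, H4 from
the product-series sum, H3 from the cross-product minus the diagonal, all
combined with priors `p1 = p2 = 1e-4`, `p12 = 1e-5` (the canonical
defaults; the design this package emulates states none). Everything is
computed in log space with log-sum-exp and a log-difference for H3, so
|z| up to 40 does not overflow, and a single-SNP region yields PP3 = 0
exactly by algebraic cancellation.

Prior effect variances default to 0.15^2 for quantitative molecular traits
and 0.2^2 for the (typically binary) GWAS trait. QTL summary statistics for
synthetic cohorts are the per-SNP marginal regressions of the trait on
dosage — the way real pQTL/eQTL inputs arise.

## 4. Gene-set enrichment

Genes are ranked by the association statistic, largest first. The ranking
statistic defaults to |z| (two-sided relevance); signed ranking is a flag.
Ties are broken lexicographically by gene id so that ranking is
deterministic. For a set C with N_C of N genes scorable, the running sum
gains `|GS_i|^H / N_R` at members (`N_R` the sum of member weights) and
loses `1/(N - N_C)` at non-members; ES is the maximum of the running sum,
H = 1 by default (the classic weighting). Because the sum terminates at 0,
ES lies in [0, 1]. The implementation evaluates only the peaks after each
member hit — an O(k) identity equivalent to the full prefix scan, verified
against a direct implementation in tests. Degenerate cases are defined, not
errors: a set equal to the whole universe has ES = 1; a set whose member
statistics are all zero has ES = 0 with a flag.

Two permutation nulls are provided. The faithful **snp_shuffle** mode
permutes the SNP-to-Z assignment of the GWAS, recomputes every gene's
association statistic, re-ranks, and recomputes ES — carrying the full
dependence structure of the pipeline into the null, at the cost of a full
re-scan per permutation. The fast **gene_shuffle** mode permutes the
gene-to-statistic assignment, equivalent to drawing a uniformly random
membership on the fixed ranking; it is exchangeable-correct for uniformly
drawn sets and is what the test suite uses. `NES = (ES - mean(ES_null)) /
SD(ES_null)` with the sample SD (n-1 denominator; the convention had to be
fixed somewhere, and the sample SD keeps NES of the null itself at exactly
mean 0, SD 1). The empirical P counts ES exceedances with the add-one rule;
since NES is a monotone transform of ES against the same null, counting on
ES and on NES are identical. Per-set RNG substreams are derived from the
master seed by set index, so results do not depend on collection order; the
substreams can be disabled to give duplicated sets identical nulls. A
degenerate null (zero SD) leaves NES missing, flagged, with the empirical P
still reported.

## 5. What the synthetic-data generator emulates

* **LD panel** — a latent Gaussian AR(1) per haplotype, thresholded at the
  allele-frequency quantile and summed to 0/1/2 dosages. One knob
  (`ld_decay`) controls neighbour correlation; 0 gives independent SNPs.
  MAFs are uniform on a configurable interval (default 0.05–0.5);
  positions are evenly spaced (default 10 kb) on one synthetic chromosome;
  alleles are fixed A/C with an exporter option to flip a random subset so
  harmonization is genuinely exercised.
* **Molecular traits** — `sqrt(h2) * standardized genetic score +
  sqrt(1-h2) * noise` from `n_causal` SNPs drawn within the cis window
  (default ±1 Mb in the standalone generator; the pipeline assigns each
  gene a disjoint SNP block). The same architecture can be projected onto
  independent cohorts, which is how discovery/replication panels share
  their genetics.
* **GWAS** — one draw `Z ~ MVN(sum_g lambda_g S W_g, S)` with each gene's
  true weights rescaled to `W'SW = 1`, so `lambda` *is* the expected
  gene-level association Z. That makes parameter recovery a sharp test:
  the Monte-Carlo mean of `z` over replicates must sit on lambda.
* **Chemical sets** — uniform draws from the gene universe, with enriched
  sets oversampling top-ranked genes with weight
  `exp(-strength * rank percentile)`; strength 0 is exactly uniform.

What it does **not** emulate: realistic allele-frequency spectra, variable
LD block structure, case/control liability-scale effects, trans effects,
covariate structure, or sample overlap between GWAS and reference panels.
Passing tests therefore demonstrate the statistical machinery under the
model's own assumptions — calibration of the permutation and enrichment
nulls, parameter recovery, posterior behaviour — not robustness to
real-data pathologies.

## 6. Numerical choices

* **LD stabilization.** Finite-panel correlation matrices are
  near-singular; `S` is stabilized as `(S + eps I)/(1 + eps)` with
  `eps = 1e-6`. Rescaling back to a unit diagonal (rather than leaving
  `1 + eps`) keeps the single-SNP reduction exact: an indicator weight
  vector returns the SNP's GWAS Z to machine precision.
* **Degenerate weighted variance.** `W'SW <= 1e-8` marks a gene
  unscorable ("degenerate weight variance") rather than dividing by a
  vanishing quantity.
* **Single-SNP loci.** The permutation null is undefined; the asymptotic P
  is reported with a flag.
* **Empirical P.** Add-one counting everywhere, for both the association
  and enrichment nulls: unbiased-conservative and never zero.
* **Seeds.** Every stochastic function is a pure function of an integer
  seed; seeds for sub-streams (per gene, per set, per pipeline stage) are
  derived deterministically from the master seed, so results are
  independent of iteration order and the caller's RNG state is never
  disturbed.

## 7. Study conditions and problem sizes

The pipeline defaults are the package's standing synthetic study: 200 genes
on disjoint 30-SNP cis blocks (10 kb spacing), `ld_decay = 0.6`, two causal
SNPs per gene at `cis_h2 = 0.5`, reference and cohort sizes of 400, three
mediated genes at `lambda = 6`, two proteome cohorts and one transcriptome
cohort, heritability screen at 0.01, association and enrichment
significance at permutation P < 0.05. Two causal SNPs and 30-SNP blocks
were chosen because they are the smallest configuration in which the
permutation test retains power for strongly mediated genes (see the
1-sparse caveat in section 1) while staying representative of a dense cis
locus.

The test suite and the acceptance script run the same machinery at reduced
sizes — loci of 10–30 SNPs, cohorts of 150–400, pipelines of 8–30 genes,
200–20000 permutations depending on what granularity the check needs, and
replicate counts of 30–50 for rate estimates. These sizes are the package's
chosen trade-off between the precision of each statistical check and a test
suite that runs in minutes on one CPU.

## 8. Known limitations

* The permutation scheme conditions on the GWAS signal; it tests whether
  the weights are more informative than a random assignment, which is
  deliberately conservative at loci with broad GWAS signal and sparse
  weights.
* The Haseman-Elston screen assumes exchangeable cis effects when tying
  the ridge penalty to its estimate; strong single-SNP architectures make
  `kappa` conservative (more shrinkage than optimal), which costs CV
  accuracy, not validity.
* Colocalization assumes a single causal variant per trait per region;
  multi-causal fine-mapping variants of the posterior are out of scope.
* The elastic-net penalty reuse across outer folds (section 2) slightly
  biases that model's CV score upward; selection between models is still
  honest because all models face the same folds.
* No multi-gene conditional analysis, no GWAS meta-analysis, no real-data
  ingestion beyond plain-text panel/summary/GMT formats (with optional
  PLINK ingestion explicitly out of scope).
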
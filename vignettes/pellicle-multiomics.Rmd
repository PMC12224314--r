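---
title: "Methods: substrate discrimination and protein-microbe association for salivary pellicle multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substrate discrimination and protein-microbe association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pellicca)
```

# Scope and data model

`pellicca` analyzes two blocks of measurements taken on the same set of
surface materials (substrates: dentine, enamel, titanium) but in
*different experiments*:

* a **protein intensity table** — LFQ-style intensities for a few hundred
  salivary-pellicle proteins across substrate × reading columns, with
  missing cells where a protein fell below the instrument's detection
  limit; and
* an **ASV abundance table** — zero-inflated, strongly right-skewed 16S
  counts for the adhering microbiota across substrate × replicate columns
  at two timepoints (2 h and 24 h of adhesion).

Because the two blocks never share a sample, any association between them
must be routed through the substrate factor. That single fact shapes the
whole pipeline.

# The pipeline, stage by stage

## Detection-limit imputation

Missingness in LFQ data is not at random: a missing cell means the
protein's intensity sat below the detection limit. The pipeline imputes
**one global constant** `c` at every missing cell (pooled across
substrates and readings), constrained to `(0, min observed intensity]`,
chosen to minimize the absolute Pearson second skewness coefficient of
the pooled distribution,

$$\mathrm{Sk}_2 = \frac{3(\bar{x} - \tilde{x})}{s}.$$

The mean is affine increasing and the median piecewise nondecreasing in
`c`, so `g(c) = mean − median` is continuous; when `g` changes sign on the
search interval, bisection finds the root (to `|g| ≤ 1e-9·mean` or an
interval below `1e-9` of its initial width) and the imputed distribution
has mean = median, hence zero `Sk₂`. When `g` does not change sign — the
typical case for raw lognormal-like intensities with moderate missingness,
where the pooled mean sits far above the median for every admissible `c` —
the constrained argmin of `|Sk₂|` is returned from bounded scalar
minimization with both interval endpoints checked.

Two consequences are worth stating plainly:

* In the no-sign-change regime the optimum often sits at the *lower*
  interval bound (`1e-9 ×` the minimum observed intensity). That is the
  faithful reading of the rule "a constant below the detection limit
  minimizing pooled skewness"; downstream stages are insensitive to the
  exact value because the screen is rank-based and association runs on
  log intensities.
* The achieved `|Sk₂|` can then slightly *exceed* the skewness of the
  present-only values — adding any mass at the bottom of a strongly
  right-skewed distribution can only widen it. The test suite asserts the
  skewness-reduction inequality only where it is mathematically
  guaranteed (the sign-change branch) and asserts grid-oracle optimality
  of the returned constant everywhere.

The objective is evaluated on the **raw intensity scale** by default (the
rule speaks of a constant *intensity*; no log transform is implied at this
step); `scale = "log10"` is available for sensitivity analysis.

## Offset-log transform for counts

Abundances are rescaled by `x → log10(α + x)` with

$$\alpha = 10^{\lfloor \log_{10} m \rfloor - 1},$$

`m` the smallest strictly positive abundance in the table: a power of ten
one decade below the minimum's decade, so zeros map just below the
smallest observed value. The bracket is read as **floor** (the convention
that keeps α a round power of ten); round-half-even is available behind
`bracket = "round"` because the notation is typographically ambiguous in
the source material. The pipeline computes one α from the pooled 2 h +
24 h counts so both timepoints share a scale.

## Kruskal-Wallis screening

Each feature is tested across substrates with the rank-sum statistic
(midranks; tie correction `1 − Σ(t³−t)/(N³−N)`; χ² tail on
`groups − 1` df). Retention is **strict**: `p < 0.05` for proteins and
annotation aggregates, `p < 0.01` for microbes, raw p-values by default
(matching the motivating analysis; Benjamini-Hochberg sits behind a
flag). A constant feature yields `H = 0, p = 1` rather than an error, so
uninformative features are silently non-significant.

Small-sample arithmetic matters here. With 3 readings × 3 substrates
(N = 9), perfect three-group separation gives the *maximum* H = 7.2 and
p = exp(−3.6) ≈ 0.027: the protein screen can only retain features that
separate essentially all three substrates, and **no** feature can reach
p < 0.01. This is why the synthetic world defaults to five microbial
replicates per substrate per timepoint — the smallest group size at which
the microbial threshold 0.01 is attainable at all (H_max = 12.5,
p ≈ 0.0019).

## Canonical LDA

On the retained features the pipeline fits canonical (Fisher) LDA: the
generalized eigenproblem of between-group scatter against the pooled
within-group covariance, regularized as

$$W_\lambda = (1-\lambda) W + \lambda \frac{\mathrm{tr}(W)}{p} I,$$

with λ the smallest of `{0, 1e-8, 1e-6, 1e-4, 1e-2}` giving condition
number < 1e12. The wide case — e.g. 110 retained proteins on 9 cases —
has a singular within-scatter, and the source material does not say how
its software coped; the shrinkage ladder is this package's choice and the
λ used is recorded in the model and the output JSON. Axes are scaled so
case scores have identity pooled within-group covariance; reported
per-feature effects are **standardized coefficients** (raw coefficient ×
pooled within-group sd); axis signs are fixed so each axis's
largest-|standardized coefficient| is positive. Case scores, centroids
and feature vectors are exported as 2-D biplot coordinates (a missing
second axis is zero-filled). A secondary two-group run (natural =
dentine + enamel vs artificial = titanium) reuses the identical code path
through a configurable label mapping.

Heatmap ordering uses complete-linkage agglomeration on Euclidean
distances via `stats::hclust`; ties follow `hclust`'s deterministic
handling (the suite validates merge heights against a brute-force O(n³)
agglomeration oracle, which ties do not affect on continuous data).

## Substrate-matched pairing and association

For protein `p` and microbe `q`, the pair set is

$$\{(l_{pi}, a_{qj}) : s_i = s_j\},$$

the full Cartesian product of experiment indices within each shared
substrate, concatenated in deterministic (substrate, i, j) order. The
construction presumes that protein levels and microbe abundances are
independent *within* a substrate, so all collinearity between blocks is
substrate-borne. Pairs are equally weighted — no effective-sample-size
correction for the induced dependence — matching the construction
literally; p-values are deliberately not attached to these correlations.

Per pair the pipeline reports Pearson r and plug-in mutual information on
equal-frequency bins (`b = clamp(⌊√(n/5)⌋, 2, 10)` per margin, ties
broken by rank order, natural log). Edge lists keep `|r| > 0.7` strictly,
label `|r| > 0.8` as strong, and top-3 signed lists are exported; the
2 h → 24 h microbe-microbe analysis uses the same machinery at
`|r| > 0.5`. Association and CCA consume **log10 imputed intensities**
and **offset-log abundances** (`protein_scale = "raw"` reverts the
former): the source describes correlating "levels" without fixing a
scale, log scale is the field norm for LFQ, and the screen is rank-based
either way.

## Regularized CCA and structure correlations

CCA is fit on the pair cases, not on the three substrate means — three
points cannot support a multi-dimensional CCA, and the pair construction
is the only stated device that yields a shared case axis. A consistent
case axis is built once per analysis: all (protein-experiment,
microbe-experiment) index pairs per substrate, with every included
feature read at those indices. Blocks are centered and whitened with
ridge-regularized covariances (`Σ + λ·mean(diag Σ)·I`, λ = 1e-3
automatically when a block is rank-deficient, else 0) and the SVD of the
whitened cross-covariance gives canonical correlations and weights.

A structural fact: under balanced Cartesian pairing the cross-covariance
between blocks is a sum over substrates of outer products of substrate
mean deviations, so its rank is at most `#substrates − 1`. With three
substrates exactly two canonical dimensions can carry signal — the 2-D
interset/intraset biplot is not a truncation but the whole picture.

Intraset correlations are each feature's correlation with its own block's
variate; interset correlations are defined (and computed) as canonical
correlation × intraset, which is exact at λ = 0 and adopted as the
definition under ridge.

## Diversity statistics

Shannon entropy (natural log by default; base switchable), Bray-Curtis
dissimilarity `Σ|u−v|/Σ(u+v)`, PCoA by Gower double-centering of −D²/2
(negative eigenvalues are reported as a diagnostic, never corrected —
axes use positive eigenvalues only), and per-taxon
`log2((median_A + δ)/(median_B + δ))` on proportion-scaled tables with
δ = one tenth of the smallest nonzero proportion, capped at ±20. Total-sum
scaling stands in for the unspecified count normalization of the original
workflow.

# The synthetic world

The generator states one fixed world; tests and acceptance checks run
against it. Proteome: per-protein baseline log10 intensity ~ N(7, 1)
(LFQ intensities 10⁵–10⁹), reading noise sd 0.2, substrate effects
~ N(0, 0.8) on 60 of 300 proteins, detection limit 5×10⁵ — about 8-11%
of cells censored, and a protein censored in *every* reading is dropped
(it does not exist in the emitted world). Microbiome: per-ASV baseline
ln-mean ~ N(ln 20, 1.5), substrate effects ~ N(0, 1) on 20 of 300 ASVs,
negative-binomial size κ = 1, structural zero probability π = 0.3, five
replicates per substrate per timepoint, and a persistence weight ρ_t = 0.7
mixing the 2 h per-substrate profile into 24 h.

Couplings — the planted cross-omic signal — act through the
**standardized substrate-mean latent protein level** z (couplings cannot
act per-experiment because the blocks are unpaired): a coupling of sign
s and strength γ shifts the NB log-mean by `s·γ·z` *and* the
structural-zero logit by `−s·γ·z`. The second term is an elaboration of
this package: a protein that promotes adhesion should raise both the
abundance and the prevalence of its microbe, and without it the
structural zeros of a strongly coupled taxon would be random noise
fighting the very signal they are supposed to express.

The strong-coupling default γ = 5 was calibrated **once, at design time,
before the acceptance tests were written**, by an attenuation pilot: the
observed pair correlation of a planted coupling is the substrate-level
correlation (≈ ±1 by construction) attenuated by within-substrate noise
on both sides (reading noise; NB dispersion; structural zeros; only
9 × 15 experiments feeding 45 Cartesian pairs per substrate triple).
γ = 5 — roughly e^±5.5, i.e. presence/absence-scale substrate
selectivity — is the regime in which a "strong" coupling survives that
attenuation; it was not revisited afterwards.

What the generator does **not** emulate: compositionality (counts are
independent NB draws, not a fixed sequencing depth), taxonomic
correlation structure among ASVs, batch effects, protein-protein
covariance beyond substrate effects, and biological (as opposed to
replicate) variance components. A green recovery test therefore
establishes that the pipeline finds planted substrate-routed couplings
under realistic marginal noise — not that it would disentangle
compositional or confounded real data.

# Numerical and policy choices

* Missing marker: empty cell or `NA` in TSV; internally `NA`, never 0.
* Substrate labels canonicalized (lowercase, trimmed); fixed vocabulary
  `{dentine, enamel, titanium}`, extensible per call.
* Venn "detected on a substrate" = at least one present reading there.
* Degenerate inputs: all-tied KW → `H = 0, p = 1`; constant pair margins →
  r undefined (`NA`, excluded from edge lists); all-zero communities and
  all-zero abundance tables are errors.
* Boundary rules are strict everywhere: `p < threshold`, `|r| > 0.7`,
  `|r| > 0.8`, `|r| > 0.5`.
* Ties in top-k lists break lexicographically by (protein, microbe).
* Seeds: one integer seed drives everything; the microbiome stage derives
  `seed + 1`, the annotation generator `seed + 2`.
* The report bundle contains no timestamps; a rerun at the same seed is
  byte-identical (the manifest echoes the configuration, including the
  output path, which is the only run-specific string).

# Known limitations

* The chi-square tail of the KW statistic is an approximation that is
  conservative at N = 9; exact permutation tails are not implemented.
* No significance machinery for canonical correlations (Bartlett/Wilks)
  or permutation p-values for pair correlations — thresholded effect
  sizes only, by design.
* The Cartesian pairing induces dependence among pairs; reported r values
  are descriptive statistics of the construction, not estimates with
  nominal sampling distributions.
* `hclust` tie-breaking may differ from a lowest-index-first rule on
  exactly tied merge heights; merge heights themselves are unaffected.
* Heat-tree output is the per-taxon differential statistic only; tree
  construction and rendering are out of scope.
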
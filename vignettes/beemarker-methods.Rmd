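---
title: "Models and methods behind beemarker"
author: "beemarker authors"
date: "`r Sys.Date()`"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beemarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beemarker)
```

# Scope

`beemarker` re-implements, as a tested and reusable chain, a cage-level
honey bee nutritranscriptomics analysis: two genetic stocks (Pol-line and
Russian) are fed one of four diets — a sucrose-only control ("sugar") or
one of three protein/lipid (PL) diets (pollen, *Chlorella*, spirulina) —
in replicate cages sourced from several parent colonies. The unit of
observation is the cage pool: one RNA-seq library and one head+thorax dry
mass per cage (pool mass divided by 8 bees). The chain runs from the
integer count matrix to DEG calls, ordination, random-forest biomarker
panels, SVM stock classification and biotype enrichment. Read alignment
and counting, GO enrichment against external databases, and mixed-model
analysis of consumption data are out of scope; the pipeline starts at a
featureCounts-style table.

# The synthetic-data generator

Every stage is exercised against simulated data with planted ground
truth, so the generator is first-class, tested code rather than a test
fixture.

## Generative model

For gene $g$ in cage $i$, counts are negative binomial,

$$K_{gi} \sim \mathrm{NB}\!\left(s_i\,\mu_{gi},\; \alpha(\mu_{gi})\right),
\qquad \alpha(\mu) = a_0 + a_1/\mu,
\qquad \mathrm{Var} = \mu + \alpha\mu^2,$$

with log-normal library size factors $s_i$ (geometric mean 1) and a mean
model on the log2 scale:

$$\log_2 \mu_{gi} = b_g
  + \Delta_{\text{diet}}\,[g \in P_{\text{diet}},\ i \in \text{PL}]
  + \Delta_{\text{stock}}\,[g \in P_{\text{stock}},\ i \in \text{stock 2}]
  + u_{g,\,c(i)} + z_i\,\gamma_g .$$

The pieces, and why they look this way:

* **Baseline abundance** $b_g \sim U(-2, 9)$ log2 counts, spanning the
  three-plus orders of magnitude a real library shows; with the default
  112 libraries roughly 5–10% of transcripts fall below the 50-read
  filter, leaving a post-filter matrix of realistic size.
* **Design**: 4 Pol-line and 3 Russian source colonies, 4 diets, 4 cages
  per colony × diet cell — 64 + 48 = 112 cage libraries, matching the
  study design this package targets.
* **Colony intercepts** $u_{g,c} \sim N(0, \sigma_c^2)$ are
  *gene-specific*. A colony offset shared by all genes is
  indistinguishable from sequencing depth and would be removed by
  normalization; only gene-level colony structure makes the downstream
  blocking covariate matter, which is exactly what the blocking tests
  need to demonstrate.
* **Latent nutrition score** $z_i \sim N(0,1)$ under sugar and
  $N(1,1)$ under any PL diet. It drives the weight response
  $w_i = w_0 + \beta z_i + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma_w^2)$, and the expression of the
  weight program through per-gene loadings $\gamma_g \sim U(0.4, 0.8)$
  log2 units per unit score. The loading range is chosen so planted
  genes behave like biomarkers — per-gene correlations with weight in
  the range a correlation-triage rule (r ≥ 0.75 for the panel tier) is
  meant to capture — rather than like faint bystanders.
* **Detectability floor**: all planted programs (diet, stock, weight)
  are sampled from transcripts with baseline log2 mean ≥ 3 (~8 counts
  per library). An effect planted in a transcript averaging one read is
  unmeasurable by construction and would say nothing about the method
  being tested; real biomarkers are, by definition, measurable
  transcripts.
* **lncRNA bias**: stock-program membership upweights lncRNAs by a
  configurable odds multiplier (default 3), so the stock DEG sets carry
  the lncRNA enrichment signal the enrichment stage is meant to detect.
* **Viral features** are ordinary count rows flagged `viral`, shifted by
  a stock-specific log2 offset (default −2 in the second stock); no
  read-level simulation is attempted.

Everything is reproducible from the single seed in `simConfig()`.

## What the simulator does not emulate

Within-cage bee-to-bee variation (the pool is the unit, as in the
design), GC/length biases, batch effects beyond colony, isoform
structure, and correlated gene-gene noise beyond what the shared latent
score induces. Tests passing on these simulations demonstrate that the
implementations do what they claim under their stated model — not that
the biological conclusions of any particular dataset are correct.

# Preprocessing

Transcripts with fewer than 50 total reads across all libraries are
removed first, then normalized and transformed — in that order. Size
factors are plain median-of-ratios against the per-gene geometric mean
over reference genes (genes positive in every library), rescaled to
geometric mean 1. Gene-wise dispersions are method-of-moments estimates
$\hat\alpha_g = \max(0,(v_g-\bar\mu_g)/\bar\mu_g^2)$ on normalized
counts — deterministic and adequate for trend fitting, as opposed to a
full likelihood machinery — and the trend $\alpha(\mu)=a_0+a_1/\mu$ is
fitted by iteratively reweighted least squares in $1/\mu$ with
gamma-style weights, excluding zero estimates, clamping $a_0$ to
$10^{-8}$ if degenerate. The variance-stabilizing transformation is the
closed form implied by that trend,

$$\mathrm{vst}(u) = \log_2\!\frac{1 + a_1 + 2a_0u +
  2\sqrt{a_0u(1+a_1+a_0u)}}{4a_0},$$

strictly increasing, finite at $u=0$ (where it equals
$\log_2((1+a_1)/(4a_0))$) and asymptotically $\log_2 u$. The VST is
fitted blind to the design: it is applied before any modelling, so
condition labels cannot leak into the machine-learning stages.
Per-gene dispersion shrinkage and rlog-style transforms are deliberately
out of scope.

# Differential expression

The DE stage is a from-scratch implementation of precision-weighted
gene-wise least squares with empirical-Bayes variance moderation, kept
numerically interchangeable with the established reference
implementation (the test suite verifies agreement to ~1e-8 on shared
configurations):

1. **log-cpm**: $\log_2((K+0.5)/(L+1)\cdot 10^6)$.
2. **Precision weights**: unweighted gene-wise fits on log-cpm; lowess
   (span 0.5) of $\sqrt{\text{residual SD}}$ on average log2 count; each
   observation's fitted log-count is interpolated on the trend (flat
   beyond the range) and weighted by the fourth inverse power. Span and
   exponent follow the established convention; neither is tuned here.
3. **Gene-wise WLS** retains the full per-gene unscaled covariance
   $(X'W_gX)^{-1}$. Because weights differ per gene, contrast variances
   $c'V_gc$ are computed exactly from the stored covariance rather than
   through the usual shared-correlation approximation — the test suite
   checks this against brute-force matrix algebra.
4. **Moderation**: the scaled inverse-chi-square prior $(d_0, s_0^2)$ is
   estimated by log-scale moment matching (solving
   $\psi'(d_0/2) = \max(0,\, \mathrm{var}(e) - \overline{\psi'(d_g/2)})$
   with $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$); when the
   observed spread does not exceed what sampling alone explains, $d_0 =
   \infty$ and the pooled scale is the mean variance. Posterior
   variances $(d_0s_0^2 + d_gs_g^2)/(d_0+d_g)$ give moderated t with
   $d_0 + d_g$ degrees of freedom.
5. **Calling**: Benjamini–Hochberg adjustment, then strict thresholds
   FDR < 0.05 and |log2FC| > 0.6 (a gene exactly at either boundary is
   excluded). The fold-change filter can be switched off because DEG
   counting conventions vary; both modes are exposed.

Design matrices are treatment-coded with the sugar diet as reference and
source colony as fixed-effect blocking indicators — deterministic, unlike
a random-effect consensus-correlation approach. Colony is nested within
stock, so a combined two-stock fit cannot include colony: within-stock
diet contrasts use per-stock fits with colony blocking, and
stock-within-diet contrasts use a combined stock + diet fit. Requesting
an aliased design raises an error naming the aliased columns rather than
silently dropping them.

Voom-style weighting assumes log-cpm is the modelling scale; VST values
are reserved for ordination, clustering and the ML stages, where a
variance-stabilized matrix is the natural input.

# Ordination, clustering, dispersion contrast

The between-sample distance is the pairwise leading-logFC distance: for
each sample pair, the root-mean-square of the `top` (default 300)
largest absolute expression differences *for that pair*. With `top`
equal to the gene count it reduces to the plain RMS difference; the
convention (RMS of the top set) matches the established ordination tool,
and the test suite confirms equality with it after double-centring.
Classical (Torgerson) MDS follows: variance explained is reported over
positive eigenvalues only, truncating the negative eigenvalues a
non-Euclidean distance can produce, and axis signs are fixed by making
each axis's first nonzero loading positive. Hierarchical clustering uses
1 − Pearson correlation with average linkage (the linkage is
configurable; nothing in the analysis depends on it strongly). The
coefficient-of-variation contrast computes per-gene CV = SD/mean within
each group and compares the two CV distributions over genes by a Welch
t-test, dropping (and counting) genes with zero within-group mean.

# Random-forest biomarker discovery

Body weight is regressed on the transposed VST matrix with ranger
forests (1000 trees by default; single-threaded for reproducibility,
seeded per fit). Recursive feature elimination alternates (a) tuning
`mtry` over {p/10, p/3, p/2, √p} by out-of-bag RMSE, (b) recording the
round, and (c) removing every feature with *strictly negative* signed
permutation importance — features that actively hurt OOB performance. A
feature the forest never used scores exactly zero and is retained, since
zero importance is absence of evidence, not evidence of harm. The
OOB-RMSE-optimal round defines the selected set (ties resolved toward
the smaller, nested set). Bias-corrected impurity importance is
available as an alternative scoring mode.

Two properties of this loop deserve honesty. First, feature selection
sees all samples, so the OOB error of later rounds is optimistic under
the null — on pure-noise responses the apparent optimum $R^2$ sits
around 0.1–0.2 rather than 0; the tests assert the typical (median over
seeds), not worst-case, behaviour. Second, because all weight-program
genes proxy the same latent score, a forest needs only enough of them to
denoise it; recovery of the full program therefore requires plants that
are individually measurable, which is what the generator's detectability
floor and biomarker-grade loadings provide.

Selected features are triaged by Pearson correlation with weight
(two-sided t on $n-2$ df). The panel rule is $r \ge 0.75$ (inclusive, as
a stated cutoff) with unadjusted $p < 0.05$ and $r > 0$; the broader
positive-significant tier is reported alongside. Correlation p-values
are not multiplicity-adjusted by default — the rule reproduces a
published triage convention, not a formal inference — and the threshold
is configurable.

# SVM stock classification

Candidates are the union of the two stocks' core DEG sets. Features are
standardized internally; a linear SVM (C = 1, no inner tuning, so the
external loop is unambiguous) is refitted while the lowest-scoring 10%
of features are eliminated per round; the reversed elimination order is
the ranking. The per-feature score is $|w_j|$ times the absolute
two-sample t-statistic of the feature computed on the current support
vectors — a documented stand-in for significance-weighted SVM-RFE; pure
$|w_j|$ scoring is available via `scoring = "svmrfe"`. Ties break toward
the smaller feature index.

Model error is measured by stratified 10-fold *external*
cross-validation: standardization and the entire ranking are recomputed
inside each training fold, so the held-out fold never informs feature
selection. On permuted labels this stays at chance level at every
feature count — the property that distinguishes external from internal
CV. The reported feature list is the full-data ranking (one list, as a
study would report), while its error bars come from the external loop;
fold assignments are kept in the returned trace.

# Set algebra and enrichment

Core DEG sets are intersections across the three PL diets within a
stock; two-set Venn accounting satisfies
$|A \cup B| = |A| + |B| - |A \cap B|$ by construction and is tested
property-style. Biotype (lncRNA) enrichment uses the 2×2 chi-square with
1 df and no continuity correction — matching the uncorrected statistic
style of the results it mirrors; Yates correction is a flag — with the
post-filter gene list as the background universe. When an expected cell
drops below 1 the function warns and reports a Fisher exact p-value
alongside.

# Numerical choices and degenerate inputs

* Dispersion IRLS: 8 reweighting iterations, fitted values floored at
  1e-10, $a_0$ clamped to 1e-8 (warning) and $a_1$ to 0.
* Trigamma inversion by Newton iteration with asymptotic endpoints
  ($1/\sqrt{y}$ for large $y$, $1/y$ for small).
* All-zero distance matrices are flagged degenerate (zero coordinates,
  NA variance explained) instead of erroring.
* Zero-variance items: clustering errors by item name; correlation
  records are flagged rather than dropped silently; a constant RF
  response reports zero importance and non-positive skill.
* Seeds: every stochastic routine takes an explicit seed; ranger runs
  single-threaded because multi-threaded forests are not bitwise
  reproducible.

# Problem sizes used by the test and acceptance runs

The packaged checks run at desk scale, chosen to make each property
statistically decidable in minutes on one core: null calibration at
2,000 genes × 24 samples × 20 seeds; prior recovery at 5,000 genes;
variance flattening at 4,000 genes × 30 samples; RF-RFE recovery at 20
planted genes among 500 with the full 112-cage design over 5 seeds; SVM
honesty and recovery at ~300 genes × 112 cages. The headline numbers of
the motivating study (e.g. a 308-feature optimum or a 46-gene panel)
derive from its deposited sequencing data and are not reproduced at
these scales; what the package demonstrates is that each algorithm
recovers what was planted, stays calibrated under the null, and matches
independent oracles where those exist.

# Known limitations

* Colony enters as fixed effects; a random-intercept treatment would
  borrow strength across colonies but sacrifices determinism and adds a
  dependency surface the analysis does not need at 7 colonies.
* The sigFeature-style SVM score is a reconstruction of a
  significance-weighted RFE; it is clearly labelled and switchable, but
  it is not a line-for-line port of any external tool.
* The RFE optimum inherits selection optimism (above); consumers who
  need unbiased error for the *selected* set should wrap the entire
  elimination in the external CV, as the SVM stage does.
* Length/GC normalization is omitted: comparisons are across samples
  within gene, never across genes.
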
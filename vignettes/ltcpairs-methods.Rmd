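---
title: "Methods: comparing co-occurrence and genetic correlation of condition pairs"
author: "ltcpairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing co-occurrence and genetic correlation of condition pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcpairs)
```

# The problem

Multimorbidity — two or more long-term conditions (LTCs) in one person — is
usually studied observationally: how often do two diagnoses co-occur in
health records beyond what age and sex explain? Genetic summary data offer
a complementary axis: two conditions can share inherited risk whether or
not they are diagnosed together. `ltcpairs` implements both axes for every
pair of a condition set and classifies each pair by the agreement between
them. Concordant pairs suggest shared biology; genetic-only pairs can flag
underdiagnosis; observational-only pairs can flag diagnostic pathways or
incidental detection rather than shared mechanism.

Because the real inputs (primary-care EHR extracts, biobank GWAS) are
access-controlled, the package is organised around a synthetic-data module
with known ground truth. Every estimator is validated by parameter
recovery, and the whole pipeline runs end to end on simulated data.

# Models and estimators

## Eligibility gates

Conditions enter the analysis when they are (1) chronic (an input flag —
code-list curation is upstream of this package), (2) common: maximum
per-database prevalence at least 0.5% (prevalence = persons ever diagnosed
/ eligible persons, eligible meaning alive, registered, aged 65+ at the
index date), and (3) heritable: SNP-heritability z-score strictly greater
than 4. Manual overrides are configuration entries recorded with reason
`manual`, never code. Pairs are all unordered combinations of included
conditions minus an explicit code-list-overlap exclusion list; within each
pair the "exposure" is the more prevalent condition by pooled prevalence
(tie broken lexicographically), and a pair is *within-domain* when both
conditions share an ICD-10 chapter.

## Observational axis

Per database, `fit_pair_logistic()` fits maximum-likelihood logistic
regression (IRLS via `stats::glm`) of the less prevalent condition on the
indicator of the more prevalent one. Age enters linearly, centred at 65;
sex as a factor. A linear age term is the minimal reading of "adjusted for
age and sex"; the surface accepts any extra covariate columns for users
who need more. Separation is detected by fitted probabilities within 1e-8
of the boundary (or IRLS hitting its 50-iteration cap) and reported as
`converged = FALSE` with a missing estimate — deliberately not penalised
regression, which would change the estimand.

Database-level log odds ratios are pooled with `meta_fixed()`:
inverse-variance weights $w_i = 1/se_i^2$, pooled estimate
$\sum w_i b_i / \sum w_i$, SE $(\sum w_i)^{-1/2}$, heterogeneity
$Q = \sum w_i (b_i - \hat b)^2 \sim \chi^2_{k-1}$. Fixed effects is the
appropriate model for two databases; Q is reported but never used to drop
pairs. Benjamini–Hochberg FDR (`bh_fdr()`, a validating wrapper over
`stats::p.adjust`) is applied within each analysis family: each database
separately, and the meta level across all pairs in the run.

## Genetic axis

`estimate_h2()` and `estimate_rg()` implement LD-score regression on the
observed scale with standardized genotypes. With per-variant LD scores
$\ell_j$ (sum of squared correlations with panel neighbours, self included)
and panel size $M$:

$$E[\chi^2_j] = 1 + na + \frac{n h^2}{M}\,\ell_j, \qquad
E[z_{1j} z_{2j}] = \frac{n_{ov}\,\rho_{ph}}{\sqrt{n_1 n_2}} +
\frac{\sqrt{n_1 n_2}\,\rho_g}{M}\,\ell_j,$$

so the slopes give $h^2$ and the genetic covariance $\rho_g$, the
univariate intercept captures confounding-style inflation, and the
cross-trait intercept absorbs sample overlap — no intercept constraining,
matching the mixed-source reality where overlap is rarely known. The
genetic correlation is $r_g = \rho_g / \sqrt{h_1^2 h_2^2}$, reported
clipped to $[-1.25, 1.25]$ with a flag when the raw value leaves
$[-1, 1]$, and reported missing (with reason) when either heritability
estimate is non-positive.

Numerical choices that matter:

* **Weights.** The variance-model weights are
  $1/(\ell_j \hat E[y_j]^2)$ for the $\chi^2$ regressions and
  $1/(\ell_j (\hat E_1 \hat E_2 + \hat E_{12}^2))$ for the product
  regression (the variance of a product of correlated normals), with
  fitted means floored at 0.1 and $\ell$ floored at 1. They are estimated
  in three passes: unit weights, a weighted pass, and one refresh from
  that weighted fit. A single refresh from the *unweighted* pass was
  evaluated first and rejected: under heteroscedasticity the unit-weight
  fit is dominated by high-LD variants, and the resulting noisy weights
  inflated the sampling sd of $\hat r_g$ by ~45% and pushed 95% CI
  coverage down to ~89%. Further iteration beyond three passes changed
  estimates by less than 1% and is unnecessary.
* **Jackknife.** SEs come from a delete-one-block jackknife over
  `n_blocks = 200` contiguous (position-ordered) variant blocks that
  re-runs the *entire* procedure — weights included — on each
  leave-one-block subset. Holding full-data weights fixed omits the
  weight-estimation variance and measurably under-covers. For $r_g$, the
  full ratio (both heritabilities and the covariance) is recomputed per
  deletion; replicates with non-positive heritability are dropped from
  the SE.
* **Gates.** The heritability gate ($z > 4$) and within-condition source
  gate ($r_g > 0.8$) are strict inequalities.

Variant QC (`qc_filter()`) keeps MAF strictly above 0.1% and INFO at or
above 0.3 when those optional columns are present. Cross-source allele
harmonisation matches by variant id, sign-flips swapped A1/A2, and drops
strand-ambiguous palindromic (A/T, C/G) variants with counts.
`select_sources()` encodes the pooling policy: candidates failing (or
missing) the within-condition $r_g$ gate versus the reference are dropped;
a retained consortium source that overlaps the reference and/or the other
biobank displaces the overlapped sources (it has more cases); the
surviving sources are mutually disjoint and pooled per variant by the same
fixed-effects engine, with effective sample size summed.

## Concordance classification

Each axis is classified `not_significant` when the pair's q-value is
$\ge$ 0.05, otherwise into weak / intermediate / strong terciles of the
point estimate (odds-ratio scale observationally, $r_g$ genetically).
Tercile cutpoints are the 1/3 and 2/3 empirical quantiles (default
quantile definition) of the *within-domain pairs significant on that axis*
— within-domain pairs are the anchor because their relationships are the
clinically least controversial; restricting to significant pairs keeps
noise-dominated estimates from dragging the cuts. Class membership is
boundary-inclusive downwards (weak $\le$ lower cut $<$ intermediate $\le$
upper cut $<$ strong). `preset_cutoffs()` ships fixed published cutpoints
(OR 1.46 / 1.90, rg 0.25 / 0.48) for exact reproduction of an external
classification. Significant pairs with OR < 1 fall below the lower cut
into "weak" but remain visible through the quadrant label.

Quadrants join the axes: `concordant_positive` (both significant, OR > 1,
rg > 0), `concordant_negative` (both significant, OR < 1, rg < 0),
`genetic_only` (rg significant and positive while the OR is not
significant or significantly below 1), `observational_only` (OR
significant and > 1, rg not significant), `null` otherwise, `unclassified`
when an estimate is missing.

`regress_obs_on_rg()` regresses the meta log-OR on $r_g$ by OLS and also
reports $100(e^{0.01\hat\beta} - 1)$, the percent change in co-occurrence
odds per 0.01 increase in $r_g$. The direction (odds as response) is a
config switch: the natural-language description of this analysis is
ambiguous about which variable is the response, but the percent-odds
interpretation only exists with the odds as outcome, so that is the
default.

## Colocalisation

`find_lead_snps()` performs greedy distance clumping (take the smallest p
below $5\times10^{-8}$, suppress neighbours within 250 kb, repeat; ties
broken by position then id). Cross-trait lead pairs on one chromosome
closer than the window (strict `<`) define regions
$[\min(pos) - w, \max(pos) + w]$, merged when overlapping; the region
width around paired leads is not externally fixed anywhere authoritative,
so the symmetric $\pm$window rule is this package's documented choice.
Coordinates are 1-based inclusive.

Per variant, the Wakefield log approximate Bayes factor is
$\tfrac12(\log(1-r) + r z^2)$ with $r = W/(V+W)$, prior effect variance
$W$ (sd 0.2 for binary traits, 0.15 quantitative — the conventional
defaults) and $V = se^2$. The five-hypothesis single-causal-variant model
uses priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; hypothesis masses
$(1,\ p_1 S_1,\ p_2 S_2,\ p_1 p_2 (S_1 S_2 - S_{12}),\ p_{12} S_{12})$
are computed in log space (log-sum-exp, with guarded cancellation for the
distinct-causal term, which is structurally zero for single-variant
regions) and normalised to PP0–PP4. The subtraction $S_1 S_2 - S_{12}$
excludes same-variant configurations from H3; a brute-force enumeration
over all causal configurations for $n \le 6$ variants validates the
algebra to 1e-10 in the test suite. PP4 > 0.9 flags high evidence for a
shared causal variant. Gene and drug annotation of candidates is out of
scope; the module emits candidate variant ids, positions and per-variant
shared posteriors.

# The synthetic-data module

`synthio` defines the study conditions the tests run under; its defaults
are fixed once, not tuned.

* **LD panel.** Block-diagonal LD: `n_blocks` blocks of `block_size`
  variants with AR(1) (`corr^|i-j|`) or exchangeable within-block
  correlation; $\ell_j$ is computed exactly as the within-block row sum of
  squared correlations, so `block_size = 1` gives $\ell_j = 1$
  identically. `corr` may be a vector recycled across blocks: real
  genomes have strongly heterogeneous LD, and a panel with one shared
  correlation has an almost degenerate LD-score distribution on which the
  LD-score regression has no leverage (the estimators reject exactly
  degenerate $\ell$). The recovery studies use `corr = seq(0, 0.9)`
  across 200 blocks of 25 (M = 5000), giving $\ell_j \in [1, 8.8]$.
  Positions are strictly increasing; the panel's seed draws only allele
  labels (non-palindromic pairs, so simulated sources harmonise without
  strand drops).
* **GWAS pairs.** Per-variant true effects drawn jointly with covariance
  $\Sigma_g / M$, $\Sigma_g = D^{1/2} R_g D^{1/2}$ (standardized scale,
  infinitesimal model; allele frequencies play no role in effect scaling,
  which keeps the $h^2$ bookkeeping exact); marginal z-scores
  $\sqrt{n_t} R\beta_t + \epsilon_t$ with block covariance $R$ and
  cross-trait error correlation $n_{ov}\rho_{ph}/\sqrt{n_1 n_2}$ — the
  exact moment structure the estimators assume, verified in tests by
  moment recovery (mean $\chi^2$, overlap product moment, slope of
  $z_1 z_2$ on $\ell$). A K-trait generalisation drives the demo.
  Non-PSD requested structures are rejected.
* **Cohorts.** Ages uniform on [65, 90], sex Bernoulli(0.457) — echoing
  the age gate and sex mix of large primary-care extracts — both
  configurable. Marginal prevalences are shifted per person on the
  log-odds scale by centred age and sex; each configured pair's second
  condition is drawn conditional on the first from the exact 2×2 cell
  probabilities solving (person-specific marginals, target OR), so the
  covariate-adjusted OR equals the target exactly. Each condition can be
  the conditional member of at most one configured pair (a dependency
  forest); the analysis is strictly pairwise, so recovery tests use
  single-pair cohorts and the demo uses a forest. Infeasible
  (prevalence, OR) combinations — cells leaving (0,1) — are rejected
  with the violated cell.
* **Coloc loci.** AR(1) LD, $\hat\beta = R\beta + \text{noise}(R/n)$,
  causal placement per hypothesis (H3 requires two distinct indices).
* **Determinism.** All generators take integer seeds; the pipeline expands
  one master seed into per-stage substreams via a documented arithmetic
  counter (`substream_seed`), so identical configurations are
  byte-identical end to end.

What the generator does *not* emulate: realistic minor-allele-frequency
spectra and frequency-dependent architecture, liability-scale phenotypes
(everything is observed-scale, matching the estimators; no
prevalence-based conversion is attempted anywhere), imputation error,
cryptic relatedness, population stratification (the univariate intercept
is therefore ~1 unless overlap is injected), higher-order disease
dependence beyond the pairwise 2×2 construction, and real LD reference
panels. Passing recovery tests therefore demonstrate the estimators are
correct under their own model assumptions, not that those assumptions
hold in any particular real dataset.

# Pipeline, problem sizes and reproducibility

`run_pipeline()` executes synth → eligibility → cooccur → rg → classify →
coloc → report from a validated configuration (unknown keys are rejected),
writing tab-separated artifacts, a JSON manifest with per-stage output
digests and row counts, and a markdown report rendered from the stage
outputs (so report and artifacts cannot disagree). Unchanged re-runs skip
stages whose recorded outputs are intact and note cache hits; `force`
recomputes.

The shipped demo uses six conditions in two ICD-10 chapters (15 pairs, 6
within-domain), two databases of 20,000 and 15,000 persons, a 4000-variant
panel, GWAS n = 100,000 and 200 jackknife blocks — sizes at which all six
conditions clear the heritability gate with comfortable margin and the
full run takes a few seconds. The test suite's recovery studies use
M = 5000 / n = 20,000 / 100 seeds (LDSC) and 50-variant loci / 100 seeds
per hypothesis (coloc); these sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping the default test run fast.

The command-line entry point of this package is R itself: the exported
functions, `run_pipeline()` and `scripts/acceptance.R` (see the README)
cover scripted use; no separate shell binary is shipped.

# Known limitations

* Only the $\ge 65$ primary analysis population is modelled; no sensitivity
  reanalysis at other age gates.
* Fixed-effects pooling only (appropriate for 2–3 inputs); no
  random-effects option.
* rg significance uses the normal approximation on the jackknife ratio;
  for very small block counts this is optimistic.
* Single-causal-variant colocalisation only; no multi-causal or
  LD-matrix-aware fine-mapping.
* The concordance quadrants inherit both axes' power: a pair can be
  "genetic-only" purely because the observational analysis was
  underpowered, and vice versa — confidence intervals matter when reading
  individual pairs.
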
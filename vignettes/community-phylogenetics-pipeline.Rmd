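---
title: "Linking species richness to phylogenetic relatedness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking species richness to phylogenetic relatedness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commphylo)
```

## What the pipeline does

`commphylo` implements a macroecological workflow for asking how the
species richness of one taxon (here: birds, recorded as county-level
presence/absence) relates to the phylogenetic relatedness of its
assemblages and to environmental covariates — the richness of a second
taxon, topographic heterogeneity, contemporary climate, and climate change
since the Last Glacial Maximum (LGM). The stages are:

1. **Consensus phylogeny.** From a posterior sample of trees, select the
   maximum clade credibility (MCC) tree and annotate its node heights.
2. **Net Relatedness Index (NRI).** Per site, compare the observed mean
   pairwise phylogenetic distance (MPD) of the resident species with a
   taxa-label permutation null.
3. **Single-variable regressions.** OLS and a simultaneous autoregressive
   (SAR) spatial error model on standardized variables.
4. **Subset selection.** Rank every covariate combination by the mean
   out-of-sample Pearson correlation of random-forest predictions over
   repeated random 50/50 splits, then compare the top combinations by SAR
   Akaike weights.

Because real county-level occurrence compilations of this kind are not
publicly deposited, the package ships a first-class synthetic-data module
that generates phylogenies, assemblages, and covariate/response tables
with *known* structure, so every stage is testable against ground truth.

## The statistics

### MPD and NRI

For a site holding species set $S$ with $|S| \ge 2$ and patristic
distances $d_{ij}$ (sum of branch lengths on the tip-to-tip path),

$$\mathrm{MPD}(S) = \binom{|S|}{2}^{-1} \sum_{i<j \in S} d_{ij},$$

$$\mathrm{NRI} = -\frac{\mathrm{MPD}_{obs} -
\overline{\mathrm{MPD}}_{null}}{\mathrm{sd}(\mathrm{MPD}_{null})}.$$

The null shuffles the labels of the distance matrix (999 permutations by
default) and recomputes MPD of the same species set under each
relabeling; this is equivalent to drawing uniform species sets of equal
richness from the pool, preserving per-site richness but not species
occurrence frequencies. Positive NRI means species are more closely
related than expected (clustering); negative means overdispersion.

Numerical choices:

* One permutation stream is shared by all sites within a call, so results
  do not depend on site order and the same relabeling is applied
  everywhere — the natural reading of a matrix-label shuffle.
* The default pool is *all* tips of the supplied tree, not just observed
  species; `pool = "observed"` exposes the other reading. Real data often
  include tree tips absent from every site, and which reading was used in
  published analyses is typically unstated; the switch makes both
  available without guessing.
* Sites with fewer than two species (MPD undefined) and sites whose null
  is degenerate (e.g. a site holding the entire pool, where every
  relabeling returns the same MPD) are reported as `NA` with an explicit
  flag, never as $\pm\infty$, and excluded from downstream regressions
  with a logged count.
* NRI is invariant to multiplying all branch lengths by a constant (the
  scale cancels in the z-score); the suite checks this to 1e-9.

### MCC tree

Each tree in the sample is scored by
$\sum_{\text{clades}} \log(\text{clade frequency in sample})$ over its
internal clades, excluding the root clade whose frequency is always 1;
the highest-scoring *sample* tree is selected (the method never
synthesizes a topology), ties broken by first occurrence. Node heights
are then annotated: each internal node receives the mean height of its
clade across the trees containing that clade, where a node's height is
its mean distance to descendant tips (equal to node age on ultrametric
trees — a definition that degrades gracefully when branch-length jitter
makes trees non-ultrametric). Because independently averaged heights can
invert parent/child order, child heights are clamped strictly below their
parent in a root-to-tip sweep; this is the standard resolution of
negative-branch artifacts in clade-annotated consensus trees. Clades are
identified as tip-label bitsets on a common taxon order, so the score is
invariant to tip and tree ordering.

### SAR spatial error model

To account for spatially autocorrelated residuals the single-variable
fits are repeated under $y = X\beta + u$, $u = \lambda W u + \varepsilon$
with $W$ a row-standardized symmetrized k-nearest-neighbor weights matrix
(default $k = 8$) on site centroids. The likelihood is concentrated over
$\lambda$: given $\lambda$, both sides are transformed by
$(I - \lambda W)$ and $\beta, \sigma^2$ follow by least squares, while
the Jacobian $\log|I - \lambda W|$ comes from the eigenvalues of $W$
(real, because $W$ is similar to a symmetric matrix; exact and cheap at a
few hundred sites). $\lambda$ is profiled over the feasible interval
inside $(-1, 1)$; an optimizer stopping at the interval edge is flagged.

Design choices, made where the field's conventions leave room:

* **Error (not lag) SAR**: the motivation is residual autocorrelation,
  and the spatial-error form is the standard choice in richness-gradient
  regressions. The spatial-lag variant is out of scope.
* **k-NN weights**: distance-band weights create islands with irregular
  county geometries; symmetrized k-NN guarantees a connected, well-
  conditioned W. The neighbor rule behind any given published SAR is
  rarely stated, so coefficients are comparable only in sign and rough
  magnitude.
* **Pseudo-r²**: Nagelkerke's
  $1 - \exp(-\tfrac{2}{n}(\ell_{model} - \ell_{null}))$ against a
  *non-spatial* intercept-only null — the convention of the spdep-era
  literature. Adjusted r² is reported for OLS.
* **AIC bookkeeping**: $k$ counts intercept, slopes, $\lambda$, and
  $\sigma^2$, so AIC values are comparable across SAR fits of different
  subset sizes; OLS AIC likewise counts $\sigma^2$.
* **Significance**: Wald tests (t for OLS, asymptotic z for SAR) flagged
  at p < .01, uncorrected for multiple testing, matching the reporting
  style of single-variable batteries in this literature.
* **Log base**: base-10 for richness-like variables and area. After
  standardization the base only affects bookkeeping, but it is fixed and
  recorded in the `transforms` attribute.

### Random-forest subset ranking

All $2^7 - 1 = 127$ non-empty subsets of the seven candidate variables
are scored (exhaustive enumeration is cheap and assumption-free; site
area is excluded from the search as a nuisance covariate). Per subset and
split, sites are partitioned uniformly at random into a training half
(odd n: training gets the extra site) and an evaluation half; a
random-forest regressor fit on the training half predicts the evaluation
half, and the Pearson correlation between predicted and observed values
is recorded *out of sample* — the only reading under which the split is
meaningful. The subset score is the mean correlation over splits
(per-split averaging, not pooling of predictions). Splits with constant
predictions or observations are excluded with a warning rather than
imputed as zero, which would bias scores toward null. Each subset draws
its RNG substream from the master seed and the subset's index, so scores
are reproducible and independent of evaluation order. The top six subsets
are refit with the SAR error model and compared by Akaike weights
$w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)$.

RF hyperparameters are the long-standing regression defaults of the tool
family: 500 trees, `mtry = max(1, p/3)`, unlimited depth. The replication
default is 1,000 splits per subset; the test suite and the bundled
acceptance script use 150–200 splits and smaller forests (25–100 trees),
sizes at which the Monte-Carlo error of a subset score is already well
below the separation the experiments probe.

## The synthetic-data generator

The generator defines the study conditions the pipeline is exercised
under; its defaults mirror the motivating design: a **112-tip** species
pool, a pseudo-posterior of trees around it, and **86** county sites.

* **Tree**: constant-rate birth-death conditioned on the tip count
  (`ape::rphylo`; speciation 1, extinction 0.2 per lineage). The simple
  conditioned simulator is used because topology realism is not under
  test — only that downstream code consumes a realistic rooted, binary,
  ultrametric tree.
* **Posterior sample**: multiplicative lognormal branch-length jitter
  (sd 0.1) plus one random nearest-neighbor interchange with probability
  0.2 per tree — enough topological and height variation to make MCC
  selection non-trivial.
* **Assemblages**: sequential weighted sampling without replacement;
  after a uniform first pick, a candidate's weight is
  $\exp(\alpha \cdot \overline{d}_{\text{to selected}})$. The sign of
  $\alpha$ gives transparent, monotone control of NRI (negative
  $\alpha$ → clustering → positive NRI), which a Gibbs or MaxEnt sampler
  would obscure. Default $\alpha = -2$: clearly clustered assemblages,
  the common empirical case for assemblages filtered by environment (the
  effect compounds over sequential picks, so even moderate $\alpha$
  yields strongly positive NRI at high richness).
* **Covariates**: each is $(I - \lambda W)^{-1}\varepsilon$ on a jittered
  grid (jitter keeps the k-NN graph well conditioned), scaled into
  field-realistic units (MAT 2 ± 2.5 degC, MAP 250 ± 100 mm, plant
  richness lognormal around ~300 species, altitudinal range 800 ± 400 m);
  default $\lambda = 0.4$, a moderate autocorrelation typical of
  county-scale climate summaries. LGM reconstruction pairs are emitted so
  that contemporary minus their mean reproduces the generated change
  field exactly, making the preprocessing arithmetic round-trippable.
* **Response**: $\log(\text{richness}) = \log 20 + \sum_i \beta_i z_i +
  \mathcal{N}(0, 0.3)$ with default effects on plant richness (0.5) and
  altitudinal range (0.3); richness is `round(exp(.))` floored at 2
  because MPD is undefined for singletons.

What the generator does **not** emulate: real geography or climate
rasters, occurrence-frequency structure (all species are exchangeable
under the null), richness–NRI coupling through assembly (the assembly
strength is constant across sites), and observation error in occurrence
records. Passing tests therefore demonstrate the *machinery* — metric
definitions, null behavior, estimator recovery, determinism — not that
any particular empirical effect size would be recovered from field data.

## Reproducibility

Every stochastic operation takes an explicit seed. The pipeline derives
stage seeds from a master seed by hashing the stage name
(`stage_seed()`), so each stage is reproducible independently of
execution order, and `run_all()` is byte-identical across reruns with the
same master seed. Posterior subsampling (e.g. keeping 5,000 of 10,000
trees) is exposed as an explicit seeded operation rather than a hidden
burn-in, since burn-in conventions vary.

Default problem sizes for self-contained runs — 1,000 posterior trees
subsampled to 500, 999 null permutations, 150 RF splits in the bundled
report script — were chosen so a full run completes in minutes on one
core while keeping Monte-Carlo error negligible relative to the effects
simulated; the test suite uses smaller sizes per case, each stated in the
test.

## Known limitations

* The MCC tree is selected from the sample; if the true MCC topology is
  absent from the sample it cannot be returned (inherent to the method).
* The SAR fit uses dense eigenvalue decomposition: exact and fast to a
  few thousand sites, not intended for raster-scale lattices.
* NTI/MNTD, abundance-weighted metrics, and richness-conserving swap
  nulls are out of scope; the NRI null here is the taxa-label shuffle
  only.
* Polytomies pass through MCC selection unchanged; no resolution is
  attempted.

## A minimal worked run

```{r, eval = FALSE}
cfg <- default_run_config(master_seed = 1, outdir = "demo_run")
cfg$n_splits <- 100   # scale the subset search down for a quick look
res <- attr(run_all(cfg), "results")
head(res$nri)
res$table1
res$table2[, c("rank", "combination", "mean_pearson", "aic_weight")]
```
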
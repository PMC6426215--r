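---
title: "Phenomics-assisted genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomics-assisted genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pgebv` implements, end to end, a phenomics-assisted genomic-prediction
analysis for a biparental doubled-haploid (DH) maize population evaluated
under heat and combined heat-and-drought stress: a synthetic-data generator
for the whole study, GBS-style SNP quality control collapsing markers into a
bin map, mixed-model BLUEs and repeatability per environment, and four
prediction methods (PLSR, random forest, ridge regression, BayesB) compared
within and across environments on marker (M), hyperspectral (H) and combined
(HM) inputs. This vignette is the package's account of the underlying
models, the simulator's assumptions, and the choices made where the design
was genuinely open.

## The trial model

Plot values follow the standard multi-environment alpha-lattice model

$$
Y_{mhlk} = \mu + a_h + E_l + aE_{hl} + r(E)_{ml} + r(E)\delta_{mlk}
  + \varepsilon_{mhlk},
$$

with genotype $a_h$, environment $E_l$ (a year-by-irrigation-treatment
cell), their interaction, replicate within environment, incomplete block
within replicate, and residual. Two usages:

* **BLUEs** (`fit_env_model()`): within one environment, genotype is fixed
  and replicate/block random; the genotype estimates are the best linear
  unbiased estimators that feed the second (prediction) step.
* **Variance components** (`fit_combined_model()`): across environments all
  factors are random, giving $\sigma^2_G$, $\sigma^2_{G\times E}$,
  $\sigma^2_{rep}$, $\sigma^2_{block}$, $\sigma^2_e$ by REML.

Entry-mean broad-sense repeatability is

$$
h^2 = \frac{\sigma^2_G}
 {\sigma^2_G + \sigma^2_{G\times E}/l + \sigma^2_e/(rl)},
$$

with $l$ environments and $r$ replicates (`repeatability()`); a
within-environment variant $\sigma^2_G / (\sigma^2_G + \sigma^2_e/r)$ is
exposed as `repeatability_env()` because per-environment repeatability
profiles (per trait and per band) are conventionally reported on that scale.
Negative REML components are truncated at zero before either formula.

REML fitting is delegated to `lme4`: the model is a standard nested
random-effects fit, the dataset small (hundreds of plots), and `lme4`'s
profiled REML is more robust than any bespoke EM loop would be. The BLUE
machinery is nevertheless verified in the tests against an explicit
generalized-least-squares oracle with the covariance assembled by hand, and
the 310 per-band models reuse the fitted design via `lme4::refit()`, which
is what makes a 4 x 311 model sweep affordable.

## The two-step prediction pipeline

Following the two-step convention, learners never see plot data: BLUEs are
computed first, then a learner maps features to grain-yield BLUEs. Feature
blocks are

* **M** — bin consensus calls in symmetric $\{-1, +1\}$ coding (missing bin
  calls mean-imputed at standardization time),
* **H** — the 62 bands x 5 flights = 310 per-environment BLUEs of
  reflectance,
* **HM** — their column concatenation.

All learners standardize columns to mean 0, SD 1 — fitted strictly on the
training partition — so marker and reflectance blocks are commensurate in
HM; the pipeline never states a block weighting, and equal per-column scale
is the neutral choice.

Two cross-validation schemes mirror the study design. *Within environment*:
genotypes of one environment are split at random into halves, both
directions are scored, and the per-replicate accuracy is the mean of the two
directional Pearson correlations between predictions and observed BLUEs
($r_{GP}$); undefined correlations (constant predictions) count as 0 rather
than being dropped, since dropping them would inflate the average. *Across
environments* (leave-one-environment-out): the learner trains on all records
of three environments and predicts the fourth, using the held-out
environment's own spectra (the scheme predicts entries pre-harvest, when
their spectra are measured but not their yield). Two variants are exposed
but are not the defaults: `use_target_spectra = FALSE` blanks the held-out
environment's H block (predictions then rely on markers and the intercept),
and `stratify_env = FALSE` pools all records before the two-fold split
instead of splitting within environment — per-environment splitting is the
default because it is what the scheme's "within environment" label means. A raw-SNP marker mode (passing the
genotype matrix in place of the bin map) is likewise available, bins being
the default since they are the objects treated as genetic markers.
Bootstrap standard
errors of $r_{GP}$ resample prediction-observation pairs (10,000 replicates
at study scale; smaller counts in desk-scale runs).

Two-fold splits are drawn per environment, not pooled, and both split
directions are scored per replicate — this doubles the information per
replicate at no cost. The per-learner replication preset
(`paper_reps()`: 1000/2000/3000/1000 for PLSR/RF/RR/BayesB) is available;
the default is 50 replicates so the 24-cell grid runs at desk scale.

## The learners

All four are implemented from scratch; they are the package's core.

**Ridge regression** (`fit_ridge()`) solves
$\hat\beta = (X^\top X + \lambda I)^{-1} X^\top y$ with an unpenalized
intercept; for $p > n$ the dual (kernel) form
$X^\top (XX^\top + \lambda I)^{-1} y$ is used — the two agree to 1e-8 and
the tests assert it on random instances. `lambda = "reml"` profiles the
restricted likelihood of the equivalent random-effects model on the
spectral decomposition of $XX^\top$ (the genomic-BLUP equivalence), so the
shrinkage level is estimated rather than tuned.

**PLSR** (`fit_plsr()`) is NIPALS deflation; at the maximum component count
it reproduces OLS, and component scores are orthogonal by construction
(both asserted). `ncomp = "cv"` minimizes inner 5-fold PRESS on a 1..15
grid within the training partition.

**Random forest** (`fit_random_forest()`) grows unpruned CART regression
trees on bootstrap resamples, splitting on the best of `mtry` randomly
drawn features by variance reduction, with `min_node` observations per
leaf. The tree builder and predictor are in C++ (as regression-forest
implementations invariably are); R's RNG drives bootstrap and feature
sampling so a seed fixes the forest exactly. Defaults `ntree = 500`,
`mtry = floor(p/3)`, `min_node = 5` follow regression-forest convention.
The installed `randomForest` package serves as an independent cross-check
in the test suite, never as the implementation.

**BayesB** (`fit_bayesb()`) is a single-site Gibbs sampler for the
point-mass-at-zero + t-slab prior: inclusion indicators
$\delta_j \sim \text{Bern}(1-\pi)$, effects
$\beta_j \mid \sigma^2_j \sim N(0, \sigma^2_j)$ with marker-specific
$\sigma^2_j \sim$ scaled-inv-$\chi^2(\nu, s^2)$ (the standard augmentation
of the t-slab), and a scaled-inv-$\chi^2$ residual variance. $\delta_j$ is
sampled with $\beta_j$ integrated out given $\sigma^2_j$; out-of-model
variances are refreshed from the prior. Defaults: $\pi = 0.95$, $\nu = 5$,
`n_iter` 6000 with 1000 burn-in at study scale (smaller in desk-scale
runs), and the slab scale solved from the heuristic that markers explain
half of the response variance:
$s^2 = 0.5\,\mathrm{var}(y)(\nu-2)/(\nu(1-\pi)p)$. With $\pi = 0$ and a
heavy slab the sampler's predictions track ridge regression (tested), and
with $\pi = 1$ it degenerates to the intercept-only model.

There is no canonical set of hyperparameters, marker codings or
convergence settings for this workflow; every default above is this
package's own decision, recorded here so it can be revisited.

## The synthetic-data generator

No real genotypes, phenotypes or images are distributed with the package;
the generator produces a study with the same statistical skeleton, plus a
truth bundle for recovery tests.

* **Genome and genotypes.** Ten chromosomes totalling 1150.16 cM with
  maize-like decreasing lengths. Each DH line is one F1 gamete doubled:
  crossovers per chromosome are Poisson(length/100) with uniform positions
  and no interference (Haldane), so the recombinant fraction between
  markers has the closed form $(1 - e^{-2d/100})/2$ that the tests check
  empirically. GBS-like noise sets calls missing (8%) or spuriously
  heterozygous (2.5%), the post-filter error levels typical of un-imputed
  GBS data.
* **Genetic architecture.** Five QTL by default (a few-QTL architecture —
  the regime in which BayesB is expected to beat ridge), drawn from the
  marker positions with Gaussian effects rescaled so the in-sample genetic
  variance is exactly the configured value; this makes $\sigma^2_G$ a hard
  invariant rather than a random target.
* **Trials.** Plot values follow the trial model above with defaults
  $\sigma^2_G = 1$, $\sigma^2_{G\times E} = 0.5$, $\sigma^2_{rep} =
  \sigma^2_{block} = 0.1$, $\sigma^2_e = 2$ (Mg ha$^{-1}$)$^2$ — strong GxE
  and a plot-level $h^2$ of 0.27, entry-mean 0.73, the regime of a stress
  trial with decent quality. Environment means reproduce the reported
  spread (about 5.7/3.6/5.9/1.9 Mg ha$^{-1}$). Genotypes are randomized
  within replicate and cut into consecutive blocks of 10 (block size is
  nowhere stated; 10 divides 97 lines into 9 full blocks and one of 7,
  recorded as padded).
* **Reflectance.** A latent physiological status per line and environment,
  $s = \alpha z_g + \gamma z_{G\times E} + \tau\epsilon$, drives
  reflectance on top of a vegetation-like baseline spectrum (green bump,
  red-edge rise). Band loadings are larger above 700 nm than in the
  visible range, amplified 2.5-fold under drought — so stress concentrates
  information in the red/IR, which the tests verify — and grow with flight
  index (later flights more informative). Two further ingredients give the
  spectra realistic environment specificity: each band's loading receives
  an environment-specific multiplicative jitter, and a second,
  yield-unrelated physiological latent (phenology/canopy structure) loads
  coherently on the whole spectrum with an environment-level coefficient.
  Without them, reflectance would be a single shared factor and a
  spectra-to-yield mapping would transfer perfectly across environments —
  contrary to how such trials behave, where a year unlike the training
  years is predicted poorly; with them, within-environment accuracy
  exceeds across-environment accuracy on average, as it should when GxE
  and environment-specific spectral responses are present.
* **What the generator does not emulate.** Pixel-level imagery, soil
  mixing, atmospheric effects, spatial field trend, epistasis, multi-trait
  genetic correlations. Passing tests therefore show the pipeline's
  statistical machinery is correct under the assumed skeleton, not that
  the real study's numbers are reproduced; the real accuracies, bin counts
  and repeatabilities are properties of the unavailable field and GBS
  data.

One documented inconsistency: the band grid is described in the source
material as 62 evenly spaced bands over 392-850 nm *at 1.9 nm resolution*,
which cannot all hold (458/62 is about 7.4 nm). The generator uses 62 evenly
spaced centers and records the discrepancy rather than guessing intent.

## Bin-map construction

The 5-step QC mirrors standard biparental GBS practice: (1) drop SNPs with
MAF not above 0.05 or missingness not below 20% (strict inequalities,
exactly as the thresholds are phrased); (2) drop lines with heterozygosity
above 5% or missingness above 20%; (3) drop SNPs whose best similarity to
any neighbour inside a centered 8-SNP window (4 a side, truncated at
chromosome ends) is below 95%; (4) merge consecutive SNPs into bins while
their similarity to the bin's running consensus stays at or above 95%; (5)
treat bins as markers, with adjacent-bin distances from the Haldane
transform $d = -50\ln(1-2\hat r)$ (pairs with $\hat r \ge 0.5$ are flagged
unresolved, never silently dropped).

"Similarity" is nowhere defined in the source; here it is orientation-free
— $\max(p, 1-p)$ over lines where both calls are homozygous — making it
invariant to arbitrary allele labeling and robust to the heterozygote error
mode, and pairs with fewer than 10 comparable lines are treated as
non-informative. Unlinked-SNP removal is one-pass (removals do not cascade)
so the result is order-independent; whether the original scripts cascaded,
and whether their window was centered or trailing, is unknowable from the
text — these are recorded decisions, not inferences. Bin consensus is the
per-line majority call with ties set missing (the consensus never invents a
call), and SNPs that join a bin in anti-orientation are flipped first so
the consensus stays phase-coherent.

On noise-free data with threshold 1.0, the greedy merge provably equals the
brute-force partition by identical call vectors, and the tests assert
exactly that; lowering the threshold can only coarsen the partition
(monotonicity, also tested). At the desk-scale default of 2,000 SNPs the
default study collapses to roughly 130 bins — bin counts scale with
population size, error rates and marker density, and the ~500-bin count of
a real 27,818-SNP dataset is not a target the simulator tries to hit.

## Problem sizes and numerical choices

Tests and the acceptance script run at sizes chosen for a desk machine: the
full trial scale (97 lines, 4 environments, 2 replicates) wherever the
quantity under test depends on it (variance-component recovery over 100
seeds; repeatability within 0.08 of its truth-implied value), reduced
replicate counts (2-6) and lightened learner settings (e.g. `ntree` 60-150,
BayesB 500-1500 iterations) for the cross-validation grids, and 6-10 master
seeds for the Monte-Carlo ordering checks (combined-input advantage,
within-vs-across, BayesB-vs-ridge), each as a one-sided t-test at
$\alpha = 0.05$. REML tolerances are `lme4` defaults; ridge REML profiles
$\log\lambda$ over $[-12, 12]$ to 1e-8; NIPALS stops when a weight or score
norm falls below 1e-12 (rank exhaustion); CART splits need a strict gain
above 1e-12 and respect `min_node` on both sides, with midpoint thresholds
between distinct values only.

## Known limitations

* Bin counts at desk-scale SNP density are an order of magnitude below a
  dense real GBS map; the greedy consensus merge also drifts on very long
  bins (votes accumulate), which matters only at thresholds well below
  0.95.
* The LOEO bootstrap SE treats the fold's predictions as fixed, ignoring
  training-set resampling variance — the usual convention, but an
  understatement of total uncertainty.
* `fit_env_model()` flags but does not impute genotypes absent from an
  environment; heavily unbalanced designs are outside the generator's
  scope.
* The BayesB sampler uses one chain; the stored traces support eyeball
  diagnostics, not formal convergence tests.
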
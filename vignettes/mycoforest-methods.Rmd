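---
title: "Linking mycorrhizal tree dominance to forest carbon stocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking mycorrhizal tree dominance to forest carbon stocks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoforest)
```

## The scientific problem

Ectomycorrhizal (EcM) and arbuscular mycorrhizal (AM) trees differ in how
their fungal partners cycle nutrients: EcM fungi can mine organic nitrogen
and tend to slow decomposition, while AM symbioses favour faster, "open"
nutrient cycling. A long-standing question in ecosystem ecology is whether
stands dominated by EcM trees store more carbon — above ground, in the
soil, or both — and whether that advantage depends on climate seasonality,
successional stage, and tree diversity.

`mycoforest` implements the full plot-level computation and statistical
inference needed to answer this question from standard forest-inventory
tables: 30 m × 30 m plots of nine 10 m × 10 m subplots in which every stem
with DBH ≥ 3 cm is measured, plus per-plot soil profiles, species
attributes, seasonality, and topography. Because real inventory campaigns
are not redistributable at desk scale, the package ships a synthetic
generator that reproduces the statistical structure of such a survey with
known effect sizes, so every stage of the pipeline can be validated
end-to-end against ground truth.

## Plot-level quantities

**Tree carbon.** Each stem's biomass comes from a single consistent
allometry, ln(biomass kg) = c0 + c1·ln(DBH² × height), applied across all
species to avoid artifacts of species-specific equations; defaults
c0 = −2.5, c1 = 0.95 give realistic stem masses for temperate trees (a
10 cm × 8 m stem weighs about 47 kg). Biomass converts to carbon with the
standard factor 0.5 and is expressed in Mg C/ha by dividing by the 0.09-ha
plot area, so tree and soil stocks share units before summation.

**Soil carbon.** Soil organic carbon density sums over the sampled depth
layers (0–10, 10–20, 20–30, 30–50, 50–100 cm):
SOCD = Σ (1 − Vᵢ)·Bᵢ·Cᵢ·Tᵢ/10, with Vᵢ the gravel volume fraction, Bᵢ bulk
density (g/cm³), Cᵢ organic C content (g/kg), Tᵢ thickness (cm), and /10
converting to Mg C/ha. Although gravel content is often reported as a
"volume percentage", the (1 − Vᵢ) structure forces the fractional reading;
percent-scale files are supported through `percent = TRUE`. Shallow
profiles sum only the layers present; plots without soil sampling stay
missing — never silently zero — and drop out of soil- and forest-carbon
models, which is why those models run on fewer plots than the tree-carbon
model.

**Mycorrhizal dominance.** EcMD is the share of stand basal area
(π·(DBH/200)² per stem) contributed by EcM species; dual EcM/AM species
contribute half their basal area to each side, so EcMD + AMD = 1. Species
with other strategies (ericoid, non-mycorrhizal — rare in such floras) are
excluded from the dominance numerator and denominator only; their stems
still count toward tree carbon and richness, a choice that preserves the
carbon mass balance. A configuration switch in the reading layer can
remove them entirely if a user prefers the stricter reading.

**Diversity.** Richness is the distinct species count per plot. Functional
diversity is Rao's quadratic entropy Q = Σᵢ Σⱼ pᵢ pⱼ dᵢⱼ over eight leaf
traits (Cmass, Nmass, Pmass, Kmass, LA, SLA, LMA, LDMC). Two genuinely
open choices: the trait distance is Gower (range-normalized), because the
traits live on heterogeneous scales, with Euclidean-on-z-scores available;
and the weights pᵢ are basal-area shares, consistent with the dominance
metric, with stem-count weighting available. Gower ranges are taken over
the whole species pool, not per plot, so distances are comparable across
plots. Missing trait cells are imputed in two steps: species-level
averages where multiple records exist, then the cross-species mean of the
trait; a trait missing for every species is an error, not a guess.

**Climate score.** Temperature seasonality (TS) and precipitation
seasonality (PS) are standardized and reduced to axis 1 of their 2 × 2
PCA, signed so the TS loading is positive: high scores mean jointly
strong seasonal fluctuation, i.e. unfavorable conditions. For two
standardized variables axis 1 always explains between 50% and 100% of the
variance; the generator's default TS/PS noise yields roughly 60%,
matching the degree of TS–PS coupling reported for such surveys.

## The succession index

Successional status is quantified by the classic compositional index.
Within each plot, a species' importance value is
IV = (relative density + relative cover + relative frequency)/3, where
relative frequency counts occupied subplots out of nine (normalized across
species) and cover falls back to basal-area share when no canopy-cover
column is measured. Designated pioneer species anchor the climax
adaptation value (CAV) scale at 1 and designated climax species at 10;
every other species is interpolated as
CAV = (10·s_climax + s_pioneer)/(s_climax + s_pioneer), with similarities
taken as Czekanowski overlap (2Σmin(aₖ,bₖ)/(Σaₖ+Σbₖ)) between the
species' plot-wise IV profile and each group's aggregated profile — the
similarity index itself is not pinned down in the succession literature,
and Czekanowski is the standard abundance-weighted choice. A
non-designated species that never co-occurs with either group gets the
neutral CAV 5.5 with a warning rather than failing the run. The plot's
compositional index Σ IV·CAV is a convex combination of CAVs, hence lies
in [1, 10]; sorting it ascending orders plots along the successional
sequence, and an equal-count tertile cut (ties broken by plot id, for
determinism) yields the early/middle/late stages. The tertile rule is our
choice: qualitative community-type binning has no reproducible threshold.

## Statistical inference

Dominance is moved off the [0, 1] boundary with the Smithson–Verkuilen
map y′ = (y(N − 1) + 0.5)/N, N being the number of plots entering the
model. Each log stock is then modelled with a linear mixed model:
transformed EcMD, z-scored richness, climate score, slope and altitude,
stage (early reference), the EcMD × richness, EcMD × climate and
EcMD × stage interactions, and an ecoregion random intercept. Two
conventions deserve comment:

* *"Generalized" linear mixed models on log stocks* are fitted as
  Gaussian linear mixed models of the log-transformed response — that is
  what log-transforming and then fitting implies; no link-function GLMM
  is involved.
* *Scaling.* Moderators are z-scored before fitting, so interaction
  coefficients are per-SD and the EcMD main effect is the slope at
  average moderator values; EcMD itself stays on its transformed (0, 1)
  scale so its coefficient reads directly as the ln-stock difference
  between pure-AM and pure-EcM stands — this is also what makes recovery
  of the generator's `beta_ecm_tree` directly checkable. Standardized
  estimates (estimate × sd(x)/sd(y); stage dummies divided by sd(y)
  only) are reported alongside for cross-term comparison.

Singular random-effect fits fall back, with a flag and warning, to
fixed-effects OLS — which also realizes the identity that zero ecoregion
variance reduces the mixed model to OLS. Collinearity is screened with
variance inflation factors computed from the fixed-effects design
(VIFⱼ = 1/(1 − R²ⱼ); aliased columns report Inf). Random-forest
permutation importance (replicate-averaged, fixed seed) ranks candidate
drivers before modelling. Model robustness uses the survey's stratified
subsampling scheme: 50% of plots per ecoregion drawn without replacement
(stratification keeps unevenly surveyed regions represented), the model
refitted B = 200 times by default, and per-term sign consistency and
2.5/50/97.5% quantiles reported. Simple-slope moderation is evaluated at
tertile midpoints (16.7/50/83.3 percentiles) of continuous moderators and
at the three stages.

## Piecewise structural equation model

The causal analysis is a from-scratch piecewise SEM. The default DAG has
nodes climate, SUS (compositional index — kept numeric so path
standardization is well defined; stage dummies would have no sd-based
scale), SR (log richness), EcMD (transformed), FD (Rao's Q), and lnC
(log stock), with climate/SUS/SR → EcMD, climate/SUS/SR/EcMD → FD, and
all five → lnC. Each endogenous node is fitted on its parents with an
ecoregion random intercept (OLS when no grouping is available or the fit
is singular). The test of d-separation enumerates one claim per
non-adjacent pair — independence conditional on the union of both nodes'
parents, tested by adding the claimed-independent variable to the
causally later node's parent model — so the basis-set size is always
(number of node pairs) − (number of edges). Global fit is Fisher's
C = −2Σln(pᵢ) against χ² with 2k df; the saturated model returns
(0, 0, 1) by convention. Indirect effects multiply standardized
coefficients along a route. The same skeleton is fitted to each stock
response.

## Fungal community module

A guild-annotated OTU table (OTUs × plots, guilds EcM/SAP/other) is
filtered by the strict low-abundance rule — total counts ≤ 10 across all
samples are removed, totals of exactly 10 included in the removal — then
summarized per plot: EcM and SAP relative abundances and Shannon
diversity H = −Σpᵢ ln pᵢ (natural log; computed on raw count shares
without rarefaction) for all, EcM, and SAP fungi. Each summary is
regressed on EcM tree dominance by OLS.

## What the generator emulates, and what it does not

`sim_config()` defaults define the simulated study: 10 ecoregions × 200
plots, a 240-species pool with 40% EcM, 5% dual, and 1.25% other
strategies, five-layer soil profiles with 55% of plots lacking soil
sampling (mirroring surveys where soil is measured on a subset), about
60 stems per plot (≈670 stems/ha ≥ 3 cm, typical of temperate secondary
forest), DBH from a shifted exponential (all ≥ 3 cm) and height from a
DBH allometry with noise. True effects default to beta_ecm_tree = 0.4,
beta_ecm_soil = 0.3, EcMD × climate = 0.1, EcMD × richness = −0.15,
with ecoregion and residual SDs of 0.3 on the ln-stock scale.

Mechanistically, each plot draws a target EcM share and a latent
succession score; these tilt species sampling (EcM vs AM weight equal to
the target share; pioneer vs climax weight logistic in the latent score
with slope 3 — a sharp turnover chosen because early and late communities
of this kind share few dominant species, and because it makes the
succession gradient strong enough for the compositional index to recover
it reliably at the survey's stem counts). The plot's realized,
boundary-transformed basal-area EcMD then enters a linear predictor with
the configured betas, ecoregion intercepts, and Gaussian noise; a
plot-level productivity multiplier on heights scales summed allometric
biomass to the implied tree carbon, and depth-declining organic-C
profiles are scaled to the implied SOCD. Because generator and estimator
share the allometry and the transform, effect recovery is exact in the
noise-free limit — that is the point: failures downstream indicate
pipeline defects, not generator mismatch.

The generator does *not* emulate spatial autocorrelation, climate
rasters, measurement error in DBH/height, species' real trait
covariances, or non-Gaussian stock residuals. Passing recovery tests
therefore demonstrates the correctness of the computation and the
calibration of the inference under the stated model, not robustness to
every feature of field data.

## Numerical and testing choices

Problem sizes used by the validation suite are deliberate: effect
recovery runs 100 survey replicates of 2,000 plots (nominal 95% CI
coverage of the true 0.4 must reach 90%, and the negative
EcMD × richness sign 90%); null calibration uses 100 replicates of 400
plots; d-separation calibration simulates 500 datasets of 400 rows from
the true DAG with OLS submodels, whose exact t-tests make the nominal
5% rejection sharp; succession recovery uses one 1,000-plot survey
(Spearman ≥ 0.8 against the latent score); oracle equivalence checks
1,000 random soil profiles, 100 Rao's Q cases at richness ≤ 10, and 50
random DAGs of ≤ 7 nodes. All randomness flows through per-call seeds;
identical configurations reproduce output files byte-for-byte.

Known limitations: CAVs depend on the designated pioneer/climax sets and
degrade when designated species are rare; the boundary-transform N is a
modelling convention (plots in model) that users can override; Wald CIs
from the mixed model are approximate with few ecoregions; and the
d-separation test treats basis-set claims as independent, which is
asymptotic rather than exact when conditioning sets overlap.

## A minimal run

```{r, eval = FALSE}
cfg <- sim_config(plots_per_ecoregion = 30, seed = 1)
sim <- simulate_forest_data(cfg)
metrics <- compute_plot_metrics(sim, quiet = TRUE)
fit <- fit_mixed_model(metrics, "tree_c")
fit
interaction_slopes(fit, "richness")
sem <- fit_paths(default_dag(), sem_data_from_metrics(metrics, "tree_c"))
sem
```
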
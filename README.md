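# mycoforest

Does dominance of ectomycorrhizal (EcM) trees make forests store more
carbon — and does the answer depend on climate seasonality, successional
stage, and tree diversity? `mycoforest` is an R package for ecosystem
ecologists who want to answer that question from plot-based forest
inventories: stems (species, DBH ≥ 3 cm, height) in 30 m × 30 m plots of
nine subplots, layered soil profiles, species attributes, and per-plot
seasonality and topography.

The package computes, per plot:

- **Tree carbon** (Mg C/ha): a single consistent allometry
  ln(biomass kg) = c₀ + c₁·ln(DBH²·height) summed over stems, × 0.5
  carbon conversion, per hectare;
- **Soil organic carbon density**: SOCD = Σ (1 − Vᵢ)·Bᵢ·Cᵢ·Tᵢ/10 over up
  to five depth layers (gravel fraction V, bulk density B, organic C
  content C, thickness T), and forest carbon = tree + soil;
- **Mycorrhizal dominance**: EcMD = share of stand basal area from EcM
  species (dual EcM/AM species split 50/50; EcMD + AMD = 1);
- **Diversity**: species richness and Rao's quadratic entropy
  Q = Σᵢⱼ pᵢpⱼdᵢⱼ over eight leaf traits (Gower distance, basal-area
  weights);
- **Succession**: the compositional index Σ IV·CAV — importance values
  IV = (rel. density + rel. cover + rel. frequency)/3 weighted by climax
  adaptation values CAV = (10·s_climax + s_pioneer)/(s_climax + s_pioneer)
  on a 1 (pioneer) to 10 (climax) scale — with tertile early/middle/late
  stages;
- **Climate score**: axis 1 of a PCA of temperature and precipitation
  seasonality, increasing with joint seasonal fluctuation.

and then infers the dominance–carbon relationship with: the
Smithson–Verkuilen boundary transform y′ = (y(N−1)+0.5)/N; linear mixed
models of each ln stock with EcMD × richness, EcMD × stage, and
EcMD × climate interactions and an ecoregion random intercept; VIF
collinearity screening; random-forest driver ranking;
ecoregion-stratified 50% subsampling for robustness; and a from-scratch
piecewise structural equation model (per-path mixed models, Shipley-style
d-separation basis set, Fisher's C = −2Σln p global fit, indirect effects
as products of standardized paths). A fungal module summarizes a
guild-annotated OTU table (low-abundance filter, guild shares, Shannon
diversity) and regresses the summaries on EcMD.

Everything runs end-to-end on a synthetic inventory generator
(`sim_config()`, `simulate_forest_data()`) whose true effect sizes are
known and recorded, so the whole pipeline is testable without field data.

## Worked example

```r
library(mycoforest)

cfg <- sim_config(plots_per_ecoregion = 30, seed = 1)  # 300 plots
sim <- simulate_forest_data(cfg)                        # truth: beta = 0.4
metrics <- compute_plot_metrics(sim, quiet = TRUE)
fit <- fit_mixed_model(metrics, "tree_c")
fit
```

```
Mixed-effects model of ln(tree_c) (ecoregion random intercept)
AIC 225.2 | R2 marginal 0.126, conditional 0.585 | sd(ecoregion) 0.311
                 term estimate     se      p std_estimate
1         (Intercept)   3.2229 0.1089 0.0000           NA
2              ecmd_t   0.4290 0.0933 0.0000       0.3319
3          richness_z   0.0342 0.0300 0.2559       0.0760
...
9   ecmd_t:richness_z  -0.1440 0.0525 0.0065      -0.1835
10   ecmd_t:climate_z   0.0837 0.0497 0.0934       0.1072
...
```

The `ecmd_t` row says moving from a pure-AM to a pure-EcM stand raises
ln(tree C) by 0.43 ± 0.09 here (true generating value 0.4, inside the
95% CI), and the negative `ecmd_t:richness_z` term says the dominance
effect weakens by ~0.14 per SD of species richness — i.e. EcM dominance
matters most in species-poor stands. Moderation can be read directly as
simple slopes, and the causal structure fitted as a piecewise SEM:

```r
interaction_slopes(fit, "richness")
#          level     slope        se        z            p
# 1 -1.151797763 0.5948532 0.1082429 5.495539 3.895194e-08
# 2  0.007730186 0.4278959 0.0933442 4.584065 4.560214e-06
# 3  1.167258136 0.2609387 0.1145112 2.278717 2.268391e-02
sem <- fit_paths(default_dag(), sem_data_from_metrics(metrics, "tree_c"))
sem$fisher_c   # $C 6.99, $df 6, $p 0.32 -> no missing paths indicated
```

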
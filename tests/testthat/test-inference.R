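test_that("boundary transform maps [0,1] strictly inside and inverts", {
  expect_equal(boundary_transform(0.5, 1000), 0.5)
  expect_equal(boundary_transform(0, 100), 0.005)
  expect_equal(boundary_transform(1, 100), 0.995)
  y <- seq(0, 1, by = 0.05)
  yt <- boundary_transform(y, 4525)
  expect_true(all(yt > 0 & yt < 1))
  expect_true(all(diff(yt) > 0))
  expect_equal(boundary_transform_inv(yt, 4525), y, tolerance = 1e-12)
  expect_error(boundary_transform(1.2, 100), "domain")
  expect_error(boundary_transform(0.5, 0), "domain")
})

test_that("simple regression reproduces exact fits and identities", {
  x <- 1:20
  out <- fit_simple_regression(x, 2 * x)
  expect_equal(out$slope, 2, tolerance = 1e-12)
  expect_equal(out$intercept, 0, tolerance = 1e-10)
  expect_equal(out$r_squared, 1)
  # standardized OLS slope equals the sample correlation
  set.seed(3)
  a <- rnorm(100); b <- 0.6 * a + rnorm(100)
  out <- fit_simple_regression(as.numeric(scale(a)), as.numeric(scale(b)))
  expect_equal(out$slope, cor(a, b), tolerance = 1e-10)
  expect_error(fit_simple_regression(rep(1, 5), rnorm(5)), "degenerate")
  expect_true(all(out$band$lwr <= out$band$fit & out$band$fit <= out$band$upr))
})

test_that("slope-test p-values are uniform under independence", {
  set.seed(11)
  p <- replicate(200, fit_simple_regression(rnorm(200), rnorm(200))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_gt(mean(p), 0.4)
  expect_lt(mean(p), 0.6)
})

test_that("VIF matches its closed form and flags aliasing", {
  set.seed(9)
  # orthogonalized columns -> VIF 1
  # orthogonalize against the intercept too, so columns are exactly uncorrelated
  X <- qr.Q(qr(cbind(1, matrix(rnorm(300), 100, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-8)
  # empirical correlation exactly 0.9 -> VIF = 1/(1-0.81)
  x1 <- as.numeric(scale(rnorm(200)))
  e <- resid(lm(rnorm(200) ~ x1)); e <- as.numeric(scale(e))
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * e
  v <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  # duplicated column reported as aliased (infinite VIF)
  v2 <- vif(cbind(x1 = x1, x1b = x1, x2 = x2))
  expect_true(any(is.infinite(v2)))
})

test_that("VIF agrees with the standard regression-based implementation", {
  skip_if_not_installed("car")
  sim <- simulate_forest_data(sim_config(plots_per_ecoregion = 15, seed = 2))
  m <- compute_plot_metrics(sim, quiet = TRUE)
  d <- prepare_model_data(m, "tree_c")
  fit <- lm(ln_y ~ ecmd_t + richness_z + climate_z + slope_z + altitude_z,
            data = d)
  ours <- vif(model.matrix(fit)[, -1])
  theirs <- car::vif(fit)
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-8)
})

test_that("mixed model recovers noise-free effects and ecoregion variance", {
  cfg <- sim_config(plots_per_ecoregion = 30, sigma_resid = 1e-9,
                    sigma_ecoregion = 0, seed = 31)
  sim <- simulate_forest_data(cfg)
  m <- compute_plot_metrics(sim, quiet = TRUE)
  fit <- suppressWarnings(fit_mixed_model(m, "tree_c"))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_lt(abs(est["ecmd_t"] - 0.4), 0.01)
  expect_lt(abs(est["ecmd_t:richness_z"] - (-0.15)), 0.01)
  expect_lt(abs(est["ecmd_t:climate_z"] - 0.1), 0.01)

  # realistic noise: ecoregion SD recovered within 25% at 2000 plots
  sim2 <- simulate_forest_data(sim_config(sigma_ecoregion = 0.5, seed = 13))
  m2 <- compute_plot_metrics(sim2, quiet = TRUE)
  fit2 <- fit_mixed_model(m2, "tree_c")
  expect_lt(abs(fit2$sigma_ecoregion - 0.5) / 0.5, 0.25)
  expect_true(all(fit2$coefficients$se > 0))
  expect_true(is.finite(fit2$AIC))
  expect_gte(fit2$r2_conditional, fit2$r2_marginal)
})

test_that("zero ecoregion variance reduces the fit to OLS", {
  cfg <- sim_config(plots_per_ecoregion = 25, sigma_ecoregion = 0, seed = 42)
  sim <- simulate_forest_data(cfg)
  m <- compute_plot_metrics(sim, quiet = TRUE)
  expect_warning(fit <- fit_mixed_model(m, "tree_c"), "singular")
  expect_true(fit$fallback_ols)
  d <- fit$data
  ols <- lm(as.formula(paste("ln_y ~", mycoforest:::MODEL_RHS)), data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("standardized estimates rescale by sd(x)/sd(y)", {
  sim <- simulate_forest_data(sim_config(plots_per_ecoregion = 15, seed = 6))
  m <- compute_plot_metrics(sim, quiet = TRUE)
  fit <- suppressWarnings(fit_mixed_model(m, "tree_c"))
  co <- fit$coefficients
  d <- fit$data
  i <- match("ecmd_t", co$term)
  expect_equal(co$std_estimate[i],
               co$estimate[i] * sd(d$ecmd_t) / sd(d$ln_y), tolerance = 1e-10)
  expect_true(is.na(co$std_estimate[co$term == "(Intercept)"]))
})

test_that("interaction slopes vary with the moderator as the algebra says", {
  sim <- simulate_forest_data(sim_config(plots_per_ecoregion = 40, seed = 19))
  m <- compute_plot_metrics(sim, quiet = TRUE)
  fit <- suppressWarnings(fit_mixed_model(m, "tree_c"))
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  sl <- interaction_slopes(fit, "richness")
  expect_equal(sl$slope,
               co["ecmd_t"] + sl$level * co["ecmd_t:richness_z"],
               ignore_attr = TRUE, tolerance = 1e-10)
  # slope at the moderator mean equals the main effect under centering
  sl0 <- interaction_slopes(fit, "richness", levels = 0)
  expect_equal(sl0$slope, unname(co["ecmd_t"]), tolerance = 1e-12)
  # negative richness interaction: low-richness slope exceeds high-richness
  expect_gt(sl$slope[1], sl$slope[3])
  sls <- interaction_slopes(fit, "stage")
  expect_equal(sls$slope[1], unname(co["ecmd_t"]), tolerance = 1e-12)
  expect_error(interaction_slopes(
    suppressWarnings(fit_mixed_model(m, "tree_c", interactions = FALSE)),
    "richness"), "specification")
})

test_that("random forest screening ranks a perfect predictor first", {
  sim <- simulate_forest_data(sim_config(plots_per_ecoregion = 15, seed = 23))
  m <- compute_plot_metrics(sim, quiet = TRUE)
  m$tree_c <- exp(m$ecmd * 3)  # response an exact function of dominance
  imp <- driver_importance(m, "tree_c", n_rep = 2, n_tree = 200, seed = 1)
  expect_equal(imp$predictor[1], "ecmd")
  # deterministic under a fixed seed
  imp2 <- driver_importance(m, "tree_c", n_rep = 2, n_tree = 200, seed = 1)
  expect_identical(imp, imp2)
})

test_that("ecoregion subsampling keeps strata and degenerates at fraction 1", {
  sim <- simulate_forest_data(sim_config(plots_per_ecoregion = 20, seed = 3))
  m <- compute_plot_metrics(sim, quiet = TRUE)
  bs <- ecoregion_subsample(m, "tree_c", fraction = 0.5, B = 8, seed = 2)
  d <- fit_mixed_model(m, "tree_c")$data
  expect_equal(bs$n_per_replicate,
               sum(floor(0.5 * table(d$ecoregion_id))))
  expect_true(all(bs$summary$q2.5 <= bs$summary$q50 &
                    bs$summary$q50 <= bs$summary$q97.5))
  expect_true(all(bs$summary$sign_consistency >= 0 &
                    bs$summary$sign_consistency <= 1))
  # fraction 1: every replicate reproduces the full-data estimates
  bs1 <- ecoregion_subsample(m, "tree_c", fraction = 1, B = 3, seed = 2)
  expect_equal(unname(bs1$replicates[1, ]), bs1$summary$full_estimate,
               tolerance = 1e-8)
  expect_true(all(bs1$summary$sign_consistency == 1))
})
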
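test_that("basal area follows the circle formula and rejects bad input", {
  expect_equal(stem_basal_area(20), pi * 0.1^2, tolerance = 1e-10)
  expect_equal(stem_basal_area(3), pi * 0.015^2, tolerance = 1e-10)
  expect_equal(stem_basal_area(3), 7.0686e-4, tolerance = 1e-4)
  expect_error(stem_basal_area(0), "domain")
  expect_error(stem_basal_area(c(5, -1)), "domain")
})

test_that("allometric biomass matches hand evaluations and is monotone", {
  expect_equal(stem_biomass(1, 1, c(0, 1)), 1)
  expect_equal(stem_biomass(10, 8, c(0.7, 0)), exp(0.7))
  expect_equal(stem_biomass(10, 8, c(-2.5, 0.95)),
               exp(-2.5 + 0.95 * log(800)), tolerance = 1e-12)
  expect_equal(stem_biomass(10, 8, c(-2.5, 0.95)), 47.01, tolerance = 1e-3)
  expect_gt(stem_biomass(11, 8), stem_biomass(10, 8))
  expect_gt(stem_biomass(10, 9), stem_biomass(10, 8))
  expect_error(stem_biomass(-1, 5), "domain")
})

test_that("plot tree carbon applies the 0.5 conversion and is additive", {
  # a stem engineered to weigh exactly 1000 kg
  h <- 6
  d <- sqrt(exp((log(1000) + 2.5) / 0.95) / h)
  one <- data.frame(dbh = d, height = h)
  expect_equal(plot_tree_carbon(one, area_ha = 0.09), 0.5 / 0.09,
               tolerance = 1e-10)
  two <- rbind(one, one)
  expect_equal(plot_tree_carbon(two), 2 * plot_tree_carbon(one),
               tolerance = 1e-12)
  # linear in biomass: doubling biomass via coefficients doubles carbon
  expect_equal(plot_tree_carbon(one, coeffs = c(-2.5 + log(2), 0.95)),
               2 * plot_tree_carbon(one), tolerance = 1e-12)
  expect_warning(z <- plot_tree_carbon(one[0, ]), "empty")
  expect_equal(z, 0)
})

test_that("mycorrhizal dominance splits dual species evenly and sums to one", {
  sp <- tiny_species()
  mono <- data.frame(plot_id = "p", subplot = 1L, species_id = "spA",
                     dbh = c(10, 12), height = 8)
  d <- mycorrhizal_dominance(mono, sp)
  expect_equal(d$ecmd, 1)
  expect_equal(d$amd, 0)

  dual <- data.frame(plot_id = "p", subplot = 1L, species_id = "spC",
                     dbh = 10, height = 8)
  d <- mycorrhizal_dominance(dual, sp)
  expect_equal(d$ecmd, 0.5)
  expect_equal(d$amd, 0.5)

  # BA_EcM = 1, BA_dual = 1, BA_AM = 2 (in m^2) -> ecmd = 1.5/4
  dbh_for_ba <- function(ba) 200 * sqrt(ba / pi)
  mix <- data.frame(plot_id = "p", subplot = 1L,
                    species_id = c("spA", "spC", "spB"),
                    dbh = dbh_for_ba(c(1, 1, 2)), height = 8)
  d <- mycorrhizal_dominance(mix, sp)
  expect_equal(d$ecmd, 0.375, tolerance = 1e-12)
  expect_equal(d$ecmd + d$amd, 1)

  # uniform DBH scaling preserves the dominance ratio
  scaled <- transform(mix, dbh = dbh * 3.7)
  expect_equal(mycorrhizal_dominance(scaled, sp)$ecmd, d$ecmd,
               tolerance = 1e-12)

  expect_error(mycorrhizal_dominance(
    data.frame(plot_id = "p", subplot = 1L, species_id = "spD",
               dbh = 10, height = 8), sp), "EcM/AM/dual")
})

test_that("species richness counts distinct species", {
  stems <- data.frame(species_id = rep("spA", 5))
  expect_equal(species_richness(stems), 1)
  expect_equal(species_richness(data.frame(species_id = c("a", "b", "c"))), 3)
  # union of two subplots' species sets: {a,b,c} and {c,d,e} -> 5
  expect_equal(species_richness(
    data.frame(species_id = c("a", "b", "c", "c", "d", "e"))), 5)
})

test_that("trait imputation averages records then fills with pool means", {
  sp <- tiny_species()
  expect_equal(impute_traits(sp)[names(sp)], sp[order(sp$species_id), ],
               tolerance = 1e-12)

  sp$SLA <- c(10, 20, 30, NA)
  out <- impute_traits(sp)
  expect_equal(out$SLA[out$species_id == "spD"], 20)
  expect_false(anyNA(out))

  # duplicate species rows averaged before imputation
  dup <- rbind(sp, sp[1, ])
  dup$SLA[5] <- 14
  out2 <- impute_traits(dup)
  expect_equal(out2$SLA[out2$species_id == "spA"], 12)

  sp$Pmass <- NA_real_
  expect_error(impute_traits(sp), "Pmass")
})

test_that("Rao's Q matches the brute-force double sum", {
  # two maximally distinct species: every Gower contribution is 1
  sp <- tiny_species()[1:2, ]
  p <- setNames(c(0.5, 0.5), sp$species_id)
  expect_equal(rao_q(p, sp), 0.5, tolerance = 1e-10)

  expect_equal(rao_q(setNames(1, "spA"), tiny_species()[1, , drop = FALSE]), 0)
  expect_error(rao_q(setNames(c(0.5, 0.4), c("spA", "spB")), tiny_species()),
               "normalization")

  # randomized oracle comparison at richness <= 10
  set.seed(42)
  for (r in 1:20) {
    k <- sample(2:10, 1)
    tm <- matrix(rlnorm(k * 8, 2, 0.5), k,
                 dimnames = list(paste0("s", 1:k),
                                 c("Cmass", "Nmass", "Pmass", "Kmass",
                                   "LA", "SLA", "LMA", "LDMC")))
    p <- runif(k); p <- p / sum(p); names(p) <- rownames(tm)
    d <- gower_oracle(tm)
    expect_equal(rao_q(p, as.data.frame(tm)), rao_oracle(p, d),
                 tolerance = 1e-8)
    # symmetric in species order
    perm <- sample(k)
    expect_equal(rao_q(p[perm], as.data.frame(tm)[perm, ]),
                 rao_q(p, as.data.frame(tm)), tolerance = 1e-10)
  }
})

test_that("climate score orientation and variance share behave as a 2-var PCA", {
  set.seed(1)
  TS <- rnorm(50, 13000, 1500)
  cs <- climate_score(TS, PS = TS / 100)        # perfectly collinear
  expect_equal(cs$var_explained, 1, tolerance = 1e-12)

  # exactly uncorrelated pair -> axis 1 explains exactly half
  TSo <- c(1, 1, -1, -1); PSo <- c(1, -1, 1, -1)
  expect_equal(climate_score(TSo, PSo)$var_explained, 0.5, tolerance = 1e-12)

  PS <- 80 + (TS - 13000) / 200 + rnorm(50, 0, 10)
  cs <- climate_score(TS, PS)
  expect_gte(cs$var_explained, 0.5)
  expect_lte(cs$var_explained, 1)
  # the jointly most seasonal plot scores highest
  i <- which.max(scale(TS) + scale(PS))
  expect_equal(which.max(cs$score), i)
  expect_gt(cor(cs$score, TS), 0)
  expect_error(climate_score(rep(1, 5), 1:5), "degenerate")
})

test_that("plot metrics table satisfies its structural invariants", {
  sim <- simulate_forest_data(sim_config(plots_per_ecoregion = 8, seed = 17))
  m <- compute_plot_metrics(sim, quiet = TRUE)
  expect_equal(nrow(m), nrow(sim$plots))
  ok <- !is.na(m$ecmd)
  expect_true(all(abs(m$ecmd[ok] + m$amd[ok] - 1) < 1e-12))
  expect_true(all(m$richness >= 1))
  expect_true(all(m$raoq >= 0, na.rm = TRUE))
  expect_true(all(m$comp_index >= 1 - 1e-9 & m$comp_index <= 10 + 1e-9))
  expect_true(all(is.na(m$forest_c) == is.na(m$soil_c)))
  expect_equal(m$forest_c[!is.na(m$forest_c)],
               (m$tree_c + m$soil_c)[!is.na(m$soil_c)])
  expect_true(all(table(m$stage) >= floor(nrow(m) / 3)))
})
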
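#' Configuration for the synthetic forest-inventory generator
#'
#' Bundles all knobs of the generator: the layout of the survey (ecoregions,
#' plots, species pool), the composition of the species pool by mycorrhizal
#' strategy, and the true effect structure that downstream inference should
#' recover. Effects are expressed on the natural-log scale of the carbon
#' stocks: \code{beta_ecm_tree} is the slope of ln tree carbon on the
#' boundary-transformed EcM dominance, and the interaction coefficients
#' multiply the product of transformed dominance with the z-scored moderator
#' (climate score or species richness).
#'
#' @param n_ecoregions number of ecoregions (random-intercept groups).
#' @param plots_per_ecoregion plots simulated per ecoregion.
#' @param n_species size of the regional species pool.
#' @param frac_ecm,frac_dual,frac_other proportions of the pool assigned the
#'   EcM, dual EcM/AM, and other (ericoid/non-mycorrhizal) strategies; the
#'   remainder is AM. Must sum to at most 1.
#' @param beta_ecm_tree,beta_ecm_soil true effects of transformed EcM
#'   dominance on ln tree carbon and ln soil carbon.
#' @param beta_int_climate,beta_int_sr true EcMD-by-climate and
#'   EcMD-by-richness interaction coefficients (applied to both stocks).
#' @param sigma_ecoregion standard deviation of ecoregion random intercepts.
#' @param sigma_resid residual standard deviation on the ln-stock scale.
#' @param allometry_coeffs length-2 numeric \code{c(c0, c1)} of the shared
#'   allometric form ln(biomass kg) = c0 + c1 ln(DBH^2 height).
#' @param mean_stems mean stems per 0.09-ha plot (Poisson, floored at 5).
#' @param pool_size_range integer range of the per-plot local species pool.
#' @param frac_soil_missing fraction of plots without soil profiles, mirroring
#'   surveys where soil sampling covers only a subset of plots.
#' @param trait_missing fraction of species-by-trait cells set missing, to
#'   exercise trait imputation.
#' @param seed integer seed; identical configs reproduce outputs exactly.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_ecoregions = 10, plots_per_ecoregion = 200,
                       n_species = 240, frac_ecm = 0.40, frac_dual = 0.05,
                       frac_other = 0.0125, beta_ecm_tree = 0.4,
                       beta_ecm_soil = 0.3, beta_int_climate = 0.1,
                       beta_int_sr = -0.15, sigma_ecoregion = 0.3,
                       sigma_resid = 0.3, allometry_coeffs = c(-2.5, 0.95),
                       mean_stems = 60, pool_size_range = c(4L, 20L),
                       frac_soil_missing = 0.55, trait_missing = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_ecoregions = as.integer(n_ecoregions),
    plots_per_ecoregion = as.integer(plots_per_ecoregion),
    n_species = as.integer(n_species),
    frac_ecm = frac_ecm, frac_dual = frac_dual, frac_other = frac_other,
    beta_ecm_tree = beta_ecm_tree, beta_ecm_soil = beta_ecm_soil,
    beta_int_climate = beta_int_climate, beta_int_sr = beta_int_sr,
    sigma_ecoregion = sigma_ecoregion, sigma_resid = sigma_resid,
    allometry_coeffs = as.numeric(allometry_coeffs),
    mean_stems = mean_stems,
    pool_size_range = as.integer(pool_size_range),
    frac_soil_missing = frac_soil_missing,
    trait_missing = trait_missing,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  prop <- c(cfg$frac_ecm, cfg$frac_dual, cfg$frac_other,
            cfg$frac_soil_missing, cfg$trait_missing)
  if (any(!is.finite(prop)) || any(prop < 0) || any(prop > 1)) {
    stop("configuration error: proportions must lie in [0, 1]")
  }
  if (cfg$frac_ecm + cfg$frac_dual + cfg$frac_other > 1 + 1e-12) {
    stop("configuration error: frac_ecm + frac_dual + frac_other exceeds 1")
  }
  if (cfg$sigma_ecoregion < 0 || cfg$sigma_resid < 0) {
    stop("configuration error: standard deviations must be >= 0")
  }
  if (cfg$n_ecoregions < 1 || cfg$plots_per_ecoregion < 1 || cfg$n_species < 1) {
    stop("configuration error: counts must be >= 1")
  }
  if (length(cfg$allometry_coeffs) != 2) {
    stop("configuration error: allometry_coeffs must be length 2 (c0, c1)")
  }
  invisible(cfg)
}

#' Generate a synthetic species-attributes table
#'
#' Draws a species pool with mycorrhizal strategies in the configured
#' proportions, eight log-normal leaf traits whose means differ by strategy
#' (EcM species tend toward lower leaf N and higher leaf dry matter content,
#' the conservative end of the leaf economics spectrum), and a
#' pioneer/climax/neither seral label with pioneers enriched among
#' high-SLA (light-demanding) draws. A configurable fraction of trait cells
#' is set missing to exercise imputation.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with columns \code{species_id}, \code{strategy},
#'   \code{seral_status}, and the eight traits
#'   (Cmass, Nmass, Pmass, Kmass, LA, SLA, LMA, LDMC).
#' @export
generate_species_pool <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_species
    frac_am <- 1 - config$frac_ecm - config$frac_dual - config$frac_other
    strategy <- sample(c("EcM", "dual", "other", "AM"), n, replace = TRUE,
                       prob = c(config$frac_ecm, config$frac_dual,
                                config$frac_other, frac_am))
    is_ecm <- strategy %in% c("EcM", "dual")
    # Log-normal traits; EcM-leaning species shifted toward the
    # conservative (low Nmass, high LDMC, low SLA) syndrome.
    traits <- data.frame(
      Cmass = rlnorm(n, log(470), 0.06),
      Nmass = rlnorm(n, log(21) - 0.18 * is_ecm, 0.22),
      Pmass = rlnorm(n, log(1.6) - 0.10 * is_ecm, 0.25),
      Kmass = rlnorm(n, log(8.5), 0.25),
      LA    = rlnorm(n, log(2200), 0.60),
      SLA   = rlnorm(n, log(15) - 0.12 * is_ecm, 0.30),
      LMA   = rlnorm(n, log(0.07) + 0.12 * is_ecm, 0.30),
      LDMC  = rlnorm(n, log(300) + 0.12 * is_ecm, 0.15)
    )
    # Seral labels: pioneers enriched among light-demanding (high-SLA) draws.
    sla_z <- as.numeric(scale(log(traits$SLA)))
    p_pioneer <- 0.30 * plogis(1.5 * sla_z)
    p_climax <- 0.30 * plogis(-1.5 * sla_z)
    u <- runif(n)
    seral <- ifelse(u < p_pioneer, "pioneer",
                    ifelse(u < p_pioneer + p_climax, "climax", "neither"))
    if (config$trait_missing > 0) {
      cells <- which(runif(n * length(TRAIT_NAMES)) < config$trait_missing)
      m <- as.matrix(traits)
      m[cells] <- NA_real_
      traits <- as.data.frame(m)
    }
    cbind(data.frame(species_id = sprintf("sp%03d", seq_len(n)),
                     strategy = strategy, seral_status = seral,
                     stringsAsFactors = FALSE),
          traits)
  })
}

#' Generate a synthetic forest inventory with known ground truth
#'
#' Simulates plots across ecoregions, stems within plots, and layered soil
#' profiles, so that the realized basal-area EcM dominance carries the
#' configured true effects on ln tree carbon and ln soil carbon. The
#' mechanism: each plot draws a target EcM share and a latent succession
#' score that jointly tilt species sampling; stems get DBH from a shifted
#' exponential (all >= 3 cm) and heights from a DBH allometry with noise;
#' the plot's stand-level productivity (a common height multiplier) and its
#' soil organic-carbon contents are then set so the plot's realized carbon
#' stocks equal the model's linear predictor built from the realized,
#' boundary-transformed dominance, z-scored moderators, ecoregion random
#' intercepts, and Gaussian residuals.
#'
#' @param config a \code{\link{sim_config}}.
#' @param species species table from \code{\link{generate_species_pool}}.
#' @return list with data.frames \code{plots}, \code{stems}, \code{soil},
#'   the \code{species} table, and \code{truth} (generating coefficients,
#'   ecoregion intercepts, per-plot latent succession scores and targets).
#' @export
generate_inventory <- function(config, species) {
  validate_sim_config(config)
  stopifnot(is.data.frame(species), nrow(species) == config$n_species)
  with_seed(config$seed + 1L, {
    n_eco <- config$n_ecoregions
    n_plot <- n_eco * config$plots_per_ecoregion
    eco <- rep(sprintf("eco%02d", seq_len(n_eco)), each = config$plots_per_ecoregion)
    plot_id <- sprintf("plot%05d", seq_len(n_plot))

    # Climate: an ecoregion-level latent seasonality plus plot noise drives
    # correlated temperature (TS) and precipitation (PS) seasonality.
    eco_clim <- rnorm(n_eco)
    clim_lat <- eco_clim[as.integer(factor(eco))] * 0.7 + rnorm(n_plot, 0, 0.7)
    TS <- 13000 + 1500 * clim_lat + rnorm(n_plot, 0, 3000)
    PS <- 80 + 10 * clim_lat + rnorm(n_plot, 0, 20)
    slope <- runif(n_plot, 0, 35)
    altitude <- pmax(50, rnorm(n_plot, 600, 200))

    succ <- rnorm(n_plot)                  # latent succession score
    ecmd_target <- rbeta(n_plot, 1.5, 1.5) # wide dominance gradient

    # Local species pools and stems: strategy weight pulls toward the
    # plot's target EcM share; seral weight follows a logistic in the
    # latent succession score (climax-favoured late, pioneer-favoured early).
    k_pool <- sample(seq(config$pool_size_range[1], config$pool_size_range[2]),
                     n_plot, replace = TRUE)
    n_stems <- pmax(5L, rpois(n_plot, config$mean_stems))
    strat <- species$strategy
    seral <- species$seral_status

    stems_list <- vector("list", n_plot)
    for (i in seq_len(n_plot)) {
      w_strat <- ifelse(strat == "EcM", ecmd_target[i],
                 ifelse(strat == "AM", 1 - ecmd_target[i],
                 ifelse(strat == "dual", 0.5, 0.02)))
      p_cl <- plogis(3 * succ[i])
      w_seral <- ifelse(seral == "climax", p_cl,
                 ifelse(seral == "pioneer", 1 - p_cl, 0.5))
      w <- w_strat * w_seral
      pool <- sample.int(nrow(species), size = k_pool[i], prob = w)
      sp <- sample(pool, n_stems[i], replace = TRUE,
                   prob = w[pool])
      dbh <- 3 + rexp(n_stems[i], rate = 1 / 8)
      height <- exp(1.1 + 0.55 * log(dbh) + rnorm(n_stems[i], 0, 0.12))
      stems_list[[i]] <- data.frame(
        plot_id = plot_id[i],
        subplot = sample.int(9L, n_stems[i], replace = TRUE),
        species_id = species$species_id[sp],
        dbh = dbh, height = height, stringsAsFactors = FALSE)
    }
    stems <- do.call(rbind, stems_list)

    # Realized moderators from the stems themselves, exactly as the
    # inference module will compute them.
    dom <- plot_dominance(apply_strategy_exclusion(stems, species, quiet = TRUE),
                          species)
    ecmd <- dom$ecmd[match(plot_id, dom$plot_id)]
    ecmd[is.na(ecmd)] <- 0.5  # plots with no EcM/AM/dual basal area (rare)
    richness <- vapply(split(stems$species_id, factor(stems$plot_id, levels = plot_id)),
                       function(s) length(unique(s)), integer(1))
    cs <- climate_score(TS, PS)
    clim_z <- as.numeric(scale(cs$score))
    sr_z <- as.numeric(scale(richness))

    x_t <- boundary_transform(ecmd, n_plot)
    u_tree <- rnorm(n_eco, 0, config$sigma_ecoregion)
    u_soil <- rnorm(n_eco, 0, config$sigma_ecoregion)
    eco_idx <- as.integer(factor(eco))
    eps_t <- rnorm(n_plot, 0, config$sigma_resid)
    eps_s <- rnorm(n_plot, 0, config$sigma_resid)
    b0_tree <- 3.3
    b0_soil <- 4.4
    eta_tree <- b0_tree + config$beta_ecm_tree * x_t +
      config$beta_int_climate * x_t * clim_z +
      config$beta_int_sr * x_t * sr_z + u_tree[eco_idx] + eps_t
    eta_soil <- b0_soil + config$beta_ecm_soil * x_t +
      config$beta_int_climate * x_t * clim_z +
      config$beta_int_sr * x_t * sr_z + u_soil[eco_idx] + eps_s

    # Scale stand height so summed allometric biomass hits the target
    # tree carbon stock exactly (a plot-level productivity multiplier).
    c0 <- config$allometry_coeffs[1]; c1 <- config$allometry_coeffs[2]
    area_ha <- 0.09
    target_kg <- exp(eta_tree) * 1000 * area_ha / 0.5
    raw_kg <- vapply(
      split(exp(c0 + c1 * log(stems$dbh^2 * stems$height)),
            factor(stems$plot_id, levels = plot_id)),
      sum, numeric(1))
    hmult <- (target_kg / raw_kg)^(1 / c1)
    stems$height <- stems$height * hmult[match(stems$plot_id, plot_id)]

    # Soil profiles: depth-declining relative C, scaled so plot SOCD
    # equals exp(eta_soil). A configured fraction of plots lacks soil.
    has_soil <- runif(n_plot) >= config$frac_soil_missing
    soil_plots <- which(has_soil)
    tops <- c(0, 10, 20, 30, 50); bots <- c(10, 20, 30, 50, 100)
    n_layers <- ifelse(runif(length(soil_plots)) < 0.1,
                       sample(3:4, length(soil_plots), replace = TRUE), 5L)
    soil_list <- vector("list", length(soil_plots))
    for (j in seq_along(soil_plots)) {
      i <- soil_plots[j]
      k <- n_layers[j]
      V <- runif(k, 0, 0.3)
      B <- pmax(0.6, rnorm(k, 1.2 + 0.06 * seq_len(k), 0.1))
      mid <- (tops[1:k] + bots[1:k]) / 2
      c_rel <- exp(-0.03 * mid)
      T_ <- bots[1:k] - tops[1:k]
      raw <- sum((1 - V) * B * c_rel * T_ / 10)
      C <- c_rel * exp(eta_soil[i]) / raw
      soil_list[[j]] <- data.frame(
        plot_id = plot_id[i], layer_index = seq_len(k),
        top_cm = tops[1:k], bottom_cm = bots[1:k],
        gravel_frac = V, bulk_density = B, organic_c = C,
        thickness = T_, stringsAsFactors = FALSE)
    }
    soil <- if (length(soil_list)) do.call(rbind, soil_list) else
      data.frame(plot_id = character(), layer_index = integer(),
                 top_cm = numeric(), bottom_cm = numeric(),
                 gravel_frac = numeric(), bulk_density = numeric(),
                 organic_c = numeric(), thickness = numeric())

    plots <- data.frame(plot_id = plot_id, ecoregion_id = eco,
                        slope = slope, altitude = altitude,
                        TS = TS, PS = PS, area_ha = area_ha,
                        stringsAsFactors = FALSE)
    truth <- list(
      beta_ecm_tree = config$beta_ecm_tree,
      beta_ecm_soil = config$beta_ecm_soil,
      beta_int_climate = config$beta_int_climate,
      beta_int_sr = config$beta_int_sr,
      b0_tree = b0_tree, b0_soil = b0_soil,
      sigma_ecoregion = config$sigma_ecoregion,
      sigma_resid = config$sigma_resid,
      ecoregion_intercepts_tree = setNames(u_tree, sprintf("eco%02d", seq_len(n_eco))),
      ecoregion_intercepts_soil = setNames(u_soil, sprintf("eco%02d", seq_len(n_eco))),
      succession_score = setNames(succ, plot_id),
      ecmd_target = setNames(ecmd_target, plot_id),
      ecmd_realized = setNames(ecmd, plot_id),
      transform_n = n_plot)
    list(plots = plots, stems = stems, soil = soil, species = species,
         truth = truth)
  })
}

#' Simulate a complete forest-inventory dataset
#'
#' Convenience wrapper: generates the species pool and the inventory from
#' one configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @return see \code{\link{generate_inventory}}.
#' @export
simulate_forest_data <- function(config = sim_config()) {
  sp <- generate_species_pool(config)
  generate_inventory(config, sp)
}

#' Simulate a guild-annotated fungal OTU table
#'
#' Generates soil fungal OTU counts whose ectomycorrhizal-guild share rises,
#' and saprotrophic share falls, with the plots' EcM tree dominance —
#' the structure the guild-versus-dominance regressions are meant to detect.
#'
#' @param ecmd numeric vector of per-plot EcM tree dominance in [0, 1];
#'   names (if any) become the plot columns.
#' @param n_otus number of OTUs.
#' @param depth mean sequencing depth per plot.
#' @param effect logistic slope tying EcM-guild share to dominance.
#' @param seed integer seed.
#' @return list with \code{counts} (OTU-by-plot integer matrix) and
#'   \code{guild} (one of "EcM", "SAP", "other" per OTU).
#' @export
simulate_otu_table <- function(ecmd, n_otus = 300, depth = 20000,
                               effect = 2, seed = 1L) {
  stopifnot(all(ecmd >= 0 & ecmd <= 1))
  with_seed(seed, {
    guild <- sample(c("EcM", "SAP", "other"), n_otus, replace = TRUE,
                    prob = c(0.35, 0.45, 0.20))
    base <- rlnorm(n_otus, 0, 1.2)   # OTU-level abundance heterogeneity
    n_plot <- length(ecmd)
    counts <- matrix(0L, n_otus, n_plot)
    for (j in seq_len(n_plot)) {
      g_mult <- ifelse(guild == "EcM", exp(effect * (ecmd[j] - 0.5)),
                ifelse(guild == "SAP", exp(-effect * (ecmd[j] - 0.5)), 1))
      lam <- base * g_mult
      p <- lam / sum(lam)
      counts[, j] <- as.integer(rpois(n_otus, depth * p))
    }
    rownames(counts) <- sprintf("otu%04d", seq_len(n_otus))
    colnames(counts) <- names(ecmd) %||% sprintf("plot%05d", seq_len(n_plot))
    list(counts = counts, guild = setNames(guild, rownames(counts)))
  })
}
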
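#' Basal area of a stem from its DBH
#'
#' Cross-sectional area at breast height, \eqn{\pi (DBH/200)^2}, with DBH in
#' cm and the result in m^2.
#'
#' @param dbh numeric DBH in cm, strictly positive.
#' @return basal area in m^2.
#' @export
stem_basal_area <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("domain error: dbh must be strictly positive")
  }
  pi * (dbh / 200)^2
}

#' Allometric stem biomass
#'
#' Single consistent allometry shared across species:
#' \eqn{\ln(biomass_{kg}) = c_0 + c_1 \ln(DBH^2 \cdot height)} with DBH in cm
#' and height in m. Using one equation for all species avoids artifacts of
#' species-specific fits when comparing stands of different composition.
#'
#' @param dbh DBH in cm (> 0).
#' @param height height in m (> 0).
#' @param coeffs numeric c(c0, c1).
#' @return biomass in kg.
#' @export
stem_biomass <- function(dbh, height, coeffs = c(-2.5, 0.95)) {
  if (any(!is.finite(dbh)) || any(dbh <= 0) ||
      any(!is.finite(height)) || any(height <= 0)) {
    stop("domain error: dbh and height must be strictly positive")
  }
  exp(coeffs[1] + coeffs[2] * log(dbh^2 * height))
}

#' Plot-level tree carbon stock
#'
#' Sums allometric biomass over the plot's stems, converts biomass to
#' carbon with the standard factor 0.5, and expresses the stock per hectare.
#'
#' @param stems stems of a single plot (columns dbh, height).
#' @param coeffs allometry coefficients c(c0, c1).
#' @param area_ha plot area in hectares (0.09 for a 30 m x 30 m plot).
#' @return tree carbon stock in Mg C/ha; 0 (with a warning) for an empty plot.
#' @export
plot_tree_carbon <- function(stems, coeffs = c(-2.5, 0.95), area_ha = 0.09) {
  if (nrow(stems) == 0) {
    warning("empty plot: tree carbon stock set to 0")
    return(0)
  }
  sum(stem_biomass(stems$dbh, stems$height, coeffs)) * 0.5 / 1000 / area_ha
}

#' Basal-area mycorrhizal dominance of a plot
#'
#' EcM dominance is the share of the stand's total basal area contributed
#' by EcM species; dual EcM/AM species contribute half their basal area to
#' each side, so EcM and AM dominance sum to one.
#'
#' @param stems stems of one plot, already restricted to EcM/AM/dual
#'   species (see \code{\link{apply_strategy_exclusion}}).
#' @param species species table with \code{strategy}.
#' @return list with \code{ecmd} and \code{amd}.
#' @export
mycorrhizal_dominance <- function(stems, species) {
  strat <- species$strategy[match(stems$species_id, species$species_id)]
  if (!all(strat %in% c("EcM", "AM", "dual"))) {
    stop("mycorrhizal_dominance expects stems of EcM/AM/dual species only")
  }
  ba <- stem_basal_area(stems$dbh)
  total <- sum(ba)
  if (!is.finite(total) || total <= 0) {
    stop("undefined-dominance error: total basal area is zero for this plot")
  }
  ecmd <- (sum(ba[strat == "EcM"]) + 0.5 * sum(ba[strat == "dual"])) / total
  list(ecmd = ecmd, amd = 1 - ecmd)
}

# Vectorized per-plot dominance over a stems table (internal).
plot_dominance <- function(stems, species) {
  strat <- species$strategy[match(stems$species_id, species$species_id)]
  ok <- strat %in% c("EcM", "AM", "dual")
  stems <- stems[ok, , drop = FALSE]; strat <- strat[ok]
  ba <- stem_basal_area(stems$dbh)
  w <- ifelse(strat == "EcM", 1, ifelse(strat == "dual", 0.5, 0))
  num <- rowsum(ba * w, stems$plot_id)
  den <- rowsum(ba, stems$plot_id)
  data.frame(plot_id = rownames(num), ecmd = num[, 1] / den[, 1],
             amd = 1 - num[, 1] / den[, 1], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Tree species richness of a plot
#'
#' @param stems stems of one plot.
#' @return number of distinct species.
#' @export
species_richness <- function(stems) {
  length(unique(stems$species_id))
}

#' Impute missing leaf trait values
#'
#' Species represented by multiple rows are first averaged per trait over
#' their available records; any remaining missing cell is filled with the
#' cross-species mean of that trait. Errors if a trait is missing for every
#' species.
#'
#' @param species species table containing the eight trait columns.
#' @return one row per species with a complete trait matrix.
#' @export
impute_traits <- function(species) {
  traits <- intersect(TRAIT_NAMES, names(species))
  if (!length(traits)) stop("no trait columns found")
  agg <- aggregate(species[traits], by = list(species_id = species$species_id),
                   FUN = function(v) mean(v, na.rm = TRUE))
  for (t in traits) {
    v <- agg[[t]]
    v[is.nan(v)] <- NA_real_
    if (all(is.na(v))) {
      stop(sprintf("imputation error: trait %s is missing for every species", t))
    }
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    agg[[t]] <- v
  }
  meta <- species[!duplicated(species$species_id),
                  setdiff(names(species), traits), drop = FALSE]
  out <- merge(meta, agg, by = "species_id", sort = TRUE)
  out[order(out$species_id), , drop = FALSE]
}

#' Rao's quadratic entropy
#'
#' Abundance-weighted expected trait distance between two randomly drawn
#' individuals: \eqn{Q = \sum_i \sum_j p_i p_j d_{ij}}. Distances are Gower
#' (range-normalized over the eight traits) by default, or Euclidean on
#' z-scored traits.
#'
#' @param abundances named numeric vector of species weights summing to 1
#'   (names are species_id); basal-area shares by convention.
#' @param trait_matrix data.frame/matrix of complete traits with species_id
#'   rownames (or a species table from \code{\link{impute_traits}}).
#' @param distance "gower" (default) or "euclidean" (on z-scores).
#' @return Rao's Q (>= 0; 0 for a single species).
#' @export
rao_q <- function(abundances, trait_matrix, distance = c("gower", "euclidean")) {
  distance <- match.arg(distance)
  if (abs(sum(abundances) - 1) > 1e-8) {
    stop("normalization error: abundances must sum to 1")
  }
  if (length(abundances) < 2) return(0)
  tm <- trait_matrix
  if (is.data.frame(tm) && "species_id" %in% names(tm)) {
    rownames(tm) <- tm$species_id
  }
  tm <- as.matrix(as.data.frame(tm)[intersect(TRAIT_NAMES, colnames(tm))])
  tm <- tm[names(abundances), , drop = FALSE]
  if (anyNA(tm)) stop("trait matrix must be complete (run impute_traits first)")
  d <- switch(distance,
              gower = as.matrix(cluster::daisy(as.data.frame(tm), metric = "gower")),
              euclidean = as.matrix(dist(scale(tm))))
  p <- as.numeric(abundances)
  as.numeric(t(p) %*% d %*% p)
}

#' Seasonality-based climate score
#'
#' Standardizes temperature seasonality (TS) and precipitation seasonality
#' (PS) and takes axis 1 of their principal component analysis, oriented so
#' the TS loading is positive: high scores mean jointly strong seasonal
#' fluctuation, i.e. less favorable conditions for growth.
#'
#' @param TS,PS numeric vectors over plots (length >= 2, non-constant).
#' @return list with \code{score} (axis-1 scores), \code{var_explained}
#'   (fraction of variance on axis 1, in [0.5, 1] for two variables), and
#'   \code{loadings}.
#' @export
climate_score <- function(TS, PS) {
  if (length(TS) < 2 || length(TS) != length(PS)) {
    stop("TS and PS must be equal-length vectors with >= 2 plots")
  }
  if (sd(TS) == 0 || sd(PS) == 0) {
    stop("degenerate-input error: TS or PS has zero variance")
  }
  p <- prcomp(cbind(TS = TS, PS = PS), center = TRUE, scale. = TRUE)
  s <- p$x[, 1]
  load <- p$rotation[, 1]
  if (load["TS"] < 0) { s <- -s; load <- -load }
  list(score = as.numeric(s),
       var_explained = p$sdev[1]^2 / sum(p$sdev^2),
       loadings = load)
}

#' Assemble the per-plot metrics table
#'
#' Runs the full plot-level computation on a validated dataset bundle:
#' stem inclusion filter, tree carbon, soil organic carbon density, forest
#' carbon, basal-area mycorrhizal dominance (with rare strategies
#' excluded), species richness, Rao's Q on imputed traits with basal-area
#' weights, the seasonality climate score, and the compositional succession
#' index with early/middle/late stages.
#'
#' @param bundle dataset bundle (\code{plots}, \code{stems}, \code{soil},
#'   \code{species}).
#' @param coeffs allometry coefficients.
#' @param min_dbh stem inclusion threshold (cm).
#' @param rao_distance trait distance for Rao's Q.
#' @param quiet suppress filter messages.
#' @return data.frame with one row per plot: plot_id, ecoregion_id,
#'   tree_c, soil_c, forest_c (Mg C/ha; soil/forest NA where soil was not
#'   sampled), ecmd, amd, richness, raoq, climate_score, comp_index, stage,
#'   slope, altitude, TS, PS.
#' @export
compute_plot_metrics <- function(bundle, coeffs = c(-2.5, 0.95), min_dbh = 3,
                                 rao_distance = "gower", quiet = FALSE) {
  validate_bundle(bundle)
  plots <- bundle$plots
  area <- plots$area_ha %||% rep(0.09, nrow(plots))
  if (is.null(plots$area_ha)) plots$area_ha <- area
  stems <- apply_stem_filter(bundle$stems, min_dbh, quiet = quiet)
  species <- impute_traits(bundle$species)

  pid <- plots$plot_id
  f <- factor(stems$plot_id, levels = pid)

  # tree carbon (all strategies count toward carbon)
  biom <- stem_biomass(stems$dbh, stems$height, coeffs)
  tree_kg <- vapply(split(biom, f), sum, numeric(1))
  tree_c <- tree_kg * 0.5 / 1000 / plots$area_ha

  # dominance on strategy-excluded stems
  dom <- plot_dominance(apply_strategy_exclusion(stems, species, quiet = quiet),
                        species)
  ecmd <- dom$ecmd[match(pid, dom$plot_id)]

  richness <- vapply(split(stems$species_id, f),
                     function(s) length(unique(s)), integer(1))

  # Rao's Q with basal-area weights; one pool-wide trait distance matrix
  # (Gower ranges taken over the full species pool).
  tm <- as.matrix(species[intersect(TRAIT_NAMES, names(species))])
  rownames(tm) <- species$species_id
  D <- switch(rao_distance,
              gower = as.matrix(cluster::daisy(as.data.frame(tm), metric = "gower")),
              euclidean = as.matrix(dist(scale(tm))))
  ba <- stem_basal_area(stems$dbh)
  ba_sp <- rowsum(ba, paste(stems$plot_id, stems$species_id, sep = "\r"))
  keys <- rownames(ba_sp)
  ba_df <- data.frame(plot_id = sub("\r.*$", "", keys),
                      species_id = sub("^.*\r", "", keys),
                      ba = ba_sp[, 1], stringsAsFactors = FALSE)
  raoq <- vapply(split(ba_df, factor(ba_df$plot_id, levels = pid)), function(d) {
    if (nrow(d) == 0) return(NA_real_)
    p <- d$ba / sum(d$ba)
    as.numeric(t(p) %*% D[d$species_id, d$species_id, drop = FALSE] %*% p)
  }, numeric(1))

  cs <- climate_score(plots$TS, plots$PS)

  soil_c <- plot_soil_carbon(bundle$soil, pid)
  forest_c <- ifelse(is.na(soil_c), NA_real_, tree_c + soil_c)

  suc <- if (quiet) {
    withCallingHandlers(succession_index(stems, species),
                        warning = function(w) {
                          if (grepl("zero similarity", conditionMessage(w)))
                            invokeRestart("muffleWarning")
                        })
  } else {
    succession_index(stems, species)
  }
  comp <- suc$comp_index[match(pid, suc$plot_id)]
  stage <- suc$stage[match(pid, suc$plot_id)]

  data.frame(plot_id = pid, ecoregion_id = plots$ecoregion_id,
             tree_c = tree_c, soil_c = soil_c, forest_c = forest_c,
             ecmd = ecmd, amd = 1 - ecmd, richness = richness, raoq = raoq,
             climate_score = cs$score, comp_index = comp, stage = stage,
             slope = plots$slope, altitude = plots$altitude,
             TS = plots$TS, PS = plots$PS, stringsAsFactors = FALSE)
}
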
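#' Soil organic carbon density of one depth layer
#'
#' \deqn{SOCD_i = (1 - V_i) B_i C_i T_i / 10}
#' with \eqn{V_i} the gravel (>2 mm) volume fraction in [0,1], \eqn{B_i}
#' bulk density (g/cm^3), \eqn{C_i} organic C content (g/kg), and
#' \eqn{T_i} thickness (cm); the /10 converts to Mg C/ha.
#'
#' @param V gravel volume fraction in [0, 1] (set \code{percent = TRUE}
#'   for inputs on the 0-100 scale).
#' @param B bulk density, g/cm^3 (> 0).
#' @param C organic carbon content, g/kg (>= 0).
#' @param T_ layer thickness, cm (> 0).
#' @param percent interpret V as a percentage and divide by 100.
#' @return layer carbon density in Mg C/ha.
#' @export
layer_socd <- function(V, B, C, T_, percent = FALSE) {
  if (percent) V <- V / 100
  if (any(V < 0 | V > 1)) stop("domain error: gravel fraction outside [0, 1]")
  if (any(B <= 0)) stop("domain error: bulk density must be positive")
  if (any(C < 0)) stop("domain error: organic C content must be non-negative")
  if (any(T_ <= 0)) stop("domain error: thickness must be positive")
  (1 - V) * B * C * T_ / 10
}

#' Soil organic carbon density of one plot
#'
#' Sums layer carbon densities over the layers actually sampled (up to five:
#' 0-10, 10-20, 20-30, 30-50, 50-100 cm); shallow profiles simply sum
#' fewer layers. Replicate rows for the same (plot, layer) are averaged
#' before summation. A plot with no layers is flagged missing (NA), never
#' silently zero.
#'
#' @param layers soil rows of one plot.
#' @param percent see \code{\link{layer_socd}}.
#' @return SOCD in Mg C/ha, or NA (with a warning) if no layers.
#' @export
plot_socd <- function(layers, percent = FALSE) {
  if (is.null(layers) || nrow(layers) == 0) {
    warning("no soil layers for plot: SOCD flagged missing")
    return(NA_real_)
  }
  if (anyDuplicated(layers$layer_index)) {
    layers <- aggregate(layers[c("gravel_frac", "bulk_density", "organic_c",
                                 "thickness")],
                        by = list(layer_index = layers$layer_index), FUN = mean)
  }
  sum(layer_socd(layers$gravel_frac, layers$bulk_density, layers$organic_c,
                 layers$thickness, percent = percent))
}

# Vectorized per-plot SOCD over a soil table for the given plot ids;
# plots without layers get NA (internal).
plot_soil_carbon <- function(soil, plot_ids, percent = FALSE) {
  out <- rep(NA_real_, length(plot_ids))
  if (is.null(soil) || nrow(soil) == 0) return(out)
  socd <- rowsum(layer_socd(soil$gravel_frac, soil$bulk_density,
                            soil$organic_c, soil$thickness, percent = percent),
                 soil$plot_id)
  m <- match(plot_ids, rownames(socd))
  out[!is.na(m)] <- socd[m[!is.na(m)], 1]
  out
}

#' Whole-forest carbon stock
#'
#' Sum of tree and soil carbon stocks; missing components propagate to a
#' missing forest stock (plots without soil sampling are excluded from
#' soil- and forest-carbon analyses rather than imputed).
#'
#' @param tree_c,soil_c stocks in Mg C/ha (may be NA).
#' @return forest carbon in Mg C/ha, NA where either component is missing.
#' @export
forest_carbon <- function(tree_c, soil_c) {
  ifelse(is.na(tree_c) | is.na(soil_c), NA_real_, tree_c + soil_c)
}

#' Natural log of a carbon stock
#'
#' Log-transform used for all stock responses; non-positive values are
#' returned as NA with a warning giving the excluded count, so such plots
#' drop out of log-scale models.
#'
#' @param x stocks (Mg C/ha).
#' @return ln(x), NA where x is missing or non-positive.
#' @export
ln_stock <- function(x) {
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive stock value(s) excluded from log scale",
                    sum(bad)))
  }
  out <- ifelse(is.na(x) | x <= 0, NA_real_, x)
  log(out)
}
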
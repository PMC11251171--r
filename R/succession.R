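#' Importance values of species within plots
#'
#' For each plot, a species' importance value (IV) is the mean of its
#' relative density (stem-count share), relative cover (measured canopy
#' cover share when a \code{cover} column is present, otherwise basal-area
#' share as proxy), and relative frequency (share of the nine subplots
#' occupied, normalized across species to sum to one). IVs sum to one
#' within a plot.
#'
#' @param stems stems table with plot_id, subplot, species_id, dbh, and
#'   optionally cover.
#' @return data.frame with plot_id, species_id, rel_density, rel_cover,
#'   rel_frequency, iv.
#' @export
importance_values <- function(stems) {
  if (nrow(stems) == 0) {
    return(data.frame(plot_id = character(), species_id = character(),
                      rel_density = numeric(), rel_cover = numeric(),
                      rel_frequency = numeric(), iv = numeric()))
  }
  cover <- if ("cover" %in% names(stems)) stems$cover else stem_basal_area(stems$dbh)
  key <- paste(stems$plot_id, stems$species_id, sep = "\r")
  cnt <- rowsum(rep(1, nrow(stems)), key)
  cov <- rowsum(cover, key)
  # subplot occupancy per (plot, species)
  u <- !duplicated(paste(key, stems$subplot, sep = "\r"))
  frq_m <- rowsum(rep(1, sum(u)), key[u])
  keys <- rownames(cnt)
  frq <- frq_m[match(keys, rownames(frq_m)), 1]
  kp <- sub("\r.*$", "", keys)
  tot_n <- rowsum(cnt[, 1], kp); tot_c <- rowsum(cov[, 1], kp)
  tot_f <- rowsum(frq, kp)
  i <- match(kp, rownames(tot_n))
  out <- data.frame(plot_id = kp, species_id = sub("^.*\r", "", keys),
                    rel_density = cnt[, 1] / tot_n[i, 1],
                    rel_cover = cov[, 1] / tot_c[i, 1],
                    rel_frequency = frq / tot_f[i, 1],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$iv <- (out$rel_density + out$rel_cover + out$rel_frequency) / 3
  out
}

# Plot-wise IV profile matrix: species x plots (internal).
iv_profile_matrix <- function(iv_rows) {
  sp <- sort(unique(iv_rows$species_id))
  pl <- sort(unique(iv_rows$plot_id))
  m <- matrix(0, length(sp), length(pl), dimnames = list(sp, pl))
  m[cbind(match(iv_rows$species_id, sp), match(iv_rows$plot_id, pl))] <- iv_rows$iv
  m
}

#' Czekanowski similarity between a species and a species group
#'
#' Percentage similarity between the species' plot-wise IV profile a and
#' the group's aggregated (summed over members) plot-wise IV profile b:
#' \eqn{2 \sum_k \min(a_k, b_k) / (\sum_k a_k + \sum_k b_k)}. Equal
#' profiles give 1; profiles with disjoint plot occupancy give 0.
#'
#' @param species_id the focal species.
#' @param group character vector of group member species ids (non-empty).
#' @param iv_rows output of \code{\link{importance_values}} over all plots.
#' @return similarity in [0, 1].
#' @export
group_similarity <- function(species_id, group, iv_rows) {
  if (length(group) == 0) stop("configuration error: empty species group")
  m <- iv_profile_matrix(iv_rows)
  a <- if (species_id %in% rownames(m)) m[species_id, ] else
    stop(sprintf("species %s has no IV records", species_id))
  b <- colSums(m[intersect(group, rownames(m)), , drop = FALSE])
  czekanowski(a, b)
}

czekanowski <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(0)
  2 * sum(pmin(a, b)) / s
}

#' Climax adaptation value from group similarities
#'
#' Interpolates a species' position on the 1 (pioneer) to 10 (climax)
#' seral scale from its similarity to the designated pioneer and climax
#' groups: \eqn{(10 s_{climax} + s_{pioneer}) / (s_{climax} + s_{pioneer})}.
#' A species similar only to the climax group scores 10; similar only to
#' the pioneer group, 1.
#'
#' @param sim_climax,sim_pioneer similarities in [0, 1].
#' @param fallback value assigned (with a warning) when both similarities
#'   are zero; set NULL to error instead.
#' @return CAV in [1, 10].
#' @export
climax_adaptation_value <- function(sim_climax, sim_pioneer, fallback = 5.5) {
  if (any(sim_climax < 0 | sim_pioneer < 0)) {
    stop("domain error: similarities must be non-negative")
  }
  denom <- sim_climax + sim_pioneer
  out <- ifelse(denom > 0, (10 * sim_climax + sim_pioneer) / denom, NA_real_)
  if (any(is.na(out) & !is.na(denom))) {
    if (is.null(fallback)) {
      stop("unassignable-CAV error: zero similarity to both groups")
    }
    warning(sprintf("%d species with zero similarity to both groups assigned CAV %.2f",
                    sum(is.na(out)), fallback))
    out[is.na(out)] <- fallback
  }
  out
}

#' Climax adaptation values for a species pool
#'
#' Designated pioneers (seral_status "pioneer") receive CAV 1 and designated
#' climax species 10; every other species is scored by similarity
#' interpolation against the two groups' aggregated IV profiles.
#'
#' @param iv_rows output of \code{\link{importance_values}}.
#' @param species species table with seral_status.
#' @param fallback see \code{\link{climax_adaptation_value}}.
#' @return data.frame species_id, sim_climax, sim_pioneer, cav.
#' @export
cav_table <- function(iv_rows, species, fallback = 5.5) {
  pioneers <- species$species_id[species$seral_status == "pioneer"]
  climaxes <- species$species_id[species$seral_status == "climax"]
  m <- iv_profile_matrix(iv_rows)
  sp <- rownames(m)
  b_pi <- colSums(m[intersect(pioneers, sp), , drop = FALSE])
  b_cl <- colSums(m[intersect(climaxes, sp), , drop = FALSE])
  sim_cl <- apply(m, 1, czekanowski, b = b_cl)
  sim_pi <- apply(m, 1, czekanowski, b = b_pi)
  cav <- climax_adaptation_value(sim_cl, sim_pi, fallback = fallback)
  cav[sp %in% pioneers] <- 1
  cav[sp %in% climaxes] <- 10
  data.frame(species_id = sp, sim_climax = sim_cl, sim_pioneer = sim_pi,
             cav = cav, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compositional index of each plot
#'
#' Sum over species of IV times CAV; because IVs sum to one within a plot,
#' the index is a convex combination of the CAVs present and lies in
#' [1, 10], with low values indicating pioneer-dominated (early) and high
#' values climax-dominated (late) communities.
#'
#' @param iv_rows output of \code{\link{importance_values}}.
#' @param cavs output of \code{\link{cav_table}} (species_id, cav).
#' @return data.frame plot_id, comp_index.
#' @export
compositional_index <- function(iv_rows, cavs) {
  cav <- cavs$cav[match(iv_rows$species_id, cavs$species_id)]
  if (anyNA(cav)) {
    stop(sprintf("species lacking CAV: %s",
                 paste(unique(iv_rows$species_id[is.na(cav)]), collapse = ", ")))
  }
  agg <- rowsum(iv_rows$iv * cav, iv_rows$plot_id)
  data.frame(plot_id = rownames(agg), comp_index = agg[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign successional stages from compositional indices
#'
#' Sorts plots by compositional index ascending (ties broken by plot_id
#' for determinism) and cuts the ordering into three equal-count tertiles:
#' early, middle, late.
#'
#' @param comp data.frame with plot_id, comp_index (>= 3 plots).
#' @return input with added rank and stage columns.
#' @export
assign_stages <- function(comp) {
  if (nrow(comp) < 3) stop("staging error: need at least 3 plots")
  ord <- order(comp$comp_index, comp$plot_id)
  rank <- integer(nrow(comp)); rank[ord] <- seq_len(nrow(comp))
  cut3 <- ceiling(3 * rank / nrow(comp))
  comp$rank <- rank
  comp$stage <- factor(c("early", "middle", "late")[cut3],
                       levels = c("early", "middle", "late"))
  comp
}

#' Compositional succession index and stages for a dataset
#'
#' Convenience wrapper chaining importance values, CAVs, the compositional
#' index, and tertile stage assignment.
#'
#' @param stems stems table (all plots).
#' @param species species table with seral_status.
#' @param fallback see \code{\link{climax_adaptation_value}}.
#' @return data.frame plot_id, comp_index, rank, stage; the CAV table is
#'   attached as attribute "cav".
#' @export
succession_index <- function(stems, species, fallback = 5.5) {
  iv <- importance_values(stems)
  cavs <- cav_table(iv, species, fallback = fallback)
  out <- assign_stages(compositional_index(iv, cavs))
  attr(out, "cav") <- cavs
  out
}
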
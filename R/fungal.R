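#' Remove low-abundance OTUs
#'
#' Drops OTUs whose total count across all plots is at or below the
#' threshold (default 10 sequences), the usual guard against PCR and
#' sequencing artifacts. Idempotent.
#'
#' @param counts OTU-by-plot integer matrix (rownames = OTU ids).
#' @param threshold OTUs with total <= threshold are removed.
#' @return filtered count matrix.
#' @export
filter_low_abundance <- function(counts, threshold = 10) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  counts[rowSums(counts) > threshold, , drop = FALSE]
}

#' Relative abundance of a fungal guild in one plot
#'
#' @param counts OTU-by-plot count matrix.
#' @param guild character vector of guild labels per OTU ("EcM", "SAP",
#'   "other").
#' @param plot_id column to summarize.
#' @param which guild to report.
#' @return guild share of the plot's total counts; NA with a warning for a
#'   zero-total plot.
#' @export
guild_relative_abundance <- function(counts, guild, plot_id,
                                     which = c("EcM", "SAP", "other")) {
  which <- match.arg(which)
  v <- counts[, plot_id]
  tot <- sum(v)
  if (tot == 0) {
    warning(sprintf("plot %s has zero total fungal counts", plot_id))
    return(NA_real_)
  }
  sum(v[guild == which]) / tot
}

#' Shannon diversity of a count vector
#'
#' \eqn{H = -\sum p_i \ln p_i} over entries with positive counts (natural
#' log). All-zero vectors are undefined and return NA.
#'
#' @param counts non-negative counts.
#' @param base logarithm base (natural by default).
#' @return Shannon index H.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(NA_real_)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Per-plot fungal community summaries
#'
#' Applies the low-abundance filter, then computes per plot: EcM and SAP
#' guild relative abundances and Shannon diversity for all fungi, EcM
#' fungi, and SAP fungi.
#'
#' @param counts OTU-by-plot count matrix.
#' @param guild guild labels per OTU.
#' @param threshold low-abundance threshold.
#' @return data.frame keyed by plot_id with ecm_abundance, sap_abundance,
#'   shannon_all, shannon_ecm, shannon_sap.
#' @export
fungal_summary <- function(counts, guild, threshold = 10) {
  counts <- as.matrix(counts)
  stopifnot(length(guild) == nrow(counts))
  keep <- rowSums(counts) > threshold
  counts <- counts[keep, , drop = FALSE]
  guild <- guild[keep]
  out <- data.frame(
    plot_id = colnames(counts),
    ecm_abundance = apply(counts, 2, function(v)
      if (sum(v) == 0) NA_real_ else sum(v[guild == "EcM"]) / sum(v)),
    sap_abundance = apply(counts, 2, function(v)
      if (sum(v) == 0) NA_real_ else sum(v[guild == "SAP"]) / sum(v)),
    shannon_all = apply(counts, 2, shannon_index),
    shannon_ecm = apply(counts[guild == "EcM", , drop = FALSE], 2, shannon_index),
    shannon_sap = apply(counts[guild == "SAP", , drop = FALSE], 2, shannon_index),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Regress fungal summaries on EcM tree dominance
#'
#' Ordinary least squares of each fungal community summary (guild relative
#' abundances and Shannon diversities) on the plots' EcM tree dominance.
#'
#' @param metrics plot metrics table (plot_id, ecmd).
#' @param summaries output of \code{\link{fungal_summary}}.
#' @return data.frame response, slope, se, p, r_squared, n.
#' @export
guild_vs_dominance <- function(metrics, summaries) {
  d <- merge(metrics[c("plot_id", "ecmd")], summaries, by = "plot_id")
  resp <- setdiff(names(summaries), "plot_id")
  out <- lapply(resp, function(r) {
    ok <- is.finite(d$ecmd) & is.finite(d[[r]])
    if (sum(ok) < 3) stop(sprintf("fewer than 3 plots for response %s", r))
    if (sd(d$ecmd[ok]) == 0) stop("degenerate predictor: EcMD constant")
    fit <- lm(d[[r]][ok] ~ d$ecmd[ok])
    s <- summary(fit)
    data.frame(response = r, slope = coef(fit)[2], se = s$coefficients[2, 2],
               p = s$coefficients[2, 4], r_squared = s$r.squared, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
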
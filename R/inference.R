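#' Boundary transform for proportions
#'
#' Shrinks a proportion off the [0, 1] boundary:
#' \eqn{y' = (y (N-1) + 0.5)/N} with N the sample size, so plots consisting
#' only of AM or only of EcM trees remain usable in models of transformed
#' dominance. The map is affine and monotone with fixed point 0.5, and never
#' returns 0 or 1 for finite N.
#'
#' @param y proportions in [0, 1].
#' @param N sample size (>= 1), typically the number of plots entering the
#'   model.
#' @return transformed proportions strictly inside (0, 1).
#' @export
boundary_transform <- function(y, N) {
  if (any(!is.na(y) & (y < 0 | y > 1))) stop("domain error: y outside [0, 1]")
  if (N < 1) stop("domain error: N must be >= 1")
  (y * (N - 1) + 0.5) / N
}

#' Inverse of the boundary transform
#' @param yt transformed proportions.
#' @param N sample size used in the forward transform.
#' @return original proportions.
#' @export
boundary_transform_inv <- function(yt, N) {
  (yt * N - 0.5) / (N - 1)
}

#' Simple linear regression with confidence band
#'
#' Ordinary least squares of y on x with the slope test and a pointwise
#' 95\% confidence band, as used for the bivariate dominance-versus-stock
#' relationships.
#'
#' @param x,y numeric vectors (>= 3 complete pairs; x non-constant).
#' @param level confidence level.
#' @return list with slope, intercept, p (slope test), r_squared,
#'   \code{band} (data.frame x, fit, lwr, upr on a grid), and the lm fit.
#' @export
fit_simple_regression <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (sd(x) == 0) stop("degenerate-fit error: zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  grid <- data.frame(x = seq(min(x), max(x), length.out = 100))
  ci <- predict(fit, grid, interval = "confidence", level = level)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p = sm$coefficients[2, 4], r_squared = sm$r.squared,
       band = cbind(grid, as.data.frame(ci)), fit = fit)
}

# Continuous moderator/covariate z-scoring helper.
zscore <- function(x) as.numeric(scale(x))

#' Prepare plot metrics for the mixed-effects models
#'
#' Restricts to complete cases for the chosen stock, log-transforms the
#' response, applies the boundary transform to EcM dominance (N defaulting
#' to the number of plots entering the model), and z-scores the continuous
#' moderators (richness, climate score, slope, altitude). Stage enters as a
#' factor with "early" as reference.
#'
#' @param metrics output of \code{\link{compute_plot_metrics}}.
#' @param response one of "tree_c", "soil_c", "forest_c".
#' @param transform_n sample size for the boundary transform (default:
#'   plots entering this model).
#' @return data.frame with ln_y, ecmd_t, richness_z, climate_z, slope_z,
#'   altitude_z, stage, ecoregion_id (+ plot_id); sds recorded in
#'   attribute "scales".
#' @export
prepare_model_data <- function(metrics,
                               response = c("tree_c", "soil_c", "forest_c"),
                               transform_n = NULL) {
  response <- match.arg(response)
  y <- metrics[[response]]
  keep <- !is.na(y) & y > 0 & !is.na(metrics$ecmd) &
    complete.cases(metrics[c("richness", "climate_score", "slope",
                             "altitude", "stage")])
  d <- metrics[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 10) stop("too few complete plots for model fitting")
  N <- transform_n %||% n
  out <- data.frame(
    plot_id = d$plot_id,
    ln_y = log(d[[response]]),
    ecmd_t = boundary_transform(d$ecmd, N),
    richness_z = zscore(d$richness),
    climate_z = zscore(d$climate_score),
    slope_z = zscore(d$slope),
    altitude_z = zscore(d$altitude),
    stage = factor(as.character(d$stage), levels = c("early", "middle", "late")),
    ecoregion_id = d$ecoregion_id,
    stringsAsFactors = FALSE)
  attr(out, "scales") <- c(sd_y = sd(out$ln_y), transform_n = N)
  out
}

MODEL_RHS <- paste(
  "ecmd_t + richness_z + climate_z + slope_z + altitude_z + stage",
  "+ ecmd_t:richness_z + ecmd_t:climate_z + ecmd_t:stage")

#' Mixed-effects model of a log carbon stock
#'
#' Fits ln(stock) on transformed EcM dominance, z-scored richness, climate
#' score, slope and altitude, successional stage (early reference), the
#' EcMD-by-richness, EcMD-by-climate and EcMD-by-stage interactions, and an
#' ecoregion random intercept. The dominance term is kept on its
#' transformed (0, 1) scale so its coefficient is directly the effect of
#' moving from pure-AM to pure-EcM stands; standardized estimates
#' (estimate times sd(x)/sd(response)) are reported alongside. A singular
#' random-effects fit triggers a flagged fixed-effects-only fallback.
#'
#' @param metrics plot metrics table, or a prepared data.frame from
#'   \code{\link{prepare_model_data}}.
#' @param response one of "tree_c", "soil_c", "forest_c".
#' @param interactions include the two-way interactions (default TRUE).
#' @param transform_n see \code{\link{prepare_model_data}}.
#' @return object of class \code{myco_lmm}: a list with \code{model},
#'   \code{coefficients} (term, estimate, se, statistic, df, p, std_estimate),
#'   \code{vif}, \code{AIC}, \code{r2_marginal}, \code{r2_conditional},
#'   \code{sigma_ecoregion}, \code{fallback_ols}, \code{data}.
#' @export
fit_mixed_model <- function(metrics, response = c("tree_c", "soil_c", "forest_c"),
                            interactions = TRUE, transform_n = NULL) {
  response <- match.arg(response)
  d <- if (!is.null(metrics$ln_y)) metrics else
    prepare_model_data(metrics, response, transform_n)
  rhs <- if (interactions) MODEL_RHS else
    "ecmd_t + richness_z + climate_z + slope_z + altitude_z + stage"
  if (length(unique(d$ecoregion_id)) < 2) {
    stop("need >= 2 ecoregions for the random intercept")
  }
  form <- as.formula(paste("ln_y ~", rhs, "+ (1 | ecoregion_id)"))
  fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
  fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular random-effects fit; falling back to fixed-effects OLS")
    fallback <- TRUE
    fit <- lm(as.formula(paste("ln_y ~", rhs)), data = d)
  }
  co <- if (fallback) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               statistic = s[, 3], df = fit$df.residual, p = s[, 4],
               stringsAsFactors = FALSE)
  } else {
    s <- coef(summary(fit))
    data.frame(term = rownames(s), estimate = s[, "Estimate"],
               se = s[, "Std. Error"], statistic = s[, "t value"],
               df = s[, "df"], p = s[, "Pr(>|t|)"], stringsAsFactors = FALSE)
  }
  rownames(co) <- NULL
  X <- model.matrix(as.formula(paste("~", rhs)), d)
  sd_y <- sd(d$ln_y)
  sdx <- apply(X, 2, sd)
  is_dummy <- grepl("^stage", colnames(X)) & !grepl(":", colnames(X))
  std <- co$estimate * ifelse(is_dummy[match(co$term, colnames(X))], 1,
                              sdx[match(co$term, colnames(X))]) / sd_y
  std[co$term == "(Intercept)"] <- NA_real_
  co$std_estimate <- std

  v <- vif(X[, colnames(X) != "(Intercept)", drop = FALSE])
  if (fallback) {
    sig_u <- 0
    var_e <- sum(resid(fit)^2) / fit$df.residual
  } else {
    vc <- as.data.frame(lme4::VarCorr(fit))
    sig_u <- vc$sdcor[vc$grp == "ecoregion_id"]
    var_e <- vc$vcov[vc$grp == "Residual"]
  }
  var_f <- var(as.numeric(X %*% co$estimate))
  out <- list(model = fit, coefficients = co, vif = v, AIC = AIC(fit),
              r2_marginal = var_f / (var_f + sig_u^2 + var_e),
              r2_conditional = (var_f + sig_u^2) / (var_f + sig_u^2 + var_e),
              sigma_ecoregion = sig_u, fallback_ols = fallback,
              response = response, data = d)
  class(out) <- "myco_lmm"
  out
}

#' @export
print.myco_lmm <- function(x, ...) {
  cat(sprintf("Mixed-effects model of ln(%s) (%s)\n", x$response,
              if (x$fallback_ols) "OLS fallback, singular random effect"
              else "ecoregion random intercept"))
  cat(sprintf("AIC %.1f | R2 marginal %.3f, conditional %.3f | sd(ecoregion) %.3f\n",
              x$AIC, x$r2_marginal, x$r2_conditional, x$sigma_ecoregion))
  df <- x$coefficients[c("term", "estimate", "se", "p", "std_estimate")]
  df[-1] <- round(df[-1], 4)
  print(df)
  invisible(x)
}

#' Wald confidence interval for a model term
#' @param fit a \code{myco_lmm}.
#' @param term term name (default the EcM dominance main effect).
#' @param level confidence level.
#' @return numeric c(lower, upper).
#' @export
term_ci <- function(fit, term = "ecmd_t", level = 0.95) {
  co <- fit$coefficients
  i <- match(term, co$term)
  if (is.na(i)) stop(sprintf("term %s not in model", term))
  q <- qt(1 - (1 - level) / 2, df = max(co$df[i], 1))
  co$estimate[i] + c(-1, 1) * q * co$se[i]
}

#' Simple slopes of EcM dominance at moderator levels
#'
#' Evaluates the slope of the transformed EcM dominance at chosen levels of
#' a moderator: tertile midpoints (16.7/50/83.3 percentiles) for continuous
#' moderators, the three stages for succession. Standard errors come from
#' the coefficient covariance matrix.
#'
#' @param fit a \code{myco_lmm} fitted with interactions.
#' @param moderator "richness", "climate", or "stage".
#' @param levels optional numeric levels (continuous moderators, on the
#'   z-scored scale).
#' @return data.frame level, slope, se, z, p.
#' @export
interaction_slopes <- function(fit, moderator = c("richness", "climate", "stage"),
                               levels = NULL) {
  moderator <- match.arg(moderator)
  co <- fit$coefficients
  V <- as.matrix(vcov(fit$model))
  b <- setNames(co$estimate, co$term)
  i0 <- match("ecmd_t", co$term)
  if (moderator == "stage") {
    terms_int <- c("ecmd_t:stagemiddle", "ecmd_t:stagelate")
    if (!all(terms_int %in% co$term)) stop("specification error: stage interaction absent")
    lev <- c("early", "middle", "late")
    out <- lapply(seq_along(lev), function(k) {
      w <- rep(0, nrow(co)); w[i0] <- 1
      if (k > 1) w[match(terms_int[k - 1], co$term)] <- 1
      est <- sum(w * co$estimate)
      se <- sqrt(drop(t(w) %*% V %*% w))
      data.frame(level = lev[k], slope = est, se = se, z = est / se,
                 p = 2 * pnorm(-abs(est / se)))
    })
    return(do.call(rbind, out))
  }
  term_int <- paste0("ecmd_t:", moderator, "_z")
  ii <- match(term_int, co$term)
  if (is.na(ii)) stop("specification error: interaction term absent from model")
  if (is.null(levels)) {
    m <- fit$data[[paste0(moderator, "_z")]]
    levels <- unname(quantile(m, c(1 / 6, 1 / 2, 5 / 6)))
  }
  out <- lapply(levels, function(m) {
    w <- rep(0, nrow(co)); w[i0] <- 1; w[ii] <- m
    est <- sum(w * co$estimate)
    se <- sqrt(drop(t(w) %*% V %*% w))
    data.frame(level = m, slope = est, se = se, z = est / se,
               p = 2 * pnorm(-abs(est / se)))
  })
  do.call(rbind, out)
}

#' Variance inflation factors of a design matrix
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} from regressing column j on the remaining
#' columns. Aliased (perfectly collinear) columns are reported as Inf.
#'
#' @param X numeric design matrix (no intercept column).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(setNames(rep(1, ncol(X)), colnames(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

#' Random-forest screening of carbon-stock drivers
#'
#' Permutation-importance ranking of the candidate drivers (EcM dominance,
#' richness, stage, climate score, slope, altitude) for a log stock,
#' averaged over replicate forests grown from different seeds.
#'
#' @param metrics plot metrics table.
#' @param response one of "tree_c", "soil_c", "forest_c".
#' @param n_rep replicate forests.
#' @param n_tree trees per forest.
#' @param seed integer seed.
#' @return data.frame predictor, importance (mean \%IncMSE), rank.
#' @export
driver_importance <- function(metrics, response = c("tree_c", "soil_c", "forest_c"),
                              n_rep = 5, n_tree = 500, seed = 1L) {
  response <- match.arg(response)
  d <- metrics[c(response, "ecmd", "richness", "stage", "climate_score",
                 "slope", "altitude")]
  d <- d[complete.cases(d) & d[[response]] > 0, ]
  if (nrow(d) < 50) warning("fewer than 50 complete plots: importances unstable")
  y <- log(d[[response]])
  X <- d[-1]
  X$stage <- factor(as.character(X$stage), levels = c("early", "middle", "late"))
  imp <- with_seed(seed, {
    reps <- lapply(seq_len(n_rep), function(r) {
      rf <- randomForest::randomForest(X, y, ntree = n_tree, importance = TRUE)
      randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    })
    Reduce(`+`, reps) / n_rep
  })
  out <- data.frame(predictor = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Ecoregion-stratified 50\% subsampling bootstrap
#'
#' Repeatedly draws floor(fraction * n_e) plots without replacement from
#' each ecoregion e, refits the mixed model, and summarizes the replicate
#' estimates: per-term sign consistency with the full-data fit and
#' 2.5/50/97.5\% quantiles. Stratifying by ecoregion keeps unevenly
#' surveyed regions represented in every replicate.
#'
#' @param metrics plot metrics table.
#' @param response one of "tree_c", "soil_c", "forest_c".
#' @param fraction per-ecoregion sampling fraction (default 0.5).
#' @param B number of replicates.
#' @param seed integer seed.
#' @param interactions passed to \code{\link{fit_mixed_model}}.
#' @return list with \code{summary} (term, full_estimate, sign_consistency,
#'   q2.5, q50, q97.5), \code{replicates} (B x terms estimate matrix), and
#'   \code{n_per_replicate}.
#' @export
ecoregion_subsample <- function(metrics, response = c("tree_c", "soil_c", "forest_c"),
                                fraction = 0.5, B = 200, seed = 1L,
                                interactions = TRUE) {
  response <- match.arg(response)
  full <- fit_mixed_model(metrics, response, interactions = interactions)
  d0 <- full$data
  counts <- table(d0$ecoregion_id)
  if (any(counts < 2)) stop("stratification error: an ecoregion has < 2 plots")
  idx_by_eco <- split(seq_len(nrow(d0)), d0$ecoregion_id)
  take <- pmax(1L, floor(fraction * lengths(idx_by_eco)))
  est <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- unlist(mapply(function(ix, k) {
        if (k >= length(ix)) ix else sample(ix, k)
      }, idx_by_eco, take, SIMPLIFY = FALSE))
      fb <- suppressWarnings(
        fit_mixed_model(d0[idx, , drop = FALSE], response,
                        interactions = interactions))
      setNames(fb$coefficients$estimate, fb$coefficients$term)[
        full$coefficients$term]
    }, numeric(nrow(full$coefficients))))
  })
  qs <- t(apply(est, 2, quantile, c(0.025, 0.5, 0.975), na.rm = TRUE))
  sgn <- colMeans(sweep(sign(est), 2, sign(full$coefficients$estimate), `==`),
                  na.rm = TRUE)
  list(summary = data.frame(term = full$coefficients$term,
                            full_estimate = full$coefficients$estimate,
                            sign_consistency = unname(sgn),
                            q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
                            row.names = NULL, stringsAsFactors = FALSE),
       replicates = est,
       n_per_replicate = sum(pmin(take, lengths(idx_by_eco))))
}
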
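#' Construct a directed acyclic graph for piecewise SEM
#'
#' @param nodes character vector of variable names.
#' @param edges data.frame with columns \code{from}, \code{to}.
#' @return object of class \code{myco_dag}; errors on cycles, self-loops,
#'   or edges naming unknown nodes.
#' @export
dag <- function(nodes, edges) {
  stopifnot(is.character(nodes), is.data.frame(edges),
            all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoints must be declared nodes")
  }
  if (any(edges$from == edges$to)) stop("self-loops not allowed")
  if (anyDuplicated(paste(edges$from, edges$to))) stop("duplicate edges")
  g <- structure(list(nodes = nodes,
                      edges = data.frame(from = as.character(edges$from),
                                         to = as.character(edges$to),
                                         stringsAsFactors = FALSE)),
                 class = "myco_dag")
  if (is.null(topo_order(g))) stop("graph is cyclic: not a DAG")
  g
}

# Kahn topological sort; NULL if cyclic (internal).
topo_order <- function(g) {
  nodes <- g$nodes
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(g$edges$to)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  avail <- nodes[indeg == 0]
  edges <- g$edges
  while (length(avail)) {
    n <- avail[1]; avail <- avail[-1]
    order <- c(order, n)
    out <- edges$to[edges$from == n]
    edges <- edges[edges$from != n, , drop = FALSE]
    for (m in out) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) avail <- c(avail, m)
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

parents_of <- function(g, node) g$edges$from[g$edges$to == node]

#' @export
print.myco_dag <- function(x, ...) {
  cat(sprintf("DAG with %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

#' Default causal skeleton for the dominance-carbon system
#'
#' Nodes: climate (seasonality score), SUS (compositional succession
#' index), SR (log species richness), EcMD (transformed EcM dominance),
#' FD (Rao's Q functional diversity), lnC (log carbon stock). Climate,
#' succession, and richness drive both dominance and functional diversity;
#' dominance also drives functional diversity; and all five drive the
#' carbon stock.
#'
#' @return a \code{myco_dag}.
#' @export
default_dag <- function() {
  dag(nodes = c("climate", "SUS", "SR", "EcMD", "FD", "lnC"),
      edges = data.frame(
        from = c("climate", "SR", "SUS", "climate", "SUS", "SR", "EcMD",
                 "EcMD", "FD", "climate", "SUS", "SR"),
        to = c("EcMD", "EcMD", "EcMD", "FD", "FD", "FD", "FD",
               "lnC", "lnC", "lnC", "lnC", "lnC")))
}

#' Basis set of independence claims implied by a DAG
#'
#' Enumerates, once per non-adjacent node pair, the claim that the pair is
#' independent conditional on the union of both nodes' parents; the
#' causally later node (topological order) is the dependent variable of the
#' test, following the union-of-parents basis-set construction used in
#' tests of d-separation.
#'
#' @param g a \code{myco_dag}.
#' @return list of claims, each a list with \code{x} (independent
#'   variable), \code{y} (dependent, causally later), \code{cond}
#'   (conditioning set).
#' @export
basis_set <- function(g) {
  ord <- topo_order(g)
  if (is.null(ord)) stop("graph is cyclic")
  adj <- paste(g$edges$from, g$edges$to)
  claims <- list()
  n <- length(ord)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      a <- ord[i]; b <- ord[j]
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      cond <- setdiff(union(parents_of(g, a), parents_of(g, b)), c(a, b))
      claims[[length(claims) + 1L]] <- list(x = a, y = b, cond = cond)
    }
  }
  claims
}

#' Fisher's C statistic over independence-claim p-values
#'
#' \eqn{C = -2 \sum \ln p_i}, chi-square distributed with 2k degrees of
#' freedom under the model (k claims). An empty claim list (saturated
#' model) returns C = 0, df = 0, p = 1.
#'
#' @param p_values numeric p-values in (0, 1].
#' @return list with \code{C}, \code{df}, \code{p}.
#' @export
fisher_c <- function(p_values) {
  if (length(p_values) == 0) return(list(C = 0, df = 0L, p = 1))
  if (any(p_values <= 0 | p_values > 1)) {
    stop("domain error: p-values must lie in (0, 1]")
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

# Fit node ~ rhs (+ random intercept); returns coefficients table (internal).
fit_submodel <- function(dep, rhs, data, random) {
  if (length(rhs) == 0) return(NULL)
  f <- paste(dep, "~", paste(rhs, collapse = " + "))
  if (!is.null(random)) {
    fit <- suppressMessages(
      lmerTest::lmer(as.formula(paste(f, "+ (1 |", random, ")")), data = data))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      fit <- lm(as.formula(f), data = data)
    }
  } else {
    fit <- lm(as.formula(f), data = data)
  }
  s <- if (inherits(fit, "lm")) summary(fit)$coefficients else coef(summary(fit))
  list(fit = fit,
       coef = data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                         p = s[, ncol(s)], stringsAsFactors = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' One submodel per endogenous node (node on its parents, with an optional
#' group random intercept), standardized path coefficients (raw estimate
#' times sd(parent)/sd(child)), d-separation tests of every basis-set
#' claim (the claimed-independent variable added to the dependent node's
#' parent model), and global fit by Fisher's C.
#'
#' @param g a \code{myco_dag}.
#' @param data data.frame containing every node variable (and the random
#'   grouping column if used).
#' @param random name of the random-intercept grouping column (e.g.
#'   "ecoregion_id"), or NULL for ordinary least squares submodels.
#' @return object of class \code{myco_sem}: list with \code{paths}
#'   (from, to, estimate, std_estimate, se, p), \code{claims}
#'   (x, y, conditioning, p), \code{fisher_c}, \code{dag},
#'   \code{submodels}.
#' @export
fit_paths <- function(g, data, random = "ecoregion_id") {
  stopifnot(inherits(g, "myco_dag"))
  missing_vars <- setdiff(g$nodes, names(data))
  if (length(missing_vars)) {
    stop(sprintf("data lacks node variable(s): %s",
                 paste(missing_vars, collapse = ", ")))
  }
  if (!is.null(random) && !random %in% names(data)) {
    stop(sprintf("random grouping column '%s' absent", random))
  }
  if (!is.null(random) && length(unique(data[[random]])) < 2) random <- NULL
  endo <- unique(g$edges$to)
  sds <- vapply(data[g$nodes], sd, numeric(1))
  submodels <- list()
  paths <- list()
  for (node in endo) {
    pa <- parents_of(g, node)
    sm <- fit_submodel(node, pa, data, random)
    submodels[[node]] <- sm$fit
    co <- sm$coef[sm$coef$term %in% pa, , drop = FALSE]
    paths[[node]] <- data.frame(
      from = co$term, to = node, estimate = co$estimate,
      std_estimate = co$estimate * sds[co$term] / sds[node],
      se = co$se, p = co$p, stringsAsFactors = FALSE)
  }
  paths <- do.call(rbind, paths)
  rownames(paths) <- NULL

  claims <- basis_set(g)
  claim_rows <- lapply(claims, function(cl) {
    rhs <- c(cl$cond, cl$x)
    sm <- fit_submodel(cl$y, rhs, data, random)
    p <- sm$coef$p[sm$coef$term == cl$x]
    data.frame(x = cl$x, y = cl$y,
               conditioning = paste(cl$cond, collapse = ", "),
               p = p, stringsAsFactors = FALSE)
  })
  claims_df <- if (length(claim_rows)) do.call(rbind, claim_rows) else
    data.frame(x = character(), y = character(), conditioning = character(),
               p = numeric())
  fc <- fisher_c(claims_df$p)
  out <- list(paths = paths, claims = claims_df, fisher_c = fc, dag = g,
              submodels = submodels)
  class(out) <- "myco_sem"
  out
}

#' @export
print.myco_sem <- function(x, ...) {
  cat(sprintf("Piecewise SEM: %d paths, %d independence claims\n",
              nrow(x$paths), nrow(x$claims)))
  cat(sprintf("Fisher's C = %.3f, df = %d, p = %.3f %s\n",
              x$fisher_c$C, x$fisher_c$df, x$fisher_c$p,
              if (x$fisher_c$p > 0.05) "(no missing paths indicated)" else
                "(model misfit indicated)"))
  df <- x$paths
  df[3:6] <- round(df[3:6], 4)
  print(df)
  invisible(x)
}

#' Indirect effect along a causal route
#'
#' Product of the standardized path coefficients along a node sequence;
#' every consecutive pair must be an edge of the fitted model.
#'
#' @param pm a fitted \code{myco_sem}.
#' @param route character vector of nodes, cause first.
#' @return the signed product of standardized coefficients.
#' @export
indirect_effect <- function(pm, route) {
  if (length(route) < 2) stop("route needs at least two nodes")
  coefs <- numeric(length(route) - 1)
  for (i in seq_along(coefs)) {
    j <- which(pm$paths$from == route[i] & pm$paths$to == route[i + 1])
    if (length(j) != 1) {
      stop(sprintf("no fitted edge %s -> %s", route[i], route[i + 1]))
    }
    coefs[i] <- pm$paths$std_estimate[j]
  }
  prod(coefs)
}

#' SEM node variables from the plot metrics table
#'
#' Maps the metrics table to the SEM node set: climate = climate score,
#' SUS = compositional index, SR = log richness, EcMD = boundary-
#' transformed dominance, FD = Rao's Q, lnC = log of the chosen stock.
#' Complete cases only.
#'
#' @param metrics plot metrics table.
#' @param response one of "tree_c", "soil_c", "forest_c".
#' @param transform_n boundary-transform sample size (default: rows kept).
#' @return data.frame with the six node columns plus ecoregion_id.
#' @export
sem_data_from_metrics <- function(metrics,
                                  response = c("tree_c", "soil_c", "forest_c"),
                                  transform_n = NULL) {
  response <- match.arg(response)
  keep <- complete.cases(metrics[c(response, "ecmd", "richness", "raoq",
                                   "climate_score", "comp_index")]) &
    metrics[[response]] > 0
  d <- metrics[keep, , drop = FALSE]
  N <- transform_n %||% nrow(d)
  data.frame(climate = d$climate_score, SUS = d$comp_index,
             SR = log(d$richness), EcMD = boundary_transform(d$ecmd, N),
             FD = d$raoq, lnC = log(d[[response]]),
             ecoregion_id = d$ecoregion_id, stringsAsFactors = FALSE)
}

#' Simulate data from a linear-Gaussian DAG
#'
#' Draws exogenous nodes standard normal and each endogenous node as the
#' coefficient-weighted sum of its parents plus an optional ecoregion
#' random intercept and unit-variance Gaussian noise. Used to calibrate
#' the d-separation test: data generated from the fitted DAG should be
#' rejected at about the nominal rate.
#'
#' @param g a \code{myco_dag}.
#' @param coefs data.frame from, to, beta (defaults: 0.3 on every edge).
#' @param n rows to simulate.
#' @param sigma residual standard deviation of endogenous nodes.
#' @param n_ecoregions number of grouping levels (0 for none).
#' @param sigma_ecoregion random-intercept sd applied to endogenous nodes.
#' @param seed integer seed.
#' @return data.frame of node columns (+ ecoregion_id when grouped).
#' @export
simulate_dag_data <- function(g, coefs = NULL, n = 400, sigma = 1,
                              n_ecoregions = 0, sigma_ecoregion = 0,
                              seed = 1L) {
  if (is.null(coefs)) {
    coefs <- data.frame(g$edges, beta = 0.3)
  }
  with_seed(seed, {
    ord <- topo_order(g)
    d <- as.data.frame(setNames(rep(list(numeric(n)), length(ord)), ord))
    eco <- NULL
    if (n_ecoregions > 0) {
      eco <- sample(sprintf("eco%02d", seq_len(n_ecoregions)), n, replace = TRUE)
    }
    for (node in ord) {
      pa <- parents_of(g, node)
      if (length(pa) == 0) {
        d[[node]] <- rnorm(n)
      } else {
        mu <- rep(0, n)
        for (p in pa) {
          b <- coefs$beta[coefs$from == p & coefs$to == node]
          mu <- mu + b * d[[p]]
        }
        if (!is.null(eco) && sigma_ecoregion > 0) {
          u <- rnorm(n_ecoregions, 0, sigma_ecoregion)
          mu <- mu + u[as.integer(factor(eco))]
        }
        d[[node]] <- mu + rnorm(n, 0, sigma)
      }
    }
    if (!is.null(eco)) d$ecoregion_id <- eco
    d
  })
}
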
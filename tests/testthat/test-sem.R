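test_that("DAG construction enforces acyclicity and edge hygiene", {
  g <- default_dag()
  expect_s3_class(g, "myco_dag")
  expect_equal(length(g$nodes), 6)
  expect_equal(nrow(g$edges), 12)
  # adding a stock -> climate arrow closes a cycle
  expect_error(dag(g$nodes, rbind(g$edges,
                                  data.frame(from = "lnC", to = "climate"))),
               "cyclic")
  expect_error(dag(c("a", "b"), data.frame(from = "a", to = "a")), "self-loop")
  expect_error(dag(c("a", "b"), data.frame(from = "a", to = "z")),
               "declared nodes")
})

test_that("basis set enumerates non-adjacent pairs with parent conditioning", {
  chain <- dag(c("X", "Y", "Z"),
               data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]]$x, "X")
  expect_equal(bs[[1]]$y, "Z")
  expect_equal(bs[[1]]$cond, "Y")

  full <- dag(c("a", "b", "c"),
              data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  expect_length(basis_set(full), 0)

  # default skeleton minus EcMD -> FD: exactly the claims for the three
  # exogenous pairs plus (EcMD, FD | climate, SUS, SR)
  g <- default_dag()
  g2 <- dag(g$nodes, g$edges[!(g$edges$from == "EcMD" & g$edges$to == "FD"), ])
  bs2 <- basis_set(g2)
  expect_length(bs2, 4)
  claim <- Filter(function(cl) setequal(c(cl$x, cl$y), c("EcMD", "FD")), bs2)
  expect_length(claim, 1)
  expect_setequal(claim[[1]]$cond, c("climate", "SUS", "SR"))
  expect_equal(claim[[1]]$y, "FD")  # FD is causally later than EcMD
})

test_that("basis-set size equals node pairs minus edges on random DAGs", {
  set.seed(14)
  for (r in 1:50) {
    n <- sample(3:7, 1)
    g <- random_dag(n, p_edge = runif(1, 0.2, 0.8))
    expect_equal(length(basis_set(g)), choose(n, 2) - nrow(g$edges))
  }
})

test_that("Fisher's C combines p-values as -2 sum log p", {
  expect_equal(fisher_c(c(1, 1, 1))$C, 0)
  fc <- fisher_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * 2 * log(0.5), tolerance = 1e-10)
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  expect_equal(fc$df, 4)
  empty <- fisher_c(numeric(0))
  expect_equal(empty$C, 0)
  expect_equal(empty$df, 0)
  expect_equal(empty$p, 1)
  expect_error(fisher_c(c(0.5, 0)), "domain")
  # permutation invariant, monotone decreasing in each p
  p <- c(0.1, 0.4, 0.9)
  expect_equal(fisher_c(p)$C, fisher_c(rev(p))$C)
  expect_gt(fisher_c(c(0.05, 0.4, 0.9))$C, fisher_c(p)$C)
})

test_that("path fitting recovers coefficients and nulls cleanly", {
  g <- default_dag()
  coefs <- data.frame(g$edges,
                      beta = c(0.3, -0.2, 0.25, 0.2, 0.3, 0.4, -0.35,
                               0.3, -0.25, -0.2, 0.15, 0.1))
  # large-sample recovery: raw path estimates match the generating betas
  # (vanishing noise is avoided because it makes the mediator collinear
  # with its parents in the stock submodel)
  d <- simulate_dag_data(g, coefs, n = 30000, sigma = 0.5, seed = 5)
  pm <- fit_paths(g, d, random = NULL)
  est <- merge(pm$paths, coefs, by = c("from", "to"))
  expect_lt(max(abs(est$estimate - est$beta)), 0.03)

  # an edge kept in the model but generated with beta 0 estimates near 0
  coefs0 <- coefs
  coefs0$beta[coefs0$from == "EcMD" & coefs0$to == "FD"] <- 0
  d0 <- simulate_dag_data(g, coefs0, n = 4000, seed = 6)
  pm0 <- fit_paths(g, d0, random = NULL)
  e0 <- pm0$paths$estimate[pm0$paths$from == "EcMD" & pm0$paths$to == "FD"]
  expect_lt(abs(e0), 0.06)

  expect_error(fit_paths(g, d[setdiff(names(d), "FD")], random = NULL),
               "lacks node")
})

test_that("grouped path fits match OLS when group variance is zero", {
  g <- default_dag()
  d <- simulate_dag_data(g, n = 500, n_ecoregions = 8, sigma_ecoregion = 0,
                         seed = 9)
  pm_ols <- fit_paths(g, d, random = NULL)
  pm_lmm <- suppressWarnings(fit_paths(g, d, random = "ecoregion_id"))
  expect_equal(pm_lmm$paths$std_estimate, pm_ols$paths$std_estimate,
               tolerance = 1e-4)
})

test_that("indirect effects multiply standardized coefficients along routes", {
  g <- default_dag()
  d <- simulate_dag_data(g, n = 500, seed = 3)
  pm <- fit_paths(g, d, random = NULL)
  s <- pm$paths$std_estimate
  k1 <- which(pm$paths$from == "EcMD" & pm$paths$to == "FD")
  k2 <- which(pm$paths$from == "FD" & pm$paths$to == "lnC")
  expect_equal(indirect_effect(pm, c("EcMD", "FD", "lnC")), s[k1] * s[k2],
               tolerance = 1e-12)
  expect_equal(indirect_effect(pm, c("FD", "lnC")), s[k2])
  expect_error(indirect_effect(pm, c("lnC", "FD")), "no fitted edge")
})

test_that("SEM runs end-to-end on synthetic inventory metrics", {
  sim <- simulate_forest_data(sim_config(plots_per_ecoregion = 25, seed = 12))
  m <- compute_plot_metrics(sim, quiet = TRUE)
  d <- sem_data_from_metrics(m, "tree_c")
  expect_true(all(c("climate", "SUS", "SR", "EcMD", "FD", "lnC",
                    "ecoregion_id") %in% names(d)))
  pm <- suppressWarnings(fit_paths(default_dag(), d))
  expect_equal(nrow(pm$paths), 12)
  expect_equal(pm$fisher_c$df, 2 * nrow(pm$claims))
  # the generated EcMD effect on the stock shows up as a positive path
  expect_gt(pm$paths$estimate[pm$paths$from == "EcMD" & pm$paths$to == "lnC"], 0)
})

test_that("d-separation p-values are calibrated under the true DAG", {
  g <- default_dag()
  g2 <- dag(g$nodes, g$edges[!(g$edges$from == "EcMD" & g$edges$to == "FD"), ])
  set.seed(2)
  p <- vapply(1:200, function(r) {
    d <- simulate_dag_data(g2, n = 150, seed = 1000 + r)
    pm <- fit_paths(g2, d, random = NULL)
    pm$fisher_c$p
  }, numeric(1))
  # uniform global-fit p-values: rejection near the nominal rate
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
})
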
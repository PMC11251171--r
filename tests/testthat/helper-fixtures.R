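# Small in-code fixtures shared across tests.

# A hand-built four-species bundle with two plots.
tiny_species <- function() {
  data.frame(
    species_id = c("spA", "spB", "spC", "spD"),
    strategy = c("EcM", "AM", "dual", "other"),
    seral_status = c("pioneer", "climax", "neither", "neither"),
    Cmass = c(450, 480, 460, 470), Nmass = c(18, 25, 21, 20),
    Pmass = c(1.2, 1.9, 1.5, 1.6), Kmass = c(7, 9, 8, 8.5),
    LA = c(1500, 3000, 2200, 2000), SLA = c(12, 18, 15, 14),
    LMA = c(0.083, 0.056, 0.067, 0.071), LDMC = c(330, 270, 300, 310),
    stringsAsFactors = FALSE)
}

tiny_bundle <- function() {
  plots <- data.frame(
    plot_id = c("p1", "p2"), ecoregion_id = c("e1", "e2"),
    slope = c(5, 12), altitude = c(400, 700),
    TS = c(12000, 14000), PS = c(70, 90), area_ha = 0.09,
    stringsAsFactors = FALSE)
  stems <- data.frame(
    plot_id = c("p1", "p1", "p1", "p2", "p2"),
    subplot = c(1L, 2L, 2L, 5L, 9L),
    species_id = c("spA", "spB", "spC", "spA", "spB"),
    dbh = c(10, 20, 15, 8, 30), height = c(8, 15, 12, 6, 20),
    stringsAsFactors = FALSE)
  soil <- data.frame(
    plot_id = rep("p1", 5), layer_index = 1:5,
    top_cm = c(0, 10, 20, 30, 50), bottom_cm = c(10, 20, 30, 50, 100),
    gravel_frac = rep(0.1, 5), bulk_density = rep(1.3, 5),
    organic_c = c(30, 20, 15, 10, 5), thickness = c(10, 10, 10, 20, 50),
    stringsAsFactors = FALSE)
  list(plots = plots, stems = stems, soil = soil, species = tiny_species())
}

# Independent Gower distance for the Rao's Q oracle: range-normalized
# mean absolute difference over trait columns.
gower_oracle <- function(tm) {
  tm <- as.matrix(tm)
  n <- nrow(tm)
  rng <- apply(tm, 2, function(v) diff(range(v)))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    contrib <- abs(tm[i, ] - tm[j, ]) / rng
    d[i, j] <- mean(contrib[rng > 0])
  }
  dimnames(d) <- list(rownames(tm), rownames(tm))
  d
}

# Brute-force Rao's Q double loop.
rao_oracle <- function(p, d) {
  q <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) q <- q + p[i] * p[j] * d[i, j]
  unname(q)
}

# Random DAG on n nodes: each forward edge (under a random order) kept
# with probability p_edge.
random_dag <- function(n, p_edge = 0.4) {
  nodes <- paste0("n", seq_len(n))
  ord <- sample(nodes)
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (runif(1) < p_edge) { from <- c(from, ord[i]); to <- c(to, ord[j]) }
  }
  if (!length(from)) { from <- ord[1]; to <- ord[2] }  # keep >= 1 edge
  dag(nodes, data.frame(from = from, to = to))
}
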
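# Independent brute-force oracles used to cross-check the package
# implementations. These are deliberately written as plain loops over the
# definitions, not via the code paths they verify.

# Spearman's coefficient as rank-then-Pearson, with explicit sums
rank_pearson_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Davies-Bouldin index straight from its definition, scalar loops only
db_oracle <- function(X, cl) {
  X <- as.matrix(X)
  ks <- sort(unique(cl))
  k <- length(ks)
  cent <- matrix(0, k, ncol(X))
  sig <- numeric(k)
  for (a in seq_len(k)) {
    rowsa <- X[cl == ks[a], , drop = FALSE]
    cent[a, ] <- colMeans(rowsa)
    s <- 0
    for (r in seq_len(nrow(rowsa))) {
      s <- s + sqrt(sum((rowsa[r, ] - cent[a, ])^2))
    }
    sig[a] <- s / nrow(rowsa)
  }
  total <- 0
  for (a in seq_len(k)) {
    worst <- 0
    for (b in seq_len(k)) {
      if (a == b) next
      dab <- sqrt(sum((cent[a, ] - cent[b, ])^2))
      worst <- max(worst, (sig[a] + sig[b]) / dab)
    }
    total <- total + worst
  }
  total / k
}

# Shannon entropy of a proportion vector by direct summation
entropy_oracle <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

# mean silhouette width from the definition (small n only)
silhouette_oracle <- function(X, cl) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    a <- if (length(own)) mean(d[i, own]) else 0
    b <- Inf
    for (g in setdiff(unique(cl), cl[i])) {
      b <- min(b, mean(d[i, cl == g]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small fully-synthetic landscape stack with constant layers, for the ES
# equation tests (values chosen per test)
constant_stack <- function(nr = 6, nc = 6, cell_size_m = 100, lu_code = 1,
                           overrides = list()) {
  base <- list(
    land_use = matrix(lu_code, nr, nc),
    population_density = matrix(500, nr, nc),
    gdp_density = matrix(10, nr, nc),
    ntl = matrix(5, nr, nc),
    la = matrix(0.5, nr, nc),
    temperature = matrix(16, nr, nc),
    precipitation = matrix(1100, nr, nc),
    aet = matrix(600, nr, nc),
    usle_R = matrix(3500, nr, nc),
    usle_K = matrix(0.25, nr, nc),
    usle_LS = matrix(1.5, nr, nc),
    usle_Cf = matrix(0.22, nr, nc),
    usle_P = matrix(0.35, nr, nc),
    hss = matrix(0.8, nr, nc),
    pol_N = matrix(29, nr, nc),
    pol_P = matrix(1.05, nr, nc))
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  layers <- lapply(names(base), function(nm) {
    raster_layer(base[[nm]], nm, cell_size_m = cell_size_m,
                 origin = c(0, nr * cell_size_m))
  })
  names(layers) <- names(base)
  landscape_stack("t0", layers,
                  poi = data.frame(x = cell_size_m, y = cell_size_m,
                                   category = "commercial"))
}

# small scenario used across tests: fast to generate, all stages exercised
small_scenario <- function(seed = 42, ...) {
  args <- list(grid_rows = 16, grid_cols = 16, es_cells_per_km = 4,
               n_villages = 30, n_poi = 150, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(landscape_scenario, args)
}

# well-separated planted archetypes (pairwise distances >> noise) for
# recovery tests
separable_library <- function(within_sd = 0.05) {
  lib <- bundle_archetype_library()
  keep <- c("key_tradeoffs", "key_synergistic", "cs_hq_la",
            "water_purification", "fp")
  bundle_archetype_library(lib$archetypes[keep, ], within_sd = within_sd)
}
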
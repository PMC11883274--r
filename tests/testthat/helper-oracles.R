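# Independent oracles and shared fixtures for the test suite.

# Brute-force DBSCAN reference: full distance matrix, core points by
# neighborhood count, core components by union-find over all core-core pairs,
# border points claimed by the cluster whose seed (minimal core index) is
# smallest among clusters owning a core neighbor. Independent of the
# package's grid-binned BFS implementation.
dbscan_oracle <- function(x, y, eps, min_pts) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nbr <- d2 <= eps^2
  core <- rowSums(nbr) >= min_pts
  parent <- seq_len(n)
  root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in which(core)) {
    for (j in which(core & nbr[i, ])) {
      ri <- root(i)
      rj <- root(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), root, integer(1))
  labels <- integer(n)
  seeds <- sort(unique(comp[core]))
  for (k in seq_along(seeds)) labels[core & comp == seeds[k]] <- k
  for (i in which(!core)) {
    cand <- labels[core & nbr[i, ]]
    if (length(cand)) labels[i] <- min(cand)
  }
  labels
}

# Sample standard deviation computed from first principles (n - 1 divisor),
# independent of stats::sd.
manual_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

# One Sigma-D calibration shared by the static-PWS and acceptance tests;
# built on first use.
shared_cal_env <- new.env(parent = emptyenv())
shared_sigma_cal <- function() {
  if (is.null(shared_cal_env$cal))
    shared_cal_env$cal <- build_sigma_to_d_calibration(optics_config(),
                                                       rng_seed = 42L)
  shared_cal_env$cal
}

# Simulate a uniform-medium spectral cube at one packing scaling.
uniform_cube <- function(D, nx, ny, cfg = optics_config(), seed = 1L,
                         sigma_n = 0.01) {
  med <- chromatin_medium(D = D, sigma_n = sigma_n)
  sp <- simulate_interference_spectrum(med, cfg, n_spectra = nx * ny,
                                       rng_seed = seed)
  spectral_cube(array(t(sp), c(nx, ny, length(cfg$lambda_grid))),
                cfg$lambda_grid, reference = matrix(1, nx, ny))
}
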
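test_that("DBSCAN handles the canonical small cases", {
  # 3 collinear points 40 nm apart: the middle point is core, one cluster
  lt <- localization_table(c(0, 40, 80), c(0, 0, 0), rep(25, 3))
  expect_equal(cluster_localizations(lt), c(1L, 1L, 1L))
  # 2 isolated points 500 nm apart: below min_pts everywhere, all noise
  lt2 <- localization_table(c(0, 500), c(0, 0), rep(25, 2))
  expect_equal(cluster_localizations(lt2), c(0L, 0L))
  expect_error(cluster_localizations(lt, eps = 0), "eps")
  expect_error(cluster_localizations(lt, min_pts = 0), "min_pts")
  expect_error(cluster_localizations(lt[0, ]), "at least one")
})

test_that("two well-separated Gaussian clusters are found intact", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 50
    lt <- localization_table(
      x = c(rnorm(n, 0, 20), rnorm(n, 1000, 20)),
      y = c(rnorm(n, 0, 20), rnorm(n, 0, 20)),
      uncertainty = rep(25, 2 * n))
    lab <- cluster_localizations(lt)
    k <- length(setdiff(unique(lab), 0L))
    pure <- !any(lab[1:n] %in% lab[(n + 1):(2 * n)][lab[(n + 1):(2 * n)] > 0])
    if (k == 2 && pure && sum(lab == 0) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 18L)   # >= 95% of seeds up to binomial wiggle at 20 draws
})

test_that("grid-binned DBSCAN equals the brute-force oracle exactly", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    # mix of clusters and uniform background, random scales
    k <- sample(1:4, 1)
    cx <- runif(k, 0, 2000)
    cy <- runif(k, 0, 2000)
    idx <- sample(k, n, replace = TRUE)
    x <- cx[idx] + rnorm(n, 0, sample(c(15, 30, 120), 1))
    y <- cy[idx] + rnorm(n, 0, sample(c(15, 30, 120), 1))
    lt <- localization_table(x, y, rep(25, n))
    got <- cluster_localizations(lt, eps = 50, min_pts = 3)
    want <- dbscan_oracle(x, y, eps = 50, min_pts = 3)
    expect_identical(got, want)
  }
})

test_that("cluster labels are invariant under rigid motions", {
  set.seed(9)
  n <- 120
  x <- c(rnorm(40, 0, 20), rnorm(40, 400, 20), runif(40, -200, 600))
  y <- c(rnorm(40, 0, 20), rnorm(40, 300, 20), runif(40, -200, 600))
  base <- cluster_localizations(localization_table(x, y, rep(25, n)))
  for (th in runif(5, 0, 2 * pi)) {
    xr <- cos(th) * x - sin(th) * y + 1234
    yr <- sin(th) * x + cos(th) * y - 987
    rot <- cluster_localizations(localization_table(xr, yr, rep(25, n)))
    expect_identical(rot, base)
  }
})

test_that("convex-hull geometry is exact and rotation invariant", {
  g <- domain_geometry(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  expect_equal(g$hull_area, 1e4)
  expect_equal(g$eq_diameter, 2 * sqrt(1e4 / pi), tolerance = 1e-12)
  expect_equal(g$eq_diameter, 112.8379, tolerance = 1e-4)
  expect_false(g$degenerate)
  # collinear: zero area, size falls back to the maximal extent
  gc <- domain_geometry(cbind(c(0, 40, 80), c(0, 0, 0)))
  expect_identical(gc$hull_area, 0)
  expect_equal(gc$size, 80)
  expect_true(gc$degenerate)
  expect_error(domain_geometry(cbind(1:2, 1:2)), "3 points")
  set.seed(11)
  pts <- cbind(rnorm(40, 0, 50), rnorm(40, 0, 30))
  a0 <- domain_geometry(pts)$hull_area
  for (th in runif(10, 0, 2 * pi)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(domain_geometry(pts %*% R)$hull_area, a0,
                 tolerance = 1e-9)
  }
})

test_that("size filtering applies the uncertainty-derived bounds", {
  # five constructed clusters with known equivalent diameters
  sizes <- c(30, 60, 200, 790, 900)
  domains <- data.frame(cluster = 1:5, n_locs = 10,
                        centroid_x = 0, centroid_y = 0,
                        hull_area_nm2 = pi * (sizes / 2)^2,
                        eq_diameter_nm = sizes, max_extent_nm = sizes,
                        size_nm = sizes, degenerate = FALSE)
  locs <- localization_table(runif(50), runif(50), rep(25, 50))
  kept <- filter_domains(domains, locs)
  expect_equal(kept$size_nm, c(60, 200, 790))
  expect_equal(unname(attr(kept, "bounds")), c(50, 800))
  # filtering is idempotent
  again <- filter_domains(kept, locs)
  expect_equal(again$size_nm, kept$size_nm)
  # the literal 25-nm reading keeps the 30-nm cluster
  lit <- filter_domains(domains, locs, uncertainty_rule = "literal-25")
  expect_equal(lit$size_nm, c(30, 60, 200, 790))
  expect_error(filter_domains(domains, data.frame(x = 1, y = 1)),
               "uncertainty")
  # retention is monotone non-increasing in the lower bound
  for (u in c(5, 20, 60, 120)) {
    locs_u <- localization_table(runif(50), runif(50), rep(u, 50))
    kept_u <- filter_domains(domains, locs_u)
    expect_true(all(kept_u$size_nm %in% kept$size_nm |
                      kept_u$size_nm > 2 * u))
    expect_equal(kept_u$size_nm, sizes[sizes > 2 * u & sizes <= 800])
  }
})

test_that("hull size tracks the generated domain radius", {
  # domain full radius ~ 2 sqrt(sigma^2 + mean uncertainty^2); the clustered
  # hull's equivalent diameter stays within [1.2, 2.4] of that radius
  set.seed(21)
  for (sigma in c(40, 80)) {
    for (rep in 1:5) {
      n <- round(30 * (sigma / 40)^2)
      u <- pmax(5, rnorm(n, 25, 5))
      lt <- localization_table(rnorm(n, 0, sigma) + rnorm(n, 0, u),
                               rnorm(n, 0, sigma) + rnorm(n, 0, u), u)
      lab <- cluster_localizations(lt)
      main <- which(lab == which.max(tabulate(lab)))
      expect_gte(length(main), 20)
      g <- domain_geometry(cbind(lt$x[main], lt$y[main]))
      r_eff <- 2 * sqrt(sigma^2 + mean(u)^2)
      expect_gt(g$eq_diameter, 1.2 * r_eff)
      expect_lt(g$eq_diameter, 2.4 * r_eff)
    }
  }
})

test_that("domains are pooled by region with empty regions reported", {
  scene <- make_scene(nx = 40, ny = 40, rng_seed = 2)
  px <- scene$pixel_size * 1000
  body_px <- unname(which(scene$label_image == 1, arr.ind = TRUE)[1, ])
  domains <- data.frame(cluster = 1:3,
                        n_locs = 5,
                        centroid_x = (body_px[1] - 0.5) * px,
                        centroid_y = (body_px[2] - 0.5) * px,
                        hull_area_nm2 = 1e4, eq_diameter_nm = 112,
                        max_extent_nm = 130, size_nm = 112,
                        degenerate = FALSE)
  s <- summarize_domains_by_region(domains, scene)
  expect_equal(unname(s$counts["body"]), 3)
  expect_equal(unname(s$counts["bleb"]), 0)   # emitted though empty
  expect_length(s$sizes$bleb, 0)
  # centroid off the frame lands in "outside", never dropped
  domains$centroid_x[1] <- -5000
  s2 <- summarize_domains_by_region(domains, scene)
  expect_equal(unname(s2$counts["outside"]), 1)
  expect_equal(sum(s2$counts), nrow(domains))
})

test_that("bleb nanodomains run smaller than body nanodomains", {
  sc <- scenario_spec()
  pooled_body <- pooled_bleb <- numeric(0)
  for (s in 1:3) {
    scene <- make_scene(rng_seed = s)
    locs <- synth_localizations(scene, sc, rng_seed = 100 + s)
    reg <- summarize_domains_by_region(call_nanodomains(locs), scene)
    pooled_body <- c(pooled_body, reg$sizes$body)
    pooled_bleb <- c(pooled_bleb, reg$sizes$bleb)
  }
  expect_lt(median(pooled_bleb), median(pooled_body))
  p <- wilcox.test(pooled_bleb, pooled_body, alternative = "less",
                   exact = FALSE)$p.value
  expect_lt(p, 0.05)
})

test_that("ThunderSTORM tables round-trip and auto-detect delimiters", {
  lt <- localization_table(c(100.5, 200.25), c(50, 75.5), c(24.1, 26.2),
                           frame = c(1L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_locs_csv(lt, path)
  back <- read_locs_csv(path)
  expect_equal(back$x, lt$x)
  expect_equal(back$uncertainty, lt$uncertainty)
  # semicolon variant
  writeLines(c("\"x [nm]\";\"y [nm]\";\"uncertainty [nm]\";\"frame\"",
               "10;20;25;1", "30;40;25;2"), path)
  semi <- read_locs_csv(path)
  expect_equal(semi$x, c(10, 30))
  writeLines(c("\"x [nm]\",\"y [nm]\"", "1,2"), path)
  expect_error(read_locs_csv(path), "uncertainty \\[nm\\]")
  expect_error(localization_table(1, Inf, 25), "finite")
  expect_error(localization_table(1, 2, -1), "positive")
})
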
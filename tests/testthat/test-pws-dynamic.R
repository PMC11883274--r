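cfg <- optics_config()

const_cube <- function(nx = 6, ny = 6, nt = 40, level = 1000) {
  temporal_cube(array(level, c(nx, ny, nt)), i0 = matrix(level, nx, ny))
}

test_that("FMM is zero on constant cubes and masks dead reference pixels", {
  fmm <- fractional_moving_mass(const_cube(), cfg)
  expect_true(all(fmm == 0))
  cube <- const_cube()
  cube$i0[2, 2] <- 0
  fmm <- fractional_moving_mass(cube, cfg)
  expect_true(is.na(fmm[2, 2]))
  expect_true(attr(fmm, "masked")[2, 2])
})

test_that("FMM is linear in the generator's moving mass", {
  scene <- make_scene(nx = 16, ny = 16, a = 6, b = 5, bleb_radius = 2)
  body <- scene$label_image == 1
  r1 <- r2 <- numeric(0)
  for (s in 1:8) {
    c1 <- synth_temporal_cube(scene, scenario_spec(fmm_body = 1e-19),
                              cfg, n_frames = 200, rng_seed = s)
    c2 <- synth_temporal_cube(scene, scenario_spec(fmm_body = 2e-19),
                              cfg, n_frames = 200, rng_seed = 100 + s)
    r1 <- c(r1, mean(fractional_moving_mass(c1, cfg)[body]))
    r2 <- c(r2, mean(fractional_moving_mass(c2, cfg)[body]))
  }
  # doubling the generator moving mass doubles the estimate
  expect_lt(abs(mean(r2) / mean(r1) - 2), 2 * 0.05)
})

test_that("FMM closed loop recovers a nucleosome-clutch-scale moving mass", {
  scene <- make_scene(nx = 24, ny = 24, a = 9, b = 7, bleb_radius = 3)
  body <- scene$label_image == 1
  est <- vapply(1:10, function(s) {
    cube <- synth_temporal_cube(scene, scenario_spec(fmm_body = 2e-19),
                                cfg, n_frames = 300, rng_seed = s)
    mean(fractional_moving_mass(cube, cfg)[body])
  }, numeric(1))
  expect_lt(abs(mean(est) / 2e-19 - 1), 0.10)
  # detrended variant stays within the same tolerance
  cube <- synth_temporal_cube(scene, scenario_spec(fmm_body = 2e-19),
                              cfg, n_frames = 300, rng_seed = 99)
  # detrending sheds some genuine low-frequency moving-mass power, so it
  # sits lower but within the same order
  fm <- fractional_moving_mass(cube, cfg, detrend = TRUE)
  fm_raw <- fractional_moving_mass(cube, cfg)
  expect_lt(mean(fm[body]), mean(fm_raw[body]))
  expect_gt(mean(fm[body]) / 2e-19, 0.5)
  expect_lt(mean(fm[body]) / 2e-19, 1.05)
})

test_that("effective diffusion flags undecaying pixels and recovers tau_d", {
  de0 <- effective_diffusion(const_cube(), cfg)
  expect_true(all(is.na(de0)))
  expect_true(all(attr(de0, "below_floor")))
  expect_error(effective_diffusion(const_cube(nt = 15), cfg), ">= 20")

  # tau_d = 0.5 s ground truth: D_e = 1 / (4 k_med^2 0.5)
  k_med <- 2 * pi * cfg$n_1 / 0.55
  de_true <- 1 / (4 * k_med^2 * 0.5)
  scene <- make_scene(nx = 24, ny = 24, a = 9, b = 7, bleb_radius = 3)
  body <- scene$label_image == 1
  est <- vapply(1:8, function(s) {
    cube <- synth_temporal_cube(scene,
                                scenario_spec(de_body = de_true,
                                              de_bleb = de_true),
                                cfg, n_frames = 300, rng_seed = s)
    as.numeric(region_diffusion(cube, body, cfg))
  }, numeric(1))
  expect_lt(abs(mean(est) / de_true - 1), 0.05)
})

test_that("faster media always rank above slower media in estimated D_e", {
  k_med <- 2 * pi * cfg$n_1 / 0.55
  de_fast <- 1 / (4 * k_med^2 * 0.2)
  de_slow <- 1 / (4 * k_med^2 * 1.0)
  scene <- make_scene(nx = 16, ny = 16, a = 6, b = 5, bleb_radius = 2)
  body <- scene$label_image == 1
  for (s in 1:20) {
    cf <- synth_temporal_cube(scene, scenario_spec(de_body = de_fast,
                                                   de_bleb = de_fast),
                              cfg, n_frames = 300, rng_seed = s)
    cs <- synth_temporal_cube(scene, scenario_spec(de_body = de_slow,
                                                   de_bleb = de_slow),
                              cfg, n_frames = 300, rng_seed = 500 + s)
    expect_gt(as.numeric(region_diffusion(cf, body, cfg)),
              as.numeric(region_diffusion(cs, body, cfg)))
  }
})

test_that("relative CVC traces invert intensity and honor the flat-trace rule", {
  flat <- relative_cvc_trace(const_cube(), matrix(TRUE, 6, 6))
  expect_true(flat$flat)
  expect_true(all(flat$cvc_rel == 0.5))
  expect_error(relative_cvc_trace(const_cube(), matrix(FALSE, 6, 6)),
               "empty")
  # monotone rising intensity -> monotone falling relative CVC
  ramp <- array(rep(seq(900, 1100, length.out = 30), each = 16),
                c(4, 4, 30))
  cube <- temporal_cube(ramp, i0 = matrix(1000, 4, 4))
  tr <- relative_cvc_trace(cube, matrix(TRUE, 4, 4))
  expect_true(all(diff(tr$cvc_rel) < 0))
  expect_true(all(tr$cvc_rel >= 0 & tr$cvc_rel <= 1))
  # invariant under a pure rescaling of detector units
  cube2 <- temporal_cube(ramp * 7.3, i0 = matrix(7300, 4, 4))
  tr2 <- relative_cvc_trace(cube2, matrix(TRUE, 4, 4))
  expect_equal(tr$cvc_rel, tr2$cvc_rel, tolerance = 1e-12)
  # affine offsets on a near-unity ratio perturb it only to second order
  cube3 <- temporal_cube(ramp * 7.3 + 5, i0 = matrix(7305, 4, 4))
  tr3 <- relative_cvc_trace(cube3, matrix(TRUE, 4, 4))
  expect_equal(tr$cvc_rel, tr3$cvc_rel, tolerance = 1e-3)
})

test_that("a generator CVC ramp is recovered in the region trace", {
  scene <- make_scene(nx = 96, ny = 96, a = 36, b = 26, bleb_radius = 10,
                      neck_width = 5)
  body <- scene$label_image == 1
  truth <- seq(0, 1, length.out = 300)
  for (s in 1:3) {
    cube <- synth_temporal_cube(scene, scenario_spec(), cfg,
                                n_frames = 300, rng_seed = s)
    tr <- relative_cvc_trace(cube, body)
    expect_gt(cor(tr$cvc_rel, truth), 0.95)
  }
})

test_that("polynomial trends are exact on polynomial input", {
  t <- seq(0, 15, by = 0.05)
  coef_true <- c(0.4, 0.02, -0.01, 8e-4, -2e-5)
  y <- drop(cbind(1, poly(t, 4, raw = TRUE)) %*% coef_true)
  fit <- fit_polynomial_trend(list(t = t, cvc_rel = y))
  expect_equal(fit$coeffs, coef_true, tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # order 0 reduces to the mean
  alt <- fit_polynomial_trend(list(t = 1:10, cvc_rel = rep(c(0, 1), 5)),
                              order = 0)
  expect_equal(unname(fit_polynomial_trend(
    list(t = 1:10, cvc_rel = rep(c(0, 1), 5)), order = 0)$coeffs), 0.5)
  expect_error(fit_polynomial_trend(list(t = 1:4, cvc_rel = 1:4)),
               "under-determined")
  # on a noisy decaying trace the trend explains variance
  set.seed(3)
  y2 <- exp(-t / 5) + rnorm(length(t), 0, 0.05)
  fit2 <- fit_polynomial_trend(list(t = t, cvc_rel = y2))
  expect_lt(sqrt(mean(fit2$residuals^2)), sd(y2))
})

test_that("CVC ensembles average trends with a standard error", {
  t <- seq(0, 10, by = 0.1)
  mk <- function(level) list(t = t, cvc_rel = rep(level, length(t)),
                             region_label = "body", cell_id = "x")
  same <- ensemble_cvc(list(mk(0.5), mk(0.5)))
  expect_equal(max(abs(same$sem)), 0, tolerance = 1e-12)
  two <- ensemble_cvc(list(mk(0.4), mk(0.6)))
  expect_equal(unique(round(two$mean, 10)), 0.5)
  expect_equal(unique(round(two$sem, 10)), 0.1)
  one <- ensemble_cvc(list(mk(0.4)))
  expect_true(one$sem_undefined)
  expect_true(all(is.na(one$sem)))
})

test_that("bleb-to-body ratios pair by cell and exclude degenerate cells", {
  df <- data.frame(cell_id = c("a", "a", "b", "b", "c", "d", "d"),
                   region = c("bleb", "body", "bleb", "body", "body",
                              "bleb", "body"),
                   cvc_mean = c(0.3, 0.6, 0.5, 0.5, 0.4, 0.2, 0))
  r <- bleb_body_cvc_ratio(df)
  expect_equal(unname(r[c("a", "b")]), c(0.5, 1))
  expect_false("c" %in% names(r))
  expect_false("d" %in% names(r))
  expect_length(attr(r, "excluded"), 2)
  same <- bleb_body_cvc_ratio(data.frame(
    cell_id = "z", region = c("bleb", "body"), cvc_mean = c(0.37, 0.37)))
  expect_identical(as.numeric(same), 1)
})

test_that("suppressed-bleb treatment lowers the CVC ratio against control", {
  scene <- make_scene(nx = 32, ny = 32, rng_seed = 1)
  ctrl <- scenario_spec()                       # bleb 0.25 / body 0.35
  trt <- scenario_spec(phi_body = 0.45, phi_bleb = 0.15)
  ratios <- sapply(1:5, function(s) {
    dc <- summarize_dynamics(
      synth_temporal_cube(scene, ctrl, cfg, n_frames = 120, rng_seed = s),
      scene$label_image, cfg, cell_id = "c")
    dt <- summarize_dynamics(
      synth_temporal_cube(scene, trt, cfg, n_frames = 120, rng_seed = s),
      scene$label_image, cfg, cell_id = "t")
    c(as.numeric(bleb_body_cvc_ratio(dc)), as.numeric(bleb_body_cvc_ratio(dt)))
  })
  expect_true(all(ratios[2, ] < ratios[1, ]))
})
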
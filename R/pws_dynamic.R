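#' Temporal image cube from single-wavelength dynamics acquisition
#'
#' Backscattered wide-field frames at a single wavelength over time, plus the
#' reference image used for normalization.
#'
#' @param intensity 3-D array `(x, y, t)`.
#' @param i0 Reference image `(x, y)`; must be strictly positive wherever
#'   pixels are analyzed.
#' @param frame_interval Frame spacing, s.
#' @param lambda_dyn Acquisition wavelength, nm.
#' @return A `temporal_cube` object.
#' @export
temporal_cube <- function(intensity, i0, frame_interval = 0.050,
                          lambda_dyn = 550) {
  stopifnot(length(dim(intensity)) == 3)
  if (dim(intensity)[3] < 10) stop("need >= 10 frames")
  stopifnot(all(dim(i0) == dim(intensity)[1:2]), frame_interval > 0)
  structure(list(intensity = intensity, i0 = i0,
                 frame_interval = frame_interval, lambda_dyn = lambda_dyn,
                 n_frames = dim(intensity)[3]),
            class = "temporal_cube")
}

#' @export
print.temporal_cube <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("temporal cube %d x %d px, %d frames @ %g ms, %g nm\n",
              d[1], d[2], d[3], 1000 * x$frame_interval, x$lambda_dyn))
  invisible(x)
}

# reference-normalized intensity as an (npix x t) matrix; masked rows are NA
normalized_frames <- function(cube) {
  d <- dim(cube$intensity)
  mask <- !(cube$i0 > 0) | is.na(cube$i0)
  i0 <- cube$i0
  i0[mask] <- NA
  x <- matrix(cube$intensity, d[1] * d[2], d[3]) / as.vector(i0)
  list(x = x, mask = mask, dim = d[1:2])
}

#' Fractional moving mass map
#'
#' For each pixel, the temporal variance of the reference-normalized intensity
#' `I(x, y, t) / I0(x, y)` divided by the normative pre-factor
#' [fmm_prefactor()], yielding the fractional moving mass in grams: the
#' product of the typical moving macromolecular cluster mass and the mobile
#' volume fraction. Temporally constant pixels give exactly zero. Pixels with
#' a non-positive reference are masked (NA).
#'
#' @param cube A [temporal_cube()].
#' @param cfg An [optics_config()].
#' @param detrend If TRUE, remove a fourth-order polynomial trend from each
#'   pixel trace before taking the variance (separates slow concentration
#'   drift from the fast moving-mass fluctuations). Default FALSE: variance of
#'   the raw normalized trace.
#' @return Matrix of FMM values, grams, with attribute `masked`.
#' @export
fractional_moving_mass <- function(cube, cfg = optics_config(),
                                   detrend = FALSE) {
  stopifnot(inherits(cube, "temporal_cube"))
  nf <- normalized_frames(cube)
  x <- nf$x
  if (detrend) {
    t_s <- (seq_len(ncol(x)) - 1) * cube$frame_interval
    basis <- stats::poly(t_s, 4, raw = TRUE)
    fit <- stats::lm.fit(cbind(1, basis), t(x))
    x <- t(as.matrix(fit$residuals))
  }
  v <- apply(x, 1, stats::var)
  fmm <- matrix(v / fmm_prefactor(cfg), nf$dim[1], nf$dim[2])
  fmm[nf$mask] <- NA
  attr(fmm, "masked") <- nf$mask
  fmm
}

# normalized temporal autocovariance for every pixel, lags 0..max_lag
# rows of x are pixel traces; returns (max_lag + 1) x npix matrix
pixel_acf <- function(x, max_lag) {
  n <- ncol(x)
  xc <- x - rowMeans(x)
  m <- stats::nextn(2L * n, 2)
  f <- stats::mvfft(t(cbind(xc, matrix(0, nrow(x), m - n))))
  ac <- Re(stats::mvfft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1), ,
                                                      drop = FALSE]
  sweep(ac, 2, ac[1, ], "/")
}

#' Effective diffusion map from temporal autocorrelation decay
#'
#' Estimates each pixel's temporal-autocorrelation decay time under the
#' single-exponential model `C(tau) = exp(-tau / tau_d)` and converts it to an
#' effective diffusion coefficient with the backscattering
#' dynamic-light-scattering convention `D_e = 1 / (4 k_med^2 tau_d)`,
#' `k_med = 2 pi n_1 / lambda_dyn`. For an exponential-ACF (AR(1)) process
#' the decay rate is fully captured by the lag-1 autocorrelation, so the
#' estimator regresses the demeaned trace on its own lag and applies the
#' Marriott-Pope small-sample correction `E[phi_hat] = phi - (1 + 3 phi) / T`
#' (naive multi-lag log-linear fits of the sample ACF inherit a
#' record-length-dependent downward bias that this correction removes).
#' Pixels with no measurable decay (constant trace, or a corrected
#' autocorrelation outside (0, 1)) are flagged below the measurement floor
#' and reported as NA; fitted values outside the measurable band are clipped
#' and flagged. The decay-time map is attached as the `tau_d` attribute.
#'
#' @param cube A [temporal_cube()] with at least 20 frames.
#' @param cfg An [optics_config()].
#' @param de_band Reportable band for D_e, um^2/s.
#' @return Matrix of D_e values, um^2/s, with attributes `tau_d` (s),
#'   `below_floor` (logical matrix) and `clipped` (logical matrix).
#' @export
effective_diffusion <- function(cube, cfg = optics_config(),
                                de_band = c(3.5e-5, 0.065)) {
  stopifnot(inherits(cube, "temporal_cube"))
  if (cube$n_frames < 20) stop("need >= 20 frames")
  nf <- normalized_frames(cube)
  n <- cube$n_frames
  x <- nf$x - rowMeans(nf$x)
  v <- rowSums(x^2)
  flat <- is.na(v) | v <= 0
  x0 <- x[, -n, drop = FALSE]
  x1 <- x[, -1, drop = FALSE]
  phi_hat <- rowSums(x0 * x1) / rowSums(x0^2)
  phi_c <- (phi_hat + 1 / n) / (1 - 3 / n)   # Marriott-Pope correction
  ok <- !flat & is.finite(phi_c) & phi_c > 0 & phi_c < 1
  tau_d <- ifelse(ok, -cube$frame_interval / log(phi_c), NA_real_)
  lam_um <- cube$lambda_dyn / 1000
  k_med <- 2 * pi * cfg$n_1 / lam_um
  de <- 1 / (4 * k_med^2 * tau_d)
  clipped <- !is.na(de) & (de < de_band[1] | de > de_band[2])
  de <- pmin(pmax(de, de_band[1]), de_band[2])
  out <- matrix(de, nf$dim[1], nf$dim[2])
  out[nf$mask] <- NA
  attr(out, "tau_d") <- matrix(tau_d, nf$dim[1], nf$dim[2])
  attr(out, "below_floor") <- matrix(!ok, nf$dim[1], nf$dim[2]) | nf$mask
  attr(out, "clipped") <- matrix(clipped, nf$dim[1], nf$dim[2])
  out
}

#' Pooled regional effective diffusion
#'
#' Region-level companion to [effective_diffusion()]: pools the lag-1
#' autoregression over all pixels of a region, removing the region's
#' *cross-sectional* mean at each frame instead of each pixel's temporal
#' mean. Because the shared slow baseline (including any concentration ramp)
#' is estimated from the spatial ensemble, the temporal-demeaning bias that
#' limits per-pixel decay estimates on short records vanishes (residual bias
#' is O(1/n_pixels)), which matters for slow dynamics where the record holds
#' few decay times. Falls back to the mean of the per-pixel map for regions
#' under `min_pixels`.
#'
#' @param cube A [temporal_cube()].
#' @param region Logical mask.
#' @param cfg An [optics_config()].
#' @param de_band Reportable band for D_e, um^2/s.
#' @param min_pixels Smallest region size for the pooled estimator.
#' @return Scalar D_e, um^2/s, with attribute `tau_d` (s).
#' @export
region_diffusion <- function(cube, region, cfg = optics_config(),
                             de_band = c(3.5e-5, 0.065), min_pixels = 10) {
  stopifnot(inherits(cube, "temporal_cube"), is.logical(region))
  nf <- normalized_frames(cube)
  sel <- as.vector(region) & !as.vector(nf$mask)
  if (!any(sel)) stop("region is empty or fully masked")
  if (sum(sel) < min_pixels) {
    de <- effective_diffusion(cube, cfg, de_band = de_band)
    out <- mean(de[region], na.rm = TRUE)
    attr(out, "tau_d") <- 1 / (4 * (2 * pi * cfg$n_1 / (cube$lambda_dyn /
                                                          1000))^2 * out)
    return(out)
  }
  x <- nf$x[sel, , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))      # remove shared baseline per frame
  n <- ncol(x)
  phi <- sum(x[, -n] * x[, -1]) / sum(x[, -n]^2)
  if (!is.finite(phi) || phi <= 0 || phi >= 1) {
    out <- NA_real_
    attr(out, "tau_d") <- NA_real_
    return(out)
  }
  tau_d <- -cube$frame_interval / log(phi)
  de <- 1 / (4 * (2 * pi * cfg$n_1 / (cube$lambda_dyn / 1000))^2 * tau_d)
  out <- min(max(de, de_band[1]), de_band[2])
  attr(out, "tau_d") <- tau_d
  out
}

#' Relative chromatin-volume-concentration trace for a region
#'
#' Averages the normalized dynamics signal `(I(t) - I0) / I0` over a region of
#' interest, takes the inverse of the resulting intensity ratio (the mean
#' backscattered signal is inversely related to chromatin concentration, so
#' `I0 / I` rises with CVC) and min-max scales it to `[0, 1]`. A flat trace
#' (min = max) returns the constant 0.5 and is flagged, so tiny quiet regions
#' do not abort a pipeline.
#'
#' @param cube A [temporal_cube()].
#' @param region Logical mask, same size as a frame.
#' @param region_label `"body"` or `"bleb"` (free-form allowed).
#' @param cell_id Identifier carried into ensembles and ratios.
#' @return A `cvc_trace`: fields `t`, `raw` (region-mean normalized
#'   intensity), `cvc_rel` in `[0, 1]`, `flat` flag, `region_label`,
#'   `cell_id`.
#' @export
relative_cvc_trace <- function(cube, region, region_label = "body",
                               cell_id = "cell1") {
  stopifnot(inherits(cube, "temporal_cube"), is.logical(region))
  stopifnot(all(dim(region) == dim(cube$intensity)[1:2]))
  nf <- normalized_frames(cube)
  sel <- as.vector(region) & !as.vector(nf$mask)
  if (!any(sel)) stop("region is empty or fully masked")
  raw <- colMeans(nf$x[sel, , drop = FALSE]) - 1     # mean (I - I0) / I0
  inv <- 1 / (1 + raw)                               # ~ I0 / I, rises with CVC
  rng <- range(inv)
  flat <- !(rng[2] > rng[1])
  cvc_rel <- if (flat) rep(0.5, length(inv)) else (inv - rng[1]) / diff(rng)
  structure(list(t = (seq_along(raw) - 1) * cube$frame_interval,
                 raw = raw, cvc_rel = cvc_rel, flat = flat,
                 region_label = region_label, cell_id = cell_id),
            class = "cvc_trace")
}

#' @export
print.cvc_trace <- function(x, ...) {
  cat(sprintf("relative CVC trace: %s / %s, %d frames over %.2f s%s\n",
              x$cell_id, x$region_label, length(x$t), max(x$t),
              if (x$flat) " [flat]" else ""))
  invisible(x)
}

#' @export
plot.cvc_trace <- function(x, ...) {
  graphics::plot(x$t, x$cvc_rel, type = "l", xlab = "time (s)",
                 ylab = "relative CVC",
                 main = sprintf("%s / %s", x$cell_id, x$region_label), ...)
  tr <- fit_polynomial_trend(x)
  graphics::lines(x$t, tr$fitted, col = "red", lwd = 2)
  invisible(x)
}

#' Polynomial trend of a CVC trace
#'
#' Least-squares polynomial (fourth order by default) of the relative CVC
#' versus time. The residual high-frequency component is preserved for
#' moving-mass cross-checks; the smooth trend carries the slow concentration
#' drift used in ensembles.
#'
#' @param trace A `cvc_trace`, or any list with numeric `t` and `cvc_rel`.
#' @param order Polynomial order (default 4).
#' @return List with `coeffs` (ascending powers), `fitted`, `residuals`,
#'   `order`.
#' @export
fit_polynomial_trend <- function(trace, order = 4) {
  t <- trace$t
  y <- trace$cvc_rel
  if (length(t) <= order + 1) stop("under-determined: need > order + 1 points")
  X <- stats::poly(t, degree = max(order, 1), raw = TRUE)[, seq_len(order),
                                                          drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  list(coeffs = unname(fit$coefficients), fitted = as.vector(fit$fitted.values),
       residuals = as.vector(fit$residuals), order = order)
}

#' Ensemble CVC trend with standard error
#'
#' Fits the polynomial trend to every trace, resamples each fitted trend onto
#' a common time grid by linear interpolation, and returns the pointwise mean
#' and standard error of the mean across cells.
#'
#' @param traces List of `cvc_trace` objects.
#' @param order Trend order passed to [fit_polynomial_trend()].
#' @param t_grid Common time grid; defaults to the grid of the first trace.
#' @return List with `t`, `mean`, `sem` (NA with `sem_undefined = TRUE` for a
#'   single trace), `n`.
#' @export
ensemble_cvc <- function(traces, order = 4, t_grid = NULL) {
  stopifnot(length(traces) >= 1)
  if (is.null(t_grid)) t_grid <- traces[[1]]$t
  curves <- vapply(traces, function(tr) {
    f <- fit_polynomial_trend(tr, order = order)
    stats::approx(tr$t, f$fitted, xout = t_grid, rule = 2)$y
  }, numeric(length(t_grid)))
  curves <- matrix(curves, nrow = length(t_grid))
  n <- length(traces)
  m <- rowMeans(curves)
  sem <- if (n >= 2) apply(curves, 1, stats::sd) / sqrt(n) else
    rep(NA_real_, length(t_grid))
  list(t = t_grid, mean = m, sem = sem, n = n, sem_undefined = n < 2)
}

#' Per-cell bleb-to-body CVC ratio
#'
#' Pairs bleb and body summaries by `cell_id` and returns the distribution of
#' per-cell ratios `bleb mean CVC / body mean CVC`. Cells missing either
#' region, or with zero body CVC, are excluded and listed in the `excluded`
#' attribute.
#'
#' @param summaries Data frame with columns `cell_id`, `region` (values
#'   `"body"` / `"bleb"`) and `cvc_mean`.
#' @return Numeric vector of ratios named by cell, with attribute `excluded`.
#' @export
bleb_body_cvc_ratio <- function(summaries) {
  stopifnot(all(c("cell_id", "region", "cvc_mean") %in% names(summaries)))
  cells <- unique(summaries$cell_id)
  ratios <- numeric(0)
  excluded <- character(0)
  for (cid in cells) {
    s <- summaries[summaries$cell_id == cid, ]
    bleb <- s$cvc_mean[s$region == "bleb"]
    body <- s$cvc_mean[s$region == "body"]
    if (length(bleb) != 1 || length(body) != 1) {
      excluded <- c(excluded, paste0(cid, ": unpaired"))
    } else if (!is.finite(body) || body == 0) {
      excluded <- c(excluded, paste0(cid, ": zero/invalid body CVC"))
    } else {
      ratios[as.character(cid)] <- bleb / body
    }
  }
  attr(ratios, "excluded") <- excluded
  ratios
}

#' Region-level dynamics summary table
#'
#' Aggregates the dynamics maps over a labeled scene into one tidy row per
#' region: mean fractional moving mass (grams), mean effective diffusion
#' (um^2/s), and the mean chromatin volume concentration obtained by inverting
#' the region's time-averaged reflectance through a CVC calibration.
#'
#' @param cube A [temporal_cube()].
#' @param scene Integer label matrix (1 = body, 2+ = blebs; 0 ignored).
#' @param cfg An [optics_config()].
#' @param cal Optional [build_cvc_calibration()] result; when NULL the
#'   analytic default is built from `cfg`.
#' @param cell_id Cell identifier for the output rows.
#' @return Data frame: `cell_id`, `region` ("body"/"bleb"), `label`, `n_px`,
#'   `fmm_g`, `de_um2_s`, `cvc_mean`.
#' @export
summarize_dynamics <- function(cube, scene, cfg = optics_config(), cal = NULL,
                               cell_id = "cell1") {
  if (is.null(cal)) cal <- build_cvc_calibration(cfg)
  fmm <- fractional_moving_mass(cube, cfg)
  nf <- normalized_frames(cube)
  mean_ratio <- matrix(rowMeans(nf$x), nf$dim[1], nf$dim[2])
  labs <- sort(unique(scene[scene > 0]))
  rows <- lapply(labs, function(l) {
    sel <- scene == l & !nf$mask
    r_mean <- mean(mean_ratio[sel])   # I / I0 is in reflectance units
    data.frame(cell_id = cell_id,
               region = if (l == 1) "body" else "bleb",
               label = l, n_px = sum(sel),
               fmm_g = mean(fmm[sel], na.rm = TRUE),
               de_um2_s = as.numeric(region_diffusion(cube, scene == l, cfg)),
               cvc_mean = as.numeric(cvc_from_reflectance(r_mean, cal)))
  })
  do.call(rbind, rows)
}
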
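#' Fractal chromatin medium for the interference forward model
#'
#' Describes the refractive-index statistics of chromatin inside one coherence
#' column. Chromatin packs into mass-fractal domains obeying `M ~ r^D`, which
#' translates into a power-law density (and hence RI) autocorrelation
#' `B(r) ~ (r / l_max)^(D - 3)` between the inner scale `l_min` and the domain
#' outer scale `l_max`, with an exponential roll-off beyond `l_max`. `sigma_n`
#' sets the RMS RI contrast at the domain outer scale, so media with different
#' `D` share the same domain-scale contrast while redistributing fluctuation
#' power across length scales.
#'
#' @param D Packing scaling (mass-fractal dimension). Physical chromatin lies
#'   in `(5/3, 3]`; values in `[1, 3.5]` are accepted for calibration sweeps.
#' @param l_min Inner correlation scale, nm.
#' @param l_max Outer (packing-domain) correlation scale, nm.
#' @param phi_cvc Mean chromatin volume concentration.
#' @param sigma_n RMS refractive-index fluctuation at the outer scale.
#' @param thickness Axial extent of the sampled column, um.
#' @param n_layers Number of axial samples.
#' @return A `chromatin_medium` object.
#' @export
chromatin_medium <- function(D, l_min = 10, l_max = 150, phi_cvc = 0.35,
                             sigma_n = 0.01, thickness = 2, n_layers = 256) {
  if (D < 1 || D > 3.5) stop("D outside [1, 3.5]")
  stopifnot(l_min > 0, l_min < l_max, sigma_n >= 0, thickness > 0,
            n_layers >= 8, phi_cvc >= 0, phi_cvc <= 1)
  structure(list(D = D, l_min = l_min, l_max = l_max, phi_cvc = phi_cvc,
                 sigma_n = sigma_n, thickness = thickness,
                 n_layers = n_layers),
            class = "chromatin_medium")
}

#' @export
print.chromatin_medium <- function(x, ...) {
  cat(sprintf(
    "chromatin medium: D = %.2f, scales %g-%g nm, sigma_n = %.3g, %g um / %d layers\n",
    x$D, x$l_min, x$l_max, x$sigma_n, x$thickness, x$n_layers))
  invisible(x)
}

# Target RI autocorrelation evaluated on a lag grid (nm).
medium_acf <- function(medium, r) {
  with(medium,
       sigma_n^2 * (pmax(r, l_min) / l_max)^(D - 3) * exp(-r / l_max))
}

# Circulant-embedding eigenvalues for the medium's ACF at spacing dz (nm).
# Negative eigenvalues (cutoff ringing) are clipped to zero.
medium_eigenvalues <- function(medium, n, dz) {
  m <- 2L * n
  idx <- seq_len(m) - 1L
  r <- pmin(idx, m - idx) * dz
  ev <- Re(stats::fft(medium_acf(medium, r)))
  ev[ev < 0] <- 0
  ev
}

#' Sample axial refractive-index fluctuation profiles
#'
#' Draws zero-mean Gaussian axial RI profiles whose autocorrelation follows the
#' medium's power-law family, by circulant embedding of the target ACF (the
#' sampled process has exactly the embedded ACF, up to clipping of negative
#' cutoff-ringing eigenvalues).
#'
#' @param medium A [chromatin_medium()].
#' @param n_profiles Number of independent profiles to draw.
#' @param rng_seed Optional integer seed for reproducibility.
#' @return A numeric matrix, `n_layers` rows x `n_profiles` columns.
#' @export
sample_ri_profile <- function(medium, n_profiles = 1, rng_seed = NULL) {
  stopifnot(inherits(medium, "chromatin_medium"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- medium$n_layers
  if (medium$sigma_n == 0)
    return(matrix(0, n, n_profiles))
  dz <- medium$thickness * 1000 / n  # nm
  m <- 2L * n
  ev <- medium_eigenvalues(medium, n, dz)
  z <- matrix(complex(real = stats::rnorm(m * n_profiles),
                      imaginary = stats::rnorm(m * n_profiles)) / sqrt(2),
              m, n_profiles)
  f <- Re(stats::mvfft(sqrt(ev / m) * z))
  f[seq_len(n), , drop = FALSE]
}

#' Simulate backscattered interference spectra
#'
#' One-dimensional Born/phase-sum forward model: the detected field is the
#' reference reflection `sqrt(Gamma)` plus the phase-delayed sum of weak
#' reflections from axial RI fluctuations,
#' `I(lambda) = | sqrt(Gamma) + sum_j w k(lambda) dz dn_j exp(2 i k(lambda) n_1 z_j) |^2`,
#' with `k = 2 pi / lambda` and a scalar NA attenuation
#' `w = (NA_c / n_i)^2 / 2`. Each returned spectrum averages `n_cols`
#' independent coherence columns, reflecting the reduced spatial coherence of
#' high-NA illumination within one pixel.
#'
#' @param medium A [chromatin_medium()].
#' @param cfg An [optics_config()]; supplies `lambda_grid`, `Gamma`, `n_1`.
#' @param n_spectra Number of independent pixel spectra.
#' @param n_cols Independent coherence columns averaged per pixel.
#' @param rng_seed Optional integer seed.
#' @return Matrix of intensities, `length(lambda_grid)` rows x `n_spectra`
#'   columns (reference-normalized units; matched media give the constant
#'   `Gamma`).
#' @export
simulate_interference_spectrum <- function(medium, cfg = optics_config(),
                                           n_spectra = 1, n_cols = 3,
                                           rng_seed = NULL) {
  stopifnot(length(cfg$lambda_grid) >= 1, n_cols >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- medium$n_layers
  dz <- medium$thickness * 1000 / n
  z <- (seq_len(n) - 0.5) * dz
  k <- 2 * pi / cfg$lambda_grid          # 1/nm
  w <- (cfg$na_c / cfg$n_i)^2 / 2
  phase <- exp(outer(z, 2i * k * cfg$n_1))       # n x n_lambda
  amp <- matrix(w * k * dz, nrow = n, ncol = length(k), byrow = TRUE)
  kernel <- amp * phase
  r_ref <- sqrt(cfg$gamma_fresnel)
  total <- n_spectra * n_cols
  prof <- sample_ri_profile(medium, n_profiles = total)
  fields <- crossprod(prof, kernel)               # total x n_lambda
  inten <- Mod(r_ref + fields)^2
  if (n_cols > 1) {
    grp <- rep(seq_len(n_spectra), each = n_cols)
    inten <- rowsum(inten, grp) / n_cols
  }
  t(inten)                                        # n_lambda x n_spectra
}

#' Spectral image cube
#'
#' Container for a PWS acquisition: backscattered intensity over
#' `(x, y, lambda)`, the wavelength grid, an optional reference/incident image
#' used for normalization, and the pixel size.
#'
#' @param intensity 3-D array `(x, y, lambda)`, non-negative.
#' @param lambda_grid Wavelengths, nm; length must match `dim(intensity)[3]`.
#' @param reference Optional `(x, y)` reference image.
#' @param pixel_size Pixel size, um.
#' @return A `spectral_cube` object.
#' @export
spectral_cube <- function(intensity, lambda_grid, reference = NULL,
                          pixel_size = 0.1) {
  stopifnot(length(dim(intensity)) == 3)
  if (dim(intensity)[3] != length(lambda_grid))
    stop("lambda axis length must match lambda_grid")
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (!is.null(reference))
    stopifnot(all(dim(reference) == dim(intensity)[1:2]))
  structure(list(intensity = intensity, lambda_grid = lambda_grid,
                 reference = reference, pixel_size = pixel_size),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("spectral cube %d x %d px, %d wavelengths (%g-%g nm)%s\n",
              d[1], d[2], d[3], min(x$lambda_grid), max(x$lambda_grid),
              if (is.null(x$reference)) ", no reference" else ", referenced"))
  invisible(x)
}

#' Per-pixel spectral standard deviation map
#'
#' The PWS summary statistic Sigma: for each pixel, the sample standard
#' deviation (n - 1 convention) of the reference-normalized spectrum across
#' wavelengths. With a reference image present the spectrum is divided by the
#' reference first; otherwise raw intensities are used and the result is
#' flagged as carrying uncalibrated units. Pixels with a non-positive
#' reference are masked (NA) rather than propagated.
#'
#' @param cube A [spectral_cube()].
#' @return Matrix of Sigma values with attributes `normalized` (logical) and
#'   `masked` (logical matrix of masked-out pixels).
#' @export
spectral_sigma_map <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (dim(cube$intensity)[3] < 3) stop("need >= 3 wavelengths")
  inten <- cube$intensity
  normalized <- !is.null(cube$reference)
  masked <- matrix(FALSE, dim(inten)[1], dim(inten)[2])
  if (normalized) {
    masked <- !(cube$reference > 0) | is.na(cube$reference)
    ref <- cube$reference
    ref[masked] <- NA
    inten <- sweep(inten, 1:2, ref, "/")
  }
  sig <- apply(inten, 1:2, stats::sd)
  sig[masked] <- NA
  attr(sig, "normalized") <- normalized
  attr(sig, "masked") <- masked
  sig
}

#' Self-calibration of the Sigma-to-D mapping
#'
#' Runs the interference forward model over a grid of packing scalings and
#' records the mean spectral standard deviation per D. The raw curve is
#' regularized by isotonic regression in the direction of its own trend, so
#' the inverse mapping used by [estimate_da_map()] is well defined. (Under
#' this forward model, media whose packing scaling approaches 3 concentrate
#' their density-correlation power below the probed backscattering frequency,
#' so Sigma falls monotonically with D; only the strict monotonicity of the
#' mapping matters for the inversion.) Stored with its seed; regeneration
#' with the same seed is bitwise identical.
#'
#' @param cfg An [optics_config()].
#' @param d_grid Packing-scaling knots, within `[1.7, 3.2]`, length >= 2.
#' @param n_replicates Independent spectra per knot (>= 100).
#' @param rng_seed Integer seed (mandatory for provenance).
#' @param medium_template A [chromatin_medium()] providing every medium
#'   parameter except `D`.
#' @param n_cols Coherence columns per pixel, as in the forward model.
#' @return A `sigma_d_calibration` with fields `d_grid`, `sigma_grid`,
#'   `sigma_raw`, `n_replicates`, `rng_seed`.
#' @export
build_sigma_to_d_calibration <- function(cfg = optics_config(),
                                         d_grid = seq(1.7, 3.2, by = 0.15),
                                         n_replicates = 150,
                                         rng_seed = 1L,
                                         medium_template = chromatin_medium(D = 2),
                                         n_cols = 3) {
  if (length(d_grid) < 2) stop("d_grid must have >= 2 knots to interpolate")
  if (any(d_grid < 1.7 | d_grid > 3.2)) stop("d_grid must lie in [1.7, 3.2]")
  if (n_replicates < 100) stop("n_replicates must be >= 100")
  d_grid <- sort(d_grid)
  set.seed(rng_seed)
  sigma_raw <- vapply(d_grid, function(D) {
    med <- medium_template
    med$D <- D
    spec <- simulate_interference_spectrum(med, cfg, n_spectra = n_replicates,
                                           n_cols = n_cols)
    mean(apply(spec, 2, stats::sd))
  }, numeric(1))
  decreasing <- stats::cor(d_grid, sigma_raw, method = "spearman") < 0
  iso <- stats::isoreg(d_grid, if (decreasing) -sigma_raw else sigma_raw)
  sigma_grid <- if (decreasing) -iso$yf else iso$yf
  structure(list(d_grid = d_grid, sigma_grid = sigma_grid,
                 decreasing = decreasing, sigma_raw = sigma_raw,
                 n_replicates = n_replicates, rng_seed = rng_seed,
                 medium_template = medium_template, n_cols = n_cols),
            class = "sigma_d_calibration")
}

#' @export
print.sigma_d_calibration <- function(x, ...) {
  cat(sprintf(
    "Sigma-D calibration: D in [%.2f, %.2f] (%d knots), %d replicates, seed %d\n",
    min(x$d_grid), max(x$d_grid), length(x$d_grid), x$n_replicates,
    x$rng_seed))
  invisible(x)
}

#' Invert a Sigma map into a packing-scaling map D_a(x, y)
#'
#' Per-pixel piecewise-linear interpolation of the inverse calibration curve.
#' Isotonic flat spots are collapsed keeping the lowest D (ties break toward
#' lower D). Pixels whose Sigma falls outside the calibrated range are clipped
#' to the nearest knot and flagged in `in_range`; they still carry an
#' estimate (the knot value), so region averages are not truncated. Pixels
#' with no estimate at all (masked reference) are FALSE in `valid_mask`.
#' D values are additionally clipped to `[1, 3.5]`.
#'
#' @param sigma_map Matrix of Sigma values (from [spectral_sigma_map()]).
#' @param cal A `sigma_d_calibration`.
#' @return A `damap` object: fields `d_a` (matrix), `valid_mask` (logical
#'   matrix; FALSE where no estimate exists) and `in_range` (logical matrix;
#'   FALSE where Sigma fell outside the calibration and was clipped).
#' @export
estimate_da_map <- function(sigma_map, cal) {
  stopifnot(inherits(cal, "sigma_d_calibration"))
  if (length(sigma_map) == 0) stop("empty sigma map")
  keep <- !duplicated(cal$sigma_grid)        # lowest D per flat spot
  sg <- cal$sigma_grid[keep]
  dg <- cal$d_grid[keep]
  if (length(sg) < 2) stop("degenerate calibration: Sigma curve is flat")
  if (sg[1] > sg[length(sg)]) {              # decreasing curve: sort for approx
    sg <- rev(sg)
    dg <- rev(dg)
  }
  v <- as.vector(sigma_map)
  oor <- !is.na(v) & (v < min(sg) | v > max(sg))
  d <- stats::approx(sg, dg, xout = v, rule = 2)$y
  d <- pmin(pmax(d, 1), 3.5)
  d_a <- matrix(d, nrow(sigma_map), ncol(sigma_map))
  valid <- matrix(!is.na(v), nrow(sigma_map), ncol(sigma_map))
  in_range <- matrix(!is.na(v) & !oor, nrow(sigma_map), ncol(sigma_map))
  d_a[is.na(v)] <- NA
  structure(list(d_a = d_a, valid_mask = valid, in_range = in_range),
            class = "damap")
}

#' @export
print.damap <- function(x, ...) {
  cat(sprintf("D_a map %d x %d px; %.1f%% valid; median D_a = %.2f\n",
              nrow(x$d_a), ncol(x$d_a), 100 * mean(x$valid_mask),
              stats::median(x$d_a[x$valid_mask])))
  invisible(x)
}

#' @export
plot.damap <- function(x, ...) {
  z <- x$d_a
  z[!x$valid_mask] <- NA
  graphics::image(z, useRaster = TRUE, asp = 1, axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "Chromatin packing scaling D_a(x, y)", ...)
  invisible(x)
}

#' Region-averaged packing scaling D_n
#'
#' Arithmetic mean of `D_a` over the intersection of a region with the map's
#' valid mask. With a logical mask a scalar is returned; with an integer label
#' image one mean per positive label (named vector), so bleb regions get their
#' own D_n alongside the nuclear body.
#'
#' @param damap A `damap` from [estimate_da_map()].
#' @param region Logical mask or integer label matrix, same size as the map.
#' @return Named numeric vector (or scalar) of region means.
#' @export
nuclear_average_d <- function(damap, region) {
  stopifnot(inherits(damap, "damap"))
  stopifnot(all(dim(region) == dim(damap$d_a)))
  avg_one <- function(mask) {
    sel <- mask & damap$valid_mask
    if (!any(sel)) stop("region does not intersect the valid mask")
    mean(damap$d_a[sel])
  }
  if (is.logical(region)) return(avg_one(region))
  labs <- sort(unique(region[region > 0]))
  if (length(labs) == 0) stop("region contains no positive labels")
  out <- vapply(labs, function(l) avg_one(region == l), numeric(1))
  names(out) <- as.character(labs)
  out
}
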
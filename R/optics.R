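#' Optical and physical constants for PWS estimators
#'
#' Bundles every instrument and physics constant shared by the static and
#' dynamic PWS estimators: refractive indices, the nucleosome dry density, the
#' illumination wavenumber, numerical apertures, the wavelength grids, and the
#' Gladstone-Dale specific refractive increment.
#'
#' @param n_m Refractive index of a nucleosome (dimensionless).
#' @param n_1 Refractive index of the nucleus.
#' @param n_i Refractive index of the immersion oil.
#' @param rho_0 Dry density of a nucleosome, g/cm^3.
#' @param k Scalar wavenumber of the illumination light, 1/cm.
#' @param gamma_fresnel Fresnel intensity coefficient for normal incidence.
#'   When `NULL` (default) it is derived as
#'   `fresnel_reflectance(n_i, n_1)`, the immersion-oil/nucleus interface.
#' @param na_c Collection numerical aperture.
#' @param na_i Illumination numerical aperture.
#' @param lambda_grid Spectral wavelengths in nm (default 500-700 nm, 2-nm step).
#' @param lambda_dyn Dynamics acquisition wavelength, nm.
#' @param frame_interval Dynamics frame interval, seconds.
#' @param n_water Refractive index of water.
#' @param alpha_gd Gladstone-Dale specific refractive increment, cm^3/g.
#'
#' @return An object of class `optics_config` (a validated list).
#' @examples
#' cfg <- optics_config()
#' cfg$gamma_fresnel   # derived oil/nucleus Fresnel coefficient
#' @export
optics_config <- function(n_m = 1.43, n_1 = 1.37, n_i = 1.518,
                          rho_0 = 0.55, k = 1.57e5,
                          gamma_fresnel = NULL,
                          na_c = 1.49, na_i = 0.52,
                          lambda_grid = seq(500, 700, by = 2),
                          lambda_dyn = 550, frame_interval = 0.050,
                          n_water = 1.334, alpha_gd = 0.18) {
  stopifnot(n_m > 1, n_1 > 1, n_i > 1, n_water > 1)
  stopifnot(rho_0 > 0, k > 0, alpha_gd > 0)
  if (!(na_i > 0 && na_i < na_c))
    stop("numerical apertures must satisfy 0 < na_i < na_c")
  if (length(lambda_grid) < 1 || any(diff(lambda_grid) <= 0))
    stop("lambda_grid must be strictly increasing")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (is.null(gamma_fresnel)) gamma_fresnel <- fresnel_reflectance(n_i, n_1)
  stopifnot(gamma_fresnel > 0, gamma_fresnel < 1)
  structure(list(
    n_m = n_m, n_1 = n_1, n_i = n_i, rho_0 = rho_0, k = k,
    gamma_fresnel = gamma_fresnel, na_c = na_c, na_i = na_i,
    lambda_grid = lambda_grid, lambda_dyn = lambda_dyn,
    frame_interval = frame_interval, n_water = n_water, alpha_gd = alpha_gd
  ), class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("PWS optics configuration\n")
  cat(sprintf("  RI: nucleosome %.3f, nucleus %.3f, oil %.3f, water %.3f\n",
              x$n_m, x$n_1, x$n_i, x$n_water))
  cat(sprintf("  rho_0 = %.2f g/cm^3, k = %.3g 1/cm, Gamma = %.3e\n",
              x$rho_0, x$k, x$gamma_fresnel))
  cat(sprintf("  NA collection %.2f, illumination %.2f\n", x$na_c, x$na_i))
  cat(sprintf("  spectral grid %g-%g nm (%d steps); dynamics %g nm @ %g ms\n",
              min(x$lambda_grid), max(x$lambda_grid), length(x$lambda_grid),
              x$lambda_dyn, 1000 * x$frame_interval))
  invisible(x)
}

#' Read / write an optics configuration as a flat key:value file
#'
#' Plain `key: value` lines (YAML-subset); `lambda_grid` is stored as
#' `min,max,step`. Unknown keys are rejected.
#'
#' @param path File path.
#' @param cfg An `optics_config`.
#' @return `read_optics_config` returns an `optics_config`;
#'   `write_optics_config` returns `path` invisibly.
#' @export
read_optics_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[[1]]), "")
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = ":")), "")
  args <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]
    if (key == "lambda_grid") {
      g <- as.numeric(strsplit(vals[i], ",")[[1]])
      args$lambda_grid <- seq(g[1], g[2], by = g[3])
    } else {
      args[[key]] <- as.numeric(vals[i])
    }
  }
  bad <- setdiff(names(args), names(formals(optics_config)))
  if (length(bad)) stop("unknown optics keys: ", paste(bad, collapse = ", "))
  do.call(optics_config, args)
}

#' @rdname read_optics_config
#' @export
write_optics_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "optics_config"))
  g <- cfg$lambda_grid
  lines <- c(
    sprintf("%s: %.12g", setdiff(names(cfg), "lambda_grid"),
            unlist(cfg[setdiff(names(cfg), "lambda_grid")])),
    sprintf("lambda_grid: %g,%g,%g", min(g), max(g), g[2] - g[1])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Fresnel intensity reflectance at a refractive-index mismatch
#'
#' Normal-incidence intensity reflectance between two media,
#' `((n_a - n_b) / (n_a + n_b))^2`. Symmetric in its arguments and zero for
#' matched media.
#'
#' @param n_a,n_b Refractive indices (> 0); vectorized.
#' @return Reflectance fraction in `[0, 1)`.
#' @examples
#' fresnel_reflectance(1.518, 1.37)  # oil / nucleus, ~2.63e-3
#' @export
fresnel_reflectance <- function(n_a, n_b) {
  if (any(n_a <= 0) || any(n_b <= 0))
    stop("refractive indices must be positive")
  ((n_a - n_b) / (n_a + n_b))^2
}

#' Gladstone-Dale map between chromatin volume concentration and RI
#'
#' The Gladstone-Dale relation models the refractive index of a chromatin
#' volume as linear in its dry-mass concentration:
#' `n = n_water + alpha_gd * rho_0 * phi`, where `phi` is the chromatin volume
#' concentration (CVC) and `alpha_gd * rho_0` the refractive increment of
#' chromatin at nucleosome dry density. `cvc_from_ri` is the exact inverse.
#'
#' @param phi CVC in `[0, 1]`; vectorized.
#' @param ri Refractive index.
#' @param cfg An [optics_config()].
#' @return `ri_from_cvc`: refractive index; `cvc_from_ri`: CVC.
#' @examples
#' ri_from_cvc(0, optics_config())   # pure water, 1.334
#' ri_from_cvc(1, optics_config())   # ~1.433, close to the nucleosome RI
#' @export
ri_from_cvc <- function(phi, cfg = optics_config()) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  cfg$n_water + cfg$alpha_gd * cfg$rho_0 * phi
}

#' @rdname ri_from_cvc
#' @export
cvc_from_ri <- function(ri, cfg = optics_config()) {
  (ri - cfg$n_water) / (cfg$alpha_gd * cfg$rho_0)
}

#' Build a reflectance-to-CVC calibration curve
#'
#' Composes the Gladstone-Dale RI of chromatin with the Fresnel reflectance
#' against the immersion-oil interface to obtain the mean-reflectance curve
#' `R(phi)`. Because `n(phi)` rises from 1.334 towards the oil index 1.518 the
#' mismatch shrinks and `R(phi)` is strictly *decreasing*: the mean
#' backscattered signal is inversely related to chromatin concentration.
#' A user-measured curve (e.g. from an electromagnetic solver) can be supplied
#' through `r_grid`; it must be strictly monotone.
#'
#' @param cfg An [optics_config()].
#' @param phi_grid CVC sample points, at least 5, spanning `[0, 1]`.
#' @param r_grid Optional externally fitted mean reflectance at `phi_grid`.
#' @return A `cvc_calibration` object with fields `phi_grid`, `r_grid`,
#'   `fit_coeffs` (monotone-spline knots) and `provenance`.
#' @export
build_cvc_calibration <- function(cfg = optics_config(),
                                  phi_grid = seq(0, 1, by = 0.05),
                                  r_grid = NULL) {
  if (length(phi_grid) < 5 || min(phi_grid) > 0 || max(phi_grid) < 1)
    stop("phi_grid needs >= 5 points spanning [0, 1]")
  if (any(phi_grid < 0 | phi_grid > 1)) stop("phi_grid must lie in [0, 1]")
  phi_grid <- sort(phi_grid)
  if (is.null(r_grid)) {
    r_grid <- fresnel_reflectance(cfg$n_i, ri_from_cvc(phi_grid, cfg))
    provenance <- "fresnel-analytic"
  } else {
    if (length(r_grid) != length(phi_grid))
      stop("r_grid must match phi_grid in length")
    provenance <- "user-supplied"
  }
  d <- diff(r_grid)
  if (!(all(d > 0) || all(d < 0)))
    stop("calibration reflectance must be strictly monotone in phi")
  # monotone Hermite spline: interpolates the grid exactly, order-preserving
  fit <- stats::splinefun(phi_grid, r_grid, method = "hyman")
  structure(list(phi_grid = phi_grid, r_grid = r_grid,
                 fit_coeffs = list(x = phi_grid, y = r_grid, method = "hyman"),
                 fun = fit, increasing = all(d > 0), provenance = provenance),
            class = "cvc_calibration")
}

#' Evaluate a CVC calibration curve
#' @param cal A `cvc_calibration`.
#' @param phi CVC values.
#' @return Mean reflectance `R(phi)`.
#' @export
reflectance_from_cvc <- function(phi, cal) {
  stopifnot(inherits(cal, "cvc_calibration"))
  cal$fun(phi)
}

#' Invert mean reflectance to chromatin volume concentration
#'
#' Finds the unique `phi` with `R(phi) = r_mean` on the calibration curve.
#' Values outside the calibration range are clipped to the nearer endpoint and
#' flagged through the `out_of_range` attribute.
#'
#' @param r_mean Mean reflectance fraction(s).
#' @param cal A `cvc_calibration` from [build_cvc_calibration()].
#' @return CVC in `[0, 1]`, with attribute `out_of_range` (logical vector).
#' @export
cvc_from_reflectance <- function(r_mean, cal) {
  if (!inherits(cal, "cvc_calibration")) stop("empty or invalid calibration")
  rng <- range(cal$r_grid)
  oor <- r_mean < rng[1] | r_mean > rng[2]
  phi <- vapply(r_mean, function(r) {
    if (is.na(r)) return(NA_real_)
    if (r <= rng[1]) return(cal$phi_grid[which.min(cal$r_grid)])
    if (r >= rng[2]) return(cal$phi_grid[which.max(cal$r_grid)])
    stats::uniroot(function(p) cal$fun(p) - r,
                   lower = 0, upper = 1, tol = 1e-10)$root
  }, numeric(1))
  attr(phi, "out_of_range") <- oor
  phi
}

#' @export
print.cvc_calibration <- function(x, ...) {
  cat(sprintf("CVC calibration (%s): %d knots, R(phi) %s from %.3e to %.3e\n",
              x$provenance, length(x$phi_grid),
              if (x$increasing) "increasing" else "decreasing",
              x$fun(0), x$fun(1)))
  invisible(x)
}

#' Normative variance pre-factor linking intensity variance to moving mass
#'
#' The fractional moving mass (FMM) estimator divides the temporal variance of
#' the reference-normalized intensity by a pre-factor `A` with units 1/g, so
#' that `Var_t[I/I0] = A * m_f`. The package defines `A` once, from a weak
#' (Born) scattering budget for mobile macromolecular clusters inside the
#' coherence volume, and uses the same constant in the synthetic generator and
#' the estimator:
#'
#' `A = 2 * Gamma * k^2 * (n_m - n_1)^2 * L_dof / (A_coh * rho_0)`
#'
#' with `L_dof = n_1 * lambda_dyn / NA_i^2` the illumination depth of field and
#' `A_coh = pi * (lambda_dyn / (2 NA_c))^2` the transverse coherence (Airy)
#' area. Interference of the moving-cluster field with the reference reflection
#' `Gamma` makes the variance linear in the moving mass
#' `m_f = rho_0 * V_cm * phi_mobile`.
#'
#' @param cfg An [optics_config()].
#' @return Scalar pre-factor, 1/g.
#' @export
fmm_prefactor <- function(cfg = optics_config()) {
  lam_cm <- cfg$lambda_dyn * 1e-7            # nm -> cm
  l_dof <- cfg$n_1 * lam_cm / cfg$na_i^2     # cm
  a_coh <- pi * (lam_cm / (2 * cfg$na_c))^2  # cm^2
  2 * cfg$gamma_fresnel * cfg$k^2 * (cfg$n_m - cfg$n_1)^2 * l_dof /
    (a_coh * cfg$rho_0)
}
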
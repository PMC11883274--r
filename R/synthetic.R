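#' Scenario specification for synthetic ground truth
#'
#' Bundles one condition's per-region ground truth for every modality: packing
#' scaling, chromatin volume concentration, fractional moving mass, effective
#' diffusion, and SMLM nanodomain geometry. Generators are pure functions of
#' `(spec, seed)`.
#'
#' @param condition Condition label, e.g. `"control"`, `"lamin-depleted"`,
#'   `"hdac-inhibited"`.
#' @param d_body,d_bleb Packing scaling per region.
#' @param phi_body,phi_bleb Mean CVC per region.
#' @param fmm_body,fmm_bleb Fractional moving mass ground truth, grams.
#' @param de_body,de_bleb Effective diffusion ground truth, um^2/s.
#' @param domain_radius_body,domain_radius_bleb Nanodomain full radius, nm
#'   (member events scatter with Gaussian sigma = radius / 2, so ~95% of a
#'   domain's events fall within the stated radius).
#' @param n_domains_body,n_domains_bleb Domain counts per region.
#' @param domain_occupancy Expected localizations per domain at the 40-nm
#'   reference radius; actual per-domain counts scale with `(radius / 40)^2`
#'   so the labeling surface density is constant across domain sizes.
#' @param background_density Uniform background events per um^2.
#' @param mean_uncertainty Mean localization uncertainty, nm.
#' @param cvc_ramp Fractional linear CVC drift over one acquisition.
#' @param n_cells Cells per condition.
#' @param rng_seed Mandatory integer seed.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(condition = "control",
                          d_body = 2.6, d_bleb = 2.2,
                          phi_body = 0.35, phi_bleb = 0.25,
                          fmm_body = 2.0e-19, fmm_bleb = 1.2e-19,
                          de_body = 2e-3, de_bleb = 3e-3,
                          domain_radius_body = 120, domain_radius_bleb = 40,
                          n_domains_body = 15, n_domains_bleb = 8,
                          domain_occupancy = 30,
                          background_density = 2,
                          mean_uncertainty = 25,
                          cvc_ramp = 0.05,
                          n_cells = 10, rng_seed = 1L) {
  vals <- c(d_body, d_bleb, phi_body, phi_bleb, fmm_body, fmm_bleb,
            de_body, de_bleb, domain_radius_body, domain_radius_bleb,
            n_domains_body, n_domains_bleb, domain_occupancy,
            mean_uncertainty)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all ground-truth values must be positive and finite")
  if (is.null(rng_seed)) stop("rng_seed is mandatory")
  structure(list(condition = condition, d_body = d_body, d_bleb = d_bleb,
                 phi_body = phi_body, phi_bleb = phi_bleb,
                 fmm_body = fmm_body, fmm_bleb = fmm_bleb,
                 de_body = de_body, de_bleb = de_bleb,
                 domain_radius_body = domain_radius_body,
                 domain_radius_bleb = domain_radius_bleb,
                 n_domains_body = n_domains_body,
                 n_domains_bleb = n_domains_bleb,
                 domain_occupancy = domain_occupancy,
                 background_density = background_density,
                 mean_uncertainty = mean_uncertainty,
                 cvc_ramp = cvc_ramp, n_cells = n_cells,
                 rng_seed = as.integer(rng_seed)),
            class = "scenario_spec")
}

#' Packaged paper-like scenario bundle
#'
#' Three conditions encoding the qualitative contrasts the estimators are
#' expected to resolve: blebs carry lower packing scaling, moving mass and CVC
#' than their nuclear bodies in every condition; lamin-depletion-like blebs
#' retain higher D and FMM than enzyme-inhibition-like blebs; the
#' HDAC-inhibition-like condition raises body CVC while suppressing bleb CVC
#' (so its bleb-to-body ratio drops below control); bleb nanodomains are
#' smaller and sparser than body nanodomains. Effect sizes are set to the
#' qualitative direction, not to any instrument-specific magnitude.
#'
#' @param rng_seed Base seed; each condition offsets it.
#' @return Named list of [scenario_spec()] objects.
#' @export
paper_like_scenarios <- function(rng_seed = 1L) {
  list(
    control = scenario_spec("control",
                            d_body = 2.6, d_bleb = 2.2,
                            phi_body = 0.35, phi_bleb = 0.25,
                            fmm_body = 2.0e-19, fmm_bleb = 1.2e-19,
                            rng_seed = rng_seed),
    `lamin-depleted` = scenario_spec("lamin-depleted",
                                     d_body = 2.55, d_bleb = 2.35,
                                     phi_body = 0.33, phi_bleb = 0.24,
                                     fmm_body = 2.2e-19, fmm_bleb = 1.6e-19,
                                     rng_seed = rng_seed + 1L),
    `hdac-inhibited` = scenario_spec("hdac-inhibited",
                                     d_body = 2.7, d_bleb = 2.0,
                                     phi_body = 0.45, phi_bleb = 0.15,
                                     fmm_body = 1.8e-19, fmm_bleb = 0.8e-19,
                                     rng_seed = rng_seed + 2L)
  )
}

#' Synthetic nucleus + bleb scene
#'
#' Elliptical nucleus body (label 1) with a circular bleb (label 2) attached
#' through a neck of configurable width, and an optional detached micronucleus
#' (label -1). With `neck_width = 0` the protrusion is emitted detached and
#' labeled as a micronucleus, matching the connectivity definition of a bleb
#' (a herniation still connected to the nuclear body).
#'
#' @param nx,ny Frame size, px.
#' @param pixel_size Pixel size, um.
#' @param a,b Nucleus semi-axes, px.
#' @param bleb_radius Bleb radius, px; must be < the nucleus minor semi-axis.
#' @param neck_width Neck width, px (0 = detached).
#' @param micronucleus Add a detached micronucleus circle.
#' @param micronucleus_radius Radius, px.
#' @param ruptured Mark the scene as ruptured (carried as a flag; rupture is a
#'   visual call upstream, not an image computation).
#' @param rng_seed Optional seed jittering the nucleus center by up to 1 px.
#' @return A `region_scene`: `label_image`, `pairing` (bleb label to parent
#'   body label), `pixel_size`, `ruptured`, `params`.
#' @export
make_scene <- function(nx = 64, ny = 64, pixel_size = 0.1,
                       a = 18, b = 13, bleb_radius = 6, neck_width = 3,
                       micronucleus = FALSE, micronucleus_radius = 4,
                       ruptured = FALSE, rng_seed = NULL) {
  if (bleb_radius >= b) stop("bleb radius must be smaller than the nucleus minor semi-axis")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  jit <- if (is.null(rng_seed)) c(0, 0) else stats::runif(2, -1, 1)
  cx <- nx / 2 - a / 3 + jit[1]
  cy <- ny / 2 + jit[2]
  gx <- matrix(seq_len(nx), nx, ny)
  gy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  lab <- matrix(0L, nx, ny)
  body <- ((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1
  lab[body] <- 1L
  attached <- neck_width > 0
  bx <- cx + a + bleb_radius - (if (attached) 1 else -2)
  bleb <- (gx - bx)^2 + (gy - cy)^2 <= bleb_radius^2
  if (attached) {
    neck <- gx >= cx + a - 2 & gx <= bx & abs(gy - cy) <= neck_width / 2
    bleb <- bleb | neck
  }
  bleb_lab <- if (attached) 2L else -1L
  lab[bleb & !body] <- bleb_lab
  if (micronucleus) {
    mx <- cx
    my <- cy - b - micronucleus_radius - 3
    mn <- (gx - mx)^2 + (gy - my)^2 <= micronucleus_radius^2
    lab[mn & lab == 0L] <- if (any(lab == -1L)) -2L else -1L
  }
  pairing <- if (attached) c(`2` = 1L) else integer(0)
  structure(list(label_image = lab, pairing = pairing,
                 pixel_size = pixel_size, ruptured = ruptured,
                 params = list(nx = nx, ny = ny, a = a, b = b, cx = cx,
                               cy = cy, bleb_radius = bleb_radius,
                               neck_width = neck_width,
                               bleb_center = c(bx, cy))),
            class = "region_scene")
}

#' @export
print.region_scene <- function(x, ...) {
  lab <- x$label_image
  cat(sprintf(
    "region scene %d x %d px (%.2f um/px): body %d px, blebs %d, micronuclei %d%s\n",
    nrow(lab), ncol(lab), x$pixel_size, sum(lab == 1),
    length(unique(lab[lab >= 2])), length(unique(lab[lab < 0])),
    if (x$ruptured) " [ruptured]" else ""))
  invisible(x)
}

# per-pixel region parameter lookup: body value for label 1, bleb value for
# labels >= 2; NA elsewhere
region_values <- function(scene, body_val, bleb_val) {
  lab <- scene$label_image
  out <- matrix(NA_real_, nrow(lab), ncol(lab))
  out[lab == 1] <- body_val
  out[lab >= 2] <- bleb_val
  out
}

#' Synthetic spectral cube for a scene
#'
#' Draws every in-region pixel's interference spectrum from the fractal-medium
#' forward model at that region's packing scaling; background pixels carry the
#' flat reference reflectance. The reference image is unity, so intensities
#' are in reflectance units. Ground truth is attached as the `truth`
#' attribute.
#'
#' @param scene A [make_scene()] result.
#' @param spec A [scenario_spec()].
#' @param cfg An [optics_config()].
#' @param medium_template A [chromatin_medium()] supplying the non-D medium
#'   parameters.
#' @param rng_seed Integer seed.
#' @return A [spectral_cube()] with attribute `truth`.
#' @export
synth_spectral_cube <- function(scene, spec, cfg = optics_config(),
                                medium_template = chromatin_medium(D = 2),
                                rng_seed = 1L) {
  set.seed(rng_seed)
  lab <- scene$label_image
  nl <- length(cfg$lambda_grid)
  inten <- array(cfg$gamma_fresnel, dim = c(nrow(lab), ncol(lab), nl))
  dmap <- region_values(scene, spec$d_body, spec$d_bleb)
  for (D in unique(stats::na.omit(as.vector(dmap)))) {
    sel <- which(!is.na(dmap) & dmap == D)
    med <- medium_template
    med$D <- D
    sp <- simulate_interference_spectrum(med, cfg, n_spectra = length(sel))
    for (j in seq_len(nl)) {
      slice <- inten[, , j]
      slice[sel] <- sp[j, ]
      inten[, , j] <- slice
    }
  }
  cube <- spectral_cube(inten, cfg$lambda_grid,
                        reference = matrix(1, nrow(lab), ncol(lab)),
                        pixel_size = scene$pixel_size)
  attr(cube, "truth") <- list(d_body = spec$d_body, d_bleb = spec$d_bleb,
                              rng_seed = rng_seed)
  cube
}

#' Synthetic temporal cube for a scene
#'
#' Each in-region pixel carries an exact discrete Ornstein-Uhlenbeck (AR(1))
#' fluctuation with stationary variance `fmm_prefactor(cfg) * fmm_true` and
#' autocorrelation `exp(-tau / tau_d)`, `tau_d = 1 / (4 k_med^2 d_e_true)` --
#' so both dynamics estimators have closed-form ground truth. A slow linear
#' CVC ramp modulates the mean reflectance through the CVC calibration. The
#' reference image is flat at `i0_counts`; intensities are
#' `i0 * (R(phi(t)) + fluctuation)`.
#'
#' @param scene A [make_scene()] result.
#' @param spec A [scenario_spec()].
#' @param cfg An [optics_config()].
#' @param n_frames Number of frames (default 300, i.e. 15 s at 50 ms).
#' @param i0_counts Reference level in detector counts.
#' @param cal Optional CVC calibration (built from `cfg` when NULL).
#' @param rng_seed Integer seed.
#' @return A [temporal_cube()] with attribute `truth` (per-region fmm, d_e,
#'   tau_d, phi trace).
#' @export
synth_temporal_cube <- function(scene, spec, cfg = optics_config(),
                                n_frames = 300, i0_counts = 1000,
                                cal = NULL, rng_seed = 1L) {
  set.seed(rng_seed)
  if (is.null(cal)) cal <- build_cvc_calibration(cfg)
  lab <- scene$label_image
  npx <- length(lab)
  dt <- cfg$frame_interval
  lam_um <- cfg$lambda_dyn / 1000
  k_med <- 2 * pi * cfg$n_1 / lam_um
  de_band <- c(3.5e-5, 0.065)
  de <- c(body = spec$de_body, bleb = spec$de_bleb)
  if (any(de < de_band[1] | de > de_band[2])) {
    warning("d_e ground truth outside the measurable band; clipping")
    de <- pmin(pmax(de, de_band[1]), de_band[2])
  }
  tau_d <- 1 / (4 * k_med^2 * de)
  A <- fmm_prefactor(cfg)
  sd_map <- sqrt(A * region_values(scene, spec$fmm_body, spec$fmm_bleb))
  sd_map[is.na(sd_map)] <- 0
  phi_ar <- region_values(scene, exp(-dt / tau_d["body"]),
                          exp(-dt / tau_d["bleb"]))
  phi_ar[is.na(phi_ar)] <- 0
  sdv <- as.vector(sd_map)
  arv <- as.vector(phi_ar)
  # slow linear CVC drift per region, fractional amplitude cvc_ramp
  tfrac <- (seq_len(n_frames) - 1) / max(1, n_frames - 1)
  phi0 <- region_values(scene, spec$phi_body, spec$phi_bleb)
  inten <- array(0, dim = c(nrow(lab), ncol(lab), n_frames))
  x <- stats::rnorm(npx) * sdv
  innov_sd <- sdv * sqrt(1 - arv^2)
  phi0v <- as.vector(phi0)
  base_r <- cal$fun(pmin(pmax(ifelse(is.na(phi0v), NA, phi0v), 0), 1))
  for (tt in seq_len(n_frames)) {
    if (tt > 1) x <- arv * x + stats::rnorm(npx) * innov_sd
    phit <- phi0v * (1 + spec$cvc_ramp * tfrac[tt])
    r <- ifelse(is.na(phi0v), cfg$gamma_fresnel,
                cal$fun(pmin(pmax(phit, 0), 1)))
    inten[, , tt] <- matrix((r + x) * i0_counts, nrow(lab), ncol(lab))
  }
  cube <- temporal_cube(inten, i0 = matrix(i0_counts, nrow(lab), ncol(lab)),
                        frame_interval = dt, lambda_dyn = cfg$lambda_dyn)
  attr(cube, "truth") <- list(
    fmm = c(body = spec$fmm_body, bleb = spec$fmm_bleb),
    de = de, tau_d = tau_d,
    phi0 = c(body = spec$phi_body, bleb = spec$phi_bleb),
    cvc_ramp = spec$cvc_ramp, rng_seed = rng_seed)
  cube
}

#' Synthetic localization table for a scene
#'
#' Places nanodomain centers uniformly within each region, draws each domain's
#' member events as Gaussian scatter (sigma = half the region's domain
#' radius) plus localization noise, and sprinkles uniform background events
#' over the frame. Per-domain occupancy scales with domain area so the
#' labeling surface density is constant.
#' Per-event uncertainties are drawn around `mean_uncertainty`. Ground-truth
#' membership is attached as the `truth` attribute.
#'
#' @param scene A [make_scene()] result.
#' @param spec A [scenario_spec()].
#' @param rng_seed Integer seed.
#' @return A [localization_table()] with attribute `truth` (domain ids,
#'   centers, region of origin).
#' @export
synth_localizations <- function(scene, spec, rng_seed = 1L) {
  set.seed(rng_seed)
  lab <- scene$label_image
  px <- scene$pixel_size * 1000  # nm per px
  draw_region <- function(region_lab, n_domains, radius, tag) {
    cells <- which(lab == region_lab, arr.ind = TRUE)
    if (nrow(cells) < n_domains)
      stop("requested domain count infeasible for region area")
    pick <- cells[sample.int(nrow(cells), n_domains), , drop = FALSE]
    centers <- (pick - stats::runif(length(pick))) * px
    do.call(rbind, lapply(seq_len(n_domains), function(i) {
      n <- stats::rpois(1, spec$domain_occupancy * (radius / 40)^2)
      if (n == 0) return(NULL)
      u <- pmax(5, stats::rnorm(n, spec$mean_uncertainty,
                                spec$mean_uncertainty / 5))
      data.frame(
        x = centers[i, 1] + stats::rnorm(n, 0, radius / 2) +
          stats::rnorm(n, 0, u),
        y = centers[i, 2] + stats::rnorm(n, 0, radius / 2) +
          stats::rnorm(n, 0, u),
        uncertainty = u, domain = paste0(tag, i), region = tag,
        cx = unname(centers[i, 1]), cy = unname(centers[i, 2]),
        row.names = NULL)
    }))
  }
  ev <- rbind(draw_region(1L, spec$n_domains_body, spec$domain_radius_body,
                          "body"),
              if (any(lab >= 2))
                draw_region(2L, spec$n_domains_bleb, spec$domain_radius_bleb,
                            "bleb"))
  area_um2 <- nrow(lab) * ncol(lab) * scene$pixel_size^2
  n_bg <- stats::rpois(1, spec$background_density * area_um2)
  if (n_bg > 0) {
    u <- pmax(5, stats::rnorm(n_bg, spec$mean_uncertainty,
                              spec$mean_uncertainty / 5))
    ev <- rbind(ev, data.frame(
      x = stats::runif(n_bg, 0, nrow(lab) * px),
      y = stats::runif(n_bg, 0, ncol(lab) * px),
      uncertainty = u, domain = "background", region = "background",
      cx = NA_real_, cy = NA_real_))
  }
  locs <- localization_table(ev$x, ev$y, ev$uncertainty)
  attr(locs, "truth") <- ev[, c("domain", "region", "cx", "cy")]
  locs
}

#' Synthetic deformation records for morphometry
#'
#' Draws per-nucleus deformation classes for a set of fields of view with
#' given per-class probabilities, for exercising [bleb_frequency()] and the
#' statistical battery against known rates.
#'
#' @param n_fov Number of fields of view.
#' @param nuclei_per_fov Nuclei per field of view.
#' @param p_bleb,p_micronucleus,p_rupture Per-nucleus class probabilities
#'   (independent draws; bleb and micronucleus may co-occur).
#' @param condition Condition label.
#' @param rng_seed Integer seed.
#' @return Data frame: `condition`, `fov_id`, `cell_id`, `blebbed`,
#'   `micronucleated`, `ruptured`, `class`, `n_blebs`.
#' @export
synth_deformation_records <- function(n_fov, nuclei_per_fov, p_bleb = 0.06,
                                      p_micronucleus = 0.02, p_rupture = 0.01,
                                      condition = "control", rng_seed = 1L) {
  set.seed(rng_seed)
  rows <- lapply(seq_len(n_fov), function(f) {
    n <- nuclei_per_fov
    blebbed <- stats::runif(n) < p_bleb
    micro <- stats::runif(n) < p_micronucleus
    rupt <- stats::runif(n) < p_rupture
    data.frame(condition = condition, fov_id = f, cell_id = seq_len(n),
               blebbed = blebbed, micronucleated = micro, ruptured = rupt,
               class = ifelse(rupt, "ruptured",
                              ifelse(blebbed, "blebbed",
                                     ifelse(micro, "micronucleated",
                                            "intact"))),
               n_blebs = as.integer(blebbed))
  })
  do.call(rbind, rows)
}
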
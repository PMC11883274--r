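#' End-to-end synthetic pipeline: one tidy row per cell
#'
#' Generates every modality for each cell of each scenario (scene, spectral
#' cube, temporal cube, localization table), runs all estimators, and joins
#' the results into a single per-cell table: nuclear and bleb packing scaling,
#' fractional moving mass, effective diffusion, mean CVC and bleb-to-body
#' ratio, nanodomain counts and median sizes, and the deformation class.
#'
#' @param scenarios Named list of [scenario_spec()] objects (default the
#'   packaged paper-like bundle).
#' @param cfg An [optics_config()].
#' @param sigma_cal A `sigma_d_calibration`; built once with
#'   `calibration_seed` when NULL.
#' @param cvc_cal A `cvc_calibration`; analytic default when NULL.
#' @param n_cells Cells per condition (default: each scenario's own
#'   `n_cells`).
#' @param nx,ny Scene size, px.
#' @param n_frames Dynamics frames per cell.
#' @param rng_seed Base seed; per-cell seeds are derived from it.
#' @param calibration_seed Seed for the self-calibration sweep.
#' @return Data frame, one row per cell.
#' @export
run_pipeline <- function(scenarios = paper_like_scenarios(),
                         cfg = optics_config(),
                         sigma_cal = NULL, cvc_cal = NULL,
                         n_cells = NULL, nx = 64, ny = 64, n_frames = 300,
                         rng_seed = 1L, calibration_seed = 99L) {
  if (is.null(sigma_cal))
    sigma_cal <- build_sigma_to_d_calibration(cfg, rng_seed = calibration_seed)
  if (is.null(cvc_cal)) cvc_cal <- build_cvc_calibration(cfg)
  rows <- list()
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    nc <- if (is.null(n_cells)) sc$n_cells else n_cells
    for (cell in seq_len(nc)) {
      seed <- sc$rng_seed + 1000L * cell + rng_seed
      cell_id <- sprintf("%s_c%02d", sc$condition, cell)
      scene <- make_scene(nx = nx, ny = ny, rng_seed = seed)
      lab <- scene$label_image
      body <- lab == 1
      bleb <- lab >= 2

      cube_s <- synth_spectral_cube(scene, sc, cfg, rng_seed = seed + 1L)
      dam <- estimate_da_map(spectral_sigma_map(cube_s), sigma_cal)
      d_body <- nuclear_average_d(dam, body)
      d_bleb <- if (any(bleb & dam$valid_mask))
        nuclear_average_d(dam, bleb) else NA_real_

      cube_t <- synth_temporal_cube(scene, sc, cfg, n_frames = n_frames,
                                    cal = cvc_cal, rng_seed = seed + 2L)
      dyn <- summarize_dynamics(cube_t, lab, cfg, cal = cvc_cal,
                                cell_id = cell_id)
      dyn_body <- dyn[dyn$region == "body", ]
      dyn_bleb <- dyn[dyn$region == "bleb", ]

      locs <- synth_localizations(scene, sc, rng_seed = seed + 3L)
      domains <- call_nanodomains(locs)
      reg <- summarize_domains_by_region(domains, scene)

      cls <- classify_deformations(scene, cell_id = cell_id)
      rows[[cell_id]] <- data.frame(
        condition = sc$condition, cell_id = cell_id, class = cls$class,
        n_blebs = cls$n_blebs,
        d_n_body = d_body, d_n_bleb = d_bleb,
        fmm_body_g = dyn_body$fmm_g[1],
        fmm_bleb_g = if (nrow(dyn_bleb)) dyn_bleb$fmm_g[1] else NA_real_,
        de_body_um2_s = dyn_body$de_um2_s[1],
        de_bleb_um2_s = if (nrow(dyn_bleb)) dyn_bleb$de_um2_s[1] else
          NA_real_,
        cvc_body = dyn_body$cvc_mean[1],
        cvc_bleb = if (nrow(dyn_bleb)) dyn_bleb$cvc_mean[1] else NA_real_,
        cvc_ratio = if (nrow(dyn_bleb)) dyn_bleb$cvc_mean[1] /
          dyn_body$cvc_mean[1] else NA_real_,
        n_domains_body = unname(reg$counts["body"]),
        n_domains_bleb = unname(reg$counts["bleb"]),
        domain_size_body_nm = if (length(reg$sizes$body))
          stats::median(reg$sizes$body) else NA_real_,
        domain_size_bleb_nm = if (length(reg$sizes$bleb))
          stats::median(reg$sizes$bleb) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
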
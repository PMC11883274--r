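#' Classify nuclear deformations from a labeled scene
#'
#' A bleb is a herniation still 4-connected to the nuclear body; a
#' disconnected component of similar size to the blebs (area within a
#' configurable window around the median bleb area) is a micronucleus; a
#' rupture is accepted only as an upstream flag (a visual call, not an image
#' computation). Labels: 1 = body, >= 2 = candidate herniations, negative =
#' detached candidates, 0 = background.
#'
#' @param scene A `region_scene` or a plain integer label matrix.
#' @param cell_id Cell identifier for the output row.
#' @param micronucleus_window Relative area window (x median bleb area) for
#'   calling detached components micronuclei; with no bleb present the window
#'   check is skipped.
#' @return One-row data frame: `cell_id`, `class` (intact / blebbed /
#'   micronucleated / ruptured), `blebbed`, `micronucleated`, `ruptured`,
#'   `n_blebs`, `bleb_area_px`, `micronucleus_area_px`.
#' @export
classify_deformations <- function(scene, cell_id = "cell1",
                                  micronucleus_window = c(0.25, 4)) {
  ruptured <- FALSE
  if (inherits(scene, "region_scene")) {
    ruptured <- isTRUE(scene$ruptured)
    lab <- scene$label_image
  } else lab <- scene
  if (!any(lab != 0)) stop("empty label image")
  if (!any(lab == 1)) stop("no nucleus body (label 1) present")
  body <- lab == 1
  touches_body <- function(mask) {
    n <- nrow(mask); m <- ncol(mask)
    any(mask[-1, ] & body[-n, ]) || any(mask[-n, ] & body[-1, ]) ||
      any(mask[, -1] & body[, -m]) || any(mask[, -m] & body[, -1])
  }
  cand <- setdiff(unique(as.vector(lab)), c(0L, 1L))
  bleb_areas <- numeric(0)
  detached_areas <- numeric(0)
  for (l in cand) {
    mask <- lab == l
    if (touches_body(mask)) bleb_areas <- c(bleb_areas, sum(mask))
    else detached_areas <- c(detached_areas, sum(mask))
  }
  micro_areas <- if (length(detached_areas) == 0) numeric(0)
  else if (length(bleb_areas) == 0) detached_areas
  else {
    ref <- stats::median(bleb_areas)
    detached_areas[detached_areas >= micronucleus_window[1] * ref &
                     detached_areas <= micronucleus_window[2] * ref]
  }
  blebbed <- length(bleb_areas) > 0
  micronucleated <- length(micro_areas) > 0
  cls <- if (ruptured) "ruptured" else if (blebbed) "blebbed" else
    if (micronucleated) "micronucleated" else "intact"
  data.frame(cell_id = cell_id, class = cls, blebbed = blebbed,
             micronucleated = micronucleated, ruptured = ruptured,
             n_blebs = length(bleb_areas),
             bleb_area_px = if (blebbed) sum(bleb_areas) else 0,
             micronucleus_area_px = if (micronucleated) sum(micro_areas)
             else 0)
}

#' Per-field-of-view bleb frequency
#'
#' Percentage of blebbed nuclei per field of view and the condition-level
#' mean with standard error over fields of view (the field of view is the
#' replicate unit for frequency-style statistics). Fields with zero nuclei
#' are excluded and listed in the `excluded` attribute.
#'
#' @param records Data frame with columns `fov_id`, `blebbed` and optionally
#'   `condition`.
#' @return List: `per_fov` (data frame `condition`, `fov_id`, `n_nuclei`,
#'   `pct_blebbed`) and `summary` (per condition: `mean_pct`, `sem_pct`,
#'   `n_fov`), with attribute `excluded`.
#' @export
bleb_frequency <- function(records) {
  stopifnot(all(c("fov_id", "blebbed") %in% names(records)))
  if (is.null(records$condition)) records$condition <- "all"
  key <- interaction(records$condition, records$fov_id, drop = TRUE)
  per <- do.call(rbind, lapply(split(records, key), function(s) {
    data.frame(condition = s$condition[1], fov_id = s$fov_id[1],
               n_nuclei = nrow(s),
               pct_blebbed = 100 * sum(s$blebbed) / nrow(s))
  }))
  excluded <- character(0)
  empty <- per$n_nuclei == 0
  if (any(empty)) {
    excluded <- sprintf("fov %s: zero nuclei", per$fov_id[empty])
    per <- per[!empty, , drop = FALSE]
  }
  if (nrow(per) == 0) stop("no field of view with nuclei")
  summ <- do.call(rbind, lapply(split(per, per$condition), function(s) {
    data.frame(condition = s$condition[1], n_fov = nrow(s),
               mean_pct = mean(s$pct_blebbed),
               sem_pct = if (nrow(s) >= 2)
                 stats::sd(s$pct_blebbed) / sqrt(nrow(s)) else NA_real_)
  }))
  rownames(per) <- rownames(summ) <- NULL
  out <- list(per_fov = per, summary = summ)
  attr(out, "excluded") <- excluded
  out
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated intensity over the cell mask - cell area x mean
#' background intensity`, the standard background-corrected integrated
#' density.
#'
#' @param image Intensity matrix.
#' @param cell_mask Logical mask of the cell.
#' @param background_mask Logical mask of a background region; must be
#'   disjoint from `cell_mask` and non-empty.
#' @return Scalar CTCF value.
#' @export
ctcf <- function(image, cell_mask, background_mask) {
  stopifnot(all(dim(image) == dim(cell_mask)),
            all(dim(image) == dim(background_mask)))
  if (any(cell_mask & background_mask))
    stop("cell and background masks must be disjoint")
  if (!any(background_mask)) stop("empty background region")
  sum(image[cell_mask]) - sum(cell_mask) * mean(image[background_mask])
}
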
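#' Localization table constructor
#'
#' Validates an SMLM localization set: planar coordinates and per-event
#' localization uncertainty, all in nanometres.
#'
#' @param x,y Coordinates, nm; must be finite.
#' @param uncertainty Per-event localization uncertainty, nm; must be > 0.
#' @param frame Acquisition frame index (optional).
#' @param intensity Optional event intensity.
#' @return A data frame of class `localization_table`.
#' @export
localization_table <- function(x, y, uncertainty, frame = NA_integer_,
                               intensity = NULL) {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  if (any(!is.finite(uncertainty)) || any(uncertainty <= 0))
    stop("uncertainty must be positive and finite")
  df <- data.frame(x = x, y = y, uncertainty = uncertainty, frame = frame)
  if (!is.null(intensity)) df$intensity <- intensity
  class(df) <- c("localization_table", "data.frame")
  df
}

#' Read a ThunderSTORM-style localization CSV
#'
#' Expects a header with columns named `x [nm]`, `y [nm]`,
#' `uncertainty [nm]` and `frame` (order free, extra columns kept as-is);
#' comma or semicolon delimiters are auto-detected.
#'
#' @param path CSV file path.
#' @return A [localization_table()].
#' @export
read_locs_csv <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr(";", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "\"")
  need <- c("x [nm]", "y [nm]", "uncertainty [nm]")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  localization_table(x = df[["x [nm]"]], y = df[["y [nm]"]],
                     uncertainty = df[["uncertainty [nm]"]],
                     frame = if ("frame" %in% names(df)) df[["frame"]] else
                       NA_integer_)
}

#' Write a localization table in ThunderSTORM column convention
#' @param locs A [localization_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_locs_csv <- function(locs, path) {
  out <- data.frame(`x [nm]` = locs$x, `y [nm]` = locs$y,
                    `uncertainty [nm]` = locs$uncertainty,
                    frame = locs$frame, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Density-based clustering of localizations (DBSCAN)
#'
#' Classic DBSCAN on Euclidean planar coordinates: a point is a core point
#' when its eps-neighborhood (self-inclusive) holds at least `min_pts` events;
#' clusters are the density-connected components of core points plus their
#' border points. Border points reachable from several clusters join the
#' cluster whose core point claims them first in ascending input order, so
#' labels are deterministic for a given input order.
#'
#' @param locs A [localization_table()] (or data frame with `x`, `y`).
#' @param eps Neighborhood radius, nm (default 50).
#' @param min_pts Minimum neighborhood size for a core point (default 3).
#' @return Integer vector of cluster labels, 0 for noise.
#' @export
cluster_localizations <- function(locs, eps = 50, min_pts = 3) {
  if (eps <= 0) stop("eps must be > 0")
  if (min_pts < 1) stop("min_pts must be >= 1")
  n <- nrow(locs)
  if (n < 1) stop("need at least one localization")
  pts <- cbind(locs$x, locs$y)
  eps2 <- eps^2
  # eps-grid spatial binning: candidate neighbors come from the 3 x 3
  # adjacent bins only, so cost scales with local density, not n^2
  cx <- floor(pts[, 1] / eps)
  cy <- floor(pts[, 2] / eps)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  nbrs <- vector("list", n)
  for (members in cells) {
    p0 <- members[1]
    cand_keys <- as.vector(outer(cx[p0] + (-1:1), cy[p0] + (-1:1), paste))
    cand <- unlist(cells[cand_keys], use.names = FALSE)
    d2 <- outer(pts[members, 1], pts[cand, 1], "-")^2 +
      outer(pts[members, 2], pts[cand, 2], "-")^2
    hit <- d2 <= eps2
    nbrs[members] <- lapply(seq_along(members),
                            function(i) cand[hit[i, ]])
  }
  core <- lengths(nbrs) >= min_pts
  labels <- integer(n)          # 0 = noise / unassigned
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- integer(n)
    queue[1L] <- i
    head <- 1L
    tail <- 1L
    visited[i] <- TRUE
    labels[i] <- cl
    while (head <= tail) {
      p <- queue[head]
      head <- head + 1L
      nb <- nbrs[[p]]
      labels[nb[labels[nb] == 0L]] <- cl
      grow <- nb[core[nb] & !visited[nb]]
      if (length(grow)) {
        visited[grow] <- TRUE
        queue[tail + seq_along(grow)] <- grow
        tail <- tail + length(grow)
      }
    }
  }
  labels
}

#' Convex-hull geometry of one nanodomain
#'
#' Fits the convex hull to a cluster's points and reports the hull area, the
#' area-equivalent circular diameter `2 sqrt(area / pi)`, and the maximum
#' pairwise extent. Degenerate (collinear) clusters get zero area and fall
#' back to the maximum extent as their size, flagged `degenerate`.
#'
#' @param points Two-column matrix or data frame of coordinates, nm; at least
#'   3 points.
#' @return List: `centroid`, `hull_area` (nm^2), `eq_diameter` (nm),
#'   `max_extent` (nm), `size` (eq_diameter, or max_extent when degenerate),
#'   `degenerate`, `hull` (indices).
#' @export
domain_geometry <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 3) stop("cannot hull fewer than 3 points")
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  area <- if (m < 3) 0 else {
    xs <- hp[, 1]; ys <- hp[, 2]
    abs(sum(xs * ys[c(2:m, 1)] - xs[c(2:m, 1)] * ys)) / 2
  }
  max_extent <- max(stats::dist(hp))
  degenerate <- area <= 0
  eq_d <- 2 * sqrt(area / pi)
  list(centroid = colMeans(pts), hull_area = area, eq_diameter = eq_d,
       max_extent = max_extent,
       size = if (degenerate) max_extent else eq_d,
       degenerate = degenerate, hull = h)
}

#' Tabulate clustered nanodomains
#'
#' Applies [domain_geometry()] to every cluster found by
#' [cluster_localizations()]; clusters too small to hull are dropped (DBSCAN
#' with `min_pts >= 3` cannot produce them).
#'
#' @param locs A [localization_table()].
#' @param labels Integer cluster labels (0 = noise).
#' @return Data frame, one row per cluster: `cluster`, `n_locs`,
#'   `centroid_x`, `centroid_y`, `hull_area_nm2`, `eq_diameter_nm`,
#'   `max_extent_nm`, `size_nm`, `degenerate`.
#' @export
domain_table <- function(locs, labels) {
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(cl) {
    sel <- labels == cl
    if (sum(sel) < 3) return(NULL)
    g <- domain_geometry(cbind(locs$x[sel], locs$y[sel]))
    data.frame(cluster = cl, n_locs = sum(sel),
               centroid_x = g$centroid[1], centroid_y = g$centroid[2],
               hull_area_nm2 = g$hull_area, eq_diameter_nm = g$eq_diameter,
               max_extent_nm = g$max_extent, size_nm = g$size,
               degenerate = g$degenerate)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster = integer(0), n_locs = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      hull_area_nm2 = numeric(0), eq_diameter_nm = numeric(0),
                      max_extent_nm = numeric(0), size_nm = numeric(0),
                      degenerate = logical(0))
  out
}

#' Remove outlier nanodomains by size
#'
#' Retains clusters whose size (area-equivalent diameter, or maximum extent
#' for degenerate hulls) lies in `(lower, upper]`, where the lower bound is
#' twice the mean localization uncertainty of the input table (the literal
#' fixed-25-nm reading is available via `uncertainty_rule`) and the upper
#' bound defaults to 800 nm. The applied bounds are attached as the `bounds`
#' attribute.
#'
#' @param domains Data frame from [domain_table()].
#' @param locs The [localization_table()] the domains came from (supplies the
#'   uncertainty column).
#' @param upper Upper size bound, nm.
#' @param uncertainty_rule `"2x-mean"` (lower bound = 2 x mean uncertainty,
#'   default) or `"literal-25"` (lower bound = 25 nm).
#' @return Filtered data frame with attribute `bounds = c(lower, upper)`.
#' @export
filter_domains <- function(domains, locs, upper = 800,
                           uncertainty_rule = c("2x-mean", "literal-25")) {
  uncertainty_rule <- match.arg(uncertainty_rule)
  if (uncertainty_rule == "2x-mean") {
    if (is.null(locs$uncertainty))
      stop("localization table lacks the 'uncertainty' column")
    lower <- 2 * mean(locs$uncertainty)
  } else lower <- 25
  keep <- domains$size_nm > lower & domains$size_nm <= upper
  out <- domains[keep, , drop = FALSE]
  attr(out, "bounds") <- c(lower = lower, upper = upper)
  out
}

#' Region-resolved nanodomain counts and sizes
#'
#' Assigns each cluster to `body`, `bleb` or `outside` by the scene label
#' under its centroid, and reports pooled per-region counts and size
#' distributions (pooled across cells within a condition, not per-cell
#' averaged). Regions with no clusters still appear with a zero count.
#'
#' @param domains Data frame from [domain_table()] / [filter_domains()].
#' @param scene Integer label matrix (0 background, 1 body, >= 2 blebs,
#'   negative micronuclei) or a `region_scene`.
#' @param pixel_size Scene pixel size, um.
#' @return List: `domains` (input plus a `region` column), `counts` (named
#'   vector over body/bleb/outside), `sizes` (list of size vectors per
#'   region).
#' @export
summarize_domains_by_region <- function(domains, scene, pixel_size = 0.1) {
  if (inherits(scene, "region_scene")) {
    pixel_size <- scene$pixel_size
    scene <- scene$label_image
  }
  px <- pixel_size * 1000   # nm per pixel
  ix <- floor(domains$centroid_x / px) + 1L
  iy <- floor(domains$centroid_y / px) + 1L
  inside <- ix >= 1 & ix <= nrow(scene) & iy >= 1 & iy <= ncol(scene)
  lab <- rep(0L, nrow(domains))
  lab[inside] <- scene[cbind(ix[inside], iy[inside])]
  region <- ifelse(lab == 1, "body", ifelse(lab >= 2, "bleb", "outside"))
  domains$region <- region
  counts <- c(body = sum(region == "body"), bleb = sum(region == "bleb"),
              outside = sum(region == "outside"))
  sizes <- list(body = domains$size_nm[region == "body"],
                bleb = domains$size_nm[region == "bleb"],
                outside = domains$size_nm[region == "outside"])
  list(domains = domains, counts = counts, sizes = sizes)
}

#' One-call nanodomain pipeline for a localization table
#'
#' Cluster, size, and filter in one step with the field-standard parameters.
#'
#' @inheritParams cluster_localizations
#' @inheritParams filter_domains
#' @return Filtered domain data frame (see [domain_table()]).
#' @export
call_nanodomains <- function(locs, eps = 50, min_pts = 3, upper = 800,
                             uncertainty_rule = "2x-mean") {
  labels <- cluster_localizations(locs, eps = eps, min_pts = min_pts)
  filter_domains(domain_table(locs, labels), locs, upper = upper,
                 uncertainty_rule = uncertainty_rule)
}
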
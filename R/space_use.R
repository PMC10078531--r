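# Movement and habitat covariates: percent minimum convex polygon (MCP) home
# ranges, centroid distances, intensity of use, habitat affiliation, and
# LiDAR vegetation-structure profiles. Coordinates in km, areas in km^2.

# Validate a track data.frame: x, y, timestamp (numeric days or POSIXct),
# strictly increasing timestamps.
check_track <- function(track) {
  stopifnot(is.data.frame(track), all(c("x", "y", "timestamp") %in% names(track)))
  ts <- as.numeric(track$timestamp)
  if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing")
  track
}

#' Percent minimum convex polygon home range
#'
#' The classical percent-MCP: the centroid is the arithmetic mean of all GPS
#' fixes, the `ceiling(level * n)` fixes nearest the centroid (Euclidean) are
#' retained, and the home range is their convex hull with area by the
#' shoelace formula.
#'
#' @param track data.frame with columns `x`, `y`, `timestamp` (km, days).
#' @param level retention fraction, e.g. 0.95 or 1 (default 0.95).
#' @return list with `polygon` (CCW vertex matrix), `area` (km^2),
#'   `centroid` (mean of all fixes), `level`, `n_fixes`, `n_retained`.
#' @export
fit_home_range <- function(track, level = 0.95) {
  check_track(track)
  pts <- cbind(track$x, track$y)
  n <- nrow(pts)
  if (n < 5L) stop("need >= 5 fixes for a home-range estimate")
  centroid <- colMeans(pts)
  d2 <- (pts[, 1L] - centroid[1L])^2 + (pts[, 2L] - centroid[2L])^2
  keep <- order(d2)[seq_len(ceiling(level * n))]
  hull <- convex_hull(pts[keep, , drop = FALSE])
  area <- polygon_area(hull)
  if (area <= 0) stop("degenerate (collinear) fixes: zero-area home range")
  list(polygon = hull, area = area, centroid = centroid, level = level,
       n_fixes = n, n_retained = length(keep))
}

#' Both-level home range for one individual
#'
#' Convenience wrapper building the 95% and 100% MCPs plus centroid.
#'
#' @inheritParams fit_home_range
#' @param individual_id label carried into the result.
#' @return object of class `"home_range"`.
#' @export
home_range <- function(track, individual_id = NA_character_, level = 0.95) {
  structure(list(individual_id = individual_id,
                 mcp95 = fit_home_range(track, level),
                 mcp100 = fit_home_range(track, 1),
                 centroid = colMeans(cbind(track$x, track$y))),
            class = "home_range")
}

#' Pairwise distances between home-range centroids
#'
#' Used as a proxy for similarity of the plant communities available to each
#' individual (near ranges see similar vegetation).
#'
#' @param ranges named list of `"home_range"` objects, or a two-column matrix
#'   of centroids with rownames.
#' @return symmetric Euclidean distance matrix (km), zero diagonal.
#' @export
centroid_distances <- function(ranges) {
  cent <- if (is.matrix(ranges)) ranges else
    do.call(rbind, lapply(ranges, function(r) r$centroid))
  if (is.null(rownames(cent)) && is.list(ranges) && !is.null(names(ranges)))
    rownames(cent) <- names(ranges)
  if (nrow(cent) < 2L) stop("need >= 2 ranges")
  as.matrix(stats::dist(cent))
}

#' Intensity-of-use index
#'
#' Ratio of total movement distance to the square of the 100% MCP area over
#' the analysis window: `IU = path_km / area_km2^2` (units km^-3). Higher
#' values mean more thorough search per unit area. The track is truncated to
#' `window_days` after its first fix before both the path length and the
#' area are computed.
#'
#' @param track data.frame with `x`, `y`, `timestamp` (timestamp in days or
#'   POSIXct; only differences matter).
#' @param window_days truncation window (default 21; `Inf` = full track).
#' @return scalar index.
#' @export
intensity_of_use <- function(track, window_days = 21) {
  check_track(track)
  ts <- as.numeric(track$timestamp)
  if (inherits(track$timestamp, "POSIXt")) ts <- ts / 86400
  keep <- ts <= ts[1L] + window_days
  sub <- track[keep, , drop = FALSE]
  steps <- sqrt(diff(sub$x)^2 + diff(sub$y)^2)
  path <- sum(steps)
  if (path == 0) return(0)
  area <- fit_home_range(sub, 1)$area
  path / area^2
}

#' Habitat affiliation of a home range
#'
#' An individual is floodplain-associated if its 95% MCP intersects the
#' (treeless) floodplain polygon with positive area; `time_fraction` is the
#' share of GPS fixes falling inside the floodplain polygon.
#'
#' @param range a `"home_range"` object.
#' @param floodplain_polygon CCW vertex matrix of the floodplain boundary.
#' @param track the individual's fix table (for the time fraction).
#' @return list with `habitat` (`"floodplain"` or `"woodland"`) and
#'   `time_fraction`.
#' @export
habitat_affiliation <- function(range, floodplain_polygon, track) {
  stopifnot(inherits(range, "home_range"))
  poly <- as.matrix(floodplain_polygon)
  if (nrow(poly) < 3L) stop("invalid floodplain polygon")
  overlap <- convex_intersection_area(range$mcp95$polygon, poly)
  frac <- mean(points_in_polygon(cbind(track$x, track$y), poly))
  list(habitat = if (overlap > 0) "floodplain" else "woodland",
       time_fraction = frac)
}

#' Vegetation-structure profile from classified LiDAR heights
#'
#' Bins point heights into the four standard classes and returns their
#' proportions: ground (height <= `ground_tol`), low vegetation
#' (`ground_tol` to 0.3 m, exclusive), medium vegetation (0.3-1.6 m,
#' inclusive), high vegetation (> 1.6 m). The nominal ground class is "0 m";
#' a small tolerance absorbs sensor noise, and the 0.3/1.6 m boundaries are
#' closed on the medium side.
#'
#' @param heights numeric vector of point heights (m), all >= 0.
#' @param ground_tol ground tolerance in m (default 0.05).
#' @param breaks the low/medium and medium/high boundaries (default
#'   `c(0.3, 1.6)`).
#' @return named proportion vector `(ground, low, medium, high)` summing to 1.
#' @export
structure_profile <- function(heights, ground_tol = 0.05, breaks = c(0.3, 1.6)) {
  h <- as.numeric(heights)
  if (!length(h)) stop("empty point set")
  if (any(h < 0)) stop("heights must be nonnegative")
  counts <- c(ground = sum(h <= ground_tol),
              low = sum(h > ground_tol & h < breaks[1L]),
              medium = sum(h >= breaks[1L] & h <= breaks[2L]),
              high = sum(h > breaks[2L]))
  counts / length(h)
}

#' Bray-Curtis dissimilarity between vegetation-structure profiles
#'
#' @param profiles matrix with one row per home range and the four structure
#'   proportions as columns.
#' @return symmetric dissimilarity matrix in \[0, 1\].
#' @export
structure_dissimilarity <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need >= 2 profiles")
  bray_curtis(profiles)
}
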
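# Spatial admission of sites into estuaries and temporal pairing of
# observations with candidate scenes.

#' Assign an estuary code by buffered containment
#'
#' A site receives the code of the estuary polygon that contains it after
#' buffering by `buffer_m` (allowing for recorded-location error). When
#' several buffered polygons contain the site, the nearest by boundary
#' distance wins; sites outside every buffered polygon get `NA`.
#'
#' @param x,y site coordinates, planar metres.
#' @param boundaries named list of polygon vertex matrices; names are the
#'   estuary codes.
#' @param buffer_m buffer width in metres.
#' @return Estuary code, or `NA_character_`.
#' @export
assign_estcode <- function(x, y, boundaries, buffer_m = 30) {
  stopifnot(length(x) == 1, length(y) == 1, length(boundaries) >= 1,
            !is.null(names(boundaries)))
  d <- vapply(boundaries, function(p) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) stop("invalid polygon")
    dist_to_polygon(x, y, p)
  }, numeric(1))
  within <- d <= buffer_m
  if (!any(within)) return(NA_character_)
  names(boundaries)[within][which.min(d[within])]
}

#' Edge exclusion for matchup sites
#'
#' A site is edge-excluded when the closed disc of radius
#' `sample_radius_m` about it intersects the shoreline or the buffered
#' roads (bridges and causeways), i.e. when the shoreline is within
#' `sample_radius_m` or a road centreline is within
#' `sample_radius_m + road_buffer_m`. Such sites suffer shadowing and
#' mixed-pixel edge effects.
#'
#' @param x,y site coordinates, planar metres.
#' @param shoreline polyline vertex matrix.
#' @param roads list of polyline vertex matrices (may be empty).
#' @param sample_radius_m matchup disc radius.
#' @param road_buffer_m half-width of the road buffer.
#' @return Logical.
#' @export
edge_excluded <- function(x, y, shoreline, roads = list(),
                          sample_radius_m = 30, road_buffer_m = 15) {
  if (dist_to_polyline(x, y, shoreline) <= sample_radius_m) return(TRUE)
  for (r in roads) {
    if (dist_to_polyline(x, y, r) <= sample_radius_m + road_buffer_m) {
      return(TRUE)
    }
  }
  FALSE
}

#' Water-persistence screen
#'
#' Tests whether the pixels in the site's matchup disc have been
#' classified as water persistently enough. Under the default `"all"`
#' rule every pixel whose centre lies in the disc must have occurrence
#' >= `threshold`; the `"mean"` rule requires the disc mean to meet the
#' threshold instead.
#'
#' @param x,y site coordinates, planar metres.
#' @param occurrence a [wq_raster()] with values in [0, 1].
#' @param radius_m disc radius.
#' @param threshold minimum water-occurrence fraction.
#' @param rule `"all"` or `"mean"`.
#' @return Logical.
#' @export
water_persistence_ok <- function(x, y, occurrence, radius_m = 30,
                                 threshold = 0.80,
                                 rule = c("all", "mean")) {
  rule <- match.arg(rule)
  px <- disc_pixels(occurrence, x, y, radius_m)
  if (nrow(px) == 0) stop("matchup disc contains no pixel centres")
  vals <- occurrence$values[px]
  if (rule == "all") all(vals >= threshold) else mean(vals) >= threshold
}

#' Screen the sites of a world for matchup eligibility
#'
#' Convenience wrapper applying [assign_estcode()], [edge_excluded()] and
#' [water_persistence_ok()] to every site.
#'
#' @param sites data.frame with `site_id`, `x`, `y`.
#' @param boundaries named list of estuary polygons.
#' @param shoreline polyline matrix.
#' @param roads list of polyline matrices.
#' @param occurrence occurrence [wq_raster()].
#' @param config a [pipeline_config()].
#' @return `sites` with `estcode`, `edge_excluded`, `water_ok` and
#'   `eligible` columns added.
#' @export
screen_sites <- function(sites, boundaries, shoreline, roads, occurrence,
                         config = pipeline_config()) {
  n <- nrow(sites)
  estcode <- character(n); edge <- logical(n); water <- logical(n)
  for (i in seq_len(n)) {
    estcode[i] <- assign_estcode(sites$x[i], sites$y[i], boundaries,
                                 buffer_m = config$radius_m)
    edge[i] <- edge_excluded(sites$x[i], sites$y[i], shoreline, roads,
                             sample_radius_m = config$radius_m,
                             road_buffer_m = config$road_buffer_m)
    water[i] <- tryCatch(
      water_persistence_ok(sites$x[i], sites$y[i], occurrence,
                           radius_m = config$radius_m,
                           threshold = config$water_threshold,
                           rule = config$water_rule),
      error = function(e) FALSE)
  }
  sites$estcode <- estcode
  sites$edge_excluded <- edge
  sites$water_ok <- water
  sites$eligible <- !is.na(estcode) & !edge & water
  sites
}

#' Pair observations with scenes inside the temporal window
#'
#' Returns every (observation, scene) pair whose absolute time difference
#' is at most `window_h` hours, annotated with the difference. Both sides
#' must carry UTC times.
#'
#' @param obs data.frame with `record_id` and POSIXct `utc_time`.
#' @param scenes data.frame with `scene_id` and POSIXct `sensing_time`,
#'   or a list of `scene` objects.
#' @param window_h half-window in hours.
#' @return data.frame `record_id`, `scene_id`, `dt_h` (one row per pair),
#'   sorted by record then |dt|.
#' @export
temporal_match <- function(obs, scenes, window_h = 24) {
  if (is.list(scenes) && !is.data.frame(scenes)) {
    scenes <- data.frame(
      scene_id = vapply(scenes, function(s) s$id, character(1)),
      sensing_time = as.POSIXct(
        vapply(scenes, function(s) as.numeric(s$sensing_time), numeric(1)),
        origin = "1970-01-01", tz = "UTC"),
      stringsAsFactors = FALSE)
  }
  if (any(is.na(obs$utc_time))) stop("observations with missing UTC time")
  if (any(is.na(scenes$sensing_time))) stop("scenes with missing UTC time")
  if (nrow(obs) == 0 || nrow(scenes) == 0) {
    return(data.frame(record_id = character(0), scene_id = character(0),
                      dt_h = numeric(0), stringsAsFactors = FALSE))
  }
  dt <- abs(outer(as.numeric(obs$utc_time),
                  as.numeric(scenes$sensing_time), `-`)) / 3600
  hit <- which(dt <= window_h, arr.ind = TRUE)
  out <- data.frame(record_id = obs$record_id[hit[, 1]],
                    scene_id = scenes$scene_id[hit[, 2]],
                    dt_h = dt[hit], stringsAsFactors = FALSE)
  out[order(out$record_id, out$dt_h), , drop = FALSE]
}
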
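# File interfaces: GeoJSON vectors, TIFF rasters with JSON sidecars, and
# CSV tables. Scene rasters are written one TIFF per band plus a sidecar
# carrying sensing time (ISO-8601 UTC) and sun/view geometry.

#' Write world vectors as GeoJSON
#'
#' Emits a FeatureCollection with the estuary polygons (ESTCODE
#' property), the shoreline and the roads, in geographic coordinates via
#' the world's local projection.
#'
#' @param world a `synthetic_world`.
#' @param path output `.geojson` path.
#' @return Invisibly, `path`.
#' @export
write_world_geojson <- function(world, path) {
  to_ll <- function(m) {
    ll <- world$proj$to_lonlat(m[, 1], m[, 2])
    lapply(seq_len(nrow(ll)), function(i) c(ll[i, "lon"], ll[i, "lat"]))
  }
  feats <- list()
  for (code in names(world$estuary)) {
    ring <- world$estuary[[code]]
    ring <- rbind(ring, ring[1, , drop = FALSE])
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(ESTCODE = code),
      geometry = list(type = "Polygon", coordinates = list(to_ll(ring))))
  }
  feats[[length(feats) + 1]] <- list(
    type = "Feature", properties = list(layer = "shoreline"),
    geometry = list(type = "LineString",
                    coordinates = to_ll(world$shoreline)))
  for (nm in names(world$roads)) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(layer = "road", name = nm),
      geometry = list(type = "LineString",
                      coordinates = to_ll(world$roads[[nm]])))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write a scene as per-band TIFFs with a JSON sidecar
#'
#' Requires the `tiff` package. Band rasters and the cloud-probability
#' raster are written as 32-bit float TIFFs; the sidecar records the
#' sensing time (ISO-8601 UTC), sun/view angles in degrees, grid
#' resolution and tile cloud fraction.
#'
#' @param scene a `scene`.
#' @param dir output directory (created).
#' @return Invisibly, the sidecar path.
#' @export
write_scene <- function(scene, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write scene rasters")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in names(scene$bands)) {
    tiff::writeTIFF(t(scene$bands[[b]]),
                    file.path(dir, paste0(b, ".tif")),
                    bits.per.sample = 32L)
  }
  tiff::writeTIFF(t(scene$cloud_prob), file.path(dir, "cloud_prob.tif"),
                  bits.per.sample = 32L)
  sidecar <- file.path(dir, "scene.json")
  jsonlite::write_json(list(
    id = scene$id,
    sensing_time = format(scene$sensing_time, "%Y-%m-%dT%H:%M:%SZ",
                          tz = "UTC"),
    sun_zenith = scene$sun_zenith, sun_azimuth = scene$sun_azimuth,
    view_zenith = scene$view_zenith, view_azimuth = scene$view_azimuth,
    res_m = scene$res_m, tile_cloud_frac = scene$tile_cloud_frac
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir directory holding the band TIFFs and `scene.json`.
#' @return A `scene` object (without synthetic truth masks).
#' @export
read_scene <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read scene rasters")
  }
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  bands <- lapply(s2_bands()$band, function(b) {
    t(tiff::readTIFF(file.path(dir, paste0(b, ".tif"))))
  })
  names(bands) <- s2_bands()$band
  structure(list(
    id = meta$id, bands = bands,
    cloud_prob = t(tiff::readTIFF(file.path(dir, "cloud_prob.tif"))),
    sensing_time = as.POSIXct(meta$sensing_time,
                              format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    sun_zenith = meta$sun_zenith, sun_azimuth = meta$sun_azimuth,
    view_zenith = meta$view_zenith, view_azimuth = meta$view_azimuth,
    tile_cloud_frac = meta$tile_cloud_frac, res_m = meta$res_m
  ), class = "scene")
}
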
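# Synthetic estuary worlds with planted ground truth.
#
# The generator emulates the inputs of the matchup pipeline: an estuary
# polygon with shoreline and road/causeway vectors, smooth true fields for
# chlorophyll and ancillary water quality, a water-occurrence raster, four
# bio-optical spectral archetypes, and sampling sites labelled by archetype.
# Everything downstream (scenes, in situ exports) is derived from the world,
# so every pipeline verdict can be checked against planted truth.

#' Bio-optical spectral archetypes
#'
#' Four archetypes sharing one spectral shape -- a broad reflectance curve
#' peaking in the green (560 nm) with a lesser secondary peak at the red
#' edge (705 nm) -- and differing mainly in overall magnitude, the pattern
#' characteristic of CDOM-dominated coastal waters. Chlorophyll couples to
#' the 705 nm peak through a saturating term, so the red-edge peak grows
#' monotonically with chlorophyll but never overtakes the green peak.
#'
#' @param magnitudes overall reflectance scale of each archetype.
#' @return A list of `bio_archetype` objects (fields: `id`, `baseline`,
#'   `green_peak_gain`, `rededge_peak_gain`, `chl_sensitivity`, `noise_sd`).
#' @export
bio_archetypes <- function(magnitudes = c(0.02, 0.04, 0.07, 0.10)) {
  bands <- s2_bands()
  lam <- bands$center_nm
  # broad asymmetric hump centred on the green band
  width <- ifelse(lam <= 560, 120, 180)
  shape <- exp(-(lam - 560)^2 / (2 * width^2))
  g560 <- exp(-((lam - 560) / 25)^2)   # narrow green peak
  g705 <- exp(-((lam - 705) / 20)^2)   # narrow red-edge peak
  lapply(seq_along(magnitudes), function(i) {
    mag <- magnitudes[i]
    gg <- 0.30 * mag
    rg <- 0.25 * mag
    structure(list(
      id = i,
      baseline = pmin(1, mag * shape + gg * g560 + rg * g705),
      green_peak_gain = gg,
      rededge_peak_gain = rg,
      chl_sensitivity = 0.30 * mag,
      noise_sd = rep(0.015 * mag, length(lam)),
      rededge_shape = g705
    ), class = "bio_archetype")
  })
}

#' Forward reflectance model
#'
#' Renders the per-band reflectance of a water pixel with chlorophyll
#' concentration `chl` under a given archetype. With `noise = FALSE` the
#' output is the archetype baseline plus a saturating chlorophyll
#' contribution at the 705 nm red-edge peak:
#' `R_b = baseline_b + chl_sensitivity * chl / (chl + 50) * g705_b`,
#' which is deterministic, equals the baseline exactly at `chl = 0`, and is
#' strictly increasing in `chl` at the 705 nm band. With `noise = TRUE`,
#' per-band Gaussian noise (`archetype$noise_sd`) is added from the current
#' RNG state. Output is clamped to [0, 1].
#'
#' @param chl chlorophyll in ug/L (vector allowed, >= 0).
#' @param archetype a `bio_archetype`.
#' @param noise logical.
#' @return If `chl` is scalar, a named per-band vector; otherwise a
#'   `length(chl) x 13` matrix.
#' @export
forward_reflectance <- function(chl, archetype, noise = FALSE) {
  if (any(!is.finite(chl)) || any(chl < 0)) {
    stop("chl must be finite and >= 0")
  }
  sat <- chl / (chl + 50)
  out <- outer(sat, archetype$chl_sensitivity * archetype$rededge_shape)
  out <- sweep(out, 2, archetype$baseline, `+`)
  if (noise) {
    out <- out + matrix(stats::rnorm(length(out), 0,
                                     rep(archetype$noise_sd,
                                         each = length(chl))),
                        nrow = length(chl))
  }
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- s2_bands()$band
  if (length(chl) == 1L) out[1, ] else out
}

# Smooth Gaussian-ish random field: white noise blurred by repeated
# box filtering (three passes ~ Gaussian), then standardised.
smooth_field <- function(nx, ny, range_px = 8) {
  f <- matrix(stats::rnorm(nx * ny), nx, ny)
  w <- max(3L, 2L * as.integer(range_px / 2) + 1L)
  kern <- rep(1 / w, w)
  blur <- function(m) {
    m <- apply(m, 2, function(col) stats::filter(col, kern, circular = TRUE))
    t(apply(t(m), 2, function(row) stats::filter(row, kern, circular = TRUE)))
  }
  for (i in 1:3) f <- blur(f)
  (f - mean(f)) / stats::sd(f)
}

# Local equirectangular projection between synthetic lon/lat and planar m.
world_projection <- function(lon0 = -71.0, lat0 = 41.5) {
  mx <- 111320 * cos(lat0 * pi / 180)
  my <- 110540
  list(lon0 = lon0, lat0 = lat0,
       to_lonlat = function(x, y) cbind(lon = lon0 + x / mx,
                                        lat = lat0 + y / my),
       to_xy = function(lon, lat) cbind(x = (lon - lon0) * mx,
                                        y = (lat - lat0) * my))
}

#' Generate a synthetic estuary world
#'
#' Builds an elliptical estuary with shoreline and a causeway road, smooth
#' true fields (chlorophyll, salinity, temperature, dissolved oxygen,
#' turbidity) on a 10 m grid, a water-occurrence raster (high inside the
#' estuary, decaying near shore), four bio-optical archetype zones, and
#' sampling sites stratified across the zones so every archetype is
#' represented. Regenerating with the same seed reproduces the world
#' bit-identically.
#'
#' @param nx,ny grid size in pixels (>= 32).
#' @param res_m pixel size, metres.
#' @param n_sites number of sampling sites (>= 1; >= 4 recommended so all
#'   archetypes are covered).
#' @param seed integer RNG seed.
#' @param cloud_top_height_m cloud-top height used when projecting shadows
#'   in rendered scenes.
#' @param chl_median median of the lognormal true chlorophyll field, ug/L.
#' @return An object of class `synthetic_world`.
#' @export
make_world <- function(nx = 64, ny = 64, res_m = 10, n_sites = 10,
                       seed = 1, cloud_top_height_m = 1000,
                       chl_median = 5) {
  if (nx < 32 || ny < 32) stop("grid must be at least 32 x 32 pixels")
  if (n_sites < 1) stop("at least one site is required")
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))

  W <- nx * res_m; H <- ny * res_m
  estuary <- ellipse_polygon(W / 2, H / 2, 0.40 * W, 0.32 * H,
                             n = 96, rotate = 0.3)
  shoreline <- rbind(estuary, estuary[1, , drop = FALSE])
  roads <- list(
    causeway = cbind(c(0, W), c(0.72 * H, 0.66 * H)),
    inland = cbind(c(0, 0.3 * W, 0.5 * W), c(0.1 * H, 0.05 * H, 0.12 * H))
  )

  # true fields on the grid
  chl_field <- exp(log(chl_median) + 0.6 * smooth_field(nx, ny, 10))
  sal_grad <- matrix(rep(seq(0, 30, length.out = nx), ny), nx, ny)
  salinity <- pmax(sal_grad + 2 * smooth_field(nx, ny, 12), 0)
  temperature <- 15 + 6 * smooth_field(nx, ny, 14)
  do_field <- pmax(8 - 0.05 * chl_field + 1.5 * smooth_field(nx, ny, 10), 0.2)
  turbidity <- pmax(5 + 4 * abs(smooth_field(nx, ny, 8)), 0.1)

  # archetype zones: four slices across the estuary's x extent
  cx <- (seq_len(nx) - 0.5) * res_m
  xr <- range(estuary[, 1])
  brk <- seq(xr[1], xr[2], length.out = 5)
  zone_of_x <- function(x) pmin(4L, pmax(1L, findInterval(x, brk,
                                                          all.inside = TRUE)))
  owt_map <- matrix(rep(zone_of_x(cx), ny), nx, ny)

  # water occurrence: ~0.95 deep inside, decaying across the 40 m nearest
  # shore, ~0 outside
  grid <- expand.grid(x = cx, y = (seq_len(ny) - 0.5) * res_m)
  inside <- point_in_polygon(grid$x, grid$y, estuary)
  dshore <- dist_to_polyline(grid$x, grid$y, shoreline)
  occ <- ifelse(inside, pmin(0.97, 0.55 + 0.42 * pmin(1, dshore / 40)), 0.02)
  occurrence <- wq_raster(matrix(occ, nx, ny), res = res_m)

  # sites: stratified over the four zones, jittered; kept within the
  # 30 m-buffered estuary
  sites_xy <- matrix(NA_real_, n_sites, 2)
  zones <- rep_len(1:4, n_sites)
  for (i in seq_len(n_sites)) {
    # most stations sit in open water (>= 60 m from shore, as monitoring
    # networks favour navigable water); every fifth is unconstrained and
    # may land near the shoreline, exercising the edge screens downstream
    interior <- (i %% 5L) != 0L
    tries <- 0L
    repeat {
      tries <- tries + 1L
      x <- stats::runif(1, brk[zones[i]], brk[zones[i] + 1])
      y <- stats::runif(1, min(estuary[, 2]), max(estuary[, 2]))
      if (!point_in_polygon(x, y, estuary)) next
      if (interior && tries < 200L &&
          dist_to_polyline(x, y, shoreline) < 60) next
      # jitter emulates recorded-location error; keep within the 30 m buffer
      xj <- x + stats::rnorm(1, 0, 8); yj <- y + stats::rnorm(1, 0, 8)
      if (interior && tries < 200L &&
          dist_to_polyline(xj, yj, shoreline) < 60) next
      if (dist_to_polygon(xj, yj, estuary) <= 30) { x <- xj; y <- yj; break }
    }
    sites_xy[i, ] <- c(x, y)
  }
  proj <- world_projection()
  ll <- proj$to_lonlat(sites_xy[, 1], sites_xy[, 2])
  pix <- cbind(pmin(nx, pmax(1, ceiling(sites_xy[, 1] / res_m))),
               pmin(ny, pmax(1, ceiling(sites_xy[, 2] / res_m))))
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    x = sites_xy[, 1], y = sites_xy[, 2],
    lon = ll[, "lon"], lat = ll[, "lat"],
    owt = owt_map[pix],
    true_chl = chl_field[pix],
    true_temperature = temperature[pix],
    true_salinity = salinity[pix],
    true_do = do_field[pix],
    true_turbidity = turbidity[pix],
    stringsAsFactors = FALSE
  )

  structure(list(
    nx = nx, ny = ny, res_m = res_m, seed = as.integer(seed),
    estuary = list(E1 = estuary), shoreline = shoreline, roads = roads,
    fields = list(chlorophyll = chl_field, salinity = salinity,
                  temperature = temperature, dissolved_oxygen = do_field,
                  turbidity = turbidity),
    owt_map = owt_map, occurrence = occurrence,
    archetypes = bio_archetypes(), sites = sites,
    cloud_top_height_m = cloud_top_height_m,
    proj = proj
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world %dx%d @ %g m, %d sites, seed %d>\n",
              x$nx, x$ny, x$res_m, nrow(x$sites), x$seed))
  invisible(x)
}

#' Render a multiband scene over a synthetic world
#'
#' Water pixels are rendered through [forward_reflectance()] from the true
#' chlorophyll field and the pixel's archetype; land pixels get a flat
#' bright-soil spectrum. A cloud-probability raster is generated from
#' smoothed noise calibrated so that approximately `cloud_cover_frac` of
#' pixels exceed probability 0.5 (identically below 0.2 when
#' `cloud_cover_frac = 0`). Cloudy pixels are rendered bright; their
#' shadows, projected along the anti-solar azimuth by
#' `h * tan(sun_zenith)` with the world's cloud-top height, are darkened.
#' The true cloud and shadow masks are kept on the scene for verification.
#'
#' @param world a `synthetic_world`.
#' @param sensing_time POSIXct (UTC) acquisition time.
#' @param sun_zenith,sun_azimuth solar geometry in degrees
#'   (`0 <= sun_zenith < 90`; azimuth clockwise from north).
#' @param view_zenith,view_azimuth viewing geometry in degrees.
#' @param cloud_cover_frac target cloudy-pixel fraction in [0, 1].
#' @param seed integer RNG seed for this scene.
#' @param scene_id identifier string.
#' @return An object of class `scene`: band matrices, `cloud_prob`,
#'   sensing time and geometry metadata, plus `true_cloud`/`true_shadow`.
#' @export
render_scene <- function(world, sensing_time, sun_zenith = 30,
                         sun_azimuth = 150, view_zenith = 5,
                         view_azimuth = 280, cloud_cover_frac = 0.1,
                         seed = 1, scene_id = NULL) {
  if (sun_zenith < 0 || sun_zenith >= 90) stop("sun_zenith must be in [0, 90)")
  if (cloud_cover_frac < 0 || cloud_cover_frac > 1) {
    stop("cloud_cover_frac must be in [0, 1]")
  }
  set.seed(as.integer(seed))
  nx <- world$nx; ny <- world$ny; res <- world$res_m
  bands <- s2_bands()
  grid <- expand.grid(x = (seq_len(nx) - 0.5) * res,
                      y = (seq_len(ny) - 0.5) * res)
  water <- matrix(point_in_polygon(grid$x, grid$y, world$estuary$E1), nx, ny)

  # per-band rasters
  lam <- bands$center_nm
  soil <- pmin(0.5, 0.10 + 0.12 * (lam - 443) / (2190 - 443))
  band_mats <- lapply(seq_len(nrow(bands)), function(b) {
    matrix(soil[b] + stats::rnorm(nx * ny, 0, 0.01), nx, ny)
  })
  names(band_mats) <- bands$band
  chl <- world$fields$chlorophyll
  for (a in world$archetypes) {
    sel <- water & world$owt_map == a$id
    if (!any(sel)) next
    refl <- forward_reflectance(chl[sel], a, noise = FALSE)
    if (is.null(dim(refl))) refl <- matrix(refl, nrow = 1)
    noise <- matrix(stats::rnorm(length(refl), 0,
                                 rep(a$noise_sd, each = nrow(refl))),
                    nrow = nrow(refl))
    refl <- pmin(pmax(refl + noise, 0), 1)
    for (b in seq_len(nrow(bands))) band_mats[[b]][sel] <- refl[, b]
  }

  # cloud probability: smoothed noise, calibrated to the target fraction
  g <- smooth_field(nx, ny, 10)
  if (cloud_cover_frac == 0) {
    cloud_prob <- 0.05 + 0.04 * tanh(g)         # identically < 0.2
  } else if (cloud_cover_frac == 1) {
    cloud_prob <- 0.95 + 0.04 * tanh(g)
  } else {
    thr <- stats::quantile(g, 1 - cloud_cover_frac, names = FALSE)
    cloud_prob <- stats::plogis((g - thr) / 0.15)
  }
  cloud_prob <- matrix(pmin(1, pmax(0, cloud_prob)), nx, ny)
  true_cloud <- cloud_prob >= 0.5

  # shadow projection: anti-solar shift by h * tan(zenith)
  h <- world$cloud_top_height_m
  d <- h * tan(sun_zenith * pi / 180)
  az <- sun_azimuth * pi / 180
  dx <- as.integer(round(-d * sin(az) / res))
  dy <- as.integer(round(-d * cos(az) / res))
  true_shadow <- shift_mask(true_cloud, dx, dy)

  for (b in seq_along(band_mats)) {
    m <- band_mats[[b]]
    m[true_shadow] <- m[true_shadow] * 0.45
    m[true_cloud] <- pmin(1, 0.85 + stats::rnorm(sum(true_cloud), 0, 0.03))
    band_mats[[b]] <- pmin(pmax(m, 0), 1)
  }

  structure(list(
    id = scene_id %||% sprintf("SC_%s_%d",
                               format(sensing_time, "%Y%m%dT%H%M%S"), seed),
    bands = band_mats, cloud_prob = cloud_prob,
    sensing_time = as.POSIXct(sensing_time, tz = "UTC"),
    sun_zenith = sun_zenith, sun_azimuth = sun_azimuth,
    view_zenith = view_zenith, view_azimuth = view_azimuth,
    tile_cloud_frac = mean(true_cloud),
    res_m = res, water = water,
    true_cloud = true_cloud, true_shadow = true_shadow
  ), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %s: %dx%d, %s UTC, sun z=%g az=%g, cloud %.0f%%>\n",
              x$id, nrow(x$cloud_prob), ncol(x$cloud_prob),
              format(x$sensing_time, "%Y-%m-%d %H:%M"),
              x$sun_zenith, x$sun_azimuth, 100 * x$tile_cloud_frac))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
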
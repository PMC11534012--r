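# Cloud, cloud-shadow and glint masking; per-band pixel extraction in the
# matchup disc; and the matchup quality filters.

#' Cloud mask by probability threshold
#'
#' A pixel is masked when its cloud probability is at or above the
#' threshold (the `>=` convention keeps the mask conservative at the
#' boundary).
#'
#' @param scene a `scene`.
#' @param threshold cloud-probability threshold in (0, 1].
#' @return Logical matrix (TRUE = cloudy).
#' @export
cloud_mask <- function(scene, threshold = 0.20) {
  if (any(scene$cloud_prob < 0 | scene$cloud_prob > 1)) {
    stop("cloud probabilities must be in [0, 1]")
  }
  scene$cloud_prob >= threshold
}

#' Cloud-shadow mask by solar projection
#'
#' Cloud-top heights are unknown, so the cloud mask is projected along the
#' anti-solar azimuth by `h * tan(sun_zenith)` for every candidate height
#' `h` and the union is taken; over-masking is accepted as conservative.
#' No near-infrared darkness condition is applied: dark water would
#' otherwise be misread as shadow.
#'
#' @param scene a `scene` (provides sun geometry and grid resolution).
#' @param cloud logical cloud mask (defaults to [cloud_mask()] at 20%).
#' @param heights_m candidate cloud-top heights in metres.
#' @return Logical matrix (TRUE = shadow).
#' @export
shadow_mask <- function(scene, cloud = cloud_mask(scene),
                        heights_m = seq(200, 2000, by = 100)) {
  if (scene$sun_zenith >= 90 || scene$sun_zenith < 0) {
    stop("sun_zenith must be in [0, 90)")
  }
  az <- scene$sun_azimuth * pi / 180
  tz <- tan(scene$sun_zenith * pi / 180)
  out <- matrix(FALSE, nrow(cloud), ncol(cloud))
  shifts <- unique(t(vapply(heights_m, function(h) {
    d <- h * tz
    c(as.integer(round(-d * sin(az) / scene$res_m)),
      as.integer(round(-d * cos(az) / scene$res_m)))
  }, integer(2))))
  for (i in seq_len(nrow(shifts))) {
    out <- out | shift_mask(cloud, shifts[i, 1], shifts[i, 2])
  }
  out
}

#' Sun-glint geometry flag
#'
#' Flags viewing geometries close to the specular reflection of the sun
#' off a flat water surface. The sun direction is mirrored about the
#' vertical; the scene is flagged when the angle between the view
#' direction and that specular direction is below the threshold.
#'
#' @param sun_zenith,sun_azimuth solar geometry, degrees.
#' @param view_zenith,view_azimuth viewing geometry, degrees.
#' @param angle_threshold_deg specular cone half-angle.
#' @return Logical.
#' @export
glint_flag <- function(sun_zenith, sun_azimuth, view_zenith, view_azimuth,
                       angle_threshold_deg = 40) {
  d2r <- pi / 180
  dirvec <- function(zen, az) {
    c(sin(zen * d2r) * sin(az * d2r), sin(zen * d2r) * cos(az * d2r),
      cos(zen * d2r))
  }
  s <- dirvec(sun_zenith, sun_azimuth)
  v <- dirvec(view_zenith, view_azimuth)
  spec <- c(-s[1], -s[2], s[3])   # mirror about the vertical normal
  ang <- acos(pmin(1, pmax(-1, sum(v * spec)))) / d2r
  ang < angle_threshold_deg
}

#' Extract per-band pixel statistics in the matchup disc
#'
#' Collects, for every band, the values of unmasked pixels whose centres
#' lie within `radius_m` of the site, with their median, standard
#' deviation and count. The valid-pixel count on the common 10 m grid
#' (`n_valid_10m`) feeds the minimum-pixel quality filter. Flags record
#' whether the disc touched cloud or shadow and whether the scene
#' geometry is glint-flagged; the QA verdict itself is set by
#' [qa_filter()].
#'
#' @param scene a `scene`.
#' @param site one-row data.frame (or list) with `site_id`, `x`, `y`;
#'   optionally `record_id`.
#' @param masks list with logical matrices `cloud` and `shadow` and
#'   logical scalar `glint` (missing pieces default to empty masks /
#'   FALSE).
#' @param radius_m disc radius in metres.
#' @return An object of class `matchup_record`.
#' @export
extract_matchup <- function(scene, site, masks = list(), radius_m = 30) {
  grid <- wq_raster(scene$cloud_prob, res = scene$res_m)
  px <- disc_pixels(grid, site$x, site$y, radius_m)
  if (nrow(px) == 0) stop("matchup disc lies off the raster")
  nxny <- dim(scene$cloud_prob)
  empty <- matrix(FALSE, nxny[1], nxny[2])
  cl <- masks$cloud %||% empty
  sh <- masks$shadow %||% empty
  gl <- isTRUE(masks$glint)
  masked <- cl[px] | sh[px]
  keep <- px[!masked, , drop = FALSE]

  stats_of <- function(v) {
    if (length(v) == 0) {
      c(median = NA_real_, sd = NA_real_, n = 0)
    } else {
      c(median = stats::median(v), sd = if (length(v) > 1) stats::sd(v)
        else 0, n = length(v))
    }
  }
  values <- lapply(scene$bands, function(b) b[keep])
  bs <- t(vapply(values, stats_of, numeric(3)))
  record <- list(
    record_id = site$record_id %||% NA_character_,
    site_id = site$site_id, scene_id = scene$id,
    n_in_disc = nrow(px),
    n_valid_10m = nrow(keep),
    band_values = values,
    band_median = stats::setNames(bs[, "median"], names(values)),
    band_sd = stats::setNames(bs[, "sd"], names(values)),
    cv_bands = NULL, median_cv = NA_real_,
    flags = list(cloud = any(cl[px]), shadow = any(sh[px]), glint = gl,
                 low_n = FALSE, high_cv = FALSE),
    accepted = NA, reason = NA_character_
  )
  class(record) <- "matchup_record"
  record
}

# Outlier-filtered coefficient of variation of one band's pixel values:
# values outside mean +/- k*SD are discarded, then CV = SD/mean.
filtered_cv <- function(v, outlier_k) {
  if (length(v) == 0) return(NA_real_)
  if (length(v) > 1 && stats::sd(v) > 0) {
    m <- mean(v); s <- stats::sd(v)
    v <- v[v >= m - outlier_k * s & v <= m + outlier_k * s]
  }
  if (length(v) == 0) return(NA_real_)
  mu <- mean(v)
  if (mu == 0) return(Inf)  # degenerate: no meaningful relative spread
  if (length(v) == 1) return(0)
  stats::sd(v) / mu
}

#' Matchup quality filter
#'
#' Recomputes, for each of the aerosol, blue, green and red bands, the
#' coefficient of variation of the disc pixel values after discarding
#' outliers beyond mean +/- `outlier_k` SD, and accepts the record iff at
#' least `min_valid` valid 10 m pixels were available, the median of the
#' four CVs is at most `max_cv`, and the scene is not glint-flagged. A
#' rejected record carries exactly one primary reason
#' (`low_n`, `glint`, `degenerate`, `high_cv`).
#'
#' @param record a `matchup_record` from [extract_matchup()].
#' @param min_valid minimum valid 10 m pixel count.
#' @param max_cv maximum median CV.
#' @param outlier_k outlier cut in SD units.
#' @return The record with `cv_bands`, `median_cv`, `flags`, `accepted`
#'   and `reason` filled in.
#' @export
qa_filter <- function(record, min_valid = 9, max_cv = 0.15,
                      outlier_k = 1.5) {
  cvs <- vapply(cv_filter_bands(), function(b) {
    filtered_cv(record$band_values[[b]], outlier_k)
  }, numeric(1))
  record$cv_bands <- cvs
  record$median_cv <- stats::median(cvs)

  if (record$n_valid_10m < min_valid) {
    record$flags$low_n <- TRUE
    record$accepted <- FALSE; record$reason <- "low_n"
  } else if (record$flags$glint) {
    record$accepted <- FALSE; record$reason <- "glint"
  } else if (any(!is.finite(cvs))) {
    record$accepted <- FALSE; record$reason <- "degenerate"
  } else if (record$median_cv > max_cv + 1e-12) {
    # the epsilon keeps a median CV of exactly max_cv (up to floating
    # point) on the accepting side of the boundary
    record$flags$high_cv <- TRUE
    record$accepted <- FALSE; record$reason <- "high_cv"
  } else {
    record$accepted <- TRUE; record$reason <- "accepted"
  }
  record
}

#' Flatten matchup records to a table
#'
#' One row per observation x scene with per-band medians, SDs and counts,
#' CV fields, flags and the QA verdict.
#'
#' @param records list of `matchup_record`s.
#' @return data.frame.
#' @export
matchup_table <- function(records) {
  if (length(records) == 0) return(data.frame())
  rows <- lapply(records, function(r) {
    row <- data.frame(record_id = r$record_id, site_id = r$site_id,
                      scene_id = r$scene_id, n_valid_10m = r$n_valid_10m,
                      median_cv = r$median_cv, accepted = r$accepted,
                      reason = r$reason, flag_cloud = r$flags$cloud,
                      flag_shadow = r$flags$shadow, flag_glint = r$flags$glint,
                      stringsAsFactors = FALSE)
    med <- as.list(r$band_median)
    names(med) <- paste0(names(med), "_median")
    sds <- as.list(r$band_sd)
    names(sds) <- paste0(names(sds), "_sd")
    cbind(row, as.data.frame(med), as.data.frame(sds))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
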
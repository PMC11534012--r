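#' Pipeline configuration
#'
#' Collects every numeric threshold the matchup workflow uses, with the
#' published protocol values as defaults: a 30 m extraction/buffer radius,
#' a +/-24 h matchup window, an 80% water-persistence threshold, a 20%
#' cloud-probability threshold, at least 9 valid 10 m pixels per matchup,
#' a median coefficient of variation of at most 0.15 across the aerosol,
#' blue, green and red bands after outlier removal at mean +/- 1.5 SD, a
#' 4-nearest-neighbour discriminant rule, and trophic-state chlorophyll
#' bounds at 5, 20 and 60 ug/L.
#'
#' @param radius_m matchup disc radius about a site, metres.
#' @param window_h temporal matchup half-window, hours.
#' @param water_threshold minimum water-occurrence fraction for pixels in
#'   the site disc.
#' @param water_rule `"all"` (every disc pixel must meet the threshold) or
#'   `"mean"` (disc mean occurrence must meet it).
#' @param cloud_prob_threshold cloud-probability mask threshold (masked at
#'   probability >= threshold).
#' @param min_valid_pixels minimum count of valid 10 m pixels in the disc.
#' @param max_median_cv maximum median coefficient of variation across the
#'   CV filter bands.
#' @param outlier_k outlier cut in SD units applied per band before the CV
#'   is computed.
#' @param shadow_heights_m candidate cloud-top heights (m) swept by the
#'   shadow projection; the shadow mask is the union over heights.
#' @param glint_angle_threshold_deg specular half-angle below which a scene
#'   is flagged for potential sun glint.
#' @param road_buffer_m half-width of the road/causeway exclusion buffer.
#' @param knn_k neighbourhood size of the nonparametric discriminant rule.
#' @param bricker_bounds increasing chlorophyll class bounds (ug/L).
#' @param fcm_m fuzzy c-means fuzzifier (> 1).
#' @param fcm_k_range candidate cluster counts for model selection.
#' @param fcm_nstart random initialisations per k.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(radius_m = 30,
                            window_h = 24,
                            water_threshold = 0.80,
                            water_rule = c("all", "mean"),
                            cloud_prob_threshold = 0.20,
                            min_valid_pixels = 9,
                            max_median_cv = 0.15,
                            outlier_k = 1.5,
                            shadow_heights_m = seq(200, 2000, by = 100),
                            glint_angle_threshold_deg = 40,
                            road_buffer_m = 15,
                            knn_k = 4,
                            bricker_bounds = c(5, 20, 60),
                            fcm_m = 2,
                            fcm_k_range = 2:8,
                            fcm_nstart = 10) {
  water_rule <- match.arg(water_rule)
  stopifnot(radius_m > 0, window_h > 0, water_threshold >= 0,
            cloud_prob_threshold > 0, min_valid_pixels > 0,
            max_median_cv > 0, outlier_k > 0, all(shadow_heights_m > 0),
            knn_k >= 1, fcm_m > 1,
            length(bricker_bounds) == 3, all(diff(bricker_bounds) > 0))
  structure(list(
    radius_m = radius_m, window_h = window_h,
    water_threshold = water_threshold, water_rule = water_rule,
    cloud_prob_threshold = cloud_prob_threshold,
    min_valid_pixels = min_valid_pixels, max_median_cv = max_median_cv,
    outlier_k = outlier_k, shadow_heights_m = shadow_heights_m,
    glint_angle_threshold_deg = glint_angle_threshold_deg,
    road_buffer_m = road_buffer_m, knn_k = knn_k,
    bricker_bounds = bricker_bounds, fcm_m = fcm_m,
    fcm_k_range = fcm_k_range, fcm_nstart = fcm_nstart
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos fail fast; missing keys take the
#' published defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}
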
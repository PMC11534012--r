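#' Multispectral band definitions
#'
#' Band table for the 13-band MSI instrument carried by the Sentinel-2
#' satellites. Centres are the nominal band-centre wavelengths in nm; `role`
#' gives the common colour name used by the matchup quality filters
#' (aerosol, blue, green, red). All synthetic rasters are rendered on a
#' common 10 m grid, so the nominal native resolution is informational only.
#'
#' @return A data.frame with columns `band`, `center_nm`, `native_res_m`,
#'   `role`.
#' @export
#' @examples
#' s2_bands()
s2_bands <- function() {
  data.frame(
    band = c("B1", "B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A",
             "B9", "B10", "B11", "B12"),
    center_nm = c(443, 490, 560, 665, 705, 740, 783, 842, 865,
                  945, 1375, 1610, 2190),
    native_res_m = c(60, 10, 10, 10, 20, 20, 20, 10, 20, 60, 60, 20, 20),
    role = c("aerosol", "blue", "green", "red", "rededge1", "rededge2",
             "rededge3", "nir", "nir_narrow", "water_vapour", "cirrus",
             "swir1", "swir2"),
    stringsAsFactors = FALSE
  )
}

# Bands entering the coefficient-of-variation homogeneity filter.
cv_filter_bands <- function() c("B1", "B2", "B3", "B4")

# Visible-range bands (centre <= 705 nm) used by spectral-shape checks.
visible_bands <- function() {
  b <- s2_bands()
  b$band[b$center_nm <= 705]
}
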
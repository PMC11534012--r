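# A minimal hand-built scene for mask/extraction tests.
toy_scene <- function(nx = 32, ny = 32, res = 10, sun_zenith = 45,
                      sun_azimuth = 180, view_zenith = 5,
                      view_azimuth = 280) {
  bands <- lapply(s2_bands()$band, function(b) matrix(0.05, nx, ny))
  names(bands) <- s2_bands()$band
  structure(list(
    id = "toy", bands = bands, cloud_prob = matrix(0, nx, ny),
    sensing_time = as.POSIXct("2021-06-01 15:30:00", tz = "UTC"),
    sun_zenith = sun_zenith, sun_azimuth = sun_azimuth,
    view_zenith = view_zenith, view_azimuth = view_azimuth,
    tile_cloud_frac = 0, res_m = res
  ), class = "scene")
}

test_that("cloud masking thresholds probability at >= 20%", {
  sc <- toy_scene()
  sc$cloud_prob[1, 1] <- 0.19
  sc$cloud_prob[2, 1] <- 0.20
  sc$cloud_prob[3, 1] <- 0.80
  m <- cloud_mask(sc, 0.20)
  expect_false(m[1, 1])
  expect_true(m[2, 1])          # boundary masked: conservative
  expect_true(m[3, 1])
  expect_equal(sum(cloud_mask(toy_scene(), 0.20)), 0)

  # lowering the threshold never unmasks a pixel
  m10 <- cloud_mask(sc, 0.10)
  expect_true(all(m10[m]))
})

test_that("shadow projection is purely geometric (no NIR condition)", {
  sc <- toy_scene(sun_zenith = 45, sun_azimuth = 90)
  cloud <- matrix(FALSE, 32, 32); cloud[20, 16] <- TRUE

  sh <- shadow_mask(sc, cloud, heights_m = 1000)
  # sun in the east: shadow 1000 m to the west (100 px at 10 m... clipped);
  # use a height that stays on-grid
  sh2 <- shadow_mask(sc, cloud, heights_m = 100)
  expect_true(sh2[10, 16])
  expect_equal(sum(sh2), 1)

  # a dark-water pixel far from any projection stays unmasked
  expect_false(sh2[30, 30])

  # nadir sun: shadow equals cloud
  scz <- toy_scene(sun_zenith = 0)
  expect_identical(shadow_mask(scz, cloud, heights_m = 1000), cloud)

  # widening the height range never unmasks
  sh_narrow <- shadow_mask(sc, cloud, heights_m = c(100, 150))
  sh_wide <- shadow_mask(sc, cloud, heights_m = c(100, 150, 200))
  expect_true(all(sh_wide[sh_narrow]))

  sc_bad <- toy_scene(); sc_bad$sun_zenith <- 95
  expect_error(shadow_mask(sc_bad, cloud), "sun_zenith")
})

test_that("glint flag follows specular geometry", {
  # view exactly specular to the sun: flagged at any positive threshold
  expect_true(glint_flag(30, 120, 30, 300, angle_threshold_deg = 5))
  # specular angle ~60 degrees, threshold 40: not flagged
  expect_false(glint_flag(30, 120, 30, 120, angle_threshold_deg = 40))
  # zero threshold never flags off-specular geometry
  expect_false(glint_flag(30, 120, 30, 300 + 1e-3, angle_threshold_deg = 0))
})

test_that("disc extraction reproduces the brute-force pixel oracle", {
  sc <- toy_scene()
  vals <- matrix(seq(0, 1, length.out = 32 * 32), 32, 32)
  for (b in names(sc$bands)) sc$bands[[b]] <- vals

  site <- list(record_id = "r1", site_id = "s1", x = 155, y = 155)
  rec <- extract_matchup(sc, site, radius_m = 30)
  oracle <- oracle_disc_pixels(wq_raster(vals, res = 10), 155, 155, 30)
  expect_equal(rec$n_valid_10m, nrow(oracle))
  expect_equal(rec$band_median[["B3"]],
               median(vals[cbind(oracle[, 1], oracle[, 2])]))

  # masking removes exactly the masked pixels
  cl <- matrix(FALSE, 32, 32)
  cl[oracle[1:4, , drop = FALSE]] <- TRUE
  rec2 <- extract_matchup(sc, site, masks = list(cloud = cl), radius_m = 30)
  expect_equal(rec2$n_valid_10m, nrow(oracle) - 4)
  keep <- oracle[-(1:4), , drop = FALSE]
  expect_equal(rec2$band_median[["B5"]],
               median(vals[cbind(keep[, 1], keep[, 2])]))
  expect_true(rec2$flags$cloud)

  # a fully masked disc yields n_valid 0 and a low_n verdict
  all_mask <- matrix(TRUE, 32, 32)
  rec3 <- qa_filter(extract_matchup(sc, site,
                                    masks = list(cloud = all_mask)))
  expect_equal(rec3$n_valid_10m, 0)
  expect_false(rec3$accepted)
  expect_equal(rec3$reason, "low_n")

  expect_error(extract_matchup(sc, list(site_id = "x", x = 1e6, y = 1e6)),
               "off the raster")
})

test_that("a 3x3 disc with values 1..9 gives median 5 and n_valid 9", {
  sc <- toy_scene(nx = 3, ny = 3)
  for (b in names(sc$bands)) sc$bands[[b]] <- matrix(1:9 / 10, 3, 3)
  sc$cloud_prob <- matrix(0, 3, 3)
  rec <- extract_matchup(sc, list(site_id = "s", x = 15, y = 15),
                         radius_m = 16)
  expect_equal(rec$n_valid_10m, 9)
  expect_equal(unname(rec$band_median[["B2"]]), 0.5)
})

test_that("the quality filter enforces the 9-pixel and CV 0.15 bounds", {
  mk_record <- function(n, cvals) {
    values <- lapply(s2_bands()$band, function(b) rep(0.1, n))
    names(values) <- s2_bands()$band
    for (b in names(cvals)) {
      # synthesise values with mean 0.1 and SD 0.1 * cv (CV as requested)
      z <- seq_len(n)
      values[[b]] <- 0.1 + (z - mean(z)) / stats::sd(z) * 0.1 * cvals[[b]]
    }
    structure(list(record_id = "r", site_id = "s", scene_id = "sc",
                   n_in_disc = n, n_valid_10m = n, band_values = values,
                   band_median = NULL, band_sd = NULL,
                   flags = list(cloud = FALSE, shadow = FALSE,
                                glint = FALSE, low_n = FALSE,
                                high_cv = FALSE),
                   accepted = NA, reason = NA_character_),
              class = "matchup_record")
  }
  # n_valid 8 with fine CVs: low_n
  r1 <- qa_filter(mk_record(8, list(B1 = 0.01, B2 = 0.01, B3 = 0.01,
                                    B4 = 0.01)), outlier_k = 100)
  expect_false(r1$accepted); expect_equal(r1$reason, "low_n")

  # CVs {0.05, 0.10, 0.20, 0.30}: median 0.15 accepted
  r2 <- qa_filter(mk_record(12, list(B1 = 0.05, B2 = 0.10, B3 = 0.20,
                                     B4 = 0.30)), outlier_k = 100)
  expect_equal(r2$median_cv, 0.15, tolerance = 1e-10)
  expect_true(r2$accepted)

  # all CVs 0.16: high_cv
  r3 <- qa_filter(mk_record(12, list(B1 = 0.16, B2 = 0.16, B3 = 0.16,
                                     B4 = 0.16)), outlier_k = 100)
  expect_false(r3$accepted); expect_equal(r3$reason, "high_cv")

  # glint-flagged records are rejected regardless of CV
  r4 <- mk_record(12, list(B1 = 0.01, B2 = 0.01, B3 = 0.01, B4 = 0.01))
  r4$flags$glint <- TRUE
  r4 <- qa_filter(r4, outlier_k = 100)
  expect_false(r4$accepted); expect_equal(r4$reason, "glint")

  # zero-mean CV band: degenerate
  r5 <- mk_record(12, list())
  for (b in cv_filter_bands <- c("B1", "B2", "B3", "B4")) {
    r5$band_values[[b]] <- rep(0, 12)
  }
  r5 <- qa_filter(r5)
  expect_false(r5$accepted); expect_equal(r5$reason, "degenerate")

  # tightening max_cv never accepts a previously rejected record
  r6 <- qa_filter(mk_record(12, list(B1 = 0.1, B2 = 0.1, B3 = 0.1,
                                     B4 = 0.1)), max_cv = 0.15,
                  outlier_k = 100)
  r7 <- qa_filter(mk_record(12, list(B1 = 0.1, B2 = 0.1, B3 = 0.1,
                                     B4 = 0.1)), max_cv = 0.05,
                  outlier_k = 100)
  expect_true(r6$accepted); expect_false(r7$accepted)
})

test_that("every extracted record gets exactly one verdict and reason", {
  w <- tiny_world(seed = 9)
  sc <- render_scene(w, scene_time(), sun_zenith = 50,
                     cloud_cover_frac = 0.2, seed = 4)
  cl <- cloud_mask(sc)
  sh <- shadow_mask(sc, cl, heights_m = seq(200, 1000, 200))
  recs <- lapply(seq_len(nrow(w$sites)), function(i) {
    qa_filter(extract_matchup(sc, list(record_id = as.character(i),
                                       site_id = w$sites$site_id[i],
                                       x = w$sites$x[i], y = w$sites$y[i]),
                              masks = list(cloud = cl, shadow = sh)))
  })
  tab <- matchup_table(recs)
  expect_equal(nrow(tab), nrow(w$sites))
  expect_true(all(tab$accepted %in% c(TRUE, FALSE)))
  expect_true(all(tab$reason[!tab$accepted] %in%
                    c("low_n", "glint", "degenerate", "high_cv")))
  expect_true(all(tab$reason[tab$accepted] == "accepted"))
  expect_true(all(tab$n_valid_10m[tab$accepted] >= 9))
  expect_true(all(tab$median_cv[tab$accepted] <= 0.15))
})
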
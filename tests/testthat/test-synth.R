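test_that("worlds are deterministic in the seed and respect geometry", {
  w1 <- tiny_world(seed = 1)
  w2 <- tiny_world(seed = 1)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))

  w3 <- tiny_world(seed = 2)
  expect_true(any(w1$sites$x != w3$sites$x | w1$sites$y != w3$sites$y))

  # every site within the 30 m-buffered estuary; truth non-negative
  expect_true(all(dist_to_polygon(w1$sites$x, w1$sites$y,
                                  w1$estuary$E1) <= 30))
  expect_true(all(w1$fields$chlorophyll >= 0))
  expect_setequal(unique(w1$sites$owt), 1:4)

  expect_error(make_world(nx = 16, ny = 16), "32")
  expect_error(make_world(n_sites = 0), "site")
})

test_that("forward model reproduces the green/red-edge spectral shape", {
  arcs <- bio_archetypes()
  for (a in arcs) {
    r0 <- forward_reflectance(0, a)
    expect_equal(unname(r0), unname(a$baseline))  # zero-signal case

    r5 <- forward_reflectance(5, a)
    r50 <- forward_reflectance(50, a)
    expect_gt(r50[["B5"]], r5[["B5"]])            # monotone at 705 nm

    r10 <- forward_reflectance(10, a)
    vis <- c("B1", "B2", "B3", "B4", "B5")
    expect_identical(names(which.max(r10[vis])), "B3")   # 560 nm maximum
    expect_gt(r10[["B5"]], r10[["B4"]])           # secondary 705 nm peak
    expect_gt(r10[["B5"]], r10[["B6"]])
    expect_true(all(r10 >= 0 & r10 <= 1))
  }
  expect_error(forward_reflectance(-1, arcs[[1]]), "chl")
})

test_that("noiseless archetype profiles are recovered exactly by clustering", {
  ap <- archetype_profiles(n_per = 12, noiseless = TRUE)
  fit <- fuzzy_cmeans(ap$profiles, 4, seed = 3)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(fit$cluster, ap$labels), 1)
})

test_that("rendered scenes carry calibrated clouds and projected shadows", {
  w <- tiny_world(seed = 4)

  sc0 <- render_scene(w, scene_time(), cloud_cover_frac = 0, seed = 1)
  expect_true(all(sc0$cloud_prob < 0.2))          # cloud-free case

  sc3 <- render_scene(w, scene_time(), cloud_cover_frac = 0.3, seed = 1)
  expect_lt(abs(mean(sc3$cloud_prob >= 0.5) - 0.3), 0.05)

  # nadir sun: shadows coincide with clouds
  scz <- render_scene(w, scene_time(), sun_zenith = 0,
                      cloud_cover_frac = 0.2, seed = 2)
  expect_identical(scz$true_shadow, scz$true_cloud)

  # oblique sun: shadow centroid displaced by h*tan(zenith) anti-solar;
  # a low cloud deck keeps the projection on this small grid
  w_low <- make_world(nx = 32, ny = 32, n_sites = 4, seed = 4,
                      cloud_top_height_m = 120)
  sc45 <- render_scene(w_low, scene_time(), sun_zenith = 45,
                       sun_azimuth = 180, cloud_cover_frac = 0.2, seed = 2)
  h <- w_low$cloud_top_height_m
  # anti-solar azimuth for sun at 180 (south) is north: displacement
  # (0, +h*tan(45)) = (0, +120 m) = (0, +12 px)
  dpx <- round(h * tan(45 * pi / 180) / w_low$res_m)
  sh <- which(sc45$true_shadow, arr.ind = TRUE)
  expect_gt(nrow(sh), 0)
  # every shadow pixel maps back to a cloud pixel...
  expect_true(all(sc45$true_cloud[cbind(sh[, 1], sh[, 2] - dpx)]))
  # ...and every cloud pixel with an on-grid projection casts a shadow
  cl <- which(sc45$true_cloud, arr.ind = TRUE)
  cl <- cl[cl[, 2] + dpx <= ncol(sc45$true_cloud), , drop = FALSE]
  expect_true(all(sc45$true_shadow[cbind(cl[, 1], cl[, 2] + dpx)]))

  expect_error(render_scene(w, scene_time(), sun_zenith = 95), "sun_zenith")
  expect_error(render_scene(w, scene_time(), cloud_cover_frac = 1.5),
               "cloud_cover_frac")

  # determinism
  sc_a <- render_scene(w, scene_time(), cloud_cover_frac = 0.15, seed = 9)
  sc_b <- render_scene(w, scene_time(), cloud_cover_frac = 0.15, seed = 9)
  expect_identical(serialize(sc_a, NULL), serialize(sc_b, NULL))
})

test_that("shadow displacement matches the trigonometric oracle", {
  w <- tiny_world(seed = 4)
  # single synthetic cloud pixel, projected at one height
  sc <- render_scene(w, scene_time(), sun_zenith = 45, sun_azimuth = 90,
                     cloud_cover_frac = 0, seed = 1)
  cloud <- matrix(FALSE, 32, 32); cloud[16, 16] <- TRUE
  sh <- shadow_mask(sc, cloud, heights_m = 100)
  # sun in the east (az 90): shadow falls to the west by 100*tan(45) = 100 m
  expect_true(sh[16 - 10, 16])
  expect_equal(sum(sh), 1)
})

test_that("dialect exports honour offsets, units and planted corruption", {
  w <- tiny_world(seed = 2)
  times <- scene_time("2019-06-01", "15:00:00")
  em <- emit_insitu_sources(w, times = times, seed = 5,
                            rates = list(qa = 0, missing_time = 0,
                                         missing_depth = 0, rfu = 0,
                                         duplicate = 0,
                                         ambiguous_method = 0))
  # buoynet is UTC-5: true 15:00 UTC prints as local 10:00
  expect_match(em$raw$buoynet$SampleDateTime[1], "10:00:00")
  # units: buoynet reports Fahrenheit
  tr <- em$truth[em$truth$source == "buoynet", ]
  expect_equal(em$raw$buoynet$WTemp, round(tr$temperature * 9 / 5 + 32, 4))

  # an RFU-labelled dialect marks every chlorophyll record expect-drop
  rfu_dialect <- source_dialect(
    name = "rfusensor",
    column_map = c(site_id = "stn", datetime = "dt", lat = "lat",
                   lon = "lon", depth = "z", chlorophyll = "RFU",
                   chl_units = "units", temperature = "t", salinity = "s",
                   dissolved_oxygen = "o", turbidity = "tb",
                   method = "m", qa = "q"),
    unit_map = c(chlorophyll = "ug/L", temperature = "C", salinity = "ppt",
                 dissolved_oxygen = "mg/L", turbidity = "NTU"),
    tz_offset = 0, chl_label = "RFU")
  em2 <- emit_insitu_sources(w, dialects = list(rfu_dialect),
                             times = times, seed = 5)
  expect_true(all(em2$raw$rfusensor$units == "RFU"))
  h <- harmonize_source(em2$raw$rfusensor, rfu_dialect)
  expect_true(all(h$rejects$rule[h$rejects$variable == "chlorophyll"] ==
                    "rfu"))
  expect_false("chlorophyll" %in% h$observations$variable)

  expect_error(emit_insitu_sources(w, dialects = list(), times = times),
               "dialect")
})
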
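test_that("UTC conversion handles offsets and the standard-time fallback", {
  r <- to_utc(as.POSIXct("2019-06-01 10:00:00", tz = "UTC"), tz_offset = -5)
  expect_equal(format(r$utc_time, "%Y-%m-%d %H:%M"), "2019-06-01 15:00")
  expect_false(r$fallback)

  # offset 0: identity
  r0 <- to_utc(as.POSIXct("2019-06-01 23:30:00", tz = "UTC"), tz_offset = 0)
  expect_equal(format(r0$utc_time, "%H:%M"), "23:30")

  # missing time: local noon shifted by round(lon/15)
  rf <- to_utc(NA, site_lon = -71.4, date = as.Date("2019-06-01"))
  expect_true(rf$fallback)
  expect_equal(format(rf$utc_time, "%H:%M"), "17:00")   # noon - (-5 h)

  expect_error(to_utc(NA, date = as.Date("2019-06-01")), "site_lon")
  expect_error(to_utc(NA, site_lon = -71), "date")
})

test_that("depth categories follow the 3 m and 6 m bounds", {
  expect_equal(depth_category(c(1.2, 3.0, 4.5, 6.0, 7.5)),
               c("surface", "middle", "middle", "middle", "bottom"))
  expect_equal(depth_category(NA), "unknown")
  expect_error(depth_category(-0.5), "negative")
})

test_that("range and QA filters apply the published strict bounds", {
  obs <- data.frame(
    record_id = sprintf("r%d", 1:6),
    site_id = "s1", variable = c("chlorophyll", "chlorophyll", "doc",
                                 "doc", "tss", "temperature"),
    value = c(0.005, 420.40, 600, 1.0, 50, -2),
    qa_pass = TRUE, stringsAsFactors = FALSE)
  out <- apply_range_filters(obs)
  expect_setequal(out$rejects$record_id, c("r1", "r3"))
  expect_true(all(out$rejects$rule == "range"))
  expect_true("r2" %in% out$observations$record_id)   # 420.40 kept
  expect_true("r6" %in% out$observations$record_id)   # no bounds on temp

  # originator QA failures are rejected with rule qa
  obs$qa_pass[5] <- FALSE
  out2 <- apply_range_filters(obs)
  expect_equal(out2$rejects$rule[out2$rejects$record_id == "r5"], "qa")
})

test_that("dedupe keeps the first record per key and logs the rest", {
  t1 <- as.POSIXct("2021-06-01 12:00:00", tz = "UTC")
  obs <- data.frame(
    record_id = c("a", "b", "c"), site_id = "s1",
    variable = "chlorophyll", date = as.Date("2021-06-01"),
    utc_time = c(t1, t1, t1 + 3600),
    value = c(5, 7, 9), stringsAsFactors = FALSE)
  out <- dedupe(obs)
  expect_equal(out$observations$record_id, c("a", "c"))  # first kept;
  expect_equal(out$rejects$record_id, "b")               # distinct times kept
  expect_equal(out$rejects$rule, "duplicate")
})

test_that("depthless records leave the matching stream only", {
  obs <- data.frame(record_id = c("a", "b"), variable = "chlorophyll",
                    depth_m = c(NA, 0.5), stringsAsFactors = FALSE)
  out <- drop_missing_depth(obs)
  expect_equal(out$observations$record_id, "b")
  expect_equal(out$rejects$rule, "missing_depth")
  # all-depth input is the identity
  all_d <- drop_missing_depth(out$observations)
  expect_equal(all_d$observations, out$observations)
  expect_equal(nrow(all_d$rejects), 0)
})

test_that("harmonization maps labels, units and QA vocabularies", {
  w <- tiny_world(seed = 3)
  times <- as.POSIXct(c("2021-06-01 14:00:00", "2021-06-06 14:00:00"),
                      tz = "UTC")
  em <- emit_insitu_sources(w, times = times, seed = 2)
  h <- harmonize_source(em$raw$buoynet, em$dialects$buoynet)
  chl <- h$observations[h$observations$variable == "chlorophyll", ]
  expect_true(all(chl$chl_category == "CHL_Fluor"))   # Chl_F source label
  expect_true(all(h$observations$qa_flags %in%
                    names(em$dialects$buoynet$qa_vocab)))
  # Fahrenheit converted to Celsius
  tr <- em$truth[em$truth$source == "buoynet", ]
  tt <- h$observations[h$observations$variable == "temperature", ]
  m <- match(tr$record_id, tt$record_id)
  expect_equal(tt$value[m], tr$temperature, tolerance = 1e-9)

  expect_error(harmonize_source(em$raw$buoynet[, -2],
                                em$dialects$buoynet), "lacks mapped")
})

test_that("synthetic exports round-trip exactly and corruptions are caught", {
  w <- tiny_world(seed = 6)
  times <- as.POSIXct(paste(seq(as.Date("2021-06-01"), by = 5,
                                length.out = 5), "14:00:00"), tz = "UTC")
  em <- emit_insitu_sources(w, times = times, seed = 9)
  parts <- lapply(names(em$raw), function(nm) {
    harmonize_source(em$raw[[nm]], em$dialects[[nm]])
  })
  obs <- do.call(rbind, lapply(parts, `[[`, "observations"))
  rejects <- do.call(rbind, lapply(parts, `[[`, "rejects"))
  rf <- apply_range_filters(obs)
  dd <- dedupe(rf$observations)
  md <- drop_missing_depth(dd$observations)
  rejects <- rbind(rejects, rf$rejects, dd$rejects, md$rejects)

  truth <- em$truth
  clean <- truth[truth$corruption == "none", ]

  # every clean record's canonical values recovered exactly
  for (v in c("chlorophyll", "temperature", "salinity",
              "dissolved_oxygen", "turbidity")) {
    sub <- md$observations[md$observations$variable == v, ]
    m <- match(clean$record_id, sub$record_id)
    expect_false(anyNA(m))
    expect_equal(sub$value[m], clean[[v]], tolerance = 1e-9)
    expect_equal(as.numeric(sub$utc_time[m]), as.numeric(clean$utc_time))
  }

  # every planted corruption with an expected rule appears in the log
  planted <- truth[truth$expected_rule != "", ]
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(rejects$record_id == planted$record_id[i] &
          rejects$rule == planted$expected_rule[i])
  }, logical(1))
  expect_true(all(hit))

  # missing-time records flagged, not dropped
  mt <- truth$record_id[truth$corruption == "missing_time"]
  sub <- md$observations[md$observations$variable == "chlorophyll", ]
  expect_true(all(mt %in% sub$record_id))
  expect_true(all(sub$time_fallback[match(mt, sub$record_id)]))

  # key uniqueness after dedupe
  key <- paste(md$observations$site_id, md$observations$variable,
               md$observations$date, md$observations$utc_time)
  expect_false(any(duplicated(key)))
})

test_that("harmonizing an already-canonical table is idempotent", {
  canon <- source_dialect(
    name = "canon",
    column_map = c(site_id = "site_id", datetime = "datetime", lat = "lat",
                   lon = "lon", depth = "depth",
                   chlorophyll = "Chlorophyll", chl_units = "chl_units",
                   temperature = "temperature", salinity = "salinity",
                   dissolved_oxygen = "dissolved_oxygen",
                   turbidity = "turbidity", method = "method", qa = "qa"),
    unit_map = c(chlorophyll = "ug/L", temperature = "C", salinity = "ppt",
                 dissolved_oxygen = "mg/L", turbidity = "NTU"),
    tz_offset = 0, chl_label = "Chlorophyll",
    qa_vocab = c("0" = "pass"), method_labels = c(sensor = "in_vivo"))
  raw <- data.frame(site_id = "s1", datetime = "06/01/2021 12:00:00",
                    lat = 41.5, lon = -71, depth = "1.5",
                    Chlorophyll = 4.2, chl_units = "ug/L",
                    temperature = 18.2, salinity = 22.1,
                    dissolved_oxygen = 8.8, turbidity = 3.3,
                    method = "sensor", qa = "0",
                    stringsAsFactors = FALSE)
  h1 <- harmonize_source(raw, canon)$observations
  expect_equal(nrow(h1), 5)
  expect_equal(h1$value[h1$variable == "chlorophyll"], 4.2)
  expect_equal(format(h1$utc_time[1], "%H:%M"), "12:00")
  expect_equal(unique(h1$depth_category), "surface")
})
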
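# Dialect-scrambled in situ exports.
#
# Real monitoring programs export the same physical observation under
# different column names, units, time zones, depth encodings and QA
# vocabularies. A `source_dialect` captures one such export convention; the
# emitter renders canonical truth through a dialect, planting a known
# fraction of corrupted records (failing QA, missing time/depth,
# RFU-only chlorophyll, duplicates) whose expected fate is recorded in the
# truth table.

#' Define a source export dialect
#'
#' @param name source label.
#' @param column_map named character vector mapping canonical column names
#'   to the source's column names; must be invertible (no duplicated source
#'   names).
#' @param unit_map named character vector: canonical variable -> unit
#'   string used by the source (e.g. `temperature = "F"`).
#' @param tz_offset hours from UTC of the source's local clock (local =
#'   UTC + offset).
#' @param depth_encoding `"numeric"` (metres) or `"coded"` (instrument
#'   strings `"D<metres>"`).
#' @param chl_label how the source labels chlorophyll: one of
#'   `"Chlorophyll"`, `"Chlorophyll-A"`, `"Chl_F"`, `"fluorescence"`,
#'   `"RFU"`. `"RFU"` marks a sensor source reporting relative fluorescence
#'   units only; such values cannot be converted to concentration and are
#'   dropped at harmonization.
#' @param qa_vocab named character vector: source QA code -> `"pass"` or
#'   `"fail"`.
#' @param method_labels named character vector: source method label ->
#'   `"in_vivo"`, `"in_vitro"` or `"unknown"`.
#' @param datetime_style `"combined"` (one `datetime` column,
#'   `%m/%d/%Y %H:%M:%S`) or `"split"` (`date` + `time` columns).
#' @return An object of class `source_dialect`.
#' @export
source_dialect <- function(name, column_map, unit_map, tz_offset,
                           depth_encoding = c("numeric", "coded"),
                           chl_label = "Chlorophyll",
                           qa_vocab = c("0" = "pass", "4" = "fail"),
                           method_labels = c(sensor = "in_vivo"),
                           datetime_style = c("combined", "split")) {
  depth_encoding <- match.arg(depth_encoding)
  datetime_style <- match.arg(datetime_style)
  if (anyDuplicated(column_map)) {
    stop("column_map is not invertible: duplicated source column names")
  }
  chl_label <- match.arg(chl_label, c("Chlorophyll", "Chlorophyll-A",
                                      "Chl_F", "fluorescence", "RFU"))
  vars <- intersect(names(column_map),
                    c("chlorophyll", "temperature", "salinity",
                      "dissolved_oxygen", "turbidity"))
  miss <- setdiff(vars, names(unit_map))
  if (length(miss)) {
    stop("unit_map missing entries for: ", paste(miss, collapse = ", "))
  }
  structure(list(name = name, column_map = column_map, unit_map = unit_map,
                 tz_offset = tz_offset, depth_encoding = depth_encoding,
                 chl_label = chl_label, qa_vocab = qa_vocab,
                 method_labels = method_labels,
                 datetime_style = datetime_style),
            class = "source_dialect")
}

#' Built-in example dialects
#'
#' Two contrasting conventions: a buoy sensor network (combined local
#' timestamps at UTC-5, Fahrenheit temperatures, coded depths, numeric QA
#' codes, in vivo fluorescence chlorophyll) and a laboratory grab-sample
#' program (split date/time at UTC-8, SI units, letter QA codes, in vitro
#' chlorophyll).
#'
#' @return Named list of [source_dialect()] objects.
#' @export
default_dialects <- function() {
  list(
    buoynet = source_dialect(
      name = "buoynet",
      column_map = c(site_id = "StationID", datetime = "SampleDateTime",
                     lat = "Latitude", lon = "Longitude",
                     depth = "SensorDepth", chlorophyll = "Chl_F",
                     chl_units = "ChlUnits", temperature = "WTemp",
                     salinity = "Sal", dissolved_oxygen = "ODO",
                     turbidity = "Turb", method = "Method", qa = "QAFlag"),
      unit_map = c(chlorophyll = "ug/L", temperature = "F",
                   salinity = "PSU", dissolved_oxygen = "mg/L",
                   turbidity = "NTU"),
      tz_offset = -5, depth_encoding = "coded", chl_label = "Chl_F",
      qa_vocab = c("0" = "pass", "1" = "pass", "4" = "fail", "5" = "fail"),
      method_labels = c(sensor = "in_vivo", unknown = "unknown"),
      datetime_style = "combined"
    ),
    grablab = source_dialect(
      name = "grablab",
      column_map = c(site_id = "site", date = "sample_date",
                     time = "sample_time", lat = "lat", lon = "lon",
                     depth = "depth_m", chlorophyll = "Chlorophyll-A",
                     chl_units = "chl_units", temperature = "temp_c",
                     salinity = "salinity_ppt",
                     dissolved_oxygen = "do_mgl", turbidity = "turbidity_ntu",
                     method = "method", qa = "qa_code"),
      unit_map = c(chlorophyll = "mg/m3", temperature = "C",
                   salinity = "ppt", dissolved_oxygen = "mg/L",
                   turbidity = "NTU"),
      tz_offset = -8, depth_encoding = "numeric", chl_label = "Chlorophyll-A",
      qa_vocab = c("A" = "pass", "P" = "pass", "R" = "fail"),
      method_labels = c("EPA 445.0" = "in_vitro", unknown = "unknown"),
      datetime_style = "split"
    )
  )
}

#' Emit dialect-scrambled in situ exports with ground truth
#'
#' Samples every site of `world` at every time in `times`, draws observed
#' values from the world's true fields with small measurement noise, plants
#' corruptions at the configured rates, and renders one raw table per
#' dialect (sites are assigned to dialects round-robin). The truth table
#' keeps the canonical values and, for every planted corruption, the
#' harmonization rule expected to catch it (`expected_rule`); records with
#' missing times are flagged `time_fallback` rather than dropped.
#'
#' @param world a `synthetic_world`.
#' @param dialects list of [source_dialect()] objects (>= 1).
#' @param times POSIXct vector of true sampling times (UTC).
#' @param seed integer RNG seed.
#' @param rates named list of corruption fractions: `qa`, `missing_time`,
#'   `missing_depth`, `rfu`, `duplicate` (defaults 0.05 each) and
#'   `ambiguous_method` (default 0.02).
#' @return List with elements `raw` (named list of data.frames, one per
#'   dialect), `truth` (canonical data.frame) and `dialects`.
#' @export
emit_insitu_sources <- function(world, dialects = default_dialects(),
                                times, seed = 1,
                                rates = list(qa = 0.05, missing_time = 0.05,
                                             missing_depth = 0.05,
                                             rfu = 0.05, duplicate = 0.05,
                                             ambiguous_method = 0.02)) {
  if (length(dialects) < 1) stop("at least one dialect is required")
  for (d in dialects) {
    if (anyDuplicated(d$column_map)) stop("non-invertible column_map")
  }
  set.seed(as.integer(seed))
  times <- as.POSIXct(times, tz = "UTC")
  sites <- world$sites
  dial_of_site <- rep_len(seq_along(dialects), nrow(sites))

  grid <- expand.grid(si = seq_len(nrow(sites)), ti = seq_along(times))
  n <- nrow(grid)
  noise <- function(v, sd) v + stats::rnorm(n, 0, sd)
  truth <- data.frame(
    record_id = sprintf("R%05d", seq_len(n)),
    source = vapply(dialects[dial_of_site[grid$si]],
                    function(d) d$name, character(1)),
    site_id = sites$site_id[grid$si],
    lat = sites$lat[grid$si], lon = sites$lon[grid$si],
    utc_time = times[grid$ti],
    depth_m = round(stats::runif(n, 0.2, 2.8), 2),
    chlorophyll = round(sites$true_chl[grid$si] *
                          exp(stats::rnorm(n, 0, 0.08)), 3),
    temperature = round(noise(sites$true_temperature[grid$si], 0.2), 2),
    salinity = round(pmax(0, noise(sites$true_salinity[grid$si], 0.2)), 2),
    dissolved_oxygen = round(pmax(0.05,
                                  noise(sites$true_do[grid$si], 0.15)), 2),
    turbidity = round(pmax(0.05,
                           noise(sites$true_turbidity[grid$si], 0.3)), 2),
    owt = sites$owt[grid$si],
    corruption = "none", expected_rule = "", time_fallback = FALSE,
    stringsAsFactors = FALSE
  )

  # disjoint corruption subsets
  pool <- sample(seq_len(n))
  take <- function(frac) {
    m <- min(length(pool), round(frac * n))
    out <- pool[seq_len(m)]
    pool <<- pool[-seq_len(m)]
    out
  }
  idx_qa <- take(rates$qa %||% 0)
  idx_rfu <- take(rates$rfu %||% 0)
  idx_mt <- take(rates$missing_time %||% 0)
  idx_md <- take(rates$missing_depth %||% 0)
  idx_amb <- take(rates$ambiguous_method %||% 0)
  truth$corruption[idx_qa] <- "qa"; truth$expected_rule[idx_qa] <- "qa"
  truth$corruption[idx_rfu] <- "rfu"; truth$expected_rule[idx_rfu] <- "rfu"
  truth$corruption[idx_mt] <- "missing_time"
  truth$time_fallback[idx_mt] <- TRUE
  truth$corruption[idx_md] <- "missing_depth"
  truth$expected_rule[idx_md] <- "missing_depth"
  truth$corruption[idx_amb] <- "ambiguous_method"
  truth$expected_rule[idx_amb] <- "ambiguous_method"

  # duplicates: copies of clean records appended at the end of each source
  idx_dup <- take(rates$duplicate %||% 0)
  if (length(idx_dup)) {
    dup <- truth[idx_dup, , drop = FALSE]
    dup$record_id <- sprintf("R%05d", n + seq_along(idx_dup))
    dup$corruption <- "duplicate"
    dup$expected_rule <- "duplicate"
    truth <- rbind(truth, dup)
  }
  truth <- truth[order(truth$source, truth$record_id), ]
  rownames(truth) <- NULL

  raw <- lapply(dialects, function(d) render_dialect_table(truth, d))
  names(raw) <- vapply(dialects, function(d) d$name, character(1))
  list(raw = raw, truth = truth, dialects = dialects)
}

# Render the truth rows belonging to one dialect into its raw export form.
render_dialect_table <- function(truth, d) {
  tr <- truth[truth$source == d$name, , drop = FALSE]
  n <- nrow(tr)
  conv <- function(var, v) {
    unit <- d$unit_map[[var]]
    switch(unit,
           "F" = v * 9 / 5 + 32,
           v)   # C, ug/L, mg/m3, ppt, PSU, mg/L, NTU are canonical scales
  }
  local_time <- tr$utc_time + d$tz_offset * 3600

  out <- data.frame(site_id = tr$site_id, stringsAsFactors = FALSE)
  if (d$datetime_style == "combined") {
    out$datetime <- format(local_time, "%m/%d/%Y %H:%M:%S", tz = "UTC")
    # a record with no clock time keeps only its (UTC) sample date
    mt <- tr$corruption == "missing_time"
    out$datetime[mt] <- format(tr$utc_time[mt], "%m/%d/%Y", tz = "UTC")
  } else {
    out$date <- format(local_time, "%Y-%m-%d", tz = "UTC")
    out$time <- format(local_time, "%H:%M:%S", tz = "UTC")
    out$time[tr$corruption == "missing_time"] <- ""
    # a record with no time has no local clock either: report the UTC date
    # of the (unknown-time) sample day
    out$date[tr$corruption == "missing_time"] <-
      format(as.Date(tr$utc_time[tr$corruption == "missing_time"],
                     tz = "UTC"), "%Y-%m-%d")
  }
  out$lat <- tr$lat; out$lon <- tr$lon
  out$depth <- if (d$depth_encoding == "coded") {
    sprintf("D%.2f", tr$depth_m)
  } else {
    as.character(tr$depth_m)
  }
  out$depth[tr$corruption == "missing_depth"] <- ""

  chl <- tr$chlorophyll
  chl_units <- rep(d$unit_map[["chlorophyll"]], n)
  is_rfu <- d$chl_label == "RFU" | tr$corruption == "rfu"
  chl[is_rfu] <- round(tr$chlorophyll[is_rfu] * 3.2 + 12, 2)  # sensor counts
  chl_units[is_rfu] <- "RFU"
  out$chlorophyll <- chl
  out$chl_units <- chl_units
  out$temperature <- round(conv("temperature", tr$temperature), 4)
  out$salinity <- round(conv("salinity", tr$salinity), 4)
  out$dissolved_oxygen <- round(conv("dissolved_oxygen",
                                     tr$dissolved_oxygen), 4)
  out$turbidity <- round(conv("turbidity", tr$turbidity), 4)

  known <- names(d$method_labels)[d$method_labels != "unknown"]
  out$method <- rep(known[1], n)
  out$method[tr$corruption == "ambiguous_method"] <- "unknown"

  pass_codes <- names(d$qa_vocab)[d$qa_vocab == "pass"]
  fail_codes <- names(d$qa_vocab)[d$qa_vocab == "fail"]
  out$qa <- sample(pass_codes, n, replace = TRUE)
  out$qa[tr$corruption == "qa"] <- sample(fail_codes,
                                          sum(tr$corruption == "qa"),
                                          replace = TRUE)
  out$record_id <- tr$record_id   # join key kept for verification

  # rename canonical -> source columns
  cm <- d$column_map
  if (d$datetime_style == "combined") {
    cm <- cm[setdiff(names(cm), c("date", "time"))]
  } else {
    cm <- cm[setdiff(names(cm), "datetime")]
  }
  for (canon in names(cm)) {
    names(out)[names(out) == canon] <- cm[[canon]]
  }
  out
}

#' Write in situ exports to CSV
#'
#' One CSV per dialect plus the canonical truth table.
#'
#' @param emitted result of [emit_insitu_sources()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_insitu_sources <- function(emitted, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(emitted$raw)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(emitted$raw[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.csv")
  tr <- emitted$truth
  tr$utc_time <- format(tr$utc_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(tr, p, row.names = FALSE)
  invisible(c(paths, p))
}
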
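# Harmonization of heterogeneous source tables into the unified
# observation schema: canonical names and units, UTC times, depth
# categories, chlorophyll method categories, QA verdicts, range filters
# and deduplication. Every dropped row is logged with the rule that
# dropped it.

canonical_variables <- function() {
  c("chlorophyll", "temperature", "salinity", "dissolved_oxygen",
    "turbidity", "ph", "doc", "tss")
}

chl_category_of <- function(label) {
  switch(label,
         "Chlorophyll" = "CHL", "Chlorophyll-A" = "CHLA",
         "Chl_F" = "CHL_Fluor", "fluorescence" = "fluorescence",
         "RFU" = "RFU",
         stop("unknown chlorophyll label: ", label))
}

# Unit conversion to canonical scales (ug/L, C, ppt, mg/L, NTU).
convert_unit <- function(value, unit, variable) {
  switch(unit,
         "C" = , "ug/L" = , "mg/m3" = , "ppt" = , "PSU" = , "psu" = ,
         "mg/L" = , "NTU" = , "unitless" = value,
         "F" = (value - 32) * 5 / 9,
         stop("unknown unit '", unit, "' for ", variable))
}

#' Convert a local timestamp (or a bare date) to UTC
#'
#' With a timestamp present, UTC = local - offset hours. With the time
#' absent, the record is placed at local noon of its calendar date using
#' the site's standard-time offset -- `tz_offset` when known, otherwise
#' `round(site_lon / 15)` hours -- and flagged as a fallback.
#'
#' @param local_datetime POSIXct local clock time (tz-naive, stored as
#'   UTC), or `NA` when the source omitted the time.
#' @param tz_offset hours from UTC (local = UTC + offset), or `NA`.
#' @param site_lon site longitude in degrees, used only for the
#'   standard-time fallback when `tz_offset` is unknown.
#' @param date calendar `Date`, required when `local_datetime` is `NA`.
#' @return List with `utc_time` (POSIXct) and `fallback` (logical).
#' @export
to_utc <- function(local_datetime, tz_offset = NA, site_lon = NA,
                   date = NULL) {
  if (length(local_datetime) != 1) stop("one timestamp at a time")
  have_offset <- !is.na(tz_offset)
  if (!is.na(local_datetime)) {
    if (!have_offset) stop("tz_offset required when a clock time is present")
    return(list(utc_time = as.POSIXct(local_datetime, tz = "UTC") -
                  tz_offset * 3600,
                fallback = FALSE))
  }
  if (is.null(date) || is.na(date)) stop("date required when time is absent")
  off <- if (have_offset) tz_offset else {
    if (is.na(site_lon)) stop("neither tz_offset nor site_lon available")
    round(site_lon / 15)
  }
  noon <- as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC")
  list(utc_time = noon - off * 3600, fallback = TRUE)
}

#' Depth category from sampling depth
#'
#' Surface is shallower than 3 m, middle is 3-6 m (both bounds inclusive),
#' bottom is deeper than 6 m. `NA` depths map to `"unknown"`.
#'
#' @param depth_m numeric vector of depths in metres (>= 0).
#' @return Character vector in
#'   `{"surface", "middle", "bottom", "unknown"}`.
#' @export
depth_category <- function(depth_m) {
  if (any(depth_m < 0, na.rm = TRUE)) stop("negative depth")
  out <- rep("unknown", length(depth_m))
  out[!is.na(depth_m) & depth_m < 3] <- "surface"
  out[!is.na(depth_m) & depth_m >= 3 & depth_m <= 6] <- "middle"
  out[!is.na(depth_m) & depth_m > 6] <- "bottom"
  out
}

empty_rejects <- function() {
  data.frame(record_id = character(0), variable = character(0),
             rule = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

reject_rows <- function(record_id, variable, rule, detail = "") {
  if (length(record_id) == 0) return(empty_rejects())
  data.frame(record_id = record_id, variable = variable, rule = rule,
             detail = detail, stringsAsFactors = FALSE)
}

#' Harmonize one raw source table
#'
#' Maps a dialect's columns to the canonical schema, converts units,
#' resolves local times to UTC (standard-time fallback for missing times),
#' decodes depths and assigns depth categories, classifies the chlorophyll
#' label and method, derives the QA verdict from the source vocabulary,
#' and rejects rows that cannot be harmonized: RFU-valued chlorophyll
#' (rule `rfu`) and chlorophyll with ambiguous or undefined method (rule
#' `ambiguous_method`). Source QA codes are retained verbatim.
#'
#' The result is long: one row per record x available variable.
#'
#' @param raw data.frame as exported by the source.
#' @param dialect the matching [source_dialect()].
#' @return List with `observations` (harmonized rows) and `rejects`
#'   (reject log).
#' @export
harmonize_source <- function(raw, dialect) {
  cm <- dialect$column_map
  if (dialect$datetime_style == "combined") {
    cm <- cm[setdiff(names(cm), c("date", "time"))]
  } else {
    cm <- cm[setdiff(names(cm), "datetime")]
  }
  missing_cols <- setdiff(unname(cm), names(raw))
  if (length(missing_cols)) {
    stop("raw table lacks mapped columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- raw
  inv <- stats::setNames(names(cm), unname(cm))
  names(x)[names(x) %in% names(inv)] <- inv[names(x)[names(x) %in%
                                                       names(inv)]]
  n <- nrow(x)
  record_id <- if ("record_id" %in% names(x)) as.character(x$record_id) else {
    sprintf("%s_%05d", dialect$name, seq_len(n))
  }

  # times
  if (dialect$datetime_style == "combined") {
    tstr <- as.character(x$datetime)
    local <- as.POSIXct(tstr, format = "%m/%d/%Y %H:%M:%S", tz = "UTC")
    dates <- as.Date(local)
    # date-only entries (missing clock time) parse as a bare date
    date_only <- is.na(local) & !is.na(tstr) & nzchar(tstr)
    dates[date_only] <- as.Date(tstr[date_only], format = "%m/%d/%Y")
  } else {
    dstr <- as.character(x$date); hstr <- as.character(x$time)
    local <- as.POSIXct(paste(dstr, hstr), format = "%Y-%m-%d %H:%M:%S",
                        tz = "UTC")
    dates <- as.Date(dstr, format = "%Y-%m-%d")
  }
  utc <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  fallback <- logical(n)
  for (i in seq_len(n)) {
    di <- if (!is.na(dates[i])) dates[i] else as.Date(local[i])
    if (is.na(local[i]) && is.na(di)) next  # neither time nor date: leave NA
    r <- to_utc(local[i], tz_offset = dialect$tz_offset,
                site_lon = suppressWarnings(as.numeric(x$lon[i])),
                date = di)
    utc[i] <- r$utc_time
    fallback[i] <- r$fallback
  }
  dates_utc <- as.Date(utc, tz = "UTC")

  # depths
  dstr <- as.character(x$depth)
  dstr[dstr == ""] <- NA
  depth_m <- if (dialect$depth_encoding == "coded") {
    as.numeric(sub("^D", "", dstr))
  } else {
    suppressWarnings(as.numeric(dstr))
  }

  # QA verdicts; codes retained verbatim
  qa_code <- as.character(x$qa)
  unknown <- setdiff(unique(qa_code), names(dialect$qa_vocab))
  if (length(unknown)) {
    stop("unknown QA code(s): ", paste(unknown, collapse = ", "))
  }
  qa_pass <- unname(dialect$qa_vocab[qa_code] == "pass")

  # chlorophyll method category
  mlab <- as.character(x$method)
  method_category <- ifelse(mlab %in% names(dialect$method_labels),
                            unname(dialect$method_labels[mlab]), "unknown")
  chl_cat <- chl_category_of(dialect$chl_label)
  chl_units <- as.character(x$chl_units)

  base <- data.frame(
    source = dialect$name, record_id = record_id,
    site_id = as.character(x$site_id),
    lat = as.numeric(x$lat), lon = as.numeric(x$lon),
    utc_time = utc, date = dates_utc, time_fallback = fallback,
    depth_m = depth_m, depth_category = depth_category(depth_m),
    method_category = method_category,
    qa_flags = qa_code, qa_pass = qa_pass, stringsAsFactors = FALSE
  )

  obs_list <- list()
  rejects <- empty_rejects()
  for (v in c("chlorophyll", "temperature", "salinity",
              "dissolved_oxygen", "turbidity")) {
    if (!v %in% names(x)) next
    val_raw <- suppressWarnings(as.numeric(x[[v]]))
    rows <- base
    rows$variable <- v
    rows$chl_category <- NA_character_
    if (v == "chlorophyll") {
      is_rfu <- !is.na(chl_units) & chl_units == "RFU"
      amb <- method_category == "unknown"
      keep <- !is_rfu & !amb
      rejects <- rbind(rejects,
                       reject_rows(record_id[is_rfu], v, "rfu",
                                   "relative fluorescence units"),
                       reject_rows(record_id[!is_rfu & amb], v,
                                   "ambiguous_method",
                                   "undefined chlorophyll method"))
      unit <- dialect$unit_map[[v]]
      rows$value <- convert_unit(val_raw, unit, v)
      rows$chl_category <- chl_cat
      rows <- rows[keep, , drop = FALSE]
    } else {
      rows$value <- convert_unit(val_raw, dialect$unit_map[[v]], v)
    }
    bad <- !is.finite(rows$value)
    if (any(bad)) {
      rejects <- rbind(rejects,
                       reject_rows(rows$record_id[bad], v, "range",
                                   "non-finite value"))
      rows <- rows[!bad, , drop = FALSE]
    }
    obs_list[[v]] <- rows
  }
  obs <- do.call(rbind, obs_list)
  rownames(obs) <- NULL
  list(observations = obs, rejects = rejects)
}

#' Apply originator-QA and published range filters
#'
#' Rows failing the originator's QA are rejected (rule `qa`). Published
#' range filters are strict inequalities: chlorophyll kept iff
#' 0.01 < v < 10,000 ug/L, TSS iff 0.01 < v < 100,000 mg/L, DOC iff
#' 0.01 < v < 500 mg/L. Other variables have no published numeric bounds
#' and pass through.
#'
#' @param obs harmonized observations.
#' @return List with `observations` and `rejects`.
#' @export
apply_range_filters <- function(obs) {
  rejects <- empty_rejects()
  fail_qa <- !obs$qa_pass
  rejects <- rbind(rejects,
                   reject_rows(obs$record_id[fail_qa], obs$variable[fail_qa],
                               "qa", "originator QA fail"))
  obs <- obs[!fail_qa, , drop = FALSE]
  bounds <- list(chlorophyll = c(0.01, 1e4), tss = c(0.01, 1e5),
                 doc = c(0.01, 500))
  out_of_range <- rep(FALSE, nrow(obs))
  for (v in names(bounds)) {
    sel <- obs$variable == v
    out_of_range[sel] <- obs$value[sel] <= bounds[[v]][1] |
      obs$value[sel] >= bounds[[v]][2]
  }
  rejects <- rbind(rejects,
                   reject_rows(obs$record_id[out_of_range],
                               obs$variable[out_of_range], "range",
                               "outside published bounds"))
  obs <- obs[!out_of_range, , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs, rejects = rejects)
}

#' Remove duplicate observations
#'
#' Retains exactly one record per (site, variable, date, time) key -- the
#' first in stable input order -- and logs the rest (rule `duplicate`).
#' Distinct times on the same day are distinct keys.
#'
#' @param obs harmonized observations.
#' @return List with `observations` and `rejects`.
#' @export
dedupe <- function(obs) {
  key <- paste(obs$site_id, obs$variable, obs$date,
               format(obs$utc_time, "%H:%M:%S"), sep = "|")
  dup <- duplicated(key)
  rejects <- reject_rows(obs$record_id[dup], obs$variable[dup],
                         "duplicate", "same site/variable/date/time")
  obs <- obs[!dup, , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs, rejects = rejects)
}

#' Exclude records without a recorded depth from the matching stream
#'
#' Depthless records stay in the unfiltered store but are not eligible for
#' satellite matching; this drops them (rule `missing_depth`) from the
#' stream headed to matchup.
#'
#' @param obs harmonized observations.
#' @return List with `observations` and `rejects`.
#' @export
drop_missing_depth <- function(obs) {
  miss <- is.na(obs$depth_m)
  rejects <- reject_rows(obs$record_id[miss], obs$variable[miss],
                         "missing_depth", "no recorded depth")
  obs <- obs[!miss, , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs, rejects = rejects)
}
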
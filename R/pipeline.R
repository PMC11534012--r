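# End-to-end orchestration: synthetic world -> scenes -> in situ exports
# -> harmonization -> site screening -> temporal matchup -> masking and
# extraction -> QA filters -> trophic classes, optical water types and
# discriminant analysis -> report tables, with a run manifest whose
# counts are conserved at every stage.

#' Run the full matchup pipeline on a synthetic world
#'
#' Generates a world and a scene series, emits dialect-scrambled in situ
#' exports, harmonizes and filters them, screens sites, builds matchups
#' under cloud/shadow/glint masking and the pixel-count/CV quality
#' filters, classifies chlorophyll into trophic-state classes, fits
#' optical water types by fuzzy c-means with validity-index selection,
#' and relates the types to water quality with the kNN discriminant
#' rule. Deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @param seed root integer seed; all stage seeds derive from it.
#' @param nx,ny world grid size (pixels at 10 m).
#' @param n_sites number of sampling sites.
#' @param n_scenes number of scenes in the series.
#' @param cloud_fracs per-scene cloud-cover fractions (recycled).
#' @param dialects in situ export dialects.
#' @param select_owt_k run validity-index selection of the cluster count
#'   (otherwise fit at `k = 4`).
#' @return A list of stage outputs with a `manifest`; see Details in the
#'   package vignette.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         nx = 64, ny = 64, n_sites = 24, n_scenes = 10,
                         cloud_fracs = c(0, 0.05, 0.15, 0.1, 0, 0.25,
                                         0.05, 0.1),
                         dialects = default_dialects(),
                         select_owt_k = FALSE) {
  seed <- as.integer(seed)
  world <- make_world(nx = nx, ny = ny, n_sites = n_sites, seed = seed)

  days <- seq(as.Date("2021-06-01"), by = 5, length.out = n_scenes)
  cloud_fracs <- rep_len(cloud_fracs, n_scenes)
  scenes <- lapply(seq_len(n_scenes), function(i) {
    render_scene(world,
                 sensing_time = as.POSIXct(paste(days[i], "15:30:00"),
                                           tz = "UTC"),
                 sun_zenith = 45 + (i %% 4) * 5,
                 sun_azimuth = 140 + i * 3,
                 view_zenith = 3 + (i %% 3),
                 view_azimuth = 280,
                 cloud_cover_frac = cloud_fracs[i],
                 seed = seed + 100L + i)
  })

  times <- as.POSIXct(paste(days, "14:00:00"), tz = "UTC")
  emitted <- emit_insitu_sources(world, dialects, times, seed = seed + 7L)

  harmonized <- lapply(names(emitted$raw), function(nm) {
    d <- emitted$dialects[[which(vapply(emitted$dialects,
                                        function(x) x$name,
                                        character(1)) == nm)]]
    harmonize_source(emitted$raw[[nm]], d)
  })
  obs <- do.call(rbind, lapply(harmonized, `[[`, "observations"))
  rejects <- do.call(rbind, lapply(harmonized, `[[`, "rejects"))
  n_candidate_rows <- sum(vapply(emitted$raw, nrow, numeric(1))) * 5

  rf <- apply_range_filters(obs)
  dd <- dedupe(rf$observations)
  store <- dd$observations               # unfiltered store keeps depthless
  md <- drop_missing_depth(store)
  stream <- md$observations
  rejects <- rbind(rejects, rf$rejects, dd$rejects, md$rejects)

  sites <- screen_sites(world$sites, world$estuary, world$shoreline,
                        world$roads, world$occurrence, config)

  chl <- stream[stream$variable == "chlorophyll" &
                  stream$depth_category == "surface", , drop = FALSE]
  chl <- chl[chl$site_id %in% sites$site_id[sites$eligible], , drop = FALSE]
  pairs <- temporal_match(chl, scenes, window_h = config$window_h)

  scene_by_id <- stats::setNames(scenes, vapply(scenes, `[[`, "", "id"))
  masks_by_id <- lapply(scene_by_id, function(sc) {
    cl <- cloud_mask(sc, config$cloud_prob_threshold)
    list(cloud = cl,
         shadow = shadow_mask(sc, cl, config$shadow_heights_m),
         glint = glint_flag(sc$sun_zenith, sc$sun_azimuth, sc$view_zenith,
                            sc$view_azimuth,
                            config$glint_angle_threshold_deg))
  })
  chl_by_id <- chl[match(pairs$record_id, chl$record_id), , drop = FALSE]
  records <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    o <- chl_by_id[i, ]
    xy <- world$proj$to_xy(o$lon, o$lat)
    rec <- extract_matchup(scene_by_id[[pairs$scene_id[i]]],
                           list(record_id = o$record_id,
                                site_id = o$site_id,
                                x = xy[1], y = xy[2]),
                           masks = masks_by_id[[pairs$scene_id[i]]],
                           radius_m = config$radius_m)
    records[[i]] <- qa_filter(rec, min_valid = config$min_valid_pixels,
                              max_cv = config$max_median_cv,
                              outlier_k = config$outlier_k)
  }
  mtab <- matchup_table(records)
  accepted <- if (nrow(mtab)) mtab[mtab$accepted, , drop = FALSE] else mtab

  # trophic classification of accepted matched chlorophyll
  acc_chl <- chl$value[match(accepted$record_id, chl$record_id)]
  tsi <- if (length(acc_chl) > 0) tsi_frequencies(acc_chl,
                                                  bounds =
                                                    config$bricker_bounds)
  else NULL

  # optical water types on band-median spectra
  owt <- NULL
  if (nrow(accepted) > 12) {
    profiles <- as.matrix(accepted[, paste0(s2_bands()$band, "_median")])
    colnames(profiles) <- s2_bands()$band
    if (select_owt_k) {
      sel <- select_k(profiles, k_range = config$fcm_k_range,
                      m = config$fcm_m, nstart = config$fcm_nstart,
                      seed = seed + 31L)
      fit <- sel$fits[[as.character(sel$k_star)]]
    } else {
      sel <- NULL
      fit <- NULL
      best <- Inf
      for (s in seq_len(config$fcm_nstart)) {
        f <- fuzzy_cmeans(profiles, 4, m = config$fcm_m,
                          seed = seed + 31L + s)
        if (f$objective < best) { best <- f$objective; fit <- f }
      }
    }
    owt <- list(selection = sel, fit = fit,
                cluster = fit$cluster, profiles = profiles)
  }

  # discriminant analysis: water-quality variables vs optical cluster
  discrim <- NULL
  if (!is.null(owt)) {
    wide <- wq_wide(store, accepted$record_id)
    feats <- c("chlorophyll", "dissolved_oxygen", "salinity",
               "temperature", "turbidity")
    feats <- feats[feats %in% colnames(wide)]
    ok <- stats::complete.cases(wide[, feats, drop = FALSE])
    labs <- factor(owt$cluster[ok])
    if (nlevels(labs) >= 2 && all(table(labs) > config$knn_k)) {
      discrim <- stepwise_select(as.matrix(wide[ok, feats, drop = FALSE]),
                                 labs, k = config$knn_k)
    }
  }

  result <- list(
    config = config, seed = seed, world = world, scenes = scenes,
    emitted = emitted, observations = store, stream = stream,
    rejects = rejects, sites = sites, pairs = pairs,
    matchups = mtab, accepted = accepted, tsi = tsi, owt = owt,
    discrim = discrim
  )
  result$manifest <- build_manifest(result, n_candidate_rows)
  result$report <- report_tables(result)
  result
}

# Wide water-quality table (one row per record key) from the long store.
wq_wide <- function(obs, record_ids) {
  sub <- obs[obs$record_id %in% record_ids, , drop = FALSE]
  vars <- unique(sub$variable)
  out <- data.frame(record_id = record_ids, stringsAsFactors = FALSE)
  for (v in vars) {
    sv <- sub[sub$variable == v, , drop = FALSE]
    out[[v]] <- sv$value[match(record_ids, sv$record_id)]
  }
  out
}

#' Run manifest with conserved stage counts
#'
#' @param result pipeline result (pre-manifest).
#' @param n_candidate_rows raw record x variable slots entering
#'   harmonization.
#' @return List of stage counts, the config hash and the seed.
#' @keywords internal
build_manifest <- function(result, n_candidate_rows) {
  rej <- result$rejects
  by_rule <- if (nrow(rej)) table(rej$rule) else table(character(0))
  cfg_json <- jsonlite::toJSON(unclass(result$config), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  n_acc <- if (nrow(result$matchups)) sum(result$matchups$accepted) else 0L
  list(
    config_hash = hash, seed = result$seed,
    ingested_rows = n_candidate_rows,
    rejected_before_store = sum(rej$rule != "missing_depth"),
    store_rows = nrow(result$observations),
    stream_rows = nrow(result$stream),
    rejected_by_rule = as.list(by_rule),
    sites_total = nrow(result$sites),
    sites_eligible = sum(result$sites$eligible),
    candidate_pairs = nrow(result$pairs),
    matchups_extracted = nrow(result$matchups),
    matchups_accepted = n_acc,
    matchups_rejected = nrow(result$matchups) - n_acc
  )
}

#' Summary report tables
#'
#' Emits the standard report set: per-variable water-quality summaries
#' (N, mean, SD, min, max, percent of records), match counts with method
#' shares, trophic-class frequencies, per-cluster water-quality
#' statistics, and the stepwise discriminant error matrix.
#'
#' @param result a [run_pipeline()] result.
#' @return Named list of data.frames (entries may be `NULL` when a stage
#'   had no data).
#' @export
report_tables <- function(result) {
  stream <- result$stream
  n_rec <- length(unique(stream$record_id))
  wq_summary <- do.call(rbind, lapply(split(stream, stream$variable),
                                      function(s) {
    data.frame(variable = s$variable[1], n = nrow(s),
               mean = mean(s$value), sd = stats::sd(s$value),
               min = min(s$value), max = max(s$value),
               percent_obs = 100 * length(unique(s$record_id)) / n_rec,
               stringsAsFactors = FALSE)
  }))
  rownames(wq_summary) <- NULL

  chl <- stream[stream$variable == "chlorophyll", , drop = FALSE]
  matched_ids <- unique(result$pairs$record_id)
  mm <- chl[chl$record_id %in% matched_ids, , drop = FALSE]
  mc <- table(factor(mm$method_category,
                     levels = c("in_vivo", "in_vitro", "unknown")))
  denom <- sum(mc[c("in_vivo", "in_vitro")])
  match_counts <- data.frame(
    category = c("observations", "matched", "accepted",
                 "in_vivo", "in_vitro"),
    count = c(n_rec, length(matched_ids),
              if (nrow(result$matchups)) sum(result$matchups$accepted)
              else 0L,
              mc[["in_vivo"]], mc[["in_vitro"]]),
    percent = c(NA, NA, NA,
                if (denom > 0) 100 * mc[["in_vivo"]] / denom else NA,
                if (denom > 0) 100 * mc[["in_vitro"]] / denom else NA),
    stringsAsFactors = FALSE)

  cluster_wq <- NULL
  if (!is.null(result$owt) && nrow(result$accepted)) {
    wide <- wq_wide(result$observations, result$accepted$record_id)
    wide$cluster <- result$owt$cluster
    vars <- setdiff(colnames(wide), c("record_id", "cluster"))
    cluster_wq <- do.call(rbind, lapply(vars, function(v) {
      do.call(rbind, lapply(split(wide[[v]], wide$cluster), function(z) {
        z <- z[!is.na(z)]
        data.frame(variable = v, n = length(z), mean = mean(z),
                   min = min(z), max = max(z),
                   q25 = unname(stats::quantile(z, 0.25)),
                   q75 = unname(stats::quantile(z, 0.75)))
      }))
    }))
    cluster_wq$cluster <- sub("\\..*$", "", rownames(cluster_wq))
    rownames(cluster_wq) <- NULL
  }

  list(wq_summary = wq_summary, match_counts = match_counts,
       tsi = result$tsi, cluster_wq = cluster_wq,
       error_matrix = if (!is.null(result$discrim))
         result$discrim$error_matrix else NULL)
}
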
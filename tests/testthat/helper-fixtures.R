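# Shared fixtures and independent brute-force oracles.

# Small world reused across tests (regenerated per file; cheap).
tiny_world <- function(seed = 1, n_sites = 8) {
  make_world(nx = 32, ny = 32, n_sites = n_sites, seed = seed)
}

scene_time <- function(day = "2021-06-01", clock = "15:30:00") {
  as.POSIXct(paste(day, clock), tz = "UTC")
}

# Exhaustive disc-membership oracle: scans every pixel centre.
oracle_disc_pixels <- function(r, x, y, radius_m) {
  hits <- NULL
  for (ix in seq_len(nrow(r$values))) {
    for (iy in seq_len(ncol(r$values))) {
      cx <- r$origin[1] + (ix - 0.5) * r$res
      cy <- r$origin[2] + (iy - 0.5) * r$res
      if ((cx - x)^2 + (cy - y)^2 <= radius_m^2) {
        hits <- rbind(hits, c(ix, iy))
      }
    }
  }
  if (is.null(hits)) cbind(ix = integer(0), iy = integer(0)) else hits
}

# Exhaustive point-to-polyline distance over dense samples of each segment.
oracle_polyline_dist <- function(px, py, line, step = 0.05) {
  best <- Inf
  for (i in seq_len(nrow(line) - 1)) {
    t <- seq(0, 1, by = step)
    xs <- line[i, 1] + t * (line[i + 1, 1] - line[i, 1])
    ys <- line[i, 2] + t * (line[i + 1, 2] - line[i, 2])
    best <- min(best, sqrt((xs - px)^2 + (ys - py)^2))
  }
  best
}

# Profiles from the four planted bio-optical archetypes.
archetype_profiles <- function(n_per = 15, noiseless = TRUE, seed = 7) {
  set.seed(seed)
  arcs <- bio_archetypes()
  lab <- rep(seq_along(arcs), each = n_per)
  chl <- stats::runif(length(lab), 1, 30)
  profs <- do.call(rbind, lapply(seq_along(lab), function(i) {
    forward_reflectance(chl[i], arcs[[lab[i]]], noise = !noiseless)
  }))
  list(profiles = profs, labels = lab, chl = chl)
}

# Four-class feature set where salinity separates classes 1-3 and only
# turbidity isolates class 4 (class 4 shares the salinity range of 1).
planted_discrim_data <- function(n_per = 60, seed = 11) {
  set.seed(seed)
  y <- factor(rep(1:4, each = n_per))
  n <- length(y)
  sal_mu <- c(0, 12, 24, 0)[as.integer(y)]
  data <- data.frame(
    salinity = sal_mu + stats::rnorm(n, 0, 1.2),
    temperature = stats::rnorm(n, 18, 4),
    dissolved_oxygen = stats::rnorm(n, 9, 2),
    chlorophyll = stats::rlnorm(n, log(6), 0.5),
    turbidity = ifelse(y == 4, 40, 5) + stats::rnorm(n, 0, 1)
  )
  list(x = as.matrix(data), y = y)
}
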
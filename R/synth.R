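# Synthetic study worlds: clustered reef grids, SST series with planted warm
# anomalies, latent bleaching-probability fields with known variogram
# structure, and effort-biased severity-coded reports. Every pipeline stage
# is testable offline against this generator's known ground truth.

# Run code under a derived seed without disturbing global RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483647)
}

#' Default planted thermal/bleaching events
#'
#' Each event strikes one archipelago cluster; mass bleaching episodes are
#' basin-scale, so event years always strike two or more clusters of a
#' region. Two cluster-events fall before the 1997/1998 El Nino (1988,
#' Caribbean), four in 1997/1998 itself (excluded from the before/after
#' periods), and sixteen after, all of identical footprint extent, so that
#' the late-period average annual extent of probable bleaching is eight
#' times the early-period average -- the decadal contrast the analysis is
#' built to detect.
#'
#' An event footprint is the hosting archipelago cluster: every reef cell of
#' the region whose nearest cluster centre is the event's. Identical
#' footprints make the planted decadal contrast exact.
#'
#' @return data frame with columns `year`, `region`, `cluster` (which reef
#'   cluster of the region hosts the event), `radius_km` (taper scale of the
#'   latent probability away from the event centre), `amplitude` (degrees C
#'   added to SST inside the footprint), `prob` (peak latent bleaching
#'   probability at the event centre).
#' @export
synth_events <- function() {
  data.frame(
    year = c(1988, 1988,
             1998, 1998, 1998, 1998,
             2002, 2002, 2002, 2002,
             2004, 2004,
             2005, 2005, 2005,
             2006, 2006,
             2009, 2009,
             2010, 2010, 2010),
    region = c("caribbean", "caribbean",
               "indian", "indian", "pacific_central", "east_pacific",
               "pacific_west", "pacific_west", "pacific_central",
               "pacific_central",
               "pacific_central", "pacific_central",
               "caribbean", "caribbean", "caribbean",
               "indian", "indian",
               "pacific_east", "pacific_east",
               "indian", "indian", "east_pacific"),
    cluster = c(1, 4,
                1, 4, 5, 1,
                1, 2, 2, 3,
                1, 4,
                2, 3, 5,
                2, 5,
                1, 4,
                3, 6, 2),
    radius_km = 400,
    amplitude = 2.5,
    prob = 0.9,
    stringsAsFactors = FALSE
  )
}

#' Synthetic-world configuration
#'
#' Defaults define the study conditions: a 1985-2010 span, six ocean regions
#' (three overlapping Pacific sections), clustered archipelago reef cells,
#' an exponential latent variogram, a low background bleaching rate away
#' from thermal events, and spatially clustered observation effort that
#' intensifies where events occur (monitoring follows bleaching).
#'
#' @param seed integer master seed; all generator randomness derives from
#'   it.
#' @param years simulated calendar years.
#' @param resolution grid resolution, degrees.
#' @param regions region table as in [region_specs()].
#' @param cells_per_region reef cells generated per region.
#' @param clusters_per_region archipelago clusters per region.
#' @param cluster_radius_km dispersion of cells around a cluster centre.
#' @param area_meanlog,area_sdlog log-normal per-cell reef area (km^2).
#' @param latent latent-field variogram: `family`, `nugget`, `psill`,
#'   `range_km` (must be a valid covariance family: exponential, spherical,
#'   gaussian or matern).
#' @param base_rate background (no-thermal-stress) bleaching probability.
#' @param events planted events, see [synth_events()].
#' @param sst SST generator: `mmm_base`, `mmm_lat_coef` (degrees C per
#'   degree of absolute latitude), `seasonal_amp` (peak-to-trough, degrees
#'   C), `noise_sd`, `noise_cap` (truncation keeping noise below the DHW
#'   accumulation threshold), `step_days` (3.5 = twice-weekly),
#'   `event_duration_days`.
#' @param effort observation effort: `centers_per_region` fixed monitoring
#'   stations, `decay_km` e-folding of survey probability with distance to
#'   the nearest station, `p_near` survey probability at a station,
#'   `event_survey` minimum survey probability over an active event
#'   footprint (bleaching events attract opportunistic surveys).
#' @param severity_noise probability a bleached surveyed cell is mis-reported
#'   as mild (severity 1).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         years = 1985:2010,
                         resolution = 0.04,
                         regions = region_specs(),
                         cells_per_region = 150,
                         clusters_per_region = 6,
                         cluster_radius_km = 120,
                         area_meanlog = 1.0,
                         area_sdlog = 0.35,
                         latent = list(family = "exponential", nugget = 0.02,
                                       psill = 0.6, range_km = 250),
                         base_rate = 0.02,
                         events = synth_events(),
                         sst = list(mmm_base = 29, mmm_lat_coef = -0.05,
                                    seasonal_amp = 3, noise_sd = 0.15,
                                    noise_cap = 0.45, step_days = 3.5,
                                    event_duration_days = 84),
                         effort = list(centers_per_region = 2,
                                       decay_km = 200, p_near = 0.9,
                                       event_survey = 0.85),
                         severity_noise = 0.1) {
  structure(as.list(environment()), class = "synth_config")
}

# km offsets -> degree offsets at a given latitude
.km_to_deg <- function(dlat_km, dlon_km, lat) {
  list(dlat = dlat_km / 111.32,
       dlon = dlon_km / (111.32 * pmax(cos(lat * pi / 180), 0.2)))
}

#' Generate a clustered synthetic reef grid
#'
#' Reef cells are placed in archipelago-like clusters inside each configured
#' region; per-cell reef areas are log-normal. Deterministic under the
#' configuration seed. Cluster centres are returned in attribute
#' `cluster_centres` (data frame: `region`, `cluster`, `lat`, `lon`) so
#' events and effort can anchor to them.
#'
#' @param cfg a [synth_config()].
#' @return a [reef_grid()].
#' @export
make_reef_grid <- function(cfg) {
  .with_seed(.sub_seed(cfg$seed, 1), {
    regions <- cfg$regions
    res <- cfg$resolution
    centres <- list(); cells <- list()
    for (i in seq_len(nrow(regions))) {
      rg <- regions[i, ]
      margin_lon <- (rg$lon_max - rg$lon_min) * 0.15
      margin_lat <- (rg$lat_max - rg$lat_min) * 0.15
      k <- cfg$clusters_per_region
      clat <- stats::runif(k, rg$lat_min + margin_lat, rg$lat_max - margin_lat)
      clon <- stats::runif(k, rg$lon_min + margin_lon, rg$lon_max - margin_lon)
      centres[[i]] <- data.frame(region = rg$name, cluster = seq_len(k),
                                 lat = clat,
                                 lon = ((clon + 180) %% 360) - 180,
                                 stringsAsFactors = FALSE)
      # equal quota per cluster: oversample, snap to cells, dedupe, trim
      quota <- round(cfg$cells_per_region / k)
      n_draw <- quota * 8
      cl <- rep(seq_len(k), each = n_draw)
      off <- .km_to_deg(stats::rnorm(k * n_draw, 0, cfg$cluster_radius_km),
                        stats::rnorm(k * n_draw, 0, cfg$cluster_radius_km),
                        clat[cl])
      lat <- pmin(pmax(clat[cl] + off$dlat, rg$lat_min + res),
                  rg$lat_max - res)
      lon360 <- pmin(pmax(clon[cl] + off$dlon, rg$lon_min + res),
                     rg$lon_max - res)
      lat <- floor(lat / res) * res + res / 2
      lon360 <- floor(lon360 / res) * res + res / 2
      keep <- !duplicated(paste(lat, lon360))
      keep <- keep & stats::ave(as.numeric(keep), cl, FUN = cumsum) <= quota
      cells[[i]] <- data.frame(lat = lat[keep],
                               lon = ((lon360[keep] + 180) %% 360) - 180,
                               region = rg$name, stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, cells)
    cells$reef_area <- stats::rlnorm(nrow(cells), cfg$area_meanlog,
                                     cfg$area_sdlog)
    # overlapping Pacific sections can collide on a cell: keep first
    g0 <- structure(list(origin = c(-90, -180), resolution = res,
                         ncol = as.integer(round(360 / res))),
                    class = "reef_grid")
    cells <- cells[!duplicated(cell_index(cells$lat, cells$lon, g0)), ]
    grid <- reef_grid(cells, resolution = res)
    attr(grid, "cluster_centres") <- do.call(rbind, centres)
    grid
  })
}

# Resolve configured events to concrete cell footprints: the reef cells of
# the hosting archipelago cluster (region cells whose nearest cluster centre
# is the event's), with the centre distance kept for the latent-probability
# taper. Anchoring footprints to whole clusters keeps every event the same
# extent, which is what makes the before/after-El-Nino contrast exactly the
# configured multiple of events.
.resolve_events <- function(grid, cfg) {
  cc <- attr(grid, "cluster_centres")
  ev <- cfg$events
  if (is.null(ev) || nrow(ev) == 0) return(list())
  lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    cc_r <- cc[cc$region == e$region, ]
    ctr <- cc_r[cc_r$cluster == e$cluster, ]
    if (nrow(ctr) == 0) stop("event references unknown cluster: ",
                             e$region, "/", e$cluster)
    idx <- which(grid$cells$region == e$region)
    dmat <- haversine_matrix(grid$cells$lat[idx], grid$cells$lon[idx],
                             cc_r$lat, cc_r$lon)
    nearest <- cc_r$cluster[max.col(-dmat)]
    sel <- idx[nearest == e$cluster]
    list(year = e$year, region = e$region, amplitude = e$amplitude,
         prob = e$prob, radius_km = e$radius_km,
         centre = c(ctr$lat, ctr$lon),
         cell_ids = grid$cells$cell_id[sel], cell_idx = sel,
         centre_dist = haversine_km(ctr$lat, ctr$lon,
                                    grid$cells$lat[sel], grid$cells$lon[sel]))
  })
}

#' Simulate SST series and the MMM climatology
#'
#' Twice-weekly SST per reef cell: a seasonal cycle whose climatological peak
#' equals the cell's MMM, truncated noise kept below the DHW accumulation
#' threshold (so cells without planted events have annual maximum DHW of
#' exactly zero by construction), plus planted warm anomalies in event years
#' centred on the cell's warm season, which force DHW > 0 over the event
#' footprint.
#'
#' @param grid a [reef_grid()] from [make_reef_grid()].
#' @param cfg a [synth_config()].
#' @param events resolved events (internal); defaults to resolving
#'   `cfg$events` against `grid`.
#' @return list with `times` (numeric days since 1970-01-01), `sst` (matrix
#'   cells x times, rownames = cell ids), `mmm` (per-cell vector), `events`
#'   (the resolved event list).
#' @export
simulate_sst <- function(grid, cfg, events = NULL) {
  if (is.null(events)) events <- .resolve_events(grid, cfg)
  s <- cfg$sst
  t0 <- as.numeric(as.Date(paste0(min(cfg$years), "-01-01")))
  t1 <- as.numeric(as.Date(paste0(max(cfg$years), "-12-31")))
  times <- seq(t0, t1, by = s$step_days)
  dates <- as.Date(floor(times), origin = "1970-01-01")
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))

  cells <- grid$cells
  n <- nrow(cells)
  mmm <- s$mmm_base + s$mmm_lat_coef * abs(cells$lat)
  peak <- ifelse(cells$lat >= 0, 258L, 75L)  # mid-Sep north, mid-Mar south

  # seasonal deficit: 0 at the warm-season peak, -seasonal_amp at the trough
  phase <- outer(peak, doy, function(p, d) cos(2 * pi * (d - p) / 365.25))
  sst <- mmm + s$seasonal_amp / 2 * (phase - 1)

  .with_seed(.sub_seed(cfg$seed, 2), {
    noise <- matrix(stats::rnorm(n * length(times), 0, s$noise_sd), n)
    noise <- pmin(pmax(noise, -s$noise_cap), s$noise_cap)
    sst <- sst + noise
  })

  # Anomalies sit inside each cell's own warm season and end (north) or
  # start (south) at the seasonal peak, so the accumulated DHW decays to zero
  # before the year ends: a planted event never leaks stress into the next
  # calendar year's maximum.
  dur <- s$event_duration_days
  for (e in events) {
    north <- cells$lat[e$cell_idx] >= 0
    for (hemi in unique(north)) {
      idx <- e$cell_idx[north == hemi]
      win <- if (hemi) c(258 - dur, 258) else c(75, 75 + dur)
      tcol <- yr == e$year & doy >= win[1] & doy < win[2]
      sst[idx, tcol] <- sst[idx, tcol] + e$amplitude
    }
  }
  rownames(sst) <- cells$cell_id
  names(mmm) <- cells$cell_id
  list(times = times, sst = sst, mmm = mmm, events = events)
}

#' Simulate the latent bleaching-probability field for one year
#'
#' A Gaussian random field with the configured variogram (covariance
#' `psill * rho(h) + nugget` on the diagonal) is simulated over the reef
#' cells and mapped to probabilities through the normal CDF anchored at the
#' configured background rate; event footprints for the year are then set to
#' the event probability. The raw Gaussian field is kept in attribute
#' `gaussian` so its empirical variogram can be audited against the
#' configured model.
#'
#' @param grid a [reef_grid()].
#' @param cfg a [synth_config()].
#' @param year calendar year (seeds the realization; fields differ by year,
#'   identically under the same master seed).
#' @param events resolved events (internal); defaults to resolving
#'   `cfg$events`.
#' @param chol_cov optional pre-computed Cholesky factor of the covariance
#'   (upper triangular), to amortize across years.
#' @return named numeric vector of true bleaching probabilities per cell.
#' @export
simulate_latent_field <- function(grid, cfg, year, events = NULL,
                                  chol_cov = NULL) {
  if (is.null(events)) events <- .resolve_events(grid, cfg)
  if (is.null(chol_cov)) chol_cov <- latent_chol(grid, cfg)
  n <- nrow(grid$cells)
  z <- .with_seed(.sub_seed(cfg$seed, 100 + (year %% 100)), {
    drop(crossprod(chol_cov, stats::rnorm(n)))
  })
  p <- stats::pnorm(stats::qnorm(cfg$base_rate) + z)
  for (e in events) {
    if (e$year == year) {
      # Gaussian taper from the event centre: near-peak probability across
      # the hosting archipelago, decaying over the footprint scale
      boost <- e$prob * exp(-0.5 * (e$centre_dist / e$radius_km)^2)
      p[e$cell_idx] <- pmax(p[e$cell_idx], boost)
    }
  }
  names(p) <- grid$cells$cell_id
  attr(p, "gaussian") <- z
  p
}

#' Cholesky factor of the latent-field covariance
#'
#' @param grid a [reef_grid()].
#' @param cfg a [synth_config()].
#' @return upper-triangular Cholesky factor of
#'   `psill * rho(D) + nugget * I` over the reef cells.
#' @export
latent_chol <- function(grid, cfg) {
  lv <- cfg$latent
  D <- haversine_matrix(grid$cells$lat, grid$cells$lon)
  C <- lv$psill * (1 - .vgm_structure(lv$family, D / lv$range_km))
  diag(C) <- lv$psill + lv$nugget + 1e-8
  chol(C)
}

#' Sample effort-biased bleaching reports for one year
#'
#' Surveyed cells are drawn with spatially clustered effort (probability
#' decaying with distance to the nearest monitoring station; stations sit at
#' fixed seeded reef cells plus, in event years, at event centres --
#' bleaching attracts surveys). Each surveyed cell reports bleaching with
#' its latent probability; bleached cells are reported at severity 2/3
#' (moderate/severe percent bleached) with a configured contamination
#' fraction mis-reported as mild, unbleached surveyed cells at severity 0.
#'
#' @param field latent probabilities from [simulate_latent_field()].
#' @param grid a [reef_grid()].
#' @param cfg a [synth_config()].
#' @param year calendar year.
#' @param events resolved events (internal).
#' @param stations optional fixed monitoring stations (data frame `lat`,
#'   `lon`), defaults to seeded draws per region.
#' @return data frame of reports in the standard schema.
#' @export
sample_reports <- function(field, grid, cfg, year, events = NULL,
                           stations = NULL) {
  if (is.null(events)) events <- .resolve_events(grid, cfg)
  if (is.null(stations)) stations <- effort_stations(grid, cfg)
  ev_y <- Filter(function(e) e$year == year, events)
  st <- rbind(stations[, c("lat", "lon")],
              do.call(rbind, lapply(ev_y, function(e) {
                data.frame(lat = e$centre[1], lon = e$centre[2])
              })))
  cells <- grid$cells
  d <- haversine_matrix(cells$lat, cells$lon, st$lat, st$lon)
  dmin <- apply(d, 1, min)
  p_survey <- cfg$effort$p_near * exp(-dmin / cfg$effort$decay_km)
  for (e in ev_y) {
    p_survey[e$cell_idx] <- pmax(p_survey[e$cell_idx],
                                 cfg$effort$event_survey)
  }

  .with_seed(.sub_seed(cfg$seed, 500 + (year %% 100)), {
    surveyed <- stats::runif(nrow(cells)) < p_survey
    idx <- which(surveyed)
    if (length(idx) == 0) return(.empty_reports())
    bleached <- stats::runif(length(idx)) < field[idx]
    mild <- bleached & stats::runif(length(idx)) < cfg$severity_noise
    pct <- numeric(length(idx))
    pct[bleached & !mild] <- round(stats::runif(sum(bleached & !mild), 11, 95), 1)
    pct[mild] <- round(stats::runif(sum(mild), 1, 10), 1)
    res <- grid$resolution
    jit_lat <- stats::runif(length(idx), -0.45, 0.45) * res
    jit_lon <- stats::runif(length(idx), -0.45, 0.45) * res
    data.frame(
      country = "Synthetica",
      location = cells$region[idx],
      site_name = paste0("site_", cells$cell_id[idx]),
      latitude = round(cells$lat[idx] + jit_lat, 6),
      longitude = round(cells$lon[idx] + jit_lon, 6),
      date = "",
      month = 9L,
      year = as.integer(year),
      depth = "",
      severity_code = assign_severity(pct),
      percent_bleached = pct,
      mortality_code = "",
      percent_mortality = "",
      survey_type = "synthetic survey",
      source = "synthetic generator",
      name = "",
      citation = "",
      comments = "",
      entry_code = "",
      database_code = 2L,
      stringsAsFactors = FALSE
    )
  })
}

.empty_reports <- function() {
  out <- data.frame(country = character(), location = character(),
                    site_name = character(), latitude = numeric(),
                    longitude = numeric(), date = character(),
                    month = integer(), year = integer(), depth = character(),
                    severity_code = integer(), percent_bleached = numeric(),
                    mortality_code = character(),
                    percent_mortality = character(),
                    survey_type = character(), name = character(),
                    source = character(), citation = character(),
                    comments = character(), entry_code = character(),
                    database_code = integer(), stringsAsFactors = FALSE)
  out
}

#' Fixed monitoring stations for the effort model
#'
#' @param grid a [reef_grid()].
#' @param cfg a [synth_config()].
#' @return data frame of station coordinates (`region`, `lat`, `lon`).
#' @export
effort_stations <- function(grid, cfg) {
  .with_seed(.sub_seed(cfg$seed, 3), {
    cells <- grid$cells
    out <- lapply(unique(cells$region), function(r) {
      sub <- cells[cells$region == r, ]
      k <- min(cfg$effort$centers_per_region, nrow(sub))
      sub <- sub[sample.int(nrow(sub), k), ]
      data.frame(region = r, lat = sub$lat, lon = sub$lon,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a complete synthetic bleaching study
#'
#' Orchestrates the generator: reef grid, SST + MMM (hence DHW ground
#' truth), latent probability fields per year, and effort-biased reports for
#' every simulated year. Byte-identical under a fixed seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `cfg`, `grid`, `times`, `sst`, `mmm`, `events`,
#'   `stations`, `latent` (matrix cells x years, colnames = years), and
#'   `reports` (all years pooled).
#' @export
simulate_bleaching_study <- function(cfg = synth_config()) {
  grid <- make_reef_grid(cfg)
  events <- .resolve_events(grid, cfg)
  therm <- simulate_sst(grid, cfg, events)
  stations <- effort_stations(grid, cfg)
  L <- latent_chol(grid, cfg)
  latent <- sapply(cfg$years, function(y) {
    simulate_latent_field(grid, cfg, y, events, L)
  })
  colnames(latent) <- cfg$years
  rownames(latent) <- grid$cells$cell_id
  reports <- do.call(rbind, lapply(seq_along(cfg$years), function(i) {
    sample_reports(latent[, i], grid, cfg, cfg$years[i], events, stations)
  }))
  rownames(reports) <- NULL
  list(cfg = cfg, grid = grid, times = therm$times, sst = therm$sst,
       mmm = therm$mmm, events = events, stations = stations,
       latent = latent, reports = reports)
}
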
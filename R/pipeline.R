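# End-to-end orchestration: ingest -> QC -> DHW -> indicator points ->
# per-region kriging -> overlap merge -> downstream statistics, with a run
# manifest and per-stage record counts.

#' Pipeline configuration
#'
#' @param reports path to a report CSV, or a data frame of reports, or
#'   `NULL` in synth mode.
#' @param grid a [reef_grid()] or path to a grid table
#'   ([write_grid()] format); `NULL` in synth mode.
#' @param sst list with `times`, `sst` matrix, `mmm` vector (as returned by
#'   [simulate_sst()]) or path to an SST series table; `NULL` in synth mode.
#' @param synth a [synth_config()] to generate all inputs, or `NULL` when
#'   real inputs are supplied.
#' @param years years to analyse.
#' @param regions region table, see [region_specs()].
#' @param thresholds probability thresholds, see [probability_thresholds()].
#' @param families variogram families to fit.
#' @param neighborhood kriging neighborhood size.
#' @param n_bins empirical variogram bins.
#' @param dhw_window,dhw_threshold DHW accumulation window (days) and
#'   HotSpot accumulation threshold (degrees C).
#' @param seed seed for any stochastic stage (synth mode).
#' @param outdir output directory, or `NULL` to skip writing files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reports = NULL, grid = NULL, sst = NULL,
                            synth = NULL, years = 1985:2010,
                            regions = region_specs(),
                            thresholds = probability_thresholds(),
                            families = variogram_families(),
                            neighborhood = 64, n_bins = 15,
                            dhw_window = 84, dhw_threshold = 1,
                            seed = 1, outdir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the bleaching-probability pipeline
#'
#' Executes every stage in order and returns a manifest plus all stage
#' outputs. In synth mode the generated reports are round-tripped through the
#' CSV reader so synthetic runs exercise the same code paths as real ones.
#' A region-year in which kriging is impossible (no presence points, or all
#' variogram families fail) gets an all-zero probability surface -- that is
#' the analysis convention, not a failure; genuinely broken inputs (missing
#' SST, unreadable reports) abort with a stage-named error.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `manifest`, `grid`, `annual` (annual max DHW),
#'   `probability` (all years stacked), `availability` (region x year
#'   kriging table), `areas` (annual reef area above each threshold),
#'   `dhw_stats` (by probability class), `fold_changes`, `trend`,
#'   `variograms` (selection objects per region-year), `kept`, `removed`,
#'   `rejects`.
#' @export
run_pipeline <- function(cfg) {
  synth_mode <- !is.null(cfg$synth)
  if (synth_mode) {
    world <- simulate_bleaching_study(cfg$synth)
    grid <- world$grid
    thermal_in <- list(times = world$times, sst = world$sst, mmm = world$mmm)
    tmp <- tempfile(fileext = ".csv")
    write_reports(world$reports, tmp)
    rr <- read_reports(tmp)
    unlink(tmp)
    years <- cfg$synth$years
  } else {
    if (is.null(cfg$reports)) stop("ingest stage: no reports supplied")
    rr <- if (is.character(cfg$reports)) read_reports(cfg$reports)
          else list(reports = cfg$reports,
                    rejects = data.frame(row = integer(), reason = character(),
                                         detail = character()))
    grid <- if (is.character(cfg$grid)) read_grid(cfg$grid) else cfg$grid
    if (is.null(grid)) stop("grid stage: no reef grid supplied")
    thermal_in <- if (is.character(cfg$sst)) read_sst_series(cfg$sst) else cfg$sst
    if (is.null(thermal_in)) stop("thermal stage: no SST input supplied")
    years <- cfg$years
    world <- NULL
  }

  # QC and deduplication
  qc <- qc_filter(rr$reports, grid)
  kept <- independent_records(qc$kept)

  # thermal stress
  dhw <- dhw_matrix(thermal_in$times, thermal_in$sst, thermal_in$mmm,
                    window_days = cfg$dhw_window,
                    threshold = cfg$dhw_threshold)
  annual <- annual_max_dhw(dhw, thermal_in$times)

  # indicators + kriging per year and region
  regions <- cfg$regions
  prob_years <- list()
  variograms <- list()
  n_presence <- 0L; n_absence <- 0L
  avail <- matrix("-", nrow = length(years), ncol = nrow(regions),
                  dimnames = list(years, regions$name))
  for (yi in seq_along(years)) {
    y <- years[yi]
    pres <- presence_cells(kept, y, grid)
    abs_ <- pseudo_absence_cells(annual, grid, y)
    n_presence <- n_presence + nrow(pres)
    n_absence <- n_absence + nrow(abs_)
    pts <- rbind(pres, abs_)
    frags <- lapply(seq_len(nrow(regions)), function(i) {
      krige_region(regions[i, ], y, pts, grid, families = cfg$families,
                   neighborhood = cfg$neighborhood, n_bins = cfg$n_bins)
    })
    for (i in seq_len(nrow(regions))) {
      if (any(frags[[i]]$provenance == "kriged")) avail[yi, i] <- "X"
      sel <- attr(frags[[i]], "selection")
      if (!is.null(sel) && !sel$all_failed) {
        variograms[[paste(regions$name[i], y, sep = "_")]] <- sel
      }
    }
    prob_years[[yi]] <- merge_overlaps(frags)
  }
  probability <- do.call(rbind, prob_years)

  # downstream statistics
  taus <- cfg$thresholds
  areas <- do.call(rbind, lapply(seq_along(years), function(yi) {
    p <- prob_years[[yi]]
    cbind(data.frame(year = years[yi]),
          as.data.frame(as.list(stats::setNames(
            vapply(taus, function(tau) threshold_area(p, grid, tau),
                   numeric(1)), names(taus)))))
  }))

  fold_changes <- vapply(names(taus), function(nm) {
    period_fold_change(areas$year, areas[[nm]])
  }, numeric(1))

  classes <- c("all", "gt50_66", "gt66_90", "gt66", "gt90")
  dhw_stats <- do.call(rbind, lapply(classes, function(cl) {
    s <- weighted_dhw_stats(probability, annual, grid, cl)
    data.frame(class = cl, mean = s$mean, median = s$median, n = s$n)
  }))

  # area-weighted mean annual max DHW of all reefs, by year, and its trend
  w <- grid$cells$reef_area[match(annual$cell_id, grid$cells$cell_id)]
  dhw_by_year <- vapply(split(seq_len(nrow(annual)), annual$year),
                        function(i) sum(annual$max_dhw[i] * w[i]) / sum(w[i]),
                        numeric(1))
  trend <- linear_trend(as.integer(names(dhw_by_year)), dhw_by_year)

  manifest <- list(
    seed = cfg$seed,
    synth_mode = synth_mode,
    years = range(years),
    counts = list(
      read = nrow(rr$reports) + nrow(rr$rejects),
      valid = nrow(rr$reports),
      rejected = nrow(rr$rejects),
      kept = nrow(qc$kept),
      removed = nrow(qc$removed),
      independent = nrow(kept),
      collapsed = attr(kept, "n_collapsed"),
      presences = n_presence,
      pseudo_absences = n_absence,
      reef_cells = nrow(grid$cells)
    ),
    total_reef_area_km2 = sum(grid$cells$reef_area),
    regions_kriged = sum(avail == "X"),
    package_version = as.character(utils::packageVersion("coralkrige"))
  )

  result <- list(manifest = manifest, grid = grid, annual = annual,
                 probability = probability,
                 availability = as.data.frame(avail),
                 areas = areas, fold_changes = fold_changes,
                 dhw_stats = dhw_stats, dhw_by_year = dhw_by_year,
                 trend = trend, variograms = variograms,
                 kept = kept, removed = qc$removed, rejects = rr$rejects,
                 world = world)
  if (!is.null(cfg$outdir)) write_pipeline_outputs(result, cfg$outdir)
  result
}

#' Write pipeline outputs to a directory
#'
#' Emits per-year probability cell tables, the region-year availability
#' table, annual threshold areas, DHW statistics by class, the kept/removed
#' report logs, variogram model cards, and a JSON manifest.
#'
#' @param result value of [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  for (y in unique(result$probability$year)) {
    tsv(result$probability[result$probability$year == y, ],
        sprintf("probability_%d.tsv", y))
  }
  avail <- cbind(year = rownames(result$availability), result$availability)
  tsv(avail, "availability.tsv")
  tsv(result$areas, "areas_by_year.tsv")
  tsv(result$dhw_stats, "dhw_stats.tsv")
  tsv(result$removed, "removals.tsv")
  tsv(result$rejects, "rejects.tsv")
  write_reports(result$kept, file.path(outdir, "reports_kept.csv"))
  cards <- do.call(rbind, lapply(names(result$variograms), function(nm) {
    m <- result$variograms[[nm]]$model
    data.frame(region_year = nm, family = m$family, nugget = m$nugget,
               psill = m$psill, range_km = m$range_km, rmse = m$rmse)
  }))
  if (!is.null(cards)) tsv(cards, "variogram_models.tsv")
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Read / write per-cell SST series tables
#'
#' Text format for gridded SST in tests and small runs: a tab-separated
#' table with columns `cell_id`, `time` (days since 1970-01-01), `sst`, plus
#' a companion MMM table `cell_id`, `mmm` appended after a `# mmm` marker
#' line.
#'
#' @param x list with `times`, `sst` matrix (rownames = cell ids), `mmm`.
#' @param path file path.
#' @return the list (read) or `path` invisibly (write).
#' @export
write_sst_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  long <- data.frame(cell_id = rep(rownames(x$sst), ncol(x$sst)),
                     time = rep(as.numeric(x$times), each = nrow(x$sst)),
                     sst = as.vector(x$sst))
  utils::write.table(long, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("# mmm", con)
  utils::write.table(data.frame(cell_id = names(x$mmm), mmm = x$mmm), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sst_series
#' @export
read_sst_series <- function(path) {
  lines <- readLines(path)
  marker <- which(lines == "# mmm")
  top <- utils::read.table(text = lines[seq_len(marker - 1)], sep = "\t",
                           header = TRUE)
  bot <- utils::read.table(text = lines[-seq_len(marker)], sep = "\t",
                           header = TRUE)
  times <- sort(unique(top$time))
  ids <- unique(top$cell_id)
  sst <- matrix(NA_real_, length(ids), length(times),
                dimnames = list(ids, NULL))
  sst[cbind(match(top$cell_id, ids), match(top$time, times))] <- top$sst
  mmm <- stats::setNames(bot$mmm, bot$cell_id)[as.character(ids)]
  names(mmm) <- ids
  list(times = times, sst = sst, mmm = mmm)
}
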
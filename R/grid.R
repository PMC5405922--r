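# The 0.04-degree analysis grid: reef cells, presence and pseudo-absence
# indicator points, and reef areas.

#' Construct a reef grid
#'
#' A reef grid is the analysis raster: a regular latitude-longitude grid
#' (default 0.04 x 0.04 degrees, aligned to origin (-90, -180) following the
#' Coral Reef Watch convention) together with a table of the cells that
#' contain coral reef. Cells are half-open `[edge, edge + res)` and
#' longitudes are normalized to `[lon0, lon0 + 360)` so Pacific regions are
#' contiguous across the antimeridian.
#'
#' @param cells data frame with columns `lat`, `lon` (cell centres or any
#'   point inside the cell), `reef_area` (km^2, >= 0) and `region` (label).
#' @param origin `(lat0, lon0)` of the grid's south-west corner.
#' @param resolution cell size in degrees.
#' @return object of class `reef_grid`: list with `origin`, `resolution`,
#'   `ncol`, and `cells` (with `cell_id`, `row`, `col` and centre
#'   coordinates filled in, one row per reef cell).
#' @export
reef_grid <- function(cells, origin = c(-90, -180), resolution = 0.04) {
  stopifnot(resolution > 0, all(cells$reef_area >= 0))
  g <- structure(list(origin = origin, resolution = resolution,
                      ncol = as.integer(round(360 / resolution)),
                      cells = NULL),
                 class = "reef_grid")
  id <- cell_index(cells$lat, cells$lon, g)
  if (anyDuplicated(id)) stop("duplicate reef cells in input")
  ctr <- cell_centre(id, g)
  g$cells <- data.frame(cell_id = id, row = ctr$row, col = ctr$col,
                        lat = ctr$lat, lon = ctr$lon,
                        reef_area = cells$reef_area,
                        region = cells$region,
                        stringsAsFactors = FALSE)
  g$cells <- g$cells[order(g$cells$cell_id), ]
  rownames(g$cells) <- NULL
  g
}

#' @export
print.reef_grid <- function(x, ...) {
  cat(sprintf("reef_grid: %d reef cells at %.3f deg, origin (%g, %g), total %.1f km^2\n",
              nrow(x$cells), x$resolution, x$origin[1], x$origin[2],
              sum(x$cells$reef_area)))
  invisible(x)
}

#' Map coordinates to grid cell ids
#'
#' @param latitude,longitude decimal degrees (vectors).
#' @param grid a [reef_grid()].
#' @return integer cell ids (`row * ncol + col`).
#' @export
cell_index <- function(latitude, longitude, grid) {
  res <- grid$resolution
  row <- floor((latitude - grid$origin[1]) / res)
  col <- floor(((longitude - grid$origin[2]) %% 360) / res)
  as.integer(row * grid$ncol + col)
}

#' Cell centres from cell ids
#'
#' @param cell_id integer cell ids.
#' @param grid a [reef_grid()].
#' @return data frame with `row`, `col`, `lat`, `lon` (lon in
#'   `[lon0, lon0 + 360)` normalized to `[-180, 180)`).
#' @export
cell_centre <- function(cell_id, grid) {
  row <- cell_id %/% grid$ncol
  col <- cell_id %% grid$ncol
  lat <- grid$origin[1] + (row + 0.5) * grid$resolution
  lon <- grid$origin[2] + (col + 0.5) * grid$resolution
  lon <- ((lon + 180) %% 360) - 180
  data.frame(row = row, col = col, lat = lat, lon = lon)
}

#' Presence indicator points for one year
#'
#' Bleaching presence in a given year is any grid cell containing at least
#' one report of severity 2 or 3 (more than 10% bleaching); lower or unknown
#' severities never create presence. Multiple reports in a cell collapse to
#' one point at the cell centre.
#'
#' @param reports QC-passed reports data frame.
#' @param year calendar year.
#' @param grid a [reef_grid()].
#' @return data frame of indicator points: `cell_id`, `lat`, `lon`, `year`,
#'   `indicator` (all 1).
#' @export
presence_cells <- function(reports, year, grid) {
  sel <- reports$year == year & reports$severity_code %in% c(2L, 3L)
  r <- reports[sel, , drop = FALSE]
  ids <- unique(cell_index(r$latitude, r$longitude, grid))
  ctr <- cell_centre(ids, grid)
  data.frame(cell_id = ids, lat = ctr$lat, lon = ctr$lon,
             year = rep.int(as.integer(year), length(ids)),
             indicator = rep.int(1L, length(ids)))
}

#' Pseudo-absence indicator points for one year
#'
#' A pseudo-absence is any reef cell whose annual maximum DHW is exactly
#' zero: the absence of thermal stress stands in for an explicit
#' "no bleaching" survey. A cell may carry both a presence point and a
#' pseudo-absence point in the same year (observed bleaching under zero
#' recorded stress), in which case its kriged probability is below 1.
#'
#' @param annual data frame from [annual_max_dhw()].
#' @param grid a [reef_grid()].
#' @param year calendar year.
#' @return data frame of indicator points (`indicator` all 0); reef cells
#'   with no DHW value are excluded and listed in attribute `missing_cells`.
#' @export
pseudo_absence_cells <- function(annual, grid, year) {
  a <- annual[annual$year == year, , drop = FALSE]
  m <- match(grid$cells$cell_id, a$cell_id)
  missing_ids <- grid$cells$cell_id[is.na(m)]
  zero <- !is.na(m) & a$max_dhw[m] == 0
  cells <- grid$cells[zero, , drop = FALSE]
  out <- data.frame(cell_id = cells$cell_id, lat = cells$lat, lon = cells$lon,
                    year = rep.int(as.integer(year), nrow(cells)),
                    indicator = rep.int(0L, nrow(cells)))
  rownames(out) <- NULL
  attr(out, "missing_cells") <- missing_ids
  out
}

#' Total reef area of a set of cells
#'
#' @param cells integer cell ids (must all be reef cells of the grid).
#' @param grid a [reef_grid()].
#' @return total reef area, km^2.
#' @export
reef_area_of <- function(cells, grid) {
  if (length(cells) == 0) return(0)
  m <- match(cells, grid$cells$cell_id)
  if (anyNA(m)) stop("unknown cell id(s): ",
                     paste(cells[is.na(m)], collapse = ", "))
  sum(grid$cells$reef_area[m])
}

#' Write / read a reef grid as a delimited cell table
#'
#' @param grid a [reef_grid()].
#' @param path output path (tab-separated).
#' @return `path` (write) or a `reef_grid` (read).
#' @export
write_grid <- function(grid, path) {
  hdr <- sprintf("# origin %g %g resolution %g", grid$origin[1],
                 grid$origin[2], grid$resolution)
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(grid$cells[, c("lat", "lon", "reef_area", "region")],
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), " +")[[1]]
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  reef_grid(tab, origin = as.numeric(hdr[3:4]),
            resolution = as.numeric(hdr[6]))
}
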
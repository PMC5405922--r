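# Ocean regions for the kriging analysis. Kriging runs separately per region
# each year; the main Pacific is split into three sections with 1000 km of
# overlap (about 9 degrees of longitude at the equator), and estimates in the
# overlaps are averaged to remove edge effects of the split.

#' Default region specifications
#'
#' Longitude bounds are given in 0-360 degrees so that regions spanning the
#' antimeridian are contiguous. The three main-Pacific sections overlap their
#' neighbours by at least `overlap_km`.
#'
#' @return data frame with columns `name`, `lon_min`, `lon_max` (0-360),
#'   `lat_min`, `lat_max`, `overlap_km`.
#' @export
region_specs <- function() {
  data.frame(
    name = c("caribbean", "indian", "east_pacific",
             "pacific_west", "pacific_central", "pacific_east"),
    lon_min = c(262,  30, 235, 105, 146, 191),
    lon_max = c(305, 105, 262, 155, 200, 235),
    lat_min = c(  7, -32, -25, -35, -35, -35),
    lat_max = c( 30,  30,  25,  35,  35,  35),
    overlap_km = c(0, 0, 0, 1000, 1000, 1000),
    stringsAsFactors = FALSE
  )
}

#' Point-in-region membership
#'
#' @param lat,lon decimal degrees.
#' @param region one row of [region_specs()].
#' @return logical vector.
#' @export
in_region <- function(lat, lon, region) {
  lon360 <- lon %% 360
  lon360 >= region$lon_min & lon360 < region$lon_max &
    lat >= region$lat_min & lat < region$lat_max
}
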
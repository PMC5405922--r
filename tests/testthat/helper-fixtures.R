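# Shared fixtures. Heavy objects (the full default synthetic study) are
# built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Full default study conditions (1985-2010, six regions), run end to end.
default_study <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- suppressWarnings(
      run_pipeline(pipeline_config(synth = synth_config(seed = 1)))
    )
  }
  .fixture_cache$study
}

# A small reef grid: a 5 x 5 block of cells near the origin of the indian
# region box, unit-ish areas.
tiny_grid <- function() {
  gg <- expand.grid(lat = seq(-2, -1.84, by = 0.04),
                    lon = seq(72, 72.16, by = 0.04))
  reef_grid(data.frame(lat = gg$lat + 0.02, lon = gg$lon + 0.02,
                       reef_area = rep(c(1.5, 2.5, 2, 1, 3), 5),
                       region = "indian"))
}

# One-region, five-year world with a 1998 two-cluster event; effort density
# is configurable so recovery can be probed against sampling density.
dense_world <- function(p_survey = 0.95, seed = 11) {
  cfg <- synth_config(
    seed = seed, years = 1996:2000,
    regions = region_specs()[2, , drop = FALSE],
    events = data.frame(year = 1998, region = "indian", cluster = c(1, 4),
                        radius_km = 400, amplitude = 2.5, prob = 0.9),
    effort = list(centers_per_region = 2, decay_km = 1e6,
                  p_near = p_survey, event_survey = p_survey)
  )
  simulate_bleaching_study(cfg)
}

# Minimal valid report table written to a temp file.
write_report_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "Country,Location,Site_Name,Latitude,Longitude,Date,Month,Year,Depth,Severity_Code,Percent_Bleached,Mortality_Code,Percent_Mortality,Survey_Type,Source,Name,Citation,Comments,Entry_Code,Database_Code",
    rows), path)
  path
}
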
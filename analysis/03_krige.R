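#!/usr/bin/env Rscript
# Stage 3: indicator kriging of annual bleaching probability.
#
# Reads the reports, reef grid, and annual maximum DHW; quality-filters and
# deduplicates the reports; builds presence cells (severity 2/3) and
# pseudo-absence cells (annual max DHW of zero); and kriges each region-year
# with lowest-RMSE semi-variogram selection, averaging the overlapping
# Pacific sections. Region-years without presences, or where every variogram
# family fails, get an all-zero surface.

library(coralkrige)

rr <- read_reports("results/inputs/reports.csv")
grid <- read_grid("results/inputs/grid.tsv")
annual <- read.table("results/thermal/annual_max_dhw.tsv", sep = "\t",
                     header = TRUE)
dir.create("results/probability", recursive = TRUE, showWarnings = FALSE)

qc <- qc_filter(rr$reports, grid)
kept <- independent_records(qc$kept)
message(sprintf("reports: %d read, %d rejected, %d removed by QC, %d kept (%d duplicates collapsed)",
                nrow(rr$reports) + nrow(rr$rejects), nrow(rr$rejects),
                nrow(qc$removed), nrow(kept), attr(kept, "n_collapsed")))

regions <- region_specs()
years <- sort(unique(annual$year))
avail <- matrix("-", length(years), nrow(regions),
                dimnames = list(years, regions$name))
cards <- list()
for (y in years) {
  pts <- rbind(presence_cells(kept, y, grid),
               pseudo_absence_cells(annual, grid, y))
  frags <- lapply(seq_len(nrow(regions)), function(i) {
    krige_region(regions[i, ], y, pts, grid)
  })
  for (i in seq_len(nrow(regions))) {
    if (any(frags[[i]]$provenance == "kriged")) {
      avail[as.character(y), i] <- "X"
      m <- attr(frags[[i]], "selection")$model
      cards[[paste(regions$name[i], y)]] <-
        data.frame(region = regions$name[i], year = y, family = m$family,
                   nugget = m$nugget, psill = m$psill,
                   range_km = m$range_km, rmse = m$rmse)
    }
  }
  prob <- merge_overlaps(frags)
  write.table(prob, sprintf("results/probability/probability_%d.tsv", y),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

write.table(cbind(year = rownames(avail), as.data.frame(avail)),
            "results/probability/availability.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(do.call(rbind, cards), "results/probability/variogram_models.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

message(sprintf("kriging done: %d of %d region-years interpolated; %d years with any region",
                sum(avail == "X"), length(avail),
                sum(apply(avail == "X", 1, any))))
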
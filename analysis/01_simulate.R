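#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study world.
#
# Builds the default study conditions -- a 1985-2010 span over six ocean
# regions (Caribbean, Indian Ocean, East Pacific, and three overlapping main
# Pacific sections), archipelago-clustered reef cells on the 0.04-degree
# grid, twice-weekly SST with planted warm events, a latent bleaching
# probability field, and effort-biased severity-coded reports -- and writes
# the pipeline's input artifacts under results/inputs/.

library(coralkrige)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
cfg <- synth_config(seed = seed)
world <- simulate_bleaching_study(cfg)

write_reports(world$reports, "results/inputs/reports.csv")
write_grid(world$grid, "results/inputs/grid.tsv")
saveRDS(list(times = world$times, sst = world$sst, mmm = world$mmm),
        "results/inputs/sst.rds")  # bulky intermediate; all else is text
truth <- data.frame(cell_id = rep(rownames(world$latent),
                                  ncol(world$latent)),
                    year = rep(colnames(world$latent),
                               each = nrow(world$latent)),
                    latent_prob = as.vector(world$latent))
write.table(truth, "results/inputs/latent_truth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

ev <- cfg$events
message(sprintf("seed %d: %d reef cells (%.0f km^2 of reef), %d reports over %d-%d",
                seed, nrow(world$grid$cells), sum(world$grid$cells$reef_area),
                nrow(world$reports), min(cfg$years), max(cfg$years)))
message(sprintf("planted events: %d before 1997, %d in 1997/98, %d after",
                sum(ev$year < 1997), sum(ev$year %in% 1997:1998),
                sum(ev$year > 1998)))
message(sprintf("severity 2/3 reports: %d of %d",
                sum(world$reports$severity_code >= 2), nrow(world$reports)))
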
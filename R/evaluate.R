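# Recovery evaluation against the generator's latent ground truth.

#' Kriging recovery error against the latent field
#'
#' Runs the indicator pipeline for one region-year of a synthetic world
#' (presences from the sampled reports, pseudo-absences from zero annual
#' DHW), kriges every reef cell of the region, and measures the mean
#' absolute error of the kriged probabilities against the latent bleaching
#' probability field. The constant-prediction baseline (the mean of the
#' observed indicators, i.e. the best spatially uninformed estimate) is
#' evaluated on the same cells.
#'
#' @param world a [simulate_bleaching_study()] result.
#' @param year calendar year to evaluate.
#' @param region_name region to evaluate.
#' @param neighborhood kriging neighborhood size.
#' @return list with `mae_kriged`, `mae_constant`, `n_cells`,
#'   `n_presences`, `n_absences`.
#' @export
krige_recovery_error <- function(world, year, region_name,
                                 neighborhood = 64) {
  grid <- world$grid
  dhw <- dhw_matrix(world$times, world$sst, world$mmm)
  annual <- annual_max_dhw(dhw, world$times)
  qc <- qc_filter(world$reports, grid)
  kept <- independent_records(qc$kept)
  pres <- presence_cells(kept, year, grid)
  abs_ <- pseudo_absence_cells(annual, grid, year)
  pts <- rbind(pres, abs_)

  region <- world$cfg$regions[world$cfg$regions$name == region_name, ]
  if (nrow(region) == 0) stop("unknown region: ", region_name)
  frag <- krige_region(region, year, pts, grid,
                       neighborhood = neighborhood)
  truth <- world$latent[match(frag$cell_id, grid$cells$cell_id),
                        as.character(year)]
  inreg <- in_region(pts$lat, pts$lon, region)
  const <- mean(pts$indicator[inreg])
  list(mae_kriged = mean(abs(frag$prob - truth)),
       mae_constant = mean(abs(const - truth)),
       n_cells = nrow(frag),
       n_presences = sum(pts$indicator[inreg] == 1),
       n_absences = sum(pts$indicator[inreg] == 0))
}
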
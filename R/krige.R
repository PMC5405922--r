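# Ordinary indicator kriging of annual bleaching probability, per region,
# with Pacific tiling, overlap averaging, and the zero-probability fallback.
#
# The ordinary-kriging system over the k neighbouring data points is
#   [ Gamma  1 ] [ lambda ]   [ gamma0 ]
#   [ 1^T    0 ] [ mu     ] = [ 1      ]
# with Gamma_ij the model semi-variance between data points i and j and
# gamma0_i between data point i and the target. The prediction is
# sum(lambda * z), clamped to [0, 1]. Between-point entries (including
# coincident distinct points, h -> 0+) carry the nugget; the self-distance
# diagonal is 0, so a cell holding both a presence and a pseudo-absence point
# is solvable whenever the nugget is positive and yields a probability
# strictly below 1.

# Solve the OK system for one target given the local gamma matrix.
.ok_solve <- function(G, g0) {
  k <- nrow(G)
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  b <- c(g0, 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(NULL)
  sol[seq_len(k)]
}

# Between-point semi-variance: nugget applies at all h >= 0 (h -> 0+ limit).
.gamma_between <- function(model, h) {
  model$nugget + model$psill * .vgm_structure(model$family,
                                              h / model$range_km, model$kappa)
}

# Kriging predictions at several targets over one point set and model.
# Coincident data points are collapsed to their mean indicator when the
# nugget is zero (a zero-nugget system with duplicates is always singular);
# remaining singular or ill-conditioned systems (e.g. an all-zero fitted
# model) are retried with a tiny nugget before raising a typed failure.
.krige_points <- function(tlat, tlon, points, model, neighborhood = 64) {
  z <- points$indicator
  nt <- length(tlat)
  if (length(unique(z)) == 1L) {
    # unbiasedness: all data equal c -> prediction c everywhere
    return(structure(rep(min(max(z[1], 0), 1), nt),
                     weights_sum = rep(1, nt), clamped = rep(FALSE, nt)))
  }
  if (model$nugget <= 0) {
    key <- paste(round(points$lat, 8), round(points$lon, 8))
    if (anyDuplicated(key)) {
      zbar <- tapply(points$indicator, key, mean)
      first <- !duplicated(key)
      points <- points[first, , drop = FALSE]
      points$indicator <- as.numeric(zbar[key[first]])
      z <- points$indicator
      if (length(unique(z)) == 1L) {
        return(structure(rep(min(max(z[1], 0), 1), nt),
                         weights_sum = rep(1, nt), clamped = rep(FALSE, nt)))
      }
    }
  }
  n <- nrow(points)
  k <- min(neighborhood, n)
  Dpp <- haversine_matrix(points$lat, points$lon)
  Gfull <- .gamma_between(model, Dpp)
  diag(Gfull) <- 0
  Dtp <- haversine_matrix(tlat, tlon, points$lat, points$lon)
  eps <- max(1e-9, 1e-6 * (model$nugget + model$psill))

  pred <- numeric(nt); wsum <- numeric(nt); clamped <- logical(nt)
  for (i in seq_len(nt)) {
    use <- order(Dtp[i, ])[seq_len(k)]
    G <- Gfull[use, use, drop = FALSE]
    g0 <- .gamma_between(model, Dtp[i, use])
    lambda <- .ok_solve(G, g0)
    if (is.null(lambda)) {
      G2 <- G + eps
      diag(G2) <- 0
      lambda <- .ok_solve(G2, g0 + eps)
    }
    if (is.null(lambda)) {
      stop(errorCondition("kriging system is singular",
                          class = c("coralkrige_singular_system", "error")))
    }
    p <- sum(lambda * z[use])
    pred[i] <- min(max(p, 0), 1)
    wsum[i] <- sum(lambda)
    clamped[i] <- (p < 0 | p > 1)
  }
  structure(pred, weights_sum = wsum, clamped = clamped)
}

#' Ordinary-kriging prediction at one target location
#'
#' @param target_lat,target_lon target coordinates, degrees.
#' @param points data frame of indicator points (`lat`, `lon`, `indicator`).
#' @param model a converged [variogram_model()].
#' @param neighborhood number of nearest data points used (default 64); the
#'   full set is used when smaller.
#' @return predicted probability, clamped to [0, 1]; attributes
#'   `weights_sum` (pre-clamp check, always 1 up to solver tolerance) and
#'   `clamped` (logical).
#' @export
krige_cell <- function(target_lat, target_lon, points, model,
                       neighborhood = 64) {
  stopifnot(nrow(points) >= 1, isTRUE(model$converged))
  .krige_points(target_lat, target_lon, points, model, neighborhood)
}

#' Krige one region-year
#'
#' Builds the empirical variogram from the in-region indicator points,
#' selects the lowest-RMSE model among the requested families, and predicts
#' the bleaching probability at every reef cell of the region. If the region
#' has no presence points that year, or every variogram family fails to
#' converge, every cell gets probability zero with `zero-fallback`
#' provenance (so sparse years underrepresent, never invent, bleaching).
#'
#' @param region one row of [region_specs()].
#' @param year calendar year.
#' @param points indicator points for the year (presences and
#'   pseudo-absences, all regions; filtered to the region internally).
#' @param grid a [reef_grid()].
#' @param families variogram families to try (default all nine).
#' @param neighborhood kriging neighborhood size.
#' @param n_bins,max_lag empirical variogram binning controls.
#' @param weights fit weighting, see [fit_variogram()].
#' @return data frame fragment: `cell_id`, `lat`, `lon`, `year`, `prob`,
#'   `provenance` (`kriged` or `zero-fallback`), `region`; attribute
#'   `selection` carries the `variogram_selection` (or `NULL`).
#' @export
krige_region <- function(region, year, points, grid,
                         families = variogram_families(), neighborhood = 64,
                         n_bins = 15, max_lag = NULL, weights = "ols") {
  cells <- grid$cells[in_region(grid$cells$lat, grid$cells$lon, region), ,
                      drop = FALSE]
  frag <- data.frame(cell_id = cells$cell_id, lat = cells$lat,
                     lon = cells$lon, year = as.integer(year),
                     prob = 0, provenance = "zero-fallback",
                     region = region$name, stringsAsFactors = FALSE)
  rownames(frag) <- NULL
  if (nrow(frag) == 0) return(frag)

  pts <- points[in_region(points$lat, points$lon, region), , drop = FALSE]
  sel <- NULL
  if (nrow(pts) >= 2 && sum(pts$indicator == 1) > 0) {
    emp <- tryCatch(empirical_variogram(pts, max_lag = max_lag,
                                        n_bins = n_bins),
                    error = function(e) NULL)
    if (!is.null(emp) && is.null(max_lag)) {
      # Strongly clustered data can leave every mixed presence/absence pair
      # beyond the default cutoff (half the maximum pairwise distance),
      # giving an identically-zero variogram although the indicators are
      # mixed. Assessing the empirical variogram then means extending the
      # cutoff to cover the full data extent.
      gz <- emp$gamma[!is.na(emp$gamma)]
      if (length(gz) && all(gz == 0)) {
        emp <- tryCatch(
          empirical_variogram(pts, max_lag = attr(emp, "max_lag") * 2.0001,
                              n_bins = n_bins),
          error = function(e) emp)
      }
    }
    if (!is.null(emp)) {
      sel <- select_variogram(emp, families, weights = weights)
      if (!sel$all_failed) {
        frag$prob <- as.numeric(.krige_points(frag$lat, frag$lon, pts,
                                              sel$model,
                                              neighborhood = neighborhood))
        frag$provenance <- "kriged"
      }
    }
  }
  attr(frag, "selection") <- sel
  frag
}

#' Merge region fragments, averaging overlaps
#'
#' Cells present in a single fragment keep their value; cells covered by two
#' or more fragments (the overlapping Pacific sections) get the arithmetic
#' mean of the estimates and `averaged-overlap` provenance.
#'
#' @param fragments list of fragments from [krige_region()] (same year and
#'   grid).
#' @return merged probability grid: `cell_id`, `lat`, `lon`, `year`, `prob`,
#'   `provenance`.
#' @export
merge_overlaps <- function(fragments) {
  all <- do.call(rbind, lapply(fragments, function(f) {
    f[, c("cell_id", "lat", "lon", "year", "prob", "provenance")]
  }))
  cnt <- table(all$cell_id)
  pm <- tapply(all$prob, all$cell_id, mean)
  first <- !duplicated(all$cell_id)
  out <- all[first, , drop = FALSE]
  key <- as.character(out$cell_id)
  out$prob <- as.numeric(pm[key])
  multi <- as.integer(cnt[key]) > 1L
  out$provenance[multi] <- "averaged-overlap"
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
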
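# Degree Heating Week (DHW) thermal stress from SST and an MMM climatology.
#
# DHW at time t accumulates HotSpots (SST exceedance over the maximum monthly
# mean) of at least `threshold` degrees C over a trailing window (default 84
# days = 12 weeks), in units of degree C-weeks. Twice-weekly input
# (Pathfinder-style) is supported by weighting each observation by the number
# of days it represents.

#' HotSpot: positive SST exceedance over the climatological maximum
#'
#' @param sst sea surface temperature, degrees C (vector).
#' @param mmm maximum monthly mean climatology, degrees C.
#' @return `pmax(0, sst - mmm)`; `NA` SST gives `NA`.
#' @export
hotspot <- function(sst, mmm) {
  pmax(0, sst - mmm)
}

#' Degree Heating Weeks for one SST series
#'
#' At each observation time t, DHW(t) is the sum over observations in
#' (t - window_days, t] of HotSpot/7 times the days represented by the
#' observation, counting only HotSpots of at least `threshold` degrees C.
#' Missing SST contributes zero and flags the affected outputs as
#' gap-affected; outputs earlier than `window_days` after the series start
#' are flagged partial.
#'
#' @param times observation times, `Date` or numeric days; strictly
#'   increasing.
#' @param sst SST values, degrees C (`NA` = missing).
#' @param mmm scalar MMM climatology for the cell, degrees C.
#' @param window_days trailing accumulation window (default 84 = 12 weeks).
#' @param threshold minimum HotSpot accumulated, degrees C (default 1).
#' @param rep_days days represented by each observation; default inferred
#'   from the median time step (3.5 for twice-weekly, 1 for daily input).
#' @return data frame with columns `time`, `dhw` (degree C-weeks), `gap`
#'   (logical: a missing SST fell inside the window), `partial` (logical:
#'   window extends before the series start).
#' @export
dhw_series <- function(times, sst, mmm, window_days = 84, threshold = 1,
                       rep_days = NULL) {
  tt <- as.numeric(times)
  n <- length(tt)
  if (n == 0) stop("empty SST series")
  if (n > 1 && any(diff(tt) <= 0)) stop("times must be strictly increasing")
  if (length(sst) != n) stop("times and sst lengths differ")
  if (is.null(rep_days)) rep_days <- if (n > 1) stats::median(diff(tt)) else 1

  hs <- sst - mmm
  contrib <- ifelse(!is.na(hs) & hs >= threshold, hs, 0) * rep_days / 7
  gap <- is.na(sst)

  cs  <- cumsum(contrib)
  csg <- cumsum(as.numeric(gap))
  # window (t - window_days, t]: drop indices with time <= t - window_days
  lo <- findInterval(tt - window_days, tt)
  pos <- lo > 0
  left <- rep(0, n); left[pos] <- cs[lo[pos]]
  gleft <- rep(0, n); gleft[pos] <- csg[lo[pos]]
  dhw <- cs - left
  gaps_in <- csg - gleft
  data.frame(
    time = times,
    dhw = dhw,
    gap = gaps_in > 0,
    partial = tt - window_days < tt[1]
  )
}

#' Degree Heating Weeks for a cells-by-times SST matrix
#'
#' Matrix form of [dhw_series()] for gridded input: one row per cell, one
#' column per observation time, all cells sharing the time axis.
#'
#' @param times shared observation times (length = `ncol(sst)`).
#' @param sst numeric matrix, cells x times.
#' @param mmm per-cell MMM vector (length = `nrow(sst)`).
#' @inheritParams dhw_series
#' @return DHW matrix of the same shape, degree C-weeks.
#' @export
dhw_matrix <- function(times, sst, mmm, window_days = 84, threshold = 1,
                       rep_days = NULL) {
  tt <- as.numeric(times)
  if (ncol(sst) != length(tt)) stop("ncol(sst) must match length(times)")
  if (nrow(sst) != length(mmm)) stop("nrow(sst) must match length(mmm)")
  if (is.null(rep_days)) {
    rep_days <- if (length(tt) > 1) stats::median(diff(tt)) else 1
  }
  hs <- sweep(sst, 1, mmm)
  contrib <- ifelse(!is.na(hs) & hs >= threshold, hs, 0) * rep_days / 7
  cs <- t(apply(contrib, 1, cumsum))
  lo <- findInterval(tt - window_days, tt)
  left <- matrix(0, nrow(sst), ncol(sst))
  pos <- lo > 0
  if (any(pos)) left[, pos] <- cs[, lo[pos], drop = FALSE]
  out <- cs - left
  dimnames(out) <- dimnames(sst)
  out
}

#' Annual maximum DHW per cell
#'
#' The annual maximum is the summary used throughout the analysis because
#' report timing within the year is unreliable in observational databases.
#'
#' @param dhw DHW matrix (cells x times) from [dhw_matrix()], with rownames
#'   taken as cell ids (row index used when absent).
#' @param times observation times (`Date` or numeric days since 1970-01-01).
#' @return data frame with columns `cell_id`, `year`, `max_dhw`.
#' @export
annual_max_dhw <- function(dhw, times) {
  yrs <- as.integer(format(as.Date(floor(as.numeric(times)),
                                   origin = "1970-01-01"), "%Y"))
  ids <- rownames(dhw)
  ids <- if (is.null(ids)) seq_len(nrow(dhw)) else as.integer(ids)
  uy <- sort(unique(yrs))
  res <- lapply(uy, function(y) {
    m <- dhw[, yrs == y, drop = FALSE]
    data.frame(cell_id = ids, year = y, max_dhw = apply(m, 1, max))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Thermal-stress mask
#'
#' A cell-year is stressed when its annual maximum DHW exceeds 0 degree
#' C-weeks; the complement of this mask is the pseudo-absence candidate set.
#'
#' @param annual data frame from [annual_max_dhw()].
#' @return the input with a logical `stressed` column appended.
#' @export
stressed_mask <- function(annual) {
  annual$stressed <- annual$max_dhw > 0
  annual
}
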
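# Empirical indicator semi-variograms, model semi-variogram families, and
# lowest-RMSE model selection.
#
# Nine families are supported: exponential, spherical, gaussian, matern,
# stein_matern, circular, linear, bessel, pentaspherical. All bounded
# families are parameterized as gamma(h) = nugget + partial_sill * g(h/range)
# with g(0) = 0 and g -> 1; the linear family uses
# gamma(h) = nugget + partial_sill * h / range (an unbounded slope), and the
# bessel family is the J0 hole-effect model, which oscillates about the sill.

.earth_radius_m <- 6371000

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized; arguments
#' are recycled.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .earth_radius_m) / 1000
}

#' Pairwise haversine distance matrix in kilometres
#'
#' @param lat,lon coordinates of the first point set.
#' @param lat2,lon2 coordinates of the second set (default: the first).
#' @return matrix of km distances, `length(lat)` x `length(lat2)`.
#' @export
haversine_matrix <- function(lat, lon, lat2 = lat, lon2 = lon) {
  geosphere::distm(cbind(lon, lat), cbind(lon2, lat2),
                   fun = function(p1, p2) {
                     geosphere::distHaversine(p1, p2, r = .earth_radius_m)
                   }) / 1000
}

#' Empirical semi-variogram of indicator points
#'
#' Method-of-moments estimator on distance bins: for each lag bin,
#' `gamma(h) = sum over pairs in the bin of (z_i - z_j)^2 / (2 N(h))`.
#' Bins with no pairs carry `NA` gamma. For 0/1 indicator data gamma is
#' bounded by 0.5 (the Bernoulli variance ceiling).
#'
#' @param points data frame with `lat`, `lon` and `indicator` (the 0/1 value;
#'   any numeric field works, so the estimator can also audit Gaussian
#'   simulations).
#' @param max_lag largest lag considered, km; default half the maximum
#'   pairwise distance.
#' @param n_bins number of equal-width lag bins (default 15).
#' @param max_points cap on the number of points entering the O(n^2) pair
#'   computation; larger sets are deterministically subsampled.
#' @return object of class `empirical_variogram`: data frame with columns
#'   `lag` (bin centre, km), `gamma`, `n_pairs`; attribute `max_lag`.
#' @export
empirical_variogram <- function(points, max_lag = NULL, n_bins = 15,
                                max_points = 3000) {
  n <- nrow(points)
  if (n < 2) stop("insufficient data: need at least 2 points")
  if (n > max_points) {
    keep <- round(seq(1, n, length.out = max_points))
    points <- points[keep, , drop = FALSE]
    n <- nrow(points)
  }
  d <- haversine_matrix(points$lat, points$lon)
  z <- points$indicator
  iu <- which(upper.tri(d))
  dd <- d[iu]
  sq <- (outer(z, z, "-")^2)[iu]
  if (is.null(max_lag)) max_lag <- max(dd) / 2
  if (max_lag <= 0) stop("max_lag must be positive")
  inb <- dd > 0 & dd <= max_lag
  bin <- pmin(n_bins, floor(dd[inb] / (max_lag / n_bins)) + 1L)
  npairs <- tabulate(bin, nbins = n_bins)
  ssq <- rep(0, n_bins)
  agg <- tapply(sq[inb], bin, sum)
  ssq[as.integer(names(agg))] <- agg
  gamma <- ifelse(npairs > 0, ssq / (2 * npairs), NA_real_)
  out <- data.frame(
    lag = (seq_len(n_bins) - 0.5) * max_lag / n_bins,
    gamma = gamma,
    n_pairs = npairs
  )
  attr(out, "max_lag") <- max_lag
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Names of the supported semi-variogram model families
#' @return character vector of nine family names.
#' @export
variogram_families <- function() {
  c("exponential", "spherical", "gaussian", "matern", "stein_matern",
    "circular", "linear", "bessel", "pentaspherical")
}

#' Construct a semi-variogram model
#'
#' @param family one of [variogram_families()].
#' @param nugget non-negative nugget.
#' @param psill non-negative partial sill.
#' @param range_km positive range parameter, km.
#' @param kappa Matern smoothness (used by `matern` and `stein_matern`;
#'   default 0.5, at which the Matern family equals the exponential).
#' @param rmse fit error (filled by [fit_variogram()]).
#' @param converged logical fit status.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(family, nugget, psill, range_km, kappa = 0.5,
                            rmse = NA_real_, converged = TRUE) {
  family <- match.arg(family, variogram_families())
  stopifnot(nugget >= 0, psill >= 0, range_km > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range_km = range_km, kappa = kappa, rmse = rmse,
                 converged = converged),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s (nugget %.4g, partial sill %.4g, range %.4g km%s) rmse %.4g\n",
              x$family, x$nugget, x$psill, x$range_km,
              if (x$family %in% c("matern", "stein_matern"))
                sprintf(", kappa %.3g", x$kappa) else "",
              x$rmse))
  invisible(x)
}

# Normalized structure functions g(u), u = h / range: 0 at u = 0, -> 1 at
# the range (bounded families) or asymptotically.
.vgm_structure <- function(family, u, kappa = 0.5) {
  d <- dim(u)
  g <- .vgm_structure_raw(family, u, kappa)
  dim(g) <- d
  g
}

.vgm_structure_raw <- function(family, u, kappa = 0.5) {
  switch(family,
    exponential = 1 - exp(-u),
    gaussian = 1 - exp(-u^2),
    spherical = ifelse(u <= 1, 1.5 * u - 0.5 * u^3, 1),
    pentaspherical = ifelse(u <= 1, 1.875 * u - 1.25 * u^3 + 0.375 * u^5, 1),
    circular = {
      v <- pmin(u, 1)
      ifelse(u <= 1, (2 / pi) * (asin(v) + v * sqrt(pmax(0, 1 - v^2))), 1)
    },
    linear = u,
    bessel = 1 - besselJ(u, 0),
    matern = {
      g <- rep(0, length(u))
      pos <- u > 0
      up <- u[pos]
      g[pos] <- 1 - (up^kappa * besselK(up, kappa)) / (2^(kappa - 1) * gamma(kappa))
      # besselK underflows for large u: the structure saturates at 1
      g[pos & !is.finite(g)] <- 1
      g
    },
    stein_matern = {
      # Stein's parameterization: scale so the effective range is comparable
      # across kappa; reduces to Matern with u' = sqrt(2 kappa) u.
      .vgm_structure("matern", sqrt(2 * kappa) * u, kappa)
    },
    stop("unknown variogram family: ", family)
  )
}

#' Evaluate a model semi-variogram
#'
#' By convention `gamma(0) = nugget`; the nugget discontinuity applies for
#' h > 0 (inside kriging systems the self-distance entry is 0, see
#' [krige_cell()]).
#'
#' @param model a [variogram_model()].
#' @param h distances, km (vector, >= 0).
#' @return semi-variance at each `h`.
#' @export
model_gamma <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"), all(h >= 0))
  model$nugget + model$psill * .vgm_structure(model$family, h / model$range_km,
                                              model$kappa)
}

#' Fit one semi-variogram family to an empirical variogram
#'
#' Least-squares fit of (nugget, partial sill, range) to the binned empirical
#' gammas by Levenberg-Marquardt with box bounds (nugget, partial sill >= 0;
#' range > 0), from several starting values. The objective is ordinary least
#' squares by default, or Cressie-style weights N(h)/h^2 via
#' `weights = "npairs"`. Non-convergence is reported as a typed failure in
#' the returned object, never as an exception.
#'
#' @param emp an [empirical_variogram()].
#' @param family one of [variogram_families()].
#' @param init optional named list with starting `nugget`, `psill`,
#'   `range_km`.
#' @param weights `"ols"` (default) or `"npairs"` (N(h)/h^2).
#' @param kappa fixed Matern smoothness for the two Matern families.
#' @return a [variogram_model()] with `rmse` set; on failure, `converged`
#'   is `FALSE` and attribute `reason` states why. `rmse` is
#'   `sqrt(mean((gamma_model - gamma_emp)^2))` over usable bins (unweighted,
#'   so selection is comparable across weighting schemes).
#' @export
fit_variogram <- function(emp, family, init = NULL,
                          weights = c("ols", "npairs"), kappa = 0.5) {
  weights <- match.arg(weights)
  family <- match.arg(family, variogram_families())
  ok <- !is.na(emp$gamma) & emp$n_pairs > 0
  if (sum(ok) < 3) {
    return(.failed_fit(family, "insufficient-data: fewer than 3 usable bins"))
  }
  h <- emp$lag[ok]
  g <- emp$gamma[ok]
  w <- if (weights == "npairs") emp$n_pairs[ok] / h^2 else rep(1, length(h))
  sw <- sqrt(w / mean(w))

  gmax <- max(g)
  hmax <- max(h)
  starts <- list(
    c(nugget = max(min(g), 1e-6), psill = max(gmax - min(g), 1e-6),
      range_km = hmax / 3),
    c(nugget = 1e-6, psill = max(gmax, 1e-6), range_km = hmax / 2),
    c(nugget = gmax / 2, psill = max(gmax / 2, 1e-6), range_km = hmax)
  )
  if (!is.null(init)) {
    starts <- c(list(c(nugget = init$nugget, psill = init$psill,
                       range_km = init$range_km)), starts)
  }

  resid_fn <- function(p) {
    m <- variogram_model(family, p[1], p[2], p[3], kappa = kappa)
    sw * (model_gamma(m, h) - g)
  }
  lower <- c(0, 0, hmax * 1e-4)
  upper <- c(gmax * 4 + 1, gmax * 4 + 1, hmax * 20)

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(pmin(pmax(p0, lower), upper), lower = lower,
                         upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    p <- as.numeric(fit$par)
    if (any(!is.finite(p))) next
    m <- variogram_model(family, p[1], p[2], p[3], kappa = kappa)
    m$rmse <- sqrt(mean((model_gamma(m, h) - g)^2))
    if (!is.finite(m$rmse)) next
    if (is.null(best) || m$rmse < best$rmse) best <- m
  }
  if (is.null(best)) {
    return(.failed_fit(family, "convergence failure: optimizer did not converge"))
  }
  best
}

.failed_fit <- function(family, reason) {
  m <- structure(list(family = family, nugget = NA_real_, psill = NA_real_,
                      range_km = NA_real_, kappa = NA_real_, rmse = Inf,
                      converged = FALSE),
                 class = "variogram_model")
  attr(m, "reason") <- reason
  m
}

#' Fit all families and select the lowest-RMSE model
#'
#' Every family in `families` is fitted; among converged fits the one with
#' minimal RMSE is selected (ties broken by position in `families`). If
#' every family fails the result carries `all_failed = TRUE` and the calling
#' region-year falls back to an all-zero probability surface.
#'
#' @param emp an [empirical_variogram()].
#' @param families family names (default all nine).
#' @param ... passed to [fit_variogram()].
#' @return list of class `variogram_selection`: `model` (the winning
#'   [variogram_model()], or `NULL`), `all_failed` (logical), `fits` (list of
#'   all attempted fits, named by family).
#' @export
select_variogram <- function(emp, families = variogram_families(), ...) {
  stopifnot(length(families) > 0)
  fits <- lapply(families, function(f) {
    tryCatch(fit_variogram(emp, f, ...),
             error = function(e) .failed_fit(f, conditionMessage(e)))
  })
  names(fits) <- families
  conv <- vapply(fits, function(m) isTRUE(m$converged), logical(1))
  if (!any(conv)) {
    return(structure(list(model = NULL, all_failed = TRUE, fits = fits),
                     class = "variogram_selection"))
  }
  rmses <- vapply(fits, function(m) m$rmse, numeric(1))
  rmses[!conv] <- Inf
  structure(list(model = fits[[which.min(rmses)]], all_failed = FALSE,
                 fits = fits),
            class = "variogram_selection")
}

#' @export
print.variogram_selection <- function(x, ...) {
  if (x$all_failed) {
    cat("variogram_selection: all families failed to converge\n")
  } else {
    cat("variogram_selection: selected ")
    print(x$model)
  }
  invisible(x)
}

#' Write a variogram audit dump
#'
#' Emits the binned empirical variogram and a model card for a region-year,
#' as delimited text.
#'
#' @param emp an [empirical_variogram()].
#' @param sel a `variogram_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variogram <- function(emp, sel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (sel$all_failed) {
    writeLines("# model: all families failed to converge", con)
  } else {
    m <- sel$model
    writeLines(sprintf("# model: %s nugget %.8g psill %.8g range_km %.8g rmse %.8g",
                       m$family, m$nugget, m$psill, m$range_km, m$rmse), con)
  }
  utils::write.table(as.data.frame(emp), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
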
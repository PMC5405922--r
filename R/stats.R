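# Downstream statistics: reef area above probability thresholds,
# area-weighted DHW by bleaching-probability class, period contrasts, Welch
# tests, and linear trends.

#' Probability thresholds for bleaching likelihood language
#'
#' "More likely than not" (>50%), "likely" (>66%), "very likely" (>90%).
#'
#' @return named numeric vector of strictly increasing thresholds.
#' @export
probability_thresholds <- function() {
  c(more_likely_than_not = 0.50, likely = 0.66, very_likely = 0.90)
}

#' Default 12-year periods either side of the 1997/1998 El Nino
#' @return list with integer vectors `early` (1985-1996) and `late`
#'   (1999-2010).
#' @export
period_pair <- function() {
  list(early = 1985:1996, late = 1999:2010)
}

#' Reef area with bleaching probability above a threshold
#'
#' @param prob probability grid data frame with `cell_id` and `prob`.
#' @param grid a [reef_grid()].
#' @param tau threshold in (0, 1); cells count when `prob` is strictly
#'   greater.
#' @return reef area, km^2.
#' @export
threshold_area <- function(prob, grid, tau) {
  stopifnot(tau > 0, tau < 1)
  reef_area_of(prob$cell_id[prob$prob > tau], grid)
}

#' Weighted median
#'
#' The smallest value at which the cumulative weight reaches half the total.
#'
#' @param x values.
#' @param w non-negative weights.
#' @return weighted median of `x`.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= sum(w) / 2)[1]]
}

# membership in a probability class
.prob_class <- function(p, class) {
  switch(class,
    "all"      = rep(TRUE, length(p)),
    "gt50_66"  = p > 0.50 & p <= 0.66,
    "gt66_90"  = p > 0.66 & p <= 0.90,
    "gt66"     = p > 0.66,
    "gt90"     = p > 0.90,
    stop("unknown probability class: ", class)
  )
}

#' Area-weighted DHW statistics by bleaching-probability class
#'
#' Pools all (cell, year) pairs whose kriged probability falls in the class,
#' and returns the reef-area-weighted mean and weighted median of the annual
#' maximum DHW. Classes use strict lower and inclusive upper bounds
#' (`gt50_66` means probability in (0.50, 0.66]) so bands never double
#' count.
#'
#' @param prob probability grid rows for all years (`cell_id`, `year`,
#'   `prob`).
#' @param annual annual maximum DHW data frame (`cell_id`, `year`,
#'   `max_dhw`).
#' @param grid a [reef_grid()].
#' @param class one of `"all"`, `"gt50_66"`, `"gt66_90"`, `"gt66"`,
#'   `"gt90"`.
#' @return list with `mean`, `median` (degree C-weeks), `n` (cell-years
#'   pooled), `values` and `weights` (for downstream tests); all-`NA` with a
#'   `reason` when the class is empty.
#' @export
weighted_dhw_stats <- function(prob, annual, grid, class = "all") {
  j <- merge(prob[, c("cell_id", "year", "prob")],
             annual[, c("cell_id", "year", "max_dhw")],
             by = c("cell_id", "year"))
  j <- j[.prob_class(j$prob, class), , drop = FALSE]
  if (nrow(j) == 0) {
    return(list(mean = NA_real_, median = NA_real_, n = 0L,
                values = numeric(0), weights = numeric(0),
                reason = "empty probability class"))
  }
  w <- grid$cells$reef_area[match(j$cell_id, grid$cells$cell_id)]
  list(mean = sum(w * j$max_dhw) / sum(w),
       median = weighted_median(j$max_dhw, w),
       n = nrow(j), values = j$max_dhw, weights = w)
}

#' Welch two-sample t-test (unequal variances, two-tailed)
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return list with `t`, `df` (Welch-Satterthwaite), `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate samples: both have zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Fold change between two periods of an annual series
#'
#' Ratio of the late-period mean to the early-period mean, e.g. of annual
#' reef area with bleaching probability above a threshold.
#'
#' @param years,values the annual series.
#' @param periods a [period_pair()]-style list with `early` and `late` year
#'   vectors.
#' @return `mean(late) / mean(early)`; `Inf` with a warning when the early
#'   mean is zero and the late mean is not.
#' @export
period_fold_change <- function(years, values, periods = period_pair()) {
  e <- values[years %in% periods$early]
  l <- values[years %in% periods$late]
  if (length(e) == 0 || length(l) == 0) stop("empty period in fold change")
  me <- mean(e); ml <- mean(l)
  if (me == 0) {
    if (ml == 0) return(NaN)
    warning("early-period mean is zero; fold change is infinite")
    return(Inf)
  }
  ml / me
}

#' Ordinary least-squares trend of an annual series
#'
#' @param years,values the annual series (at least 3 years).
#' @return list with `slope` (units per year), `p` (two-sided, slope != 0),
#'   `intercept`. A constant series returns slope 0, p 1.
#' @export
linear_trend <- function(years, values) {
  stopifnot(length(years) >= 3, length(years) == length(values))
  if (stats::var(values) == 0) {
    return(list(slope = 0, p = 1, intercept = values[1]))
  }
  fit <- stats::lm(values ~ years)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["years", "Estimate"]),
       p = unname(sm["years", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]))
}
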
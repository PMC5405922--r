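test_that("threshold areas count strictly exceeding cells, weighted by reef area", {
  gg <- expand.grid(lat = seq(-2, -1.92, 0.04), lon = seq(72, 72, 0.04))
  g <- reef_grid(data.frame(lat = gg$lat + 0.02, lon = gg$lon + 0.02,
                            reef_area = 1, region = "indian"))
  prob <- data.frame(cell_id = g$cells$cell_id, prob = c(0.55, 0.7, 0.95))
  expect_equal(threshold_area(prob, g, 0.5), 3)
  expect_equal(threshold_area(prob, g, 0.66), 2)
  expect_equal(threshold_area(prob, g, 0.9), 1)
  prob$prob <- 0
  expect_equal(threshold_area(prob, g, 0.5), 0)
})

test_that("threshold area is non-increasing in the threshold", {
  g <- tiny_grid()
  set.seed(14)
  for (i in 1:5) {
    prob <- data.frame(cell_id = g$cells$cell_id,
                       prob = runif(nrow(g$cells)))
    taus <- sort(runif(4, 0.05, 0.95))
    areas <- vapply(taus, function(t) threshold_area(prob, g, t), numeric(1))
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("weighted mean and median follow their definitions", {
  expect_equal(weighted_median(c(4, 8), c(1, 3)), 8)
  expect_equal(weighted_median(5, 2), 5)
  g <- tiny_grid()
  two <- g$cells$cell_id[1:2]
  g$cells$reef_area[1:2] <- c(1, 3)
  prob <- data.frame(cell_id = two, year = 1998L, prob = c(0.95, 0.95))
  ann <- data.frame(cell_id = two, year = 1998L, max_dhw = c(4, 8))
  s <- weighted_dhw_stats(prob, ann, g, "gt90")
  expect_equal(s$mean, 7)       # (1*4 + 3*8) / 4
  expect_equal(s$median, 8)
  one <- weighted_dhw_stats(prob[1, ], ann, g, "gt90")
  expect_equal(one$mean, 4); expect_equal(one$median, 4)
})

test_that("weighted statistics match a brute-force expansion oracle", {
  g <- default_study()$grid
  set.seed(19)
  cells <- g$cells[sample.int(nrow(g$cells), 20), ]
  w_int <- sample(1:9, 20, replace = TRUE)
  g$cells$reef_area[match(cells$cell_id, g$cells$cell_id)] <- w_int
  dhw <- round(runif(20, 0, 20), 2)
  prob <- data.frame(cell_id = cells$cell_id, year = 1998L, prob = 0.99)
  ann <- data.frame(cell_id = cells$cell_id, year = 1998L, max_dhw = dhw)
  s <- weighted_dhw_stats(prob, ann, g, "gt90")
  j <- merge(prob, ann, by = c("cell_id", "year"))
  wj <- w_int[match(j$cell_id, cells$cell_id)]
  expanded <- rep(j$max_dhw, wj)
  expect_equal(s$mean, mean(expanded))
  # first value where the cumulative weight reaches half the total equals
  # the left-continuous (type-1) quantile of the expanded sample
  expect_equal(s$median, unname(stats::quantile(expanded, 0.5, type = 1)))
  expect_gte(s$mean, min(dhw)); expect_lte(s$mean, max(dhw))
})

test_that("probability classes use strict lower and inclusive upper bounds", {
  g <- tiny_grid()
  ids <- g$cells$cell_id[1:4]
  prob <- data.frame(cell_id = ids, year = 1998L,
                     prob = c(0.50, 0.55, 0.66, 0.90))
  ann <- data.frame(cell_id = ids, year = 1998L, max_dhw = 1:4)
  in_band <- function(cl) {
    s <- weighted_dhw_stats(prob, ann, g, cl); s$values
  }
  expect_setequal(in_band("gt50_66"), c(2, 3))  # 0.50 excluded, 0.66 included
  expect_setequal(in_band("gt66_90"), 4)        # 0.90 included
  expect_setequal(in_band("gt90"), numeric(0))
  s <- weighted_dhw_stats(prob, ann, g, "gt90")
  expect_true(is.na(s$mean))
  expect_match(s$reason, "empty")
})

test_that("welch_t reproduces the textbook computation", {
  id <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0); expect_equal(id$p, 1)
  # a = {1,2,3}, b = {1,2,3,4,5}: t = -1/sqrt(1/3 + 1/2), WS df = 5.882
  h <- welch_t(c(1, 2, 3), c(1, 2, 3, 4, 5))
  expect_equal(h$t, -1 / sqrt(1 / 3 + 0.5), tolerance = 1e-12)
  expect_equal(h$df, (1 / 3 + 0.5)^2 / ((1 / 3)^2 / 2 + 0.5^2 / 4),
               tolerance = 1e-12)
  expect_equal(h$p, 2 * stats::pt(-abs(h$t), h$df), tolerance = 1e-12)
  expect_equal(h$p, 0.316133, tolerance = 1e-5)
  sw <- welch_t(c(1, 2, 3, 4, 5), c(1, 2, 3))
  expect_equal(sw$t, -h$t); expect_equal(sw$p, h$p)
  expect_error(welch_t(c(2, 2), c(3, 3)), "degenerate")
})

test_that("period fold change is the ratio of period means", {
  yrs <- 1985:2010
  v <- ifelse(yrs <= 1996, 1, ifelse(yrs >= 1999, 8, 99))
  expect_equal(period_fold_change(yrs, v), 8)
  expect_equal(period_fold_change(yrs, rep(2, 26)), 1)
  ev <- c(0, 2); lv <- c(4, 4)
  expect_equal(period_fold_change(c(1985, 1986, 1999, 2000), c(ev, lv)), 4)
  # scale equivariance
  expect_equal(period_fold_change(yrs, v * 17), 8)
  expect_error(period_fold_change(1999:2010, v[15:26]), "empty period")
  expect_warning(f <- period_fold_change(yrs, ifelse(yrs <= 1996, 0, 5)),
                 "infinite")
  expect_equal(f, Inf)
})

test_that("linear trends recover slopes and handle constants", {
  yrs <- 1985:2010
  tr <- linear_trend(yrs, 1.2 + 0.08 * (yrs - 1985))
  expect_equal(tr$slope, 0.08, tolerance = 1e-12)
  cst <- linear_trend(yrs, rep(3, 26))
  expect_equal(cst$slope, 0); expect_equal(cst$p, 1)
  # closed-form OLS on a 5-point fixture
  x <- 1:5; y <- c(2, 4, 5, 4, 7)
  tr2 <- linear_trend(x, y)
  expect_equal(tr2$slope, sum((x - 3) * (y - mean(y))) / sum((x - 3)^2))
})
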
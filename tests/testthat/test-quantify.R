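# A minimal valid cell table for quantification tests.
toy_table <- function(n = 8, dist = seq(5, 40, length.out = n),
                      segs = NULL) {
  if (is.null(segs))
    segs <- matrix(rep(c(10, 1, 1, 1), each = n), n, 4)
  data.frame(cell_id = sprintf("c%02d", seq_len(n)),
             x_um = dist, y_um = 0, dist_tip_um = dist,
             ch_cuc = 1, ch_wag = 1, ch_pin = rowSums(segs),
             seg_distal = segs[, 1], seg_proximal = segs[, 2],
             seg_lat1 = segs[, 3], seg_lat2 = segs[, 4],
             group = "g", grid_row = seq_len(n), grid_col = 1L)
}

test_that("single-cell polarity classification covers the canonical cases", {
  cl <- function(...) classify_cell_polarity(...)$class
  expect_equal(cl(10, 1, 1, 1), "apical")
  expect_equal(cl(1, 10, 1, 1), "basal")
  expect_equal(cl(10, 9, 1, 1), "bipolar")       # opposite within ratio
  expect_equal(cl(2, 2, 2, 2), "nonpolar")       # no dominance
  expect_equal(cl(10, 1, 9, 1), "apical-lateral")
  expect_equal(cl(1, 10, 1, 9), "basal-lateral")
  expect_equal(cl(1, 1, 10, 1), "lateral")
  expect_equal(cl(1, 8, 10, 1), "basal-lateral") # lateral dominant, basal close
  expect_error(classify_cell_polarity(1, NA, 1, 1), "missing segment")
  expect_error(classify_cell_polarity(1, -2, 1, 1), ">= 0")
  pc <- classify_cell_polarity(10, 5, 1, 1)
  expect_equal(pc$confidence, 2)                 # dominant / subdominant
})

test_that("polarity calls are invariant to common rescaling of the signals", {
  set.seed(3)
  for (k in 1:40) {
    s <- runif(4, 0.1, 10)
    c1 <- classify_cell_polarity(s[1], s[2], s[3], s[4])$class
    sc <- runif(1, 0.01, 100)
    c2 <- classify_cell_polarity(sc * s[1], sc * s[2], sc * s[3], sc * s[4])$class
    expect_identical(c1, c2)
  }
})

test_that("table-level classification excludes incomplete cells with a reason", {
  tab <- toy_table(4)
  tab$seg_lat1[2] <- NA
  calls <- classify_polarity_table(tab)
  expect_equal(nrow(calls), 3)
  excl <- attr(calls, "excluded")
  expect_equal(excl$cell_id, "c02")
  expect_match(excl$reason, "missing")
})

test_that("reversal position averages the five closest basal cells", {
  d <- c(8, 9, 11, 12, 15, 20, 30)
  n <- length(d)
  segs <- matrix(rep(c(1, 10, 1, 1), each = n), n, 4)  # all basal
  tab <- toy_table(n, dist = d, segs = segs)
  expect_equal(reversal_position(tab), 11)   # mean(8, 9, 11, 12, 15)
  tab5 <- toy_table(5, dist = rep(5, 5),
                    segs = matrix(rep(c(1, 10, 1, 1), each = 5), 5, 4))
  expect_equal(reversal_position(tab5), 5)
  tab4 <- toy_table(4, dist = 1:4,
                    segs = matrix(rep(c(1, 10, 1, 1), each = 4), 4, 4))
  expect_error(reversal_position(tab4), "insufficient basal")
  # permutation of records and distances of non-basal cells are irrelevant
  tab_mix <- toy_table(10, dist = c(d, 1, 2, 3))
  tab_mix[1:7, c("seg_distal", "seg_proximal")] <-
    data.frame(seg_distal = rep(1, 7), seg_proximal = rep(10, 7))
  est1 <- reversal_position(tab_mix)
  est2 <- reversal_position(tab_mix[sample(10), ])
  expect_equal(est1, 11)
  expect_equal(est2, est1)
})

test_that("reversal position matches a sort-take-five oracle on random tables", {
  set.seed(21)
  for (k in 1:25) {
    n <- 30
    d <- runif(n, 0, 100)
    basal <- runif(n) < 0.5
    if (sum(basal) < 5) basal[1:5] <- TRUE
    segs <- t(vapply(basal, function(b)
      if (b) c(1, 10, 1, 1) else c(10, 1, 1, 1), numeric(4)))
    tab <- toy_table(n, dist = d, segs = segs)
    expect_equal(reversal_position(tab), mean(sort(d[basal])[1:5]))
  }
})

test_that("polarity frequency analysis gives the Pearson chi-squared", {
  calls <- factor(c(rep("apical", 10), rep("basal", 10)),
                  levels = c("apical", "basal", "nonpolar"))
  grp <- rep(c("control", "clone"), each = 10)
  res <- polarity_frequencies(calls, grp)
  expect_equal(res$statistic, 20)          # all expected counts are 5
  expect_equal(res$df, 1)
  expect_equal(res$dropped_classes, "nonpolar")
  # identical distributions give zero
  calls2 <- factor(rep(c("apical", "basal"), 10))
  res2 <- polarity_frequencies(calls2, rep(c("a", "b"), each = 10))
  expect_equal(res2$statistic, 0)
  expect_error(polarity_frequencies(calls, rep("only", 20)), "degenerate")
  expect_error(polarity_frequencies(factor(rep("apical", 20)), grp),
               "degenerate")
})

test_that("control-versus-clone frequency shift is detected as significant", {
  # control mostly apical, clones mostly basal (ectopic-boundary phenotype)
  cls <- c(rep("apical", 15), rep("basal", 2), rep("apical", 3), rep("basal", 14))
  grp <- c(rep("control", 17), rep("clone", 17))
  res <- polarity_frequencies(factor(cls), grp)
  expect_gt(res$statistic, qchisq(0.95, df = res$df))
  expect_lt(res$p.value, 0.05)
})

test_that("point-biserial equals Pearson on 0/1 codes", {
  r <- point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(unname(r$estimate), 0.894427191, tolerance = 1e-8)
  set.seed(13)
  for (k in 1:50) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(unname(point_biserial(x, y)$estimate),
                 cor(x, y), tolerance = 1e-12)
  }
  expect_error(point_biserial(1:5, rep(1, 5)), "degenerate grouping")
  expect_error(point_biserial(1:2, c(0, 1)), "n >= 3")
  z <- point_biserial(rep(2, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(z$estimate), 0)
  expect_true(attr(z, "zero_variance"))
  # factor labels are accepted
  rf <- point_biserial(c(1, 2, 3, 4), factor(c("a", "a", "b", "b")))
  expect_equal(unname(rf$estimate), unname(r$estimate))
})

test_that("expression regression returns OLS slope, R2, and errors", {
  x <- c(1, 2, 3, 4, 5)
  fit <- suppressWarnings(expression_regression(x, 2 * x))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  set.seed(2)
  xr <- rnorm(500); yr <- rnorm(500)       # independent: R2 near zero
  expect_lt(expression_regression(xr, yr)$r_squared, 0.05)
  expect_error(expression_regression(1:2, 1:2), "n >= 3")
  expect_error(expression_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(expression_regression(c(1, 2, NA), 1:3), "finite")
})

test_that("ROI selection returns the proximal-inward block and reports gaps", {
  tab <- expand.grid(grid_row = 1:6, grid_col = 1:6)
  tab$cell_id <- sprintf("r%dc%d", tab$grid_row, tab$grid_col)
  roi <- select_roi_grid(tab, "r2c2")
  expect_equal(nrow(roi$cells), 16)
  expect_equal(sort(unique(roi$cells$grid_row)), 2:5)
  expect_equal(sort(unique(roi$cells$grid_col)), 2:5)
  expect_equal(nrow(roi$missing), 0)
  # origin two rows from the proximal edge: half the block is absent
  roi2 <- select_roi_grid(tab, "r5c2")
  expect_equal(nrow(roi2$cells), 8)
  expect_equal(nrow(roi2$missing), 8)
  expect_true(all(roi2$missing$grid_row > 6))
  expect_error(select_roi_grid(tab, "r9c9"), "not found")
  expect_error(select_roi_grid(tab[, "cell_id", drop = FALSE], "r2c2"),
               "grid_row")
})

test_that("cell tables round-trip through CSV with validation", {
  tab <- toy_table(6)
  f <- tempfile(fileext = ".csv")
  write_cell_table(tab, f)
  back <- read_cell_table(f)
  expect_equal(back$dist_tip_um, tab$dist_tip_um)
  expect_equal(back$seg_distal, tab$seg_distal)
  bad <- tab; bad$dist_tip_um[1] <- -5
  expect_error(validate_cell_table(bad), ">= 0")
  expect_error(validate_cell_table(tab[, 1:4]), "missing columns")
})
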
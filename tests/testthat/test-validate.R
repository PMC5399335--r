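mk_pred <- function(ids, gbv) data.frame(id = ids, gbv = gbv)

test_that("accuracy reproduces closed-form correlation, SE and slope", {
  ids <- sprintf("s%03d", 1:102)
  set.seed(71)
  x <- rnorm(102)
  # identity: r = 1, slope = 1
  a1 <- accuracy(mk_pred(ids, x), data.frame(sire_id = ids, ebv = x))
  expect_equal(a1$r, 1)
  expect_equal(a1$regression_coef, 1, tolerance = 1e-12)
  # gbv = 2 ebv: r = 1, slope of ebv on gbv = 0.5
  a2 <- accuracy(mk_pred(ids, 2 * x), data.frame(sire_id = ids, ebv = x))
  expect_equal(a2$r, 1)
  expect_equal(a2$regression_coef, 0.5, tolerance = 1e-12)
  # the SE formula at r = 0.5, n = 102
  e <- x * 0.5 + sqrt(0.75) * rnorm(102)
  af <- accuracy(mk_pred(ids, x), data.frame(sire_id = ids, ebv = e))
  expect_equal(af$se, sqrt((1 - af$r^2) / 100), tolerance = 1e-12)
  expect_equal(sqrt((1 - 0.5^2) / 100), 0.0866, tolerance = 1e-3)
})

test_that("accuracy equals an independent two-pass correlation", {
  set.seed(72)
  ids <- sprintf("s%03d", 1:60)
  g <- rnorm(60); e <- 0.6 * g + rnorm(60, 0, 0.8)
  a <- accuracy(mk_pred(ids, g), data.frame(sire_id = ids, ebv = e))
  two_pass <- sum((g - mean(g)) * (e - mean(e))) /
    sqrt(sum((g - mean(g))^2) * sum((e - mean(e))^2))
  expect_equal(a$r, two_pass, tolerance = 1e-12)
})

test_that("groups are reported separately and degenerate inputs flagged", {
  ids <- sprintf("s%03d", 1:40)
  set.seed(73)
  g <- rnorm(40); e <- g + rnorm(40, 0, 0.5)
  grp <- setNames(rep(c("Merino", "BL"), each = 20), ids)
  a <- accuracy(mk_pred(ids, g), data.frame(sire_id = ids, ebv = e),
                groups = grp)
  expect_setequal(a$group_label, c("Merino", "BL"))
  expect_equal(a$n, c(20, 20))
  # zero variance in predictions
  az <- accuracy(mk_pred(ids, rep(1, 40)), data.frame(sire_id = ids, ebv = e))
  expect_true(is.na(az$r))
  expect_equal(az$flag, "zero_variance")
})

test_that("strain adjustment removes between-group mean differences", {
  set.seed(74)
  ids <- sprintf("s%03d", 1:60)
  strain <- setNames(rep(c("fine", "strong"), each = 30), ids)
  # pure strain shifts, no within-strain association
  g <- rnorm(60) + ifelse(strain == "fine", 2, -2)
  e <- rnorm(60) + ifelse(strain == "fine", 3, -3)
  raw <- accuracy(mk_pred(ids, g), data.frame(sire_id = ids, ebv = e))
  adj <- accuracy(mk_pred(ids, g), data.frame(sire_id = ids, ebv = e),
                  covariate_adjust = strain)
  expect_gt(raw$r, 0.5)          # inflated by the strain means
  expect_lt(abs(adj$r), 0.3)     # gone after residualization
})

test_that("the regression of EBV on unbiased predictions approaches one", {
  set.seed(75)
  slopes <- replicate(10, {
    n <- 400
    tbv <- rnorm(n, 0, sqrt(0.3))
    gbv <- 0.3 / (0.3 + 0.1) * (tbv + rnorm(n, 0, sqrt(0.1)))  # BLUP-like
    a <- accuracy(mk_pred(sprintf("s%d", 1:n), gbv),
                  data.frame(sire_id = sprintf("s%d", 1:n), ebv = tbv))
    a$regression_coef
  })
  expect_lt(abs(mean(slopes) - 1), 0.1)
})

test_that("se decreases monotonically in n at fixed r", {
  se_at <- function(n) sqrt((1 - 0.5^2) / (n - 2))
  expect_true(all(diff(sapply(c(10, 50, 100, 500), se_at)) < 0))
})

test_that("stratified comparison reports per-stratum differences with bootstrap", {
  set.seed(76)
  ids <- sprintf("s%03d", 1:80)
  strata <- setNames(rep(c("high", "low"), each = 40), ids)
  tbv <- rnorm(80)
  ebv <- tbv + rnorm(80, 0, 0.2)
  pred_good <- mk_pred(ids, tbv + rnorm(80, 0, 0.3))
  pred_poor <- mk_pred(ids, tbv + rnorm(80, 0, 1.2))
  out <- stratified_comparison(list(moderate = pred_poor, dense = pred_good),
                               data.frame(sire_id = ids, ebv = ebv),
                               strata = strata, n_boot = 300, seed = 5)
  expect_setequal(out$accuracy$stratum, c("high", "low"))
  expect_equal(nrow(out$differences), 2)
  # the bootstrap interval covers the point difference
  expect_true(all(out$differences$boot_lo <= out$differences$diff + 1e-9))
  expect_true(all(out$differences$boot_hi >= out$differences$diff - 1e-9))
  # identical predictions under both panels: difference exactly zero
  same <- stratified_comparison(list(a = pred_good, b = pred_good),
                                data.frame(sire_id = ids, ebv = ebv),
                                strata = strata, n_boot = 50, seed = 6)
  expect_true(all(same$differences$diff == 0))
  # small strata carry a low-n flag
  tiny <- stratified_comparison(list(a = pred_good, b = pred_poor),
                                data.frame(sire_id = ids[1:8], ebv = ebv[1:8]),
                                strata = strata[1:8], n_boot = 50, seed = 7)
  expect_true(all(tiny$accuracy$low_n))
})
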
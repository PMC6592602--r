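test_that("two-point construction matches hand algebra and the closed form", {
  tp <- fit_two_point(1, 20, 4, 80)
  expect_equal(coef(tp), c(ec50 = 2, beta = 2), tolerance = 1e-12)

  for (pts in list(c(0.474, 5, 7.110, 20),     # Cd LC5/LC20
                   c(1.416, 5, 9.501, 20),     # Zn LC5/LC20
                   c(0.226, 5, 1.299, 20))) {  # Cu LC5/LC20
    fit <- fit_two_point(pts[1], pts[2], pts[3], pts[4])
    expect_equal(coef(fit), oracle_two_point(pts[1], pts[2], pts[3], pts[4]),
                 tolerance = 1e-10)
    # the curve passes through both points exactly
    expect_equal(predict(fit, c(pts[1], pts[3])), c(pts[2], pts[4]),
                 tolerance = 1e-9)
  }
  cd <- fit_two_point(0.474, 5, 7.110, 20, "Cd")
  expect_equal(coef(cd)[["beta"]], 0.5753751, tolerance = 1e-6)
  expect_equal(coef(cd)[["ec50"]], 79.11300, tolerance = 1e-6)
  expect_equal(predict(cd, 7.110), 20, tolerance = 1e-9)
  expect_equal(lc(cd, 5), 0.474, tolerance = 1e-9)
})

test_that("degenerate two-point inputs are rejected", {
  expect_error(fit_two_point(1, 20, 1, 80), "equal concentrations")
  expect_error(fit_two_point(1, 20, 4, 20), "equal effects")
  expect_error(fit_two_point(1, 0, 4, 80), "strictly inside")
})

test_that("effect and LC are mutual inverses and the curve is monotone", {
  set.seed(101)
  for (i in 1:25) {
    cv <- random_curve()
    x <- c(1, 5, 20, 50, 80, 99)
    expect_equal(predict(cv, lc(cv, x)), x, tolerance = 1e-9)
    cc <- sort(10^stats::runif(8, -2, 3))
    expect_true(all(diff(predict(cv, cc)) > 0))
  }
  cv <- curves$Zn
  expect_equal(predict(cv, coef(cv)[["ec50"]]), 50, tolerance = 1e-12)
  expect_identical(predict(cv, 0), 0)
  expect_lt(lc(cv, 20), lc(cv, 40))
  expect_error(lc(cv, 0), "strictly inside")
  expect_error(lc(cv, 100), "strictly inside")
})

test_that("effects are invariant to the unit in which the dose is given", {
  cv <- loglogistic_curve(9.501, 0.82, "Zn")
  in_mgL <- predict(cv, 3.7)
  expect_equal(predict(cv, convert_concentration(3.7, "mg/L", "mM", "Zn"),
                       unit = "mM"), in_mgL, tolerance = 1e-12)
  expect_equal(predict(cv, convert_concentration(3.7, "mg/L", "uM", "Zn"),
                       unit = "uM"), in_mgL, tolerance = 1e-12)
})

test_that("least-squares fit recovers exact data and reduces to two-point", {
  cv <- loglogistic_curve(10, 1.5)
  doses <- c(1, 3, 10, 30, 100)
  fit <- fit_loglogistic(doses, predict(cv, doses))
  expect_equal(coef(fit), coef(cv), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-6)

  f2 <- fit_loglogistic(c(1, 4), c(20, 80))
  expect_equal(coef(f2), c(ec50 = 2, beta = 2), tolerance = 1e-4)
})

test_that("five-level Zn fit beats an exhaustive grid search", {
  rows <- lc24[lc24$compound == "Zn", ]
  fit <- fit_loglogistic(rows$conc_mg_per_L, rows$lc_level)
  rss <- function(ec50, beta) {
    r <- (rows$conc_mg_per_L / ec50)^beta
    sum((rows$lc_level - 100 * r / (1 + r))^2)
  }
  grid <- expand.grid(ec50 = seq(20, 200, length.out = 150),
                      beta = seq(0.3, 2, length.out = 150))
  grid_best <- min(mapply(rss, grid$ec50, grid$beta))
  expect_lte(fit$rss, grid_best + 1e-8)
  # the five levels are mutually consistent with one curve
  expect_lt(fit$rss, 1e-4)
  expect_equal(coef(fit)[["ec50"]], 51.69, tolerance = 1e-3)
  expect_equal(coef(fit)[["beta"]], 0.818, tolerance = 1e-2)
})

test_that("fit rejects invalid input and simulate() draws plausible tables", {
  expect_error(fit_loglogistic(1, 10), "at least 2")
  expect_error(fit_loglogistic(c(1, 2), c(10, NA)), "non-finite")
  expect_error(fit_loglogistic(c(1, 2), c(10, 100)), "\\[0, 100\\)")

  cv <- loglogistic_curve(10, 1.5)
  tabs <- simulate(cv, nsim = 3, seed = 9, conc = c(2, 10, 50),
                   n_per_dose = 500)
  expect_length(tabs, 3)
  expect_true(all(tabs[[1]]$dead <= 500))
  expect_equal(tabs[[1]]$effect, 100 * tabs[[1]]$dead / 500)
})

test_that("curves rebuilt from the bundled LC table invert to its entries", {
  for (cp in c("Zn", "Cu", "Cd")) {
    cv <- curves[[cp]]
    rows <- lc24[lc24$compound == cp, ]
    expect_equal(lc(cv, rows$lc_level), rows$conc_mg_per_L, tolerance = 1e-3)
  }
})
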
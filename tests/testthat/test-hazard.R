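test_that("hazard conversion reproduces the window mortality", {
  zn <- curves$Zn
  h <- hazard_from_lc(zn, lc(zn, 20))
  expect_equal(h, -log(0.8) / 24, tolerance = 1e-9)
  expect_equal(100 * (1 - exp(-h * 24)), 20, tolerance = 1e-9)
  expect_identical(hazard_from_lc(zn, 0), 0)
  cc <- c(0.5, 2, 9, 40, 120)
  expect_true(all(diff(hazard_from_lc(zn, cc)) > 0))
})

test_that("IA combination is the competing-risks form of the survival product", {
  zn <- curves$Zn; cd <- curves$Cd
  hm <- hazard_model(list(Zn = zn, Cd = cd), rule = "IA")
  conc <- c(Zn = lc(zn, 20), Cd = lc(cd, 20))
  h <- combined_hazard(hm, conc)
  surv24 <- exp(-h * 24)
  expect_equal(surv24, 0.8 * 0.8, tolerance = 1e-9)
  expect_equal(100 * (1 - surv24),
               predict_ia(mixture(list(zn, cd), unname(conc))),
               tolerance = 1e-9)
  # single component: every rule reduces to hazard_from_lc
  for (rule in c("IA", "CA")) {
    hm1 <- hazard_model(list(Zn = zn), rule = rule)
    expect_equal(combined_hazard(hm1, c(Zn = 5)), hazard_from_lc(zn, 5),
                 tolerance = 1e-8)
  }
})

test_that("CA combination reproduces the CA mixture effect over the window", {
  zn <- curves$Zn; cd <- curves$Cd
  hm <- hazard_model(list(Zn = zn, Cd = cd), rule = "CA")
  conc <- c(Zn = 9.501, Cd = 7.110)
  h <- combined_hazard(hm, conc)
  y <- predict_ca(mixture(list(zn, cd), unname(conc)))
  expect_equal(100 * (1 - exp(-h * 24)), y, tolerance = 1e-6)
})

test_that("the Zn protection factor is U-shaped with unit endpoints", {
  expect_identical(zn_protection_factor(0), 1)
  g <- zn_protection_factor(c(0.445, 1.416, 9.501, 31.495, 84.823, 500))
  expect_true(all(g > 0 & g <= 1))
  # protection deepens from LC2 to around LC40 ...
  expect_true(all(diff(g[1:4]) < 0))
  # ... and is lost again beyond the overload threshold
  expect_gt(g[5], g[4])
  expect_gt(g[6], g[5])
  # the configured floor is attained at the optimum
  zz <- seq(0.1, 200, by = 0.1)
  expect_equal(min(zn_protection_factor(zz)), 0.25, tolerance = 1e-3)
})

test_that("protective rule scales only Cd and vanishes without Zn", {
  zn <- curves$Zn; cd <- curves$Cd
  hm <- hazard_model(list(Zn = zn, Cd = cd), rule = "protective_zn_cd")
  # Zn = 0: Cd hazard unchanged
  expect_equal(combined_hazard(hm, c(Zn = 0, Cd = 7.110)),
               hazard_from_lc(cd, 7.110), tolerance = 1e-9)
  # with Zn present, the mixture hazard drops below the IA combination
  hm_ia <- hazard_model(list(Zn = zn, Cd = cd), rule = "IA")
  conc <- c(Zn = 9.501, Cd = 7.110)
  expect_lt(combined_hazard(hm, conc), combined_hazard(hm_ia, conc))
  # but Zn's own hazard still acts in full
  expect_gte(combined_hazard(hm, conc), hazard_from_lc(zn, 9.501))
  expect_error(hazard_model(list(Zn = zn), rule = "protective_zn_cd"),
               "needs")
})

test_that("the IA-prediction deficit of protective mixtures is U-shaped", {
  zn <- curves$Zn; cd <- curves$Cd
  hm <- hazard_model(list(Zn = zn, Cd = cd), rule = "protective_zn_cd")
  cd20 <- lc(cd, 20)
  deficit <- vapply(c(2, 5, 20, 40, 60), function(lvl) {
    znc <- lc(zn, lvl)
    obs <- 100 * (1 - exp(-combined_hazard(hm, c(Zn = znc, Cd = cd20)) * 24))
    predict_ia(mixture(list(zn, cd), c(znc, cd20))) - obs
  }, numeric(1))
  # expected mortality sits below the IA prediction at every level ...
  expect_true(all(deficit > 0))
  # ... deepest in the protective mid-range, attenuated at Zn overload
  expect_lt(deficit[5], min(deficit[2:4]))
  expect_gt(max(deficit[2:4]), deficit[1])
})
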
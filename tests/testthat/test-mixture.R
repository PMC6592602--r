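test_that("IA prediction follows the survival product", {
  zn <- curves$Zn; cu <- curves$Cu; cd <- curves$Cd
  # single compound at its EC50
  expect_equal(predict_ia(mixture(zn, coef(zn)[["ec50"]])), 50,
               tolerance = 1e-9)
  # each component at its own LC20: 100 (1 - 0.8^k)
  two <- mixture(list(zn, cd), c(lc(zn, 20), lc(cd, 20)))
  expect_equal(predict_ia(two), 36, tolerance = 1e-6)
  three <- mixture(list(zn, cu, cd), c(lc(zn, 20), lc(cu, 20), lc(cd, 20)))
  expect_equal(predict_ia(three), 48.8, tolerance = 1e-6)
})

test_that("CA reduces to the single curve and respects sham additivity", {
  set.seed(202)
  for (i in 1:20) {
    cv <- random_curve()
    dose <- lc(cv, stats::runif(1, 1, 99))
    # n = 1: CA and IA both collapse to the curve itself
    y1 <- predict(cv, dose)
    expect_equal(predict_ca(mixture(cv, dose)), y1, tolerance = 1e-8)
    expect_equal(predict_ia(mixture(cv, dose)), y1, tolerance = 1e-9)
    # sham mixture: the same compound split into k parts
    k <- sample(2:4, 1)
    sham <- mixture(rep(list(cv), k), rep(dose / k, k))
    expect_equal(predict_ca(sham), y1, tolerance = 1e-8)
  }
})

test_that("CA bisection agrees with a brute-force grid scan", {
  set.seed(303)
  for (i in 1:20) {
    k <- sample(2:3, 1)
    cvs <- replicate(k, random_curve(), simplify = FALSE)
    conc <- vapply(cvs, function(cv) lc(cv, stats::runif(1, 2, 80)), 1)
    y <- predict_ca(mixture(cvs, conc))
    ec50 <- vapply(cvs, function(cv) coef(cv)[["ec50"]], 1)
    beta <- vapply(cvs, function(cv) coef(cv)[["beta"]], 1)
    expect_equal(y, oracle_ca_grid(conc, ec50, beta), tolerance = 2e-3)
  }
})

test_that("CA and IA are monotone in every component concentration", {
  zn <- curves$Zn; cd <- curves$Cd
  base <- c(5, 3)
  for (j in 1:2) {
    up <- base; up[j] <- up[j] * 2
    expect_gt(predict_ca(mixture(list(zn, cd), up)),
              predict_ca(mixture(list(zn, cd), base)))
    expect_gt(predict_ia(mixture(list(zn, cd), up)),
              predict_ia(mixture(list(zn, cd), base)))
  }
  # all-zero mixture returns 0 by convention
  expect_identical(predict_ca(mixture(list(zn, cd), c(0, 0))), 0)
  # solver diagnostics are exposed
  d <- predict_ca(mixture(list(zn, cd), base), details = TRUE)
  expect_lt(abs(d$residual), 1e-8)
})

test_that("CA solver reports a residual within tolerance of the balance", {
  zn <- curves$Zn; cd <- curves$Cd
  mix <- mixture(list(zn, cd), c(lc(zn, 20), lc(cd, 20)))
  y <- predict_ca(mix)
  expect_gt(y, 20)  # joint action exceeds either single LC20
  q <- (y / (100 - y))
  tu <- lc(zn, 20) / (coef(zn)[["ec50"]] * q^(1 / coef(zn)[["beta"]])) +
    lc(cd, 20) / (coef(cd)[["ec50"]] * q^(1 / coef(cd)[["beta"]]))
  expect_equal(tu, 1, tolerance = 1e-8)
  # a strict shared-slope mode is available
  ys <- predict_ca(mix, shared_beta = 0.7)
  expect_false(isTRUE(all.equal(y, ys)))
})

test_that("interaction calls follow the exact signed-rank decision rule", {
  pred <- list(y_ca = 40, y_ia = 45)
  # 6 distinct replicates all strictly below both predictions
  obs <- c(12, 15, 9, 18, 14, 11)
  call <- classify_interaction(obs, pred)
  expect_identical(call$label, "antagonistic")
  expect_equal(call$p_vs_ca, 1 / 64, tolerance = 1e-12)
  expect_equal(call$p_vs_ia, 1 / 64, tolerance = 1e-12)
  # the exact p agrees with full enumeration of sign patterns
  expect_equal(call$p_vs_ca, oracle_signed_rank_p_less(obs - pred$y_ca),
               tolerance = 1e-12)
  # all above both -> synergistic, with the mirrored exact p
  call_up <- classify_interaction(obs + 60, pred)
  expect_identical(call_up$label, "synergistic")
  expect_equal(call_up$p_vs_ca, 1 / 64, tolerance = 1e-12)
})

test_that("ties and discordant directions collapse to additive", {
  pred <- list(y_ca = 30, y_ia = 30)
  tied <- classify_interaction(rep(30, 6), pred)
  expect_identical(tied$label, "additive")
  expect_identical(tied$p_vs_ca, 1)
  expect_identical(tied$direction_vs_ca, 0)
  # below CA but above IA: mixed directions, no call
  mixed <- classify_interaction(c(26, 27, 25, 28, 26.5, 27.5),
                                list(y_ca = 40, y_ia = 20))
  expect_identical(mixed$label, "additive")
  expect_error(classify_interaction(c(10, 20), pred), "at least 3")
  expect_error(classify_interaction(c(10, 20, 150), pred), "\\[0, 100\\]")
})

test_that("ratio profiles follow the stated conventions", {
  expect_equal(ratio_profile(c(20, 20, 20), 20), c(1, 1, 1))
  expect_equal(ratio_profile(50, 100), 0.5)
  expect_error(ratio_profile(c(1, 2), 0), "positive")
  named <- ratio_profile(c(LC5 = 10, LC20 = 30), 20)
  expect_named(named, c("LC5", "LC20"))
})
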
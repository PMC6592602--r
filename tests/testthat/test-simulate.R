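test_that("deterministic bookkeeping matches the closed-form egg budget", {
  # 10 founders laying 5 eggs/adult/day over 4 days, no deaths:
  # 10 + 10*5*4 = 210 individuals (founders plus eggs/larvae)
  cfg <- sim_config(duration_days = 4, n_start_adults = 10, fecundity = 5,
                    deterministic = TRUE)
  sim <- simulate_population(cfg)
  expect_equal(tail(sim$hourly$total_all, 1), 210, tolerance = 1e-9)
  expect_equal(sim$mortality$n_alive, rep(10, 5))
})

test_that("founders never die without exposure and splits never create", {
  # hazard-free, no transfers: every founder survives
  cfg <- sim_config(duration_days = 6, seed = 11)
  sim <- simulate_population(cfg)
  expect_true(all(sim$mortality$n_alive == 10))
  # with transfers, founders can only be diluted away, never multiplied
  cfg_s <- sim_config(duration_days = 6, seed = 11,
                      schedule = dilution_schedule(c(36, 72, 108, 144), 2))
  sim_s <- simulate_population(cfg_s)
  expect_true(all(diff(sim_s$mortality$n_alive) <= 0))
  expect_true(all(sim_s$counts$counted_n >= 0))
  # without reproduction the population can only shrink
  cfg0 <- sim_config(duration_days = 4, fecundity = 0, seed = 12,
                     schedule = dilution_schedule(c(36, 72), 2))
  tot <- simulate_population(cfg0)$hourly$total_all
  expect_true(all(diff(tot) <= 0))
})

test_that("founder mortality follows the binomial hazard construction", {
  cd <- curves$Cd
  hm <- hazard_model(list(Cd = cd), rule = "IA")
  dead <- vapply(1:25, function(s) {
    cfg <- sim_config(exposure = c(Cd = lc(cd, 20)), hazard = hm,
                      duration_days = 1, n_start_adults = 1000,
                      fecundity = 0, seed = s)
    m <- simulate_population(cfg)$mortality
    1000 - m$n_alive[m$time_h == 24]
  }, numeric(1))
  # each replicate inside the exact binomial 99.9% interval around 20%
  ci <- qbinom(c(0.0005, 0.9995), 1000, 0.2)
  expect_true(all(dead >= ci[1] & dead <= ci[2]))
  # and the mean close to the nominal construction
  expect_equal(mean(dead) / 1000, 0.2, tolerance = 0.02)
})

test_that("expectation mode matches the mean of sampled runs", {
  mk <- function(det, seed = NULL)
    sim_config(duration_days = 4, fecundity = 20, deterministic = det,
               seed = seed)
  expected <- tail(simulate_population(mk(TRUE))$hourly$total_all, 1)
  sampled <- vapply(1:60, function(s)
    tail(simulate_population(mk(FALSE, s))$hourly$total_all, 1), numeric(1))
  se <- sd(sampled) / sqrt(length(sampled))
  expect_lt(abs(mean(sampled) - expected), 4 * se + 1)
})

test_that("reconstruction recovers the undiluted trajectory on average", {
  sched <- dilution_schedule(c(36, 72, 108, 144), 2)
  ref <- simulate_population(
    sim_config(duration_days = 7, fecundity = 20, deterministic = TRUE))
  rec <- vapply(1:40, function(s) {
    sim <- simulate_population(
      sim_config(duration_days = 7, fecundity = 20, schedule = sched,
                 seed = s))
    sim$counts$true_n[sim$counts$day == 7]
  }, numeric(1))
  ref_n <- ref$counts$counted_n[ref$counts$day == 7]
  se <- sd(rec) / sqrt(length(rec))
  expect_lt(abs(mean(rec) - ref_n), 4 * se + 0.05 * ref_n)
})

test_that("development slows and counts collapse under strong exposure", {
  cd <- curves$Cd
  hm <- hazard_model(list(Cd = cd), rule = "IA")
  sim <- simulate_population(
    sim_config(exposure = c(Cd = lc(cd, 20)), hazard = hm,
               duration_days = 10, seed = 21,
               schedule = dilution_schedule(seq(36, 240, 36), 2)))
  ctrl <- simulate_population(
    sim_config(duration_days = 10, seed = 21,
               schedule = dilution_schedule(seq(36, 240, 36), 2)))
  expect_lt(max(sim$counts$true_n), max(ctrl$counts$true_n))
  expect_lt(sim$counts$true_n[10], ctrl$counts$true_n[10])
  # body lengths under exposure stay behind the control's
  if (!is.null(sim$lengths) && !is.null(ctrl$lengths)) {
    d5 <- function(x) mean(x$length_mm[x$day == 5])
    expect_lt(d5(sim$lengths), d5(ctrl$lengths))
  }
})

test_that("a fixed seed reproduces a generated experiment byte for byte", {
  des <- zncd_series_design(n_replicates = 2)
  hm <- hazard_model(curves[c("Zn", "Cd")], rule = "protective_zn_cd")
  e1 <- generate_experiment(des, hm, seed = 33)
  e2 <- generate_experiment(des, hm, seed = 33)
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$mortality, e2$mortality)
  expect_identical(e1$lengths, e2$lengths)
  e3 <- generate_experiment(des, hm, seed = 34)
  expect_false(identical(e1$counts, e3$counts))
})

test_that("refitting simulated mortalities recovers the generating curve", {
  zn <- curves$Zn
  doses <- lc24$conc_mg_per_L[lc24$compound == "Zn"]
  ok <- 0
  for (s in 1:20) {
    tab <- simulate(zn, nsim = 1, seed = 700 + s, conc = doses,
                    n_per_dose = 1000)[[1]]
    eff <- pmin(99.9, pmax(0.05, tab$effect))
    fit <- fit_loglogistic(tab$conc, eff)
    rel <- abs(coef(fit) / coef(zn) - 1)
    if (rel[["ec50"]] < 0.1 && rel[["beta"]] < 0.15) ok <- ok + 1
  }
  expect_gte(ok, 18)
})
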
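#' Life-stage parameters for the simulated C. elegans population
#'
#' Stage durations (hours at 20 C), representative body lengths (mm) and
#' relative hazard-sensitivity multipliers for the six modelled stages:
#' egg, four larval stages and adult. Defaults give a 72 h egg-to-adult
#' time (development through four larval stages in ~3 days), body lengths
#' anchored at ~0.37 mm at the first molt and ~1.06 mm at the onset of
#' egg laying, with adults growing toward 1.5 mm; larvae are more
#' sensitive to metal exposure than adults, eggs much less (shell
#' protection).
#'
#' @param duration_h named durations for `egg`, `L1`, `L2`, `L3`, `L4`
#'   (adult duration is governed by the lifespan settings of
#'   [sim_config()]).
#' @param length_mm named lengths for all six stages; the adult value is
#'   the length at the start of adulthood.
#' @param sensitivity named hazard multipliers for all six stages
#'   (adult = 1 so LC tables, which were determined on adults, apply
#'   unscaled).
#' @return a data frame of class `"stage_params"` with one row per stage.
#' @export
stage_params <- function(
    duration_h = c(egg = 14, L1 = 16, L2 = 12, L3 = 12, L4 = 18),
    length_mm = c(egg = 0.05, L1 = 0.25, L2 = 0.37, L3 = 0.50, L4 = 0.65,
                  adult = 1.06),
    sensitivity = c(egg = 0.2, L1 = 2, L2 = 1.8, L3 = 1.5, L4 = 1.2,
                    adult = 1)) {
  stages <- c("egg", "L1", "L2", "L3", "L4", "adult")
  if (!all(names(duration_h) == stages[1:5]) || any(duration_h <= 0))
    stop("duration_h must be positive and named egg, L1..L4", call. = FALSE)
  if (!all(stages %in% names(length_mm)))
    stop("length_mm must cover all six stages", call. = FALSE)
  if (any(diff(length_mm[stages]) <= 0))
    stop("body lengths must increase with stage", call. = FALSE)
  if (!all(stages %in% names(sensitivity)) || any(sensitivity < 0))
    stop("sensitivity must be non-negative for all six stages", call. = FALSE)
  structure(data.frame(stage = stages,
                       duration_h = c(unname(duration_h[stages[1:5]]), Inf),
                       length_mm = unname(length_mm[stages]),
                       sensitivity = unname(sensitivity[stages])),
            class = c("stage_params", "data.frame"))
}

#' Configuration of a simulated population-toxicity experiment
#'
#' Describes one well: the founder cohort, the exposure, the hazard
#' model combining the metals' lethal effects, sub-lethal effect scaling,
#' the transfer/dilution schedule and the bookkeeping times.
#'
#' Sub-lethal effects share the lethal dose scale: writing `y` for the
#' 24 h-equivalent mortality of the exposure (from the combined hazard),
#' stage durations are multiplied by `1 + dev_delay_mult * y/100` and the
#' egg-laying rate by `max(0, 1 - fecundity_red_mult * y/100)`. The
#' default multipliers are strong enough that near 20%-lethal exposures
#' development slows and reproduction largely stops after one new
#' generation.
#'
#' @param exposure named concentrations (mg/L) for the hazard model's
#'   compounds; empty or all-zero for a control.
#' @param hazard a [hazard_model()]; may be `NULL` for a control well
#'   with no exposure.
#' @param duration_days experiment length in days.
#' @param schedule a [dilution_schedule()] of transfer/split events.
#' @param n_start_adults founder adults per well (default 10).
#' @param fecundity eggs per adult per day during the fertile window.
#' @param maturation_h hours after the final molt before egg laying
#'   starts (newly molted adults must first reach the egg-laying size of
#'   ~1.06 mm); founder adults enter the well already mature. With the
#'   default 72 h egg-to-adult development this gives a 4-day egg-to-egg
#'   generation time.
#' @param fertile_window_days length of the egg-laying window (days),
#'   counted from the end of maturation.
#' @param post_fertile_lifespan_days adult survival beyond the fertile
#'   window, absent exposure.
#' @param dev_delay_mult,fecundity_red_mult sub-lethal effect multipliers
#'   (see Details).
#' @param stages a [stage_params()] table.
#' @param deterministic if `TRUE`, propagate expected values instead of
#'   sampling (no randomness).
#' @param seed optional integer seed applied at the start of
#'   [simulate_population()].
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(exposure = numeric(), hazard = NULL,
                       duration_days = 10,
                       schedule = dilution_schedule(),
                       n_start_adults = 10,
                       fecundity = 50, maturation_h = 24,
                       fertile_window_days = 4,
                       post_fertile_lifespan_days = 12,
                       dev_delay_mult = 3, fecundity_red_mult = 3,
                       stages = stage_params(),
                       deterministic = FALSE, seed = NULL) {
  stopifnot(duration_days > 0, n_start_adults >= 0, fecundity >= 0,
            maturation_h >= 0,
            fertile_window_days >= 0, post_fertile_lifespan_days >= 0,
            dev_delay_mult >= 0, fecundity_red_mult >= 0)
  if (length(exposure) && is.null(hazard) && any(exposure > 0))
    stop("an exposure needs a hazard model", call. = FALSE)
  if (!is.null(hazard)) stopifnot(inherits(hazard, "hazard_model"))
  stopifnot(inherits(schedule, "dilution_schedule"),
            inherits(stages, "stage_params"))
  structure(list(exposure = exposure, hazard = hazard,
                 duration_days = duration_days, schedule = schedule,
                 n_start_adults = n_start_adults, fecundity = fecundity,
                 maturation_h = maturation_h,
                 fertile_window_days = fertile_window_days,
                 post_fertile_lifespan_days = post_fertile_lifespan_days,
                 dev_delay_mult = dev_delay_mult,
                 fecundity_red_mult = fecundity_red_mult,
                 stages = stages, deterministic = deterministic, seed = seed),
            class = "sim_config")
}

#' Simulate one well of a population-toxicity experiment
#'
#' Stage-structured stochastic simulation on a 1 h time step. Each hour,
#' every individual dies with probability `1 - exp(-h * s)` where `h` is
#' the exposure's combined per-hour hazard and `s` its stage sensitivity;
#' survivors age, molting to the next stage when the (exposure-delayed)
#' stage duration is reached; adults inside the fertile window lay eggs at
#' the (exposure-reduced) configured rate; adults beyond the fertile
#' window plus post-fertile lifespan die of senescence; transfer events
#' subsample every cohort binomially with probability `1/split_divisor`.
#' Founder adults are tracked separately so that founder mortality (the
#' quantity scored in short mixture assays) is available. In
#' deterministic mode all random draws are replaced by their expected
#' values.
#'
#' @param config a [sim_config()].
#' @return an object of class `"population_sim"`: a list with
#' \describe{
#'   \item{hourly}{data frame of per-hour in-well totals by stage,
#'     `total` (larvae + adults, the countable population), `total_all`
#'     (including eggs) and `founders_alive`.}
#'   \item{counts}{daily counted well abundances (larvae + adults) with
#'     the cumulative dilution factor and the reconstructed population.}
#'   \item{lengths}{data frame of daily body-length samples (mm) of up to
#'     20 of the largest (post-larval protocol) individuals.}
#'   \item{mortality}{founder cohort records: `time_h`, `n_start`,
#'     `n_alive`.}
#'   \item{hazard_per_h, y24}{the combined hazard and its 24 h-equivalent
#'     mortality (percent).}
#' }
#' @examples
#' cfg <- sim_config(duration_days = 4, n_start_adults = 10, fecundity = 5,
#'                   deterministic = TRUE)
#' sim <- simulate_population(cfg)
#' tail(sim$hourly$total_all, 1)  # 10 founders + 10*5*4 eggs laid = 210
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  det <- config$deterministic
  st <- config$stages
  n_stage <- nrow(st)
  adult_idx <- n_stage

  # exposure-wide scalars
  h0 <- if (is.null(config$hazard) || !length(config$exposure) ||
            all(config$exposure == 0)) 0
        else combined_hazard(config$hazard, config$exposure)
  y24 <- 100 * (1 - exp(-h0 * 24))
  delay <- 1 + config$dev_delay_mult * y24 / 100
  fec_factor <- max(0, 1 - config$fecundity_red_mult * y24 / 100)
  fec_per_h <- config$fecundity / 24 * fec_factor
  dur_eff <- st$duration_h * delay
  p_die <- 1 - exp(-h0 * st$sensitivity)    # per stage, per hour
  mat_h <- config$maturation_h
  fertile_end <- mat_h + config$fertile_window_days * 24
  max_adult_h <- fertile_end + config$post_fertile_lifespan_days * 24

  # cohorts: stage index, age in stage (h), count, founder flag;
  # founders enter as already-mature adults (age = maturation_h)
  cohorts <- data.frame(stage = adult_idx, age = mat_h,
                        n = config$n_start_adults, founder = TRUE)
  n_hours <- round(config$duration_days * 24)
  sched_t <- round(config$schedule$time_h)
  hourly <- matrix(0, n_hours + 1L, n_stage,
                   dimnames = list(NULL, st$stage))
  hourly[1L, adult_idx] <- config$n_start_adults
  founders <- numeric(n_hours + 1L)
  founders[1L] <- config$n_start_adults
  count_days <- seq_len(config$duration_days)
  counts <- data.frame(day = count_days, counted_n = NA_real_)
  len_samples <- vector("list", config$duration_days)

  draw_deaths <- function(n, p) {
    if (det) n * p else stats::rbinom(length(n), n, p)
  }

  cohort_length <- function(stage, age) {
    # larvae interpolate toward the next stage's length; adults grow
    # from 1.06 mm toward 1.5 mm over 4 days
    ifelse(stage == adult_idx,
           st$length_mm[adult_idx] +
             (1.5 - st$length_mm[adult_idx]) * pmin(1, age / 96),
           st$length_mm[stage] +
             (st$length_mm[pmin(stage + 1L, n_stage)] - st$length_mm[stage]) *
             pmin(1, age / dur_eff[stage]))
  }

  for (t in seq_len(n_hours)) {
    if (nrow(cohorts)) {
      # mortality
      dead <- draw_deaths(cohorts$n, p_die[cohorts$stage])
      cohorts$n <- cohorts$n - dead
      # egg laying (from survivors, before this hour's aging)
      fertile <- cohorts$stage == adult_idx & cohorts$age >= mat_h &
        cohorts$age < fertile_end
      n_fertile <- sum(cohorts$n[fertile])
      eggs <- if (n_fertile > 0 && fec_per_h > 0) {
        if (det) n_fertile * fec_per_h
        else stats::rpois(1L, n_fertile * fec_per_h)
      } else 0
      # aging and stage transitions
      cohorts$age <- cohorts$age + 1
      molt <- cohorts$stage < adult_idx & cohorts$age >= dur_eff[cohorts$stage]
      cohorts$stage[molt] <- cohorts$stage[molt] + 1L
      cohorts$age[molt] <- 0
      # senescence
      senile <- cohorts$stage == adult_idx & cohorts$age >= max_adult_h
      cohorts$n[senile] <- 0
      if (eggs > 0)
        cohorts <- rbind(cohorts,
                         data.frame(stage = 1L, age = 0, n = eggs,
                                    founder = FALSE))
      # transfer/split events
      if (t %in% sched_t) {
        div <- config$schedule$split_divisor[match(t, sched_t)]
        if (div > 1L)
          cohorts$n <- if (det) cohorts$n / div
                       else stats::rbinom(nrow(cohorts), cohorts$n, 1 / div)
      }
      cohorts <- cohorts[cohorts$n > 0, , drop = FALSE]
      if (nrow(cohorts))
        cohorts <- stats::aggregate(n ~ stage + age + founder, cohorts, sum)
    }
    # bookkeeping
    if (nrow(cohorts)) {
      tot <- tapply(cohorts$n, factor(cohorts$stage, levels = seq_len(n_stage)),
                    sum, default = 0)
      hourly[t + 1L, ] <- tot
      founders[t + 1L] <- sum(cohorts$n[cohorts$founder])
    }
    if (t %% 24 == 0) {
      d <- t %/% 24
      alive <- cohorts[cohorts$stage > 1L, , drop = FALSE]  # larvae + adults
      counts$counted_n[counts$day == d] <- sum(alive$n)
      if (nrow(alive)) {
        alive$len <- cohort_length(alive$stage, alive$age)
        alive <- alive[order(-alive$len), , drop = FALSE]
        take <- pmin(alive$n, pmax(0, 20 - c(0, cumsum(alive$n))[-(nrow(alive) + 1L)]))
        take_i <- round(take)
        lens <- rep(alive$len, take_i)
        if (length(lens)) {
          noise <- if (det) 0 else stats::rnorm(length(lens), 0, 0.03)
          len_samples[[d]] <- data.frame(day = d,
                                         length_mm = pmax(0.01, lens + noise))
        }
      }
    }
  }

  fac <- cumulative_dilution_factor(config$schedule, counts$day * 24)
  counts$factor <- fac
  counts$true_n <- counts$counted_n * fac
  mort_t <- seq(0, n_hours, by = 24)
  out <- list(
    config = config,
    hazard_per_h = h0, y24 = y24,
    hourly = data.frame(hour = 0:n_hours, hourly,
                        total = rowSums(hourly[, -1L, drop = FALSE]),
                        total_all = rowSums(hourly),
                        founders_alive = founders),
    counts = counts,
    lengths = do.call(rbind, len_samples),
    mortality = data.frame(time_h = mort_t,
                           n_start = config$n_start_adults,
                           n_alive = founders[mort_t + 1L]))
  class(out) <- "population_sim"
  out
}

#' @export
print.population_sim <- function(x, ...) {
  cat("Simulated C. elegans population well\n")
  cat(sprintf("  exposure: %s\n",
              if (!length(x$config$exposure) || all(x$config$exposure == 0))
                "control"
              else paste(names(x$config$exposure), signif(x$config$exposure, 4),
                         "mg/L", collapse = " + ")))
  cat(sprintf("  combined hazard %.4g /h (24 h-equivalent mortality %.3g%%)\n",
              x$hazard_per_h, x$y24))
  cat(sprintf("  duration %g days; final in-well count %g (reconstructed %g)\n",
              x$config$duration_days,
              x$counts$counted_n[nrow(x$counts)],
              x$counts$true_n[nrow(x$counts)]))
  invisible(x)
}

#' @export
plot.population_sim <- function(x, reconstructed = TRUE, ...) {
  if (reconstructed)
    graphics::plot(x$counts$day, x$counts$true_n + 1, log = "y", type = "b",
                   xlab = "day", ylab = "population size (N + 1)", ...)
  else
    graphics::plot(x$hourly$hour / 24, x$hourly$total, type = "l",
                   xlab = "day", ylab = "in-well count", ...)
  invisible(x)
}
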
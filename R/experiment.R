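#' Dose-response curves for the bundled metals
#'
#' Builds the Zn, Cu and Cd log-logistic curves from an LC table
#' (default: the bundled 24 h adult table): a least-squares fit over all
#' five Zn levels and exact two-point constructions for Cu and Cd.
#'
#' @param table an `lc_table`; default [celegans_lc_table()].
#' @return named list of `"loglogistic"` curves.
#' @export
metal_curves <- function(table = celegans_lc_table()) {
  cps <- unique(table$compound)
  stats::setNames(lapply(cps, curve_from_lc_table, table = table), cps)
}

#' Treatment designs for the simulated experiments
#'
#' `zncd_series_design()` is the short mixture assay: Zn at its LC2, LC5,
#' LC20, LC40 and LC60 levels, alone and combined with the LC20
#' concentration of Cd, plus a Cd-only and a control well; 6 replicates,
#' 48 h, no transfers. `lc_series_design()` is the long population assay:
#' control, the three single metals and the four mixtures at matched LC
#' levels (LC20: 10 days; LC5: 12 days), 3 replicates, split-in-two
#' transfers every 36 h.
#'
#' @param lc_table LC table supplying the exposure levels.
#' @param n_replicates replicates per treatment.
#' @return a data frame of class `"experiment_design"` with one row per
#'   treatment x replicate: `treatment`, `replicate`, `duration_days` and
#'   one concentration column per metal (mg/L); the schedule is attached
#'   as the `"schedule"` attribute (a list keyed by treatment).
#' @export
zncd_series_design <- function(lc_table = celegans_lc_table(),
                               n_replicates = 6) {
  zn_levels <- c(2, 5, 20, 40, 60)
  znc <- lc_table$conc_mg_per_L[lc_table$compound == "Zn"][
    match(zn_levels, lc_table$lc_level[lc_table$compound == "Zn"])]
  cd20 <- lc_table$conc_mg_per_L[lc_table$compound == "Cd" &
                                   lc_table$lc_level == 20]
  rows <- rbind(
    data.frame(treatment = "control", Zn = 0, Cd = 0),
    data.frame(treatment = paste0("Zn_LC", zn_levels), Zn = znc, Cd = 0),
    data.frame(treatment = "Cd_LC20", Zn = 0, Cd = cd20),
    data.frame(treatment = paste0("Zn_LC", zn_levels, "+Cd_LC20"),
               Zn = znc, Cd = cd20))
  des <- merge(rows, data.frame(replicate = seq_len(n_replicates)))
  des$duration_days <- 2
  des <- des[order(match(des$treatment, rows$treatment), des$replicate), ]
  rownames(des) <- NULL
  attr(des, "schedule") <- list()  # no transfers in the 48 h assay
  class(des) <- c("experiment_design", "data.frame")
  des
}

#' @rdname zncd_series_design
#' @param level LC level of the exposures (20 or 5).
#' @export
lc_series_design <- function(lc_table = celegans_lc_table(), level = 20,
                             n_replicates = 3) {
  conc_of <- function(cp) lc_table$conc_mg_per_L[lc_table$compound == cp &
                                                   lc_table$lc_level == level]
  zn <- conc_of("Zn"); cu <- conc_of("Cu"); cd <- conc_of("Cd")
  rows <- data.frame(
    treatment = c("control", "Zn", "Cu", "Cd", "ZnCu", "ZnCd", "CuCd",
                  "ZnCuCd"),
    Zn = c(0, zn, 0, 0, zn, zn, 0, zn),
    Cu = c(0, 0, cu, 0, cu, 0, cu, cu),
    Cd = c(0, 0, 0, cd, 0, cd, cd, cd))
  duration <- if (level <= 5) 12 else 10
  des <- merge(rows, data.frame(replicate = seq_len(n_replicates)))
  des$duration_days <- duration
  des <- des[order(match(des$treatment, rows$treatment), des$replicate), ]
  rownames(des) <- NULL
  sched <- dilution_schedule(seq(36, duration * 24, by = 36), 2)
  attr(des, "schedule") <- stats::setNames(
    rep(list(sched), nrow(rows)), rows$treatment)
  class(des) <- c("experiment_design", "data.frame")
  des
}

#' Generate a full synthetic experiment
#'
#' Runs [simulate_population()] for every treatment x replicate of a
#' design and assembles the four analysis tables: population counts,
#' dilution schedules, body lengths and founder mortality. With `dir`
#' set, the tables are additionally written as CSV files (plus a
#' ground-truth JSON of the per-well hazards and 24 h-equivalent
#' mortalities).
#'
#' @param design an `"experiment_design"` (see [zncd_series_design()]).
#' @param hazard a [hazard_model()] covering the design's metals.
#' @param seed integer seed; per-well seeds are derived from it so a
#'   fixed seed reproduces the experiment byte for byte.
#' @param dir optional output directory for the CSV tables.
#' @param ... further arguments passed to [sim_config()] (e.g.
#'   `n_start_adults`, `fecundity`).
#' @return a list of class `"synthetic_experiment"` with data frames
#'   `counts` (`treatment, replicate, day, counted_n`), `schedule`
#'   (`treatment, time_h, split_divisor`), `lengths`
#'   (`treatment, replicate, day, length_mm`), `mortality`
#'   (`treatment, replicate, time_h, n_start, n_alive`) and a
#'   `ground_truth` data frame of per-treatment hazards.
#' @export
generate_experiment <- function(design, hazard, seed = 1, dir = NULL, ...) {
  stopifnot(inherits(design, "experiment_design"))
  metals <- intersect(c("Zn", "Cu", "Cd"), names(design))
  schedules <- attr(design, "schedule")
  set.seed(seed)
  well_seeds <- sample.int(.Machine$integer.max, nrow(design))
  counts <- list(); lengths <- list(); mortality <- list(); truth <- list()
  for (i in seq_len(nrow(design))) {
    tr <- design$treatment[i]
    expo <- unlist(design[i, metals])
    sched <- schedules[[tr]] %||% dilution_schedule()
    cfg <- sim_config(exposure = expo,
                      hazard = if (any(expo > 0)) hazard else NULL,
                      duration_days = design$duration_days[i],
                      schedule = sched, seed = well_seeds[i], ...)
    sim <- simulate_population(cfg)
    rep_i <- design$replicate[i]
    counts[[i]] <- data.frame(treatment = tr, replicate = rep_i,
                              sim$counts[c("day", "counted_n")])
    if (!is.null(sim$lengths))
      lengths[[i]] <- data.frame(treatment = tr, replicate = rep_i,
                                 sim$lengths)
    mortality[[i]] <- data.frame(treatment = tr, replicate = rep_i,
                                 sim$mortality)
    if (rep_i == 1L)
      truth[[tr]] <- data.frame(treatment = tr, hazard_per_h = sim$hazard_per_h,
                                y24 = sim$y24)
  }
  sched_df <- do.call(rbind, lapply(names(schedules), function(tr) {
    s <- schedules[[tr]]
    if (!length(s$time_h)) return(NULL)
    data.frame(treatment = tr, time_h = s$time_h,
               split_divisor = s$split_divisor)
  }))
  if (is.null(sched_df))
    sched_df <- data.frame(treatment = character(), time_h = numeric(),
                           split_divisor = integer())
  out <- list(counts = do.call(rbind, counts),
              schedule = sched_df,
              lengths = do.call(rbind, lengths),
              mortality = do.call(rbind, mortality),
              ground_truth = do.call(rbind, truth),
              seed = seed)
  rownames(out$ground_truth) <- NULL
  class(out) <- "synthetic_experiment"
  if (!is.null(dir)) write_experiment(out, dir)
  out
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic population-toxicity experiment (seed ", x$seed, ")\n",
      sep = "")
  cat("  ", length(unique(x$counts$treatment)), "treatments x",
      length(unique(x$counts$replicate)), "replicates,",
      max(x$counts$day), "days\n")
  invisible(x)
}

#' Write / read the four experiment tables as CSV
#'
#' @param experiment a `"synthetic_experiment"`.
#' @param dir directory (created if missing).
#' @return `dir`, invisibly (`read_experiment` returns the list of
#'   tables).
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("counts", "schedule", "lengths", "mortality")) {
    df <- experiment[[nm]]
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE, na = "")
  }
  jsonlite::write_json(experiment$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  out <- lapply(c(counts = "counts", schedule = "schedule",
                  lengths = "lengths", mortality = "mortality"),
                function(nm) utils::read.csv(file.path(dir, paste0(nm, ".csv"))))
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) out$ground_truth <- jsonlite::fromJSON(gt)
  out
}

#' Classify every ZnCd mixture of a simulated (or real) mortality table
#'
#' For each Zn level, predicts the mixture effect of Zn + LC20 Cd under
#' CA and IA from the supplied curves and classifies the observed
#' replicate founder mortalities at the requested time point with
#' [classify_interaction()].
#'
#' @param mortality mortality table (`treatment, replicate, time_h,
#'   n_start, n_alive`) using the treatment names of
#'   [zncd_series_design()].
#' @param curves named list with `Zn` and `Cd` curves.
#' @param lc_table LC table supplying the exposure concentrations.
#' @param time_h time point to classify (24 or 48).
#' @param alpha per-test significance level.
#' @return data frame: one row per Zn level with the observed mean
#'   mortality, CA/IA predictions, p-values and the interaction label.
#' @export
classify_zncd_series <- function(mortality, curves,
                                 lc_table = celegans_lc_table(),
                                 time_h = 24, alpha = 0.05) {
  zn_levels <- c(2, 5, 20, 40, 60)
  znc <- lc_table$conc_mg_per_L[lc_table$compound == "Zn"][
    match(zn_levels, lc_table$lc_level[lc_table$compound == "Zn"])]
  cd20 <- lc_table$conc_mg_per_L[lc_table$compound == "Cd" &
                                   lc_table$lc_level == 20]
  out <- lapply(seq_along(zn_levels), function(i) {
    tr <- paste0("Zn_LC", zn_levels[i], "+Cd_LC20")
    rec <- mortality[mortality$treatment == tr & mortality$time_h == time_h, ]
    if (!nrow(rec)) return(NULL)
    obs <- mortality_fraction(rec$n_start, rec$n_alive)
    # predictions for the exposure window actually observed: survival
    # under each single metal over time_h is the 24 h survival to the
    # power time_h/24 (constant hazards)
    scale_y <- function(y) 100 * (1 - (1 - y / 100)^(time_h / 24))
    mix <- mixture(curves[c("Zn", "Cd")], c(znc[i], cd20))
    pred <- list(y_ca = scale_y(predict_ca(mix)),
                 y_ia = scale_y(predict_ia(mix)))
    call <- classify_interaction(obs, pred, alpha)
    data.frame(zn_level = zn_levels[i], time_h = time_h,
               observed_mean = mean(obs),
               y_ca = pred$y_ca, y_ia = pred$y_ia,
               p_vs_ca = call$p_vs_ca, p_vs_ia = call$p_vs_ia,
               label = call$label)
  })
  do.call(rbind, out)
}
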
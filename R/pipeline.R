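#' File-based pipeline stages
#'
#' Thin orchestration over the package's computational functions, reading
#' and writing plain CSV so the stages chain into reproducible runs (each
#' stage's output is a valid input to the next). The same stages back the
#' command-line script shipped in `inst/cli/nematox-cli.R`.
#'
#' * `pipeline_fit`: dose-mortality CSV (`compound, conc_mg_per_L,
#'   n_start, n_dead`) -> fitted LC table CSV at the requested levels.
#' * `pipeline_predict`: LC table CSV + mixture spec CSV (`mixture_id,
#'   compound`, and `conc_mg_per_L` or `lc_level`) -> CA/IA prediction CSV.
#' * `pipeline_classify`: prediction CSV + observed replicate CSV
#'   (`mixture_id, replicate, effect`) -> interaction-call CSV.
#' * `pipeline_endpoints`: counts + schedule CSVs -> endpoint table CSV.
#' * `run_full_experiment`: simulate the ZnCd series, compute endpoints,
#'   predictions and interaction calls, and write a manifest with the
#'   seed and md5 checksums of every output.
#'
#' @param mortality_csv,lc_table_csv,mixture_csv,predictions_csv,observed_csv,counts_csv,schedule_csv input file paths.
#' @param out,out_dir output file path / directory.
#' @param lc_levels LC levels to tabulate in `pipeline_fit`.
#' @param alpha significance level for interaction calls.
#' @param transform endpoint transform (see [auc_population()]).
#' @return each stage returns its output data frame invisibly (and writes
#'   it to `out`).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_fit <- function(mortality_csv, out,
                         lc_levels = c(2, 5, 20, 40, 60)) {
  df <- utils::read.csv(mortality_csv)
  need <- c("compound", "conc_mg_per_L", "n_start", "n_dead")
  if (!all(need %in% names(df)))
    stop("fit input needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rows <- lapply(unique(df$compound), function(cp) {
    d <- df[df$compound == cp, ]
    eff <- pmin(99.9, pmax(0.0, 100 * d$n_dead / d$n_start))
    fit <- fit_loglogistic(d$conc_mg_per_L, eff, weights = d$n_start,
                           compound = cp)
    data.frame(compound = cp, lc_level = lc_levels,
               conc_mg_per_L = lc(fit, lc_levels), conc_spread = NA_real_)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, out, row.names = FALSE, quote = FALSE, na = "")
  invisible(tab)
}

#' @rdname pipeline
#' @export
pipeline_predict <- function(lc_table_csv, mixture_csv, out) {
  tab <- read_lc_table(lc_table_csv)
  spec <- utils::read.csv(mixture_csv)
  if (!all(c("mixture_id", "compound") %in% names(spec)))
    stop("mixture spec needs mixture_id and compound columns", call. = FALSE)
  curves <- metal_curves(tab)
  rows <- lapply(unique(spec$mixture_id), function(id) {
    d <- spec[spec$mixture_id == id, ]
    conc <- vapply(seq_len(nrow(d)), function(j) {
      if ("conc_mg_per_L" %in% names(d) && !is.na(d$conc_mg_per_L[j]))
        d$conc_mg_per_L[j]
      else {
        hit <- tab$conc_mg_per_L[tab$compound == d$compound[j] &
                                   tab$lc_level == d$lc_level[j]]
        if (!length(hit))
          stop("no LC", d$lc_level[j], " entry for ", d$compound[j],
               call. = FALSE)
        hit
      }
    }, numeric(1))
    mix <- mixture(curves[d$compound], conc)
    pred <- predict_mixture(mix)
    data.frame(mixture_id = id, y_ca = pred$y_ca, y_ia = pred$y_ia)
  })
  res <- do.call(rbind, rows)
  utils::write.csv(res, out, row.names = FALSE, quote = FALSE, na = "")
  invisible(res)
}

#' @rdname pipeline
#' @export
pipeline_classify <- function(predictions_csv, observed_csv, out,
                              alpha = 0.05) {
  pred <- utils::read.csv(predictions_csv)
  obs <- utils::read.csv(observed_csv)
  rows <- lapply(unique(pred$mixture_id), function(id) {
    p <- pred[pred$mixture_id == id, ][1, ]
    o <- obs$effect[obs$mixture_id == id]
    if (length(o) < 3L) return(NULL)
    call <- classify_interaction(o, list(y_ca = p$y_ca, y_ia = p$y_ia), alpha)
    data.frame(mixture_id = id, y_ca = p$y_ca, y_ia = p$y_ia,
               observed_mean = mean(o), label = call$label,
               p_vs_ca = call$p_vs_ca, p_vs_ia = call$p_vs_ia)
  })
  res <- do.call(rbind, rows)
  utils::write.csv(res, out, row.names = FALSE, quote = FALSE, na = "")
  invisible(res)
}

#' @rdname pipeline
#' @export
pipeline_endpoints <- function(counts_csv, schedule_csv, out,
                               transform = "log_pseudocount") {
  counts <- utils::read.csv(counts_csv)
  sched <- utils::read.csv(schedule_csv)
  schedules <- if (nrow(sched))
    lapply(split(sched, sched$treatment),
           function(s) dilution_schedule(s$time_h, s$split_divisor))
  else dilution_schedule()
  tab <- endpoint_table(counts, schedules, transform = transform)
  utils::write.csv(tab, out, row.names = FALSE, quote = FALSE, na = "")
  invisible(tab)
}

#' @rdname pipeline
#' @param seed integer seed for the simulated experiment.
#' @param protection parameters for [zn_protection_factor()].
#' @export
run_full_experiment <- function(out_dir, seed = 1, alpha = 0.05,
                                protection = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  curves <- metal_curves()
  hm <- hazard_model(curves[c("Zn", "Cd")], rule = "protective_zn_cd",
                     protection = protection)
  exp <- generate_experiment(zncd_series_design(), hm, seed = seed,
                             dir = out_dir)
  ep <- endpoint_table(exp$counts, dilution_schedule())
  utils::write.csv(ep, file.path(out_dir, "endpoints.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  calls <- rbind(classify_zncd_series(exp$mortality, curves, time_h = 24,
                                      alpha = alpha),
                 classify_zncd_series(exp$mortality, curves, time_h = 48,
                                      alpha = alpha))
  utils::write.csv(calls, file.path(out_dir, "interaction_calls.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  files <- list.files(out_dir, pattern = "\\.csv$|\\.json$",
                      full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(seed = seed, alpha = alpha,
                   package_version = as.character(utils::packageVersion("nematox")),
                   files = data.frame(file = basename(files),
                                      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(list(experiment = exp, endpoints = ep, calls = calls,
                 manifest = manifest))
}

#' Command-line dispatcher
#'
#' Backs the `inst/cli/nematox-cli.R` script. Subcommands: `fit`,
#' `predict`, `classify`, `endpoints`, `simulate`, `full-experiment`.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first, then `key=value` pairs).
#' @return exit status (0 on success), invisibly.
#' @export
nematox_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: nematox-cli.R <fit|predict|classify|endpoints|simulate|full-experiment> key=value ...\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  kv <- strsplit(args[-1], "=", fixed = TRUE)
  opts <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                          vapply(kv, `[[`, "", 1))
  num <- function(x, default) if (is.null(opts[[x]])) default
                              else as.numeric(opts[[x]])
  chr <- function(x, default = NULL) opts[[x]] %||% default
  switch(cmd,
    "fit" = pipeline_fit(chr("mortality"), chr("out")),
    "predict" = pipeline_predict(chr("lc_table"), chr("mixtures"),
                                 chr("out")),
    "classify" = pipeline_classify(chr("predictions"), chr("observed"),
                                   chr("out"), alpha = num("alpha", 0.05)),
    "endpoints" = pipeline_endpoints(chr("counts"), chr("schedule"),
                                     chr("out")),
    "simulate" = {
      curves <- metal_curves()
      hm <- hazard_model(curves[c("Zn", "Cd")], rule = "protective_zn_cd")
      generate_experiment(zncd_series_design(), hm,
                          seed = num("seed", 1), dir = chr("out_dir", "."))
    },
    "full-experiment" = run_full_experiment(chr("out_dir", "."),
                                            seed = num("seed", 1),
                                            alpha = num("alpha", 0.05)),
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
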
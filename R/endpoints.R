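#' Area under the population-size vs. time curve
#'
#' Trapezoid-rule integral of (optionally transformed) abundance over
#' days, via [pracma::trapz()]. The default transform is
#' `log10(n + 1)`: the pseudo-count keeps extinct populations (n = 0)
#' finite, and the log scale reflects the multiplicative growth of
#' multi-generation cultures. Units are log10-individuals x days
#' (individual-days with `transform = "none"`).
#'
#' @param day observation days, strictly increasing, length >= 2.
#' @param n non-negative abundances (typically dilution-corrected; see
#'   [reconstruct_population()]).
#' @param transform `"log_pseudocount"` (default) or `"none"`.
#' @return the area (scalar).
#' @examples
#' auc_population(c(0, 1), c(9, 999))          # (1 + 3)/2 = 2
#' auc_population(0:3, c(10, 50, 80, 20), transform = "none")
#' @export
auc_population <- function(day, n, transform = c("log_pseudocount", "none")) {
  transform <- match.arg(transform)
  if (length(day) < 2L)
    stop("need at least two time points for an area", call. = FALSE)
  if (length(day) != length(n)) stop("day and n lengths differ", call. = FALSE)
  if (any(!is.finite(day)) || any(!is.finite(n)) || any(n < 0))
    stop("inputs must be finite and n non-negative", call. = FALSE)
  if (any(diff(day) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  v <- if (transform == "log_pseudocount") log10(n + 1) else n
  pracma::trapz(day, v)
}

#' Population endpoint triple: area, maximum, end size
#'
#' Summarises a population time series by the three endpoints used to
#' compare treatments: (i) the trapezoid-rule area under the (log)
#' population vs. time curve, (ii) the maximum population attained and the
#' day it is first attained, (iii) the population at the end of the
#' experiment.
#'
#' @inheritParams auc_population
#' @return a list of class `"endpoint_summary"` with `auc`, `max_n`,
#'   `max_day`, `end_n`, `end_day` and the transform used.
#' @export
endpoint_summary <- function(day, n, transform = c("log_pseudocount", "none")) {
  transform <- match.arg(transform)
  auc <- auc_population(day, n, transform)
  imax <- which.max(n)  # first occurrence on ties
  structure(list(auc = auc, max_n = n[imax], max_day = day[imax],
                 end_n = n[length(n)], end_day = day[length(day)],
                 transform = transform),
            class = "endpoint_summary")
}

#' @export
print.endpoint_summary <- function(x, digits = 4, ...) {
  cat("Population endpoints (transform: ", x$transform, ")\n", sep = "")
  cat("  AUC:  ", format(x$auc, digits = digits), "\n")
  cat("  max N:", format(x$max_n, digits = digits),
      " at day", x$max_day, "\n")
  cat("  end N:", format(x$end_n, digits = digits),
      " at day", x$end_day, "\n")
  invisible(x)
}

#' Signed percent difference relative to a reference
#'
#' `percent_vs_control(t, c)` returns `100 (c - t) / c`, the percentage by
#' which a treatment is *smaller* than the control (positive when the
#' treatment is reduced). For "larger than" comparisons between two
#' treatments use `direction = "larger"`, giving `100 (t - c) / c`.
#'
#' @param treatment_value,control_value numeric; `control_value` must be
#'   nonzero (positive in practice).
#' @param direction `"smaller"` (default) or `"larger"`.
#' @return signed percent difference.
#' @examples
#' percent_vs_control(0.5, 1)              # 50% smaller
#' percent_vs_control(2, 1, "larger")      # 100% larger
#' @export
percent_vs_control <- function(treatment_value, control_value,
                               direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  if (any(control_value == 0))
    stop("control value of zero: percent difference undefined", call. = FALSE)
  if (direction == "smaller")
    100 * (control_value - treatment_value) / control_value
  else
    100 * (treatment_value - control_value) / control_value
}

#' Mortality fraction of a founder cohort
#'
#' @param n_start number of animals at the start (> 0).
#' @param n_alive number still alive, `0 <= n_alive <= n_start`.
#' @return percent mortality, `100 (n_start - n_alive) / n_start`.
#' @examples
#' mortality_fraction(10, 8)  # 20
#' @export
mortality_fraction <- function(n_start, n_alive) {
  if (any(n_start <= 0)) stop("n_start must be positive", call. = FALSE)
  if (any(n_alive < 0 | n_alive > n_start))
    stop("n_alive must lie in [0, n_start]", call. = FALSE)
  100 * (n_start - n_alive) / n_start
}

#' Endpoint table for a counted experiment
#'
#' Applies dilution correction and [endpoint_summary()] to every
#' treatment x replicate series of a counts table.
#'
#' @param counts data frame with columns `treatment`, `replicate`, `day`,
#'   `counted_n`.
#' @param schedules either a single [dilution_schedule()] applied to all
#'   series, or a named list of schedules keyed by treatment.
#' @param transform passed to [endpoint_summary()].
#' @param reconstruct if `FALSE`, endpoints are computed on raw counts.
#' @return data frame, one row per treatment x replicate, with columns
#'   `treatment`, `replicate`, `auc`, `max_n`, `max_day`, `end_n`.
#' @export
endpoint_table <- function(counts, schedules = dilution_schedule(),
                           transform = "log_pseudocount", reconstruct = TRUE) {
  need <- c("treatment", "replicate", "day", "counted_n")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  pick_sched <- function(tr) {
    if (inherits(schedules, "dilution_schedule")) return(schedules)
    schedules[[tr]] %||% dilution_schedule()
  }
  keys <- unique(counts[c("treatment", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- counts$treatment == keys$treatment[i] &
      counts$replicate == keys$replicate[i]
    ser <- counts[sel, , drop = FALSE]
    ser <- ser[order(ser$day), , drop = FALSE]
    n <- if (reconstruct)
      reconstruct_population(ser$day, ser$counted_n,
                             pick_sched(as.character(keys$treatment[i])))$true_n
    else ser$counted_n
    ep <- endpoint_summary(ser$day, n, transform)
    data.frame(treatment = keys$treatment[i], replicate = keys$replicate[i],
               auc = ep$auc, max_n = ep$max_n, max_day = ep$max_day,
               end_n = ep$end_n)
  })
  do.call(rbind, out)
}
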
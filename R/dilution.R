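#' Serial-dilution (transfer) schedules
#'
#' During long population assays, wells are periodically transferred to
#' fresh medium and split so that counts stay tractable; a schedule records
#' each split event as a time (hours since the start of exposure) and an
#' integer divisor (2 for a split in two). The cumulative product of the
#' divisors of all events up to a time point relates a counted well to the
#' whole population it represents.
#'
#' @param time_h event times in hours, strictly increasing, >= 0.
#' @param split_divisor integer divisors >= 1, one per event.
#' @return an object of class `"dilution_schedule"`.
#' @examples
#' # split in two every 36 h: a factor 64 by day 10
#' sched <- dilution_schedule(seq(36, 240, by = 36), 2)
#' cumulative_dilution_factor(sched, 240)
#' @export
dilution_schedule <- function(time_h = numeric(), split_divisor = integer()) {
  if (length(split_divisor) == 1L && length(time_h) > 1L)
    split_divisor <- rep(split_divisor, length(time_h))
  if (length(time_h) != length(split_divisor))
    stop("one divisor per event time required", call. = FALSE)
  if (length(time_h)) {
    if (any(!is.finite(time_h)) || any(time_h < 0))
      stop("event times must be finite and non-negative", call. = FALSE)
    if (any(diff(time_h) <= 0))
      stop("event times must be strictly increasing", call. = FALSE)
    if (any(split_divisor < 1) || any(split_divisor != round(split_divisor)))
      stop("split divisors must be integers >= 1", call. = FALSE)
  }
  structure(list(time_h = as.numeric(time_h),
                 split_divisor = as.integer(split_divisor)),
            class = "dilution_schedule")
}

#' @export
print.dilution_schedule <- function(x, ...) {
  n <- length(x$time_h)
  cat("Dilution schedule with", n, "event(s)\n")
  if (n) {
    df <- data.frame(time_h = x$time_h, day = x$time_h / 24,
                     split_divisor = x$split_divisor,
                     cumulative = cumprod(x$split_divisor))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Transfer schedule of the heavily diluted control wells
#'
#' In fast-growing control wells of the 10-day assay the standard
#' split-in-two every 36 h is not enough to keep counts tractable; from
#' day 6 the cumulative reduction is stepped up to 64x at day 6, 128x at
#' day 8, 512x at day 9 and 2048x at day 10. This helper encodes that
#' protocol as per-event divisors (36 h cadence with divisors 2, 2, 2, 8,
#' 2, 4 and a final 4x split at day 10).
#'
#' @return a [dilution_schedule()] whose cumulative factor is 8 before
#'   day 6, 64 at day 6, 128 at day 8, 512 at day 9 and 2048 at day 10.
#' @examples
#' cumulative_dilution_factor(lc20_control_schedule(), c(144, 192, 216, 240))
#' @export
lc20_control_schedule <- function() {
  dilution_schedule(time_h = c(36, 72, 108, 144, 180, 216, 240),
                    split_divisor = c(2, 2, 2, 8, 2, 4, 4))
}

#' Cumulative dilution factor at a time point
#'
#' Product of the split divisors of all events at or before `t_h`; 1 when
#' no event has happened yet.
#'
#' @param schedule a [dilution_schedule()].
#' @param t_h time(s) in hours.
#' @return numeric vector of cumulative factors.
#' @export
cumulative_dilution_factor <- function(schedule, t_h) {
  stopifnot(inherits(schedule, "dilution_schedule"))
  if (any(!is.finite(t_h)) || any(t_h < 0))
    stop("time must be finite and non-negative", call. = FALSE)
  if (!length(schedule$time_h)) return(rep(1, length(t_h)))
  cum <- cumprod(schedule$split_divisor)
  idx <- findInterval(t_h, schedule$time_h)
  ifelse(idx == 0, 1, cum[pmax(idx, 1)])
}

#' Reconstruct whole-population sizes from counted wells
#'
#' Multiplies each counted abundance by the cumulative dilution factor in
#' force at its observation time, recovering the population size the well
#' represents. With an empty schedule the counts are returned unchanged.
#'
#' @param day observation days (counts are assumed taken at `day * 24` h).
#' @param counted_n non-negative counted abundances.
#' @param schedule a [dilution_schedule()].
#' @return data frame with columns `day`, `counted_n`, `factor`, `true_n`.
#' @examples
#' sched <- dilution_schedule(seq(36, 240, by = 36), 2)
#' reconstruct_population(c(1, 5, 10), c(10, 40, 7), sched)
#' @export
reconstruct_population <- function(day, counted_n, schedule = dilution_schedule()) {
  if (length(day) != length(counted_n))
    stop("day and counted_n lengths differ", call. = FALSE)
  if (any(counted_n < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(diff(day) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  f <- cumulative_dilution_factor(schedule, day * 24)
  data.frame(day = day, counted_n = counted_n, factor = f,
             true_n = counted_n * f)
}
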
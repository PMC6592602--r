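#' Two-parameter log-logistic dose-response curves
#'
#' The package models graded mortality as the two-parameter log-logistic
#' \deqn{y(c) = 100 \frac{(c/EC_{50})^\beta}{1 + (c/EC_{50})^\beta}}
#' with effects expressed as percentages in \[0, 100): `ec50` is the
#' concentration producing a 50% effect and `beta` the (dimensionless)
#' slope on log-concentration scale. Concentrations are carried internally
#' in mg/L on a metal-ion basis; convert at the boundary with
#' [convert_concentration()].
#'
#' @param ec50 positive EC50 in mg/L.
#' @param beta positive slope.
#' @param compound optional compound label (e.g. `"Zn"`).
#' @return an object of class `"loglogistic"`.
#' @seealso [fit_loglogistic()], [fit_two_point()], [lc()]
#' @examples
#' cv <- loglogistic_curve(51.68, 0.819, "Zn")
#' predict(cv, conc = 51.68)  # 50
#' lc(cv, 20)
#' @export
loglogistic_curve <- function(ec50, beta, compound = NULL) {
  stopifnot(length(ec50) == 1L, length(beta) == 1L)
  if (!is.finite(ec50) || ec50 <= 0) stop("ec50 must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(
    list(coefficients = c(ec50 = as.numeric(ec50), beta = as.numeric(beta)),
         compound = compound, unit = "mg/L",
         data = NULL, residuals = NULL, rss = NULL, fitted.values = NULL),
    class = "loglogistic")
}

#' Construct the curve passing exactly through two dose-effect points
#'
#' A two-parameter curve is exactly identified by two distinct points; the
#' slope follows in closed form from the log-odds of the two effects,
#' \deqn{\beta = \frac{\log[(y_2/(100-y_2)) / (y_1/(100-y_1))]}{\log(c_2/c_1)},}
#' and the EC50 from either point. Useful when only two LC levels are
#' reported for a compound (here, LC5 and LC20 for Cu and Cd).
#'
#' @param conc1,conc2 distinct positive concentrations (mg/L).
#' @param effect1,effect2 distinct effects in percent, each in (0, 100).
#' @inheritParams loglogistic_curve
#' @return a `"loglogistic"` object passing through both points exactly.
#' @examples
#' fit_two_point(1, 20, 4, 80)           # ec50 = 2, beta = 2
#' fit_two_point(0.474, 5, 7.110, 20, "Cd")
#' @export
fit_two_point <- function(conc1, effect1, conc2, effect2, compound = NULL) {
  check_effect_open(c(effect1, effect2))
  if (any(c(conc1, conc2) <= 0) || !all(is.finite(c(conc1, conc2))))
    stop("concentrations must be positive and finite", call. = FALSE)
  if (conc1 == conc2) stop("degenerate fit: equal concentrations", call. = FALSE)
  if (effect1 == effect2) stop("degenerate fit: equal effects", call. = FALSE)
  lodds <- function(y) log(y / (100 - y))
  beta <- (lodds(effect2) - lodds(effect1)) / (log(conc2) - log(conc1))
  if (!is.finite(beta) || beta <= 0)
    stop("two-point fit gave a non-positive slope; effects must increase with concentration",
         call. = FALSE)
  ec50 <- conc1 / (effect1 / (100 - effect1))^(1 / beta)
  loglogistic_curve(ec50, beta, compound)
}

#' Fit a log-logistic curve to dose-effect points by least squares
#'
#' Minimises the sum of squared deviations between observed effects
#' (percent) and the curve, over `(log10 ec50, log10 beta)` so both
#' parameters stay positive without constrained optimisation. The search
#' starts from the exact two-point construction through the most extreme
#' doses (with a small multistart around it). With exactly two points the
#' result coincides with [fit_two_point()].
#'
#' @param conc positive concentrations, mg/L.
#' @param effect observed effects in percent; interior points (0, 100) are
#'   required for the two-point start, observed values may touch 0 or 100.
#' @param weights optional non-negative case weights.
#' @inheritParams loglogistic_curve
#' @return a `"loglogistic"` object with `data`, `fitted.values`,
#'   `residuals` and `rss` filled in.
#' @examples
#' cv <- loglogistic_curve(10, 1.5)
#' doses <- c(1, 3, 10, 30, 100)
#' fit <- fit_loglogistic(doses, predict(cv, doses))
#' coef(fit)  # recovers (10, 1.5)
#' @export
fit_loglogistic <- function(conc, effect, weights = NULL, compound = NULL) {
  if (length(conc) != length(effect))
    stop("conc and effect lengths differ", call. = FALSE)
  if (length(conc) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(conc)) || any(!is.finite(effect)))
    stop("non-finite inputs", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (any(effect < 0 | effect >= 100))
    stop("effects must lie in [0, 100)", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(conc))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)

  obj <- function(par) {
    ec50 <- 10^par[1]; beta <- 10^par[2]
    r <- conc / ec50
    yhat <- 100 * r^beta / (1 + r^beta)
    sum(weights * (effect - yhat)^2)
  }
  # start from the two-point fit through the extreme doses, clamped interior
  o <- order(conc)
  y1 <- min(max(effect[o[1]], 0.5), 99.5)
  y2 <- min(max(effect[o[length(o)]], 0.5), 99.5)
  start <- tryCatch({
    tp <- fit_two_point(conc[o[1]], y1, conc[o[length(o)]], y2)
    log10(coef(tp))
  }, error = function(e) c(log10(stats::median(conc)), 0))
  starts <- rbind(start,
                  start + c(0.5, 0.25), start - c(0.5, 0.25),
                  c(log10(stats::median(conc)), 0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ec50 <- 10^best$par[1]; beta <- 10^best$par[2]
  out <- loglogistic_curve(ec50, beta, compound)
  out$data <- data.frame(conc = conc, effect = effect, weight = weights)
  out$fitted.values <- predict(out, conc)
  out$residuals <- effect - out$fitted.values
  out$rss <- best$value
  out$convergence <- best$convergence
  out
}

check_effect_open <- function(y) {
  if (any(!is.finite(y)) || any(y <= 0 | y >= 100))
    stop("effects must lie strictly inside (0, 100) percent", call. = FALSE)
  invisible(y)
}

#' Predicted effect of a concentration
#'
#' @param object a `"loglogistic"` curve.
#' @param conc non-negative concentrations.
#' @param unit unit of `conc`; converted to the curve's internal mg/L
#'   scale (metal-ion basis) before evaluation.
#' @param compound compound name or molar mass for unit conversion;
#'   defaults to the curve's own compound label.
#' @param ... unused.
#' @return effects in percent, each in \[0, 100).
#' @export
predict.loglogistic <- function(object, conc = NULL, unit = "mg/L",
                                compound = object$compound, ...) {
  if (is.null(conc)) {
    if (is.null(object$data)) stop("no stored data; supply conc", call. = FALSE)
    conc <- object$data$conc
    unit <- "mg/L"
  }
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  conc <- convert_concentration(conc, unit, "mg/L", compound)
  cf <- object$coefficients
  r <- (conc / cf[["ec50"]])^cf[["beta"]]
  unname(100 * r / (1 + r))
}

#' Effect of a dose on a log-logistic curve
#'
#' Convenience wrapper around [predict.loglogistic()].
#' @inheritParams predict.loglogistic
#' @param curve a `"loglogistic"` curve.
#' @return effect percent in \[0, 100).
#' @export
effect_at <- function(curve, conc, unit = "mg/L", compound = curve$compound) {
  stopifnot(inherits(curve, "loglogistic"))
  predict(curve, conc, unit = unit, compound = compound)
}

#' Lethal/effective concentration at a given effect level
#'
#' Inverts the curve in closed form,
#' \eqn{c = EC_{50} (x/(100-x))^{1/\beta}}.
#'
#' @param curve a `"loglogistic"` curve.
#' @param level effect level(s) in percent, strictly inside (0, 100).
#' @param unit unit of the returned concentration.
#' @return concentrations in `unit` (default mg/L).
#' @examples
#' lc(loglogistic_curve(2, 2), c(20, 50, 80))
#' @export
lc <- function(curve, level, unit = "mg/L") {
  stopifnot(inherits(curve, "loglogistic"))
  check_effect_open(level)
  cf <- curve$coefficients
  out <- cf[["ec50"]] * (level / (100 - level))^(1 / cf[["beta"]])
  convert_concentration(unname(out), "mg/L", unit, curve$compound)
}

#' @export
coef.loglogistic <- function(object, ...) object$coefficients

#' @export
residuals.loglogistic <- function(object, ...) {
  if (is.null(object$residuals))
    stop("curve was not fitted to data; no residuals", call. = FALSE)
  object$residuals
}

#' @export
print.loglogistic <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  lbl <- if (!is.null(x$compound)) paste0(" [", x$compound, "]") else ""
  cat("Log-logistic dose-response curve", lbl, "\n", sep = "")
  cat("  EC50: ", format(cf[["ec50"]], digits = digits), " mg/L   beta: ",
      format(cf[["beta"]], digits = digits), "\n", sep = "")
  if (!is.null(x$rss))
    cat("  fitted to ", nrow(x$data), " points, residual SS = ",
        format(x$rss, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
summary.loglogistic <- function(object, ...) {
  out <- list(coefficients = object$coefficients, compound = object$compound,
              rss = object$rss, n = if (!is.null(object$data)) nrow(object$data) else 0L,
              lc = lc(object, c(5, 10, 20, 50)))
  class(out) <- "summary.loglogistic"
  out
}

#' @export
print.summary.loglogistic <- function(x, digits = 4, ...) {
  cat("Log-logistic curve",
      if (!is.null(x$compound)) paste0(" [", x$compound, "]"), "\n", sep = "")
  print(round(x$coefficients, digits))
  cat("LC estimates (mg/L):\n")
  print(round(stats::setNames(x$lc, paste0("LC", c(5, 10, 20, 50))), digits))
  if (x$n > 0)
    cat("n = ", x$n, ", residual SS = ", format(x$rss, digits = digits),
        "\n", sep = "")
  invisible(x)
}

#' @export
plot.loglogistic <- function(x, from = NULL, to = NULL, n = 200, ...) {
  cf <- x$coefficients
  if (is.null(from)) from <- cf[["ec50"]] / 100
  if (is.null(to)) to <- cf[["ec50"]] * 100
  cc <- exp(seq(log(from), log(to), length.out = n))
  graphics::plot(cc, predict(x, cc), type = "l", log = "x",
                 xlab = "concentration (mg/L)", ylab = "effect (%)", ...)
  if (!is.null(x$data))
    graphics::points(x$data$conc, x$data$effect, pch = 19)
  invisible(x)
}

#' Simulate binomial mortality data from a curve
#'
#' Draws `nsim` replicate mortality tables: at each dose, the number of
#' deaths among `n_per_dose` organisms is binomial with probability given
#' by the curve, and the observed effect is the dead fraction in percent.
#'
#' @param object a `"loglogistic"` curve.
#' @param nsim number of replicate tables.
#' @param seed optional seed.
#' @param conc doses (mg/L); default the stored data's doses.
#' @param n_per_dose organisms per dose.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `conc`, `n`, `dead`,
#'   `effect`.
#' @export
simulate.loglogistic <- function(object, nsim = 1, seed = NULL,
                                 conc = NULL, n_per_dose = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conc)) {
    if (is.null(object$data)) stop("no stored doses; supply conc", call. = FALSE)
    conc <- object$data$conc
  }
  p <- predict(object, conc) / 100
  lapply(seq_len(nsim), function(i) {
    dead <- stats::rbinom(length(conc), n_per_dose, p)
    data.frame(conc = conc, n = n_per_dose, dead = dead,
               effect = 100 * dead / n_per_dose)
  })
}
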
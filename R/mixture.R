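#' Define a metal mixture exposure
#'
#' A mixture is an ordered set of components, each a log-logistic curve
#' paired with an exposure concentration (mg/L, metal-ion basis).
#'
#' @param curves a list of `"loglogistic"` curves (a single curve is
#'   promoted to a one-component mixture).
#' @param conc numeric vector of concentrations, one per curve, all >= 0.
#' @return an object of class `"mixture"`.
#' @examples
#' tab <- celegans_lc_table()
#' zn <- curve_from_lc_table(tab, "Zn")
#' cd <- curve_from_lc_table(tab, "Cd")
#' mix <- mixture(list(zn, cd), c(lc(zn, 20), lc(cd, 20)))
#' predict_ia(mix)
#' predict_ca(mix)
#' @export
mixture <- function(curves, conc) {
  if (inherits(curves, "loglogistic")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, TRUE, "loglogistic")))
    stop("curves must be loglogistic objects", call. = FALSE)
  if (length(conc) != length(curves))
    stop("one concentration per component required", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(list(curves = curves, conc = as.numeric(conc)), class = "mixture")
}

#' @export
print.mixture <- function(x, ...) {
  cat("Metal mixture with", length(x$conc), "component(s):\n")
  for (i in seq_along(x$conc)) {
    cf <- coef(x$curves[[i]])
    cat(sprintf("  %-4s %8.4g mg/L  (EC50 %.4g, beta %.3g)\n",
                x$curves[[i]]$compound %||% paste0("#", i),
                x$conc[i], cf[["ec50"]], cf[["beta"]]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Independent Action prediction
#'
#' Under Independent Action the components act through unrelated modes of
#' action and survival probabilities multiply:
#' \deqn{y = 100\left[1 - \prod_i \frac{1}{1 + (c_i/EC_{50,i})^{\beta_i}}\right].}
#'
#' @param mix a [mixture()].
#' @return predicted effect in percent, in \[0, 100).
#' @export
predict_ia <- function(mix) {
  stopifnot(inherits(mix, "mixture"))
  surv <- vapply(seq_along(mix$conc), function(i)
    1 - predict(mix$curves[[i]], mix$conc[i]) / 100, numeric(1))
  100 * (1 - prod(surv))
}

#' Concentration Addition prediction
#'
#' Under Concentration Addition the components share a mode of action and
#' behave as dilutions of one another; the mixture effect `y` solves
#' \deqn{\sum_i \frac{c_i}{EC_{50,i}\,(y/(100-y))^{1/\beta_i}} = 1.}
#' The left side decreases strictly in `y`, so the root is unique and is
#' found by bracketed bisection on (0, 100). With a single component the
#' solution is the component's own dose-response effect.
#'
#' By default each component uses its own slope (the exponent is
#' `1/beta_i`); `shared_beta` forces one common slope on all components,
#' the strict reading of a model written with a single slope symbol.
#'
#' @param mix a [mixture()].
#' @param tol absolute tolerance on the effect (percent).
#' @param shared_beta optional single slope overriding every component's.
#' @param details if `TRUE` return a list with solver diagnostics.
#' @return predicted effect in percent (or a list when `details = TRUE`
#'   with `y`, `iterations`, `residual`).
#' @export
predict_ca <- function(mix, tol = 1e-10, shared_beta = NULL, details = FALSE) {
  stopifnot(inherits(mix, "mixture"))
  active <- mix$conc > 0
  if (!any(active)) {
    if (details) return(list(y = 0, iterations = 0L, residual = 0))
    return(0)
  }
  cs <- mix$conc[active]
  ec50 <- vapply(mix$curves[active], function(k) coef(k)[["ec50"]], numeric(1))
  beta <- vapply(mix$curves[active], function(k) coef(k)[["beta"]], numeric(1))
  if (!is.null(shared_beta)) {
    stopifnot(is.finite(shared_beta), shared_beta > 0)
    beta[] <- shared_beta
  }
  # sum of toxic units minus one; strictly decreasing in y
  f <- function(y) sum(cs / (ec50 * (y / (100 - y))^(1 / beta))) - 1
  lo <- 1e-9; hi <- 100 - 1e-9
  if (f(hi) > 0)
    stop("CA solver failed to bracket: effect at upper bound still below the toxic-unit balance",
         call. = FALSE)
  it <- 0L
  while (hi - lo > tol && it < 200L) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    it <- it + 1L
  }
  y <- (lo + hi) / 2
  if (details) list(y = y, iterations = it, residual = f(y)) else y
}

#' Joint CA/IA prediction for a mixture
#'
#' @inheritParams predict_ca
#' @return a list of class `"mixture_prediction"` with elements `y_ca`,
#'   `y_ia` and solver diagnostics.
#' @export
predict_mixture <- function(mix, tol = 1e-10, shared_beta = NULL) {
  ca <- predict_ca(mix, tol = tol, shared_beta = shared_beta, details = TRUE)
  structure(list(y_ca = ca$y, y_ia = predict_ia(mix),
                 iterations = ca$iterations, residual = ca$residual),
            class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, digits = 4, ...) {
  cat("Predicted mixture effect (%):\n")
  cat("  Concentration Addition:", format(x$y_ca, digits = digits), "\n")
  cat("  Independent Action:    ", format(x$y_ia, digits = digits), "\n")
  invisible(x)
}

#' Classify an observed mixture effect against CA and IA predictions
#'
#' Replicate-level observed effects are compared with each model's
#' predicted constant by the one-sample Wilcoxon signed-rank test.
#' Exact differences of zero are discarded (classic zero handling); the
#' exact null distribution is used whenever the remaining absolute
#' differences are untied, otherwise the usual normal approximation.
#' Direction is established by two one-sided tests at level `alpha` each:
#' the call is `"synergistic"` when the observed effects are significantly
#' above both predictions, `"antagonistic"` when significantly below both,
#' and `"additive"` otherwise (including discordant directions).
#'
#' @param observed numeric vector (>= 3) of replicate effects in percent.
#' @param prediction a `"mixture_prediction"` (or list with `y_ca`, `y_ia`).
#' @param alpha significance level for each one-sided test.
#' @return a list of class `"interaction_call"`: `label`, one-sided
#'   p-values `p_vs_ca`/`p_vs_ia` (in the direction of the observed median
#'   deviation), `direction_vs_ca`/`direction_vs_ia` (-1, 0, 1) and `alpha`.
#' @examples
#' pred <- list(y_ca = 30, y_ia = 36)
#' classify_interaction(c(12, 15, 9, 18, 14, 11), pred)
#' @export
classify_interaction <- function(observed, prediction, alpha = 0.05) {
  if (length(observed) < 3L)
    stop("need at least 3 replicate observations", call. = FALSE)
  if (any(!is.finite(observed)) || any(observed < 0 | observed > 100))
    stop("observed effects must lie in [0, 100]", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  one <- function(mu) {
    d <- observed - mu
    d <- d[d != 0]
    if (!length(d))
      return(list(p_less = 1, p_greater = 1, direction = 0))
    test <- function(alt) {
      exact <- !any(duplicated(abs(d)))
      suppressWarnings(stats::wilcox.test(d, mu = 0, alternative = alt,
                                          exact = exact)$p.value)
    }
    list(p_less = test("less"), p_greater = test("greater"),
         direction = sign(stats::median(d)))
  }
  ca <- one(prediction$y_ca)
  ia <- one(prediction$y_ia)
  syn <- ca$p_greater < alpha && ia$p_greater < alpha
  ant <- ca$p_less < alpha && ia$p_less < alpha
  label <- if (syn) "synergistic" else if (ant) "antagonistic" else "additive"
  pick <- function(z) if (z$direction >= 0) z$p_greater else z$p_less
  structure(list(label = label,
                 p_vs_ca = pick(ca), p_vs_ia = pick(ia),
                 direction_vs_ca = ca$direction, direction_vs_ia = ia$direction,
                 alpha = alpha, n = length(observed),
                 y_ca = prediction$y_ca, y_ia = prediction$y_ia,
                 observed_mean = mean(observed)),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, digits = 4, ...) {
  cat("Mixture interaction call:", toupper(x$label), "\n")
  cat(sprintf("  observed mean %.4g%% (n = %d) vs CA %.4g%% / IA %.4g%%\n",
              x$observed_mean, x$n, x$y_ca, x$y_ia))
  cat(sprintf("  one-sided p vs CA = %.4g, vs IA = %.4g (alpha = %g each)\n",
              x$p_vs_ca, x$p_vs_ia, x$alpha))
  invisible(x)
}

#' Mixture-to-reference ratio profile
#'
#' Element-wise ratio of an outcome in mixtures (e.g. ZnCd mortality at a
#' series of Zn levels) to the outcome in the matching reference exposure
#' (e.g. Cd alone). For mortality a ratio above 1 means greater toxicity
#' in the mixture; for population size a ratio below 1 does.
#'
#' @param mixture_values numeric outcomes per level (optionally named).
#' @param reference_value positive scalar reference outcome, or a vector
#'   matching `mixture_values`.
#' @return numeric vector of ratios, named like `mixture_values`.
#' @export
ratio_profile <- function(mixture_values, reference_value) {
  if (any(!is.finite(reference_value)) || any(reference_value <= 0))
    stop("reference outcome must be positive (ratio undefined otherwise)",
         call. = FALSE)
  if (length(reference_value) != 1L &&
      length(reference_value) != length(mixture_values))
    stop("reference must be scalar or match mixture_values in length",
         call. = FALSE)
  mixture_values / reference_value
}
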
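#' Constant hazard rate reproducing a dose-response mortality window
#'
#' Converts the expected mortality `y(c)` of a curve over an exposure
#' window (24 h by default, matching LC tables determined at 24 h) into
#' the constant per-hour hazard `h = -log(1 - y/100) / window`, so that a
#' cohort held at `c` for the window dies with probability `y(c)/100`.
#'
#' @param curve a [loglogistic_curve()].
#' @param conc concentration in mg/L, >= 0.
#' @param window exposure window in hours over which the curve's
#'   mortality applies.
#' @return per-hour hazard rate (>= 0).
#' @examples
#' zn <- curve_from_lc_table(celegans_lc_table(), "Zn")
#' hazard_from_lc(zn, lc(zn, 20))   # -log(0.8)/24
#' @export
hazard_from_lc <- function(curve, conc, window = 24) {
  stopifnot(inherits(curve, "loglogistic"), window > 0)
  y <- predict(curve, conc)
  if (any(y >= 100)) stop("mortality at or above 100%: hazard undefined",
                          call. = FALSE)
  -log(1 - y / 100) / window
}

#' Concentration-dependent protection factor of Zn on Cd toxicity
#'
#' A phenomenological U-shaped factor `g(z)` scaling Cd's effective
#' concentration in the presence of Zn at `z` mg/L: moderate Zn induces
#' detoxification capacity (export, chelation, storage) that also handles
#' Cd, while beyond an overload threshold that capacity saturates and the
#' protection is lost. The factor is
#' \deqn{g(z) = 1 - (1 - g_{min})\, s(z)/s_{max}, \quad
#'       s(z) = \frac{z}{z + K} \cdot \frac{1}{1 + (z/z_{ov})^{h}},}
#' a smooth product of a protection-onset saturation (half-maximal at `K`)
#' and an overload roll-off around `z_ov`, normalised so the minimum of
#' `g` equals `g_min` at the protection-optimal Zn concentration.
#' `g(0) = 1` (no Zn, no protection) and `g` returns toward 1 at high Zn.
#'
#' Defaults place the protection optimum near the Zn LC40 (~31.5 mg/L)
#' and the overload threshold at 1 mM Zn (65.38 mg/L, about the Zn LC60),
#' mirroring the saturation of Zn-inducible detoxification reported for
#' the cdf-2 transporter.
#'
#' @param zn_conc Zn concentration(s), mg/L.
#' @param g_min minimum of the factor, in (0, 1\]; default 0.25.
#' @param k_onset Zn concentration of half-maximal protection onset
#'   (mg/L); default the Zn LC5, 1.416.
#' @param z_overload overload threshold (mg/L); default 65.38 (1 mM Zn).
#' @param h_overload Hill steepness of the overload roll-off; default 4.
#' @return protection factors in (0, 1\].
#' @export
zn_protection_factor <- function(zn_conc, g_min = 0.25, k_onset = 1.416,
                                 z_overload = 65.38, h_overload = 4) {
  stopifnot(g_min > 0, g_min <= 1, k_onset > 0, z_overload > 0, h_overload > 0)
  if (any(zn_conc < 0)) stop("Zn concentration must be >= 0", call. = FALSE)
  s <- function(z) (z / (z + k_onset)) / (1 + (z / z_overload)^h_overload)
  smax <- stats::optimize(s, c(0, 10 * z_overload), maximum = TRUE)$maximum
  smax <- s(smax)
  1 - (1 - g_min) * s(zn_conc) / smax
}

#' Hazard model for single metals and mixtures
#'
#' Bundles per-compound dose-response curves with a rule for combining
#' their lethal effects into one per-hour hazard:
#' * `"IA"` - independent competing risks: single-compound hazards add,
#'   so survival over the LC window is the product of single-compound
#'   survivals (the Independent Action model).
#' * `"CA"` - the hazard reproducing the Concentration Addition effect of
#'   the instantaneous mixture over the window.
#' * `"protective_zn_cd"` - like IA, but Cd's effective concentration is
#'   scaled by [zn_protection_factor()] of the Zn concentration; Zn's own
#'   hazard always acts in full.
#'
#' @param curves named list of `"loglogistic"` curves (names are compound
#'   labels, e.g. `Zn`, `Cd`).
#' @param rule combination rule, one of `"IA"`, `"CA"`,
#'   `"protective_zn_cd"`.
#' @param window LC window in hours (see [hazard_from_lc()]).
#' @param protection parameter list passed to [zn_protection_factor()]
#'   (used by the protective rule only).
#' @return an object of class `"hazard_model"`.
#' @export
hazard_model <- function(curves, rule = c("IA", "CA", "protective_zn_cd"),
                         window = 24, protection = list()) {
  rule <- match.arg(rule)
  if (inherits(curves, "loglogistic")) curves <- list(curves)
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    nm <- vapply(curves, function(k) k$compound %||% "", character(1))
    if (any(!nzchar(nm)))
      stop("curves must be named (or carry compound labels)", call. = FALSE)
    names(curves) <- nm
  }
  if (rule == "protective_zn_cd" && !all(c("Zn", "Cd") %in% names(curves)))
    stop("protective_zn_cd rule needs 'Zn' and 'Cd' curves", call. = FALSE)
  structure(list(curves = curves, rule = rule, window = window,
                 protection = protection),
            class = "hazard_model")
}

#' Combined per-hour hazard of a (possibly mixed) exposure
#'
#' @param hm a [hazard_model()].
#' @param conc named concentrations (mg/L) matching `hm`'s compounds;
#'   compounds absent from `conc` are taken as 0.
#' @return per-hour hazard rate.
#' @examples
#' tab <- celegans_lc_table()
#' hm <- hazard_model(list(Zn = curve_from_lc_table(tab, "Zn"),
#'                         Cd = curve_from_lc_table(tab, "Cd")),
#'                    rule = "protective_zn_cd")
#' combined_hazard(hm, c(Zn = 9.501, Cd = 7.110))
#' @export
combined_hazard <- function(hm, conc) {
  stopifnot(inherits(hm, "hazard_model"))
  full <- stats::setNames(numeric(length(hm$curves)), names(hm$curves))
  if (is.null(names(conc)) && length(conc) == length(full)) {
    full[] <- conc
  } else {
    if (is.null(names(conc))) stop("conc must be named", call. = FALSE)
    unknown <- setdiff(names(conc), names(full))
    if (length(unknown))
      stop("no curve for compound(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    full[names(conc)] <- conc
  }
  if (any(full < 0)) stop("concentrations must be >= 0", call. = FALSE)
  switch(hm$rule,
    IA = sum(vapply(names(full), function(cp)
      hazard_from_lc(hm$curves[[cp]], full[[cp]], hm$window), numeric(1))),
    CA = {
      mix <- mixture(hm$curves, unname(full[names(hm$curves)]))
      y <- predict_ca(mix)
      if (y >= 100) stop("CA effect at 100%: hazard undefined", call. = FALSE)
      -log(1 - y / 100) / hm$window
    },
    protective_zn_cd = {
      g <- do.call(zn_protection_factor,
                   c(list(zn_conc = full[["Zn"]]), hm$protection))
      eff <- full
      eff[["Cd"]] <- full[["Cd"]] * g
      sum(vapply(names(eff), function(cp)
        hazard_from_lc(hm$curves[[cp]], eff[[cp]], hm$window), numeric(1)))
    })
}
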
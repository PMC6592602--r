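#' Molar masses of the test metals (metal-ion basis)
#'
#' Concentrations throughout the package refer to the free metal ion, not
#' the salt used to prepare exposure media, so conversions between mass and
#' molar units use the atomic mass of the metal.
#'
#' @format Named numeric vector of atomic masses in g/mol for Zn, Cu and Cd.
#' @export
metal_molar_mass <- c(Zn = 65.38, Cu = 63.546, Cd = 112.414)

.conc_units <- c("mg/L", "mM", "uM")

#' Resolve a compound to its molar mass
#'
#' @param compound either a single compound name known to the package
#'   (`"Zn"`, `"Cu"`, `"Cd"`) or a positive numeric molar mass in g/mol.
#' @return molar mass in g/mol.
#' @keywords internal
resolve_molar_mass <- function(compound) {
  if (is.numeric(compound)) {
    if (length(compound) != 1L || !is.finite(compound) || compound <= 0)
      stop("molar mass must be a single positive number", call. = FALSE)
    return(as.numeric(compound))
  }
  if (is.character(compound) && length(compound) == 1L &&
      compound %in% names(metal_molar_mass))
    return(unname(metal_molar_mass[compound]))
  stop("unknown compound '", compound,
       "'; give a known metal name or a molar mass in g/mol", call. = FALSE)
}

#' Convert a concentration between mass and molar units
#'
#' Converts between mg/L, mM and uM (micromolar) on a metal-ion basis:
#' mg/L divided by molar mass (g/mol) gives mM, and 1 mM = 1000 uM.
#'
#' @param value non-negative numeric vector of concentrations.
#' @param from,to units, each one of `"mg/L"`, `"mM"`, `"uM"`.
#' @param compound compound name or molar mass (g/mol); required whenever
#'   the conversion crosses between mass and molar units.
#' @return numeric vector in the target unit.
#' @examples
#' convert_concentration(9.501, "mg/L", "mM", "Zn")   # 0.1453
#' convert_concentration(1.299, "mg/L", "uM", "Cu")   # 20.4
#' @export
convert_concentration <- function(value, from, to, compound = NULL) {
  from <- match_unit(from)
  to <- match_unit(to)
  if (any(!is.finite(value)) || any(value < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  if (from == to) return(value)
  # go through mM as the molar pivot
  mm_needed <- (from == "mg/L") != (to == "mg/L")
  if (mm_needed && is.null(compound))
    stop("compound (or molar mass) needed to convert between mass and molar units",
         call. = FALSE)
  in_mM <- switch(from,
    "mg/L" = value / resolve_molar_mass(compound),
    "mM"   = value,
    "uM"   = value / 1000)
  switch(to,
    "mg/L" = in_mM * resolve_molar_mass(compound),
    "mM"   = in_mM,
    "uM"   = in_mM * 1000)
}

match_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L)
    stop("unit must be a single string", call. = FALSE)
  u <- c("mg/L" = "mg/L", "mM" = "mM", "uM" = "uM",
         "µM" = "uM", "um" = "uM", "mm" = "mM", "mg/l" = "mg/L")
  hit <- u[match(unit, names(u))]
  if (is.na(hit))
    stop("unknown concentration unit '", unit,
         "'; use one of mg/L, mM, uM", call. = FALSE)
  unname(hit)
}
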
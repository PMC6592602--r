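#' Read and write LC tables
#'
#' LC tables map effect levels (percent mortality after a fixed exposure
#' window) to concentrations for one or more compounds. The CSV layout has
#' columns `compound`, `lc_level`, `conc_mg_per_L` and optionally
#' `conc_spread` (a reported spread, carried as annotation only). A bundled
#' table of 24 h adult C. elegans lethal concentrations for Zn, Cu and Cd
#' ships with the package; see [celegans_lc_table()].
#'
#' @param path CSV file path.
#' @return a data frame of class `"lc_table"`, sorted by compound and
#'   level, with entries strictly increasing in concentration within each
#'   compound.
#' @export
read_lc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_lc_table(df)
}

#' @rdname read_lc_table
#' @param x an `lc_table` (or coercible data frame).
#' @export
write_lc_table <- function(x, path) {
  x <- as_lc_table(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_lc_table
#' @export
as_lc_table <- function(x) {
  need <- c("compound", "lc_level", "conc_mg_per_L")
  if (!all(need %in% names(x)))
    stop("LC table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!"conc_spread" %in% names(x)) x$conc_spread <- NA_real_
  x <- x[order(x$compound, x$lc_level), , drop = FALSE]
  if (any(x$lc_level <= 0 | x$lc_level >= 100))
    stop("lc_level must lie in (0, 100)", call. = FALSE)
  if (any(x$conc_mg_per_L <= 0))
    stop("concentrations must be positive", call. = FALSE)
  for (cp in unique(x$compound)) {
    cc <- x$conc_mg_per_L[x$compound == cp]
    if (any(diff(cc) <= 0))
      stop("entries for ", cp, " must increase strictly with LC level",
           call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("lc_table", "data.frame")
  x
}

#' Bundled 24 h lethal-concentration table for Zn, Cu and Cd
#'
#' Reference LC2-LC60 values (mg/L, metal-ion basis) for adult
#' C. elegans after 24 h of exposure in K-medium: the concentrations used
#' as exposure levels throughout the package's examples and simulated
#' experiments. Zn carries five levels (LC2, 5, 20, 40, 60); Cu and Cd
#' only LC5 and LC20.
#'
#' @return an `lc_table` data frame.
#' @examples
#' celegans_lc_table()
#' @export
celegans_lc_table <- function() {
  read_lc_table(system.file("extdata", "zn_cu_cd_lc24h.csv",
                            package = "nematox", mustWork = TRUE))
}

#' Dose-response curve from an LC table
#'
#' Builds a compound's log-logistic curve from its LC entries: an exact
#' two-point construction when exactly two levels are available, otherwise
#' a least-squares fit over all levels (see [fit_loglogistic()]).
#'
#' @param table an `lc_table`.
#' @param compound compound name present in the table.
#' @return a `"loglogistic"` curve.
#' @examples
#' curve_from_lc_table(celegans_lc_table(), "Cd")
#' @export
curve_from_lc_table <- function(table, compound) {
  table <- as_lc_table(table)
  rows <- table[table$compound == compound, , drop = FALSE]
  if (nrow(rows) < 2L)
    stop("need at least two LC levels for ", compound, call. = FALSE)
  if (nrow(rows) == 2L)
    fit_two_point(rows$conc_mg_per_L[1], rows$lc_level[1],
                  rows$conc_mg_per_L[2], rows$lc_level[2], compound)
  else
    fit_loglogistic(rows$conc_mg_per_L, rows$lc_level, compound = compound)
}
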
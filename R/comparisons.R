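#' One-way ANOVA with Dunnett and Tukey post-hoc comparisons
#'
#' Fits a one-way fixed-effects ANOVA to replicate endpoint values,
#' reports the overall F test, Tukey HSD over all group pairs, and - when
#' a control group is named - Dunnett-style many-to-one comparisons
#' against it (single-step adjusted via the equicorrelated multivariate-t
#' distribution, as implemented in \pkg{multcomp}).
#'
#' A degenerate input in which every observation is identical is reported
#' as F = 0 with all p-values 1 (no evidence of any difference).
#'
#' @param values numeric endpoint values.
#' @param group group labels (coerced to factor), >= 2 groups with >= 2
#'   replicates each.
#' @param control optional control group label for the Dunnett step.
#' @return a list of class `"endpoint_anova"`: `f`, `p`, `df`, `tukey`
#'   (data frame: comparison, estimate, adjusted p), and `dunnett` (or
#'   `NULL`).
#' @examples
#' set.seed(1)
#' v <- c(rnorm(4, 10), rnorm(4, 10), rnorm(4, 14))
#' g <- rep(c("control", "Zn", "Cd"), each = 4)
#' anova_dunnett_tukey(v, g, control = "control")
#' @export
anova_dunnett_tukey <- function(values, group, control = NULL) {
  group <- factor(group)
  if (length(values) != length(group))
    stop("values and group lengths differ", call. = FALSE)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L))
    stop("every group needs at least 2 replicates", call. = FALSE)
  if (!is.null(control)) {
    if (!control %in% levels(group))
      stop("control label not among groups", call. = FALSE)
    group <- stats::relevel(group, ref = control)
  }
  pairs <- utils::combn(levels(group), 2)
  cmp_names <- paste(pairs[2, ], pairs[1, ], sep = " - ")

  if (stats::var(values) == 0) {
    tuk <- data.frame(comparison = cmp_names, estimate = 0, p_adj = 1)
    dun <- if (!is.null(control)) {
      others <- setdiff(levels(group), control)
      data.frame(comparison = paste(others, control, sep = " - "),
                 estimate = 0, p_adj = 1)
    }
    return(structure(list(f = 0, p = 1,
                          df = c(nlevels(group) - 1L,
                                 length(values) - nlevels(group)),
                          tukey = tuk, dunnett = dun),
                     class = "endpoint_anova"))
  }

  dat <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  th <- stats::TukeyHSD(fit)$g
  tuk <- data.frame(comparison = rownames(th), estimate = th[, "diff"],
                    p_adj = th[, "p adj"], row.names = NULL)
  dun <- NULL
  if (!is.null(control)) {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    dun <- data.frame(comparison = names(sm$test$coefficients),
                      estimate = as.vector(sm$test$coefficients),
                      p_adj = as.vector(sm$test$pvalues), row.names = NULL)
  }
  structure(list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                 df = an[["Df"]], tukey = tuk, dunnett = dun),
            class = "endpoint_anova")
}

#' @export
print.endpoint_anova <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  cat("Tukey HSD:\n")
  print(transform(x$tukey, estimate = signif(estimate, digits),
                  p_adj = signif(p_adj, digits)), row.names = FALSE)
  if (!is.null(x$dunnett)) {
    cat("Dunnett (vs control):\n")
    print(transform(x$dunnett, estimate = signif(estimate, digits),
                    p_adj = signif(p_adj, digits)), row.names = FALSE)
  }
  invisible(x)
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise comparisons
#'
#' Rank-based one-way analysis (with the usual tie correction) followed by
#' pairwise two-sided Wilcoxon rank-sum tests whose p-values are
#' multiplied by the number of comparisons (Bonferroni), capped at 1.
#' Exact rank-sum p-values are used whenever sample sizes permit and no
#' ties are present. All-identical input yields H = 0 and p = 1.
#'
#' @inheritParams anova_dunnett_tukey
#' @return a list of class `"kruskal_bonferroni"`: `h`, `df`, `p`,
#'   `pairwise` (data frame: comparison, p_raw, p_adj).
#' @export
kruskal_bonferroni <- function(values, group) {
  group <- factor(group)
  if (length(values) != length(group))
    stop("values and group lengths differ", call. = FALSE)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(levels(group), 2)
  m <- ncol(pairs)
  if (stats::var(values) == 0) {
    pw <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                     p_raw = 1, p_adj = 1)
    return(structure(list(h = 0, df = nlevels(group) - 1L, p = 1,
                          pairwise = pw),
                     class = "kruskal_bonferroni"))
  }
  kw <- stats::kruskal.test(values, group)
  pw <- lapply(seq_len(m), function(j) {
    sel <- group %in% pairs[, j]
    x <- values[sel & group == pairs[1, j]]
    y <- values[sel & group == pairs[2, j]]
    p <- if (stats::var(c(x, y)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(comparison = paste(pairs[1, j], pairs[2, j], sep = " vs "),
               p_raw = p, p_adj = min(1, p * m))
  })
  structure(list(h = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, pairwise = do.call(rbind, pw)),
            class = "kruskal_bonferroni")
}

#' @export
print.kruskal_bonferroni <- function(x, digits = 4, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.4g, p = %.4g\n", x$df, x$h, x$p))
  cat("Pairwise rank-sum (Bonferroni-adjusted):\n")
  print(transform(x$pairwise, p_raw = signif(p_raw, digits),
                  p_adj = signif(p_adj, digits)), row.names = FALSE)
  invisible(x)
}

#' Per-treatment body-length slopes over time with pairwise contrasts
#'
#' Fits an ordinary least-squares line of body length (mm) on day for each
#' treatment separately and compares slopes between treatment pairs via
#' the day x treatment interaction term of a two-treatment fixed-effects
#' regression (estimate, standard error and t-test p of the slope
#' difference).
#'
#' @param lengths data frame with columns `treatment`, `day`, `length_mm`
#'   (a `replicate` column, if present, is ignored by the fixed-effects
#'   fit).
#' @param contrasts optional 2-column matrix or list of treatment pairs to
#'   contrast; default all pairs.
#' @return a list of class `"length_slopes"`: `slopes` (treatment, slope
#'   mm/day, se, n) and `contrasts` (pair, estimate, se, p).
#' @export
length_slopes <- function(lengths, contrasts = NULL) {
  need <- c("treatment", "day", "length_mm")
  if (!all(need %in% names(lengths)))
    stop("lengths needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  lengths$treatment <- factor(lengths$treatment)
  trts <- levels(lengths$treatment)
  slopes <- lapply(trts, function(tr) {
    d <- lengths[lengths$treatment == tr, , drop = FALSE]
    if (length(unique(d$day)) < 2L)
      stop("treatment ", tr, " has fewer than 2 distinct days", call. = FALSE)
    fit <- stats::lm(length_mm ~ day, data = d)
    cf <- summary(fit)$coefficients
    se <- if (nrow(d) > 2L) cf["day", "Std. Error"] else NA_real_
    data.frame(treatment = tr, slope = cf["day", "Estimate"], se = se,
               n = nrow(d))
  })
  slopes <- do.call(rbind, slopes)
  if (is.null(contrasts)) contrasts <- utils::combn(trts, 2)
  if (is.list(contrasts)) contrasts <- do.call(cbind, contrasts)
  cons <- lapply(seq_len(ncol(contrasts)), function(j) {
    pr <- contrasts[, j]
    d <- lengths[lengths$treatment %in% pr, , drop = FALSE]
    d$treatment <- factor(d$treatment, levels = pr)
    fit <- stats::lm(length_mm ~ day * treatment, data = d)
    cf <- summary(fit)$coefficients
    row <- grep("^day:treatment", rownames(cf))
    data.frame(pair = paste(pr[2], pr[1], sep = " - "),
               estimate = cf[row, "Estimate"], se = cf[row, "Std. Error"],
               p = cf[row, "Pr(>|t|)"], row.names = NULL)
  })
  structure(list(slopes = slopes, contrasts = do.call(rbind, cons)),
            class = "length_slopes")
}

#' @export
print.length_slopes <- function(x, digits = 4, ...) {
  cat("Body-length slopes (mm/day):\n")
  print(transform(x$slopes, slope = signif(slope, digits),
                  se = signif(se, digits)), row.names = FALSE)
  cat("Slope contrasts:\n")
  print(transform(x$contrasts, estimate = signif(estimate, digits),
                  se = signif(se, digits), p = signif(p, digits)),
        row.names = FALSE)
  invisible(x)
}
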
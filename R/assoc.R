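#' Single-marker one-way ANOVA with variance explained
#'
#' Two-class one-way ANOVA of a quantitative trait on a biallelic marker:
#' `F = MS_between / MS_within` with degrees of freedom `(1, n - 2)`, and
#' phenotypic variance explained (PVE) as eta-squared,
#' `100 * SS_between / SS_total`. For a two-class layout the identity
#' `PVE = 100 * F / (F + n - 2)` holds exactly (see [pve_from_f()]).
#' Missing genotypes are dropped (count reported in `glance()`).
#'
#' @param data A data frame with one row per line.
#' @param value Column holding the trait value (tidy-eval).
#' @param allele Column holding the allele class, two levels, `NA` = missing
#'   (tidy-eval).
#'
#' @return An object of class `marker_assoc`. `tidy()` returns per-allele
#'   summaries (n, mean, sd); `glance()` returns a one-row tibble with
#'   `statistic` (F), `df`, `df_residual`, `p_value`, `pve_percent`,
#'   `stars` (`"**"` p < 0.01, `"*"` p < 0.05), `n`, `n_dropped`.
#' @export
#'
#' @examples
#' d <- data.frame(tgw = c(1, 2, 3, 4, 5, 6),
#'                 allele = rep(c("b", "a"), each = 3))
#' glance(marker_anova(d, tgw, allele))
marker_anova <- function(data, value, allele) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(allele), data))
  keep <- !is.na(v) & !is.na(g)
  n_dropped <- sum(!keep)
  v <- v[keep]
  g <- g[keep]
  classes <- sort(unique(g))
  if (length(classes) != 2L || any(table(g) < 2L)) {
    bsa_abort(
      "marker_anova needs exactly two allele classes with >= 2 lines each.",
      "slafbsa_error_class")
  }
  fit <- stats::lm(v ~ g)
  an <- stats::anova(fit)
  ssb <- an$`Sum Sq`[1]
  ssw <- an$`Sum Sq`[2]
  n <- length(v)
  per_class <- tibble::tibble(
    allele = classes,
    n = as.integer(table(g)[classes]),
    mean = unname(vapply(classes, function(k) mean(v[g == k]), numeric(1))),
    sd = unname(vapply(classes, function(k) stats::sd(v[g == k]), numeric(1)))
  )
  p <- an$`Pr(>F)`[1]
  structure(
    list(per_class = per_class,
         statistic = an$`F value`[1], df = 1L, df_residual = n - 2L,
         p_value = p,
         pve_percent = 100 * ssb / (ssb + ssw),
         stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
         n = n, n_dropped = n_dropped),
    class = "marker_assoc"
  )
}

#' @export
print.marker_assoc <- function(x, ...) {
  cat(sprintf(
    "<marker_assoc> F(%d, %d) = %.2f%s, p = %.3g, PVE = %.1f%% (n = %d)\n",
    x$df, x$df_residual, x$statistic, x$stars, x$p_value, x$pve_percent, x$n))
  print(x$per_class)
  invisible(x)
}

#' @rdname marker_anova
#' @param x A `marker_assoc` object.
#' @param ... Unused.
#' @method tidy marker_assoc
#' @export
tidy.marker_assoc <- function(x, ...) x$per_class

#' @rdname marker_anova
#' @method glance marker_assoc
#' @export
glance.marker_assoc <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, df_residual = x$df_residual,
    p_value = x$p_value, pve_percent = x$pve_percent, stars = x$stars,
    n = x$n, n_dropped = x$n_dropped
  )
}

#' Variance explained from a printed F statistic
#'
#' Recovers the eta-squared phenotypic variance explained (in percent) of a
#' two-class one-way ANOVA from its F statistic and the number of lines:
#' `100 * F / (F + n - 2)`. Identical to the SS-ratio computed by
#' [marker_anova()] on the same data.
#'
#' @param f F statistic(s) (>= 0).
#' @param n Number of lines (>= 3).
#' @return PVE in percent.
#' @export
#'
#' @examples
#' pve_from_f(54.88, 150)  # 27.05 -> prints as 27.1 at one decimal
pve_from_f <- function(f, n) {
  if (any(n < 3)) {
    bsa_abort("`n` must be at least 3.", "slafbsa_error_domain")
  }
  stopifnot(all(f >= 0))
  100 * f / (f + n - 2)
}

#' Per-group allele frequencies
#'
#' Counts and percentages of each allele among non-missing lines, optionally
#' split by a grouping column (e.g. geographic region). Percentages are
#' rounded to whole percent for reporting; the unrounded frequency is also
#' returned.
#'
#' @param data A data frame with one row per line.
#' @param allele Allele column (tidy-eval); `NA` = missing, excluded.
#' @param group Optional grouping column (tidy-eval).
#'
#' @return A tibble with columns `group` (if supplied), `allele`, `n`,
#'   `frequency`, `percent` (rounded to whole percent).
#' @export
allele_frequencies <- function(data, allele, group = NULL) {
  g_quo <- rlang::enquo(group)
  a <- as.character(rlang::eval_tidy(rlang::enquo(allele), data))
  grp <- if (rlang::quo_is_null(g_quo)) rep("all", length(a)) else
    as.character(rlang::eval_tidy(g_quo, data))
  keep <- !is.na(a)
  d <- tibble::tibble(group = grp[keep], allele = a[keep]) |>
    dplyr::count(.data$group, .data$allele, name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n),
                  percent = round(100 * .data$frequency)) |>
    dplyr::ungroup()
  if (rlang::quo_is_null(g_quo)) d$group <- NULL
  d
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_control`; relative expression against a
#' reference sample is `2^-(dCt_sample - dCt_reference)`. The reference
#' against itself is exactly 1.
#'
#' @param ct_target Target-gene Ct of the sample(s).
#' @param ct_control Endogenous-control Ct of the sample(s).
#' @param ref_ct_target Target-gene Ct of the reference sample.
#' @param ref_ct_control Endogenous-control Ct of the reference sample.
#' @return Relative expression ratio(s).
#' @export
#'
#' @examples
#' ddct_expression(24, 20, 25, 20)  # ddCt = -1 -> ratio 2
ddct_expression <- function(ct_target, ct_control, ref_ct_target,
                            ref_ct_control) {
  cts <- c(ct_target, ct_control, ref_ct_target, ref_ct_control)
  if (!all(is.finite(cts))) {
    bsa_abort("All Ct values must be finite.", "slafbsa_error_validation")
  }
  ddct <- (ct_target - ct_control) - (ref_ct_target - ref_ct_control)
  2^(-ddct)
}
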
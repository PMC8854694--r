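# Statistical layer: the tests named in the figure legends, with explicit
# contracts and machine-readable results.

new_epiq_stat <- function(method, statistic = NA_real_, df = NULL,
                          p_value = NA_real_, p_adjusted = NA_real_,
                          adjust_method = NA_character_, m = NA_integer_,
                          effect = NULL, note = NA_character_) {
  structure(
    list(method = method, statistic = statistic, df = df,
         p_value = p_value, p_adjusted = p_adjusted,
         adjust_method = adjust_method, m = m, effect = effect, note = note),
    class = "epiq_stat"
  )
}

#' @export
print.epiq_stat <- function(x, ...) {
  cat(sprintf("<epiq_stat> %s\n", x$method))
  if (!is.na(x$statistic)) {
    cat(sprintf("  statistic = %.4g", x$statistic))
    if (!is.null(x$df)) cat(sprintf(" (df %s)", paste(x$df, collapse = ", ")))
    cat("\n")
  }
  cat(sprintf("  p = %.4g", x$p_value))
  if (!is.na(x$p_adjusted)) {
    cat(sprintf("; adjusted p = %.4g (%s, m = %d)",
                x$p_adjusted, x$adjust_method, x$m))
  }
  cat("\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
#' @method tidy epiq_stat
tidy.epiq_stat <- function(x, ...) {
  tibble(
    method = x$method,
    statistic = x$statistic,
    df1 = if (length(x$df) >= 1) x$df[1] else NA_real_,
    df2 = if (length(x$df) >= 2) x$df[2] else NA_real_,
    p_value = x$p_value,
    p_adjusted = x$p_adjusted,
    adjust_method = x$adjust_method,
    m = x$m,
    note = x$note
  )
}

#' @export
#' @method glance epiq_stat
glance.epiq_stat <- function(x, ...) tidy(x)

# Two-sided Fisher probability-mass p-value for one 2x2 table with fixed
# margins: the sum of hypergeometric probabilities of all tables no more
# probable than the observed one (with the customary small relative
# tolerance for floating-point ties).
fisher_p_2x2 <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  supp <- lo:hi
  probs <- dhyper(supp, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Fisher's exact test of independence for a 2x2 table
#'
#' The p-value is computed by the probability-mass method: with the table
#' margins fixed, it is the total hypergeometric probability of all tables
#' whose probability does not exceed that of the observed table. A
#' Bonferroni-adjusted p for a family of `m` comparisons is reported
#' alongside the raw p, since published figure legends in this area adjust
#' families of direction-proportion comparisons (typically m = 4).
#'
#' @param table A 2x2 matrix or data.frame of non-negative integer counts
#'   (rows = groups, columns = outcomes).
#' @param m Family size for the Bonferroni adjustment (default 1, i.e. no
#'   adjustment).
#' @return An `epiq_stat` with `p_value` (raw), `p_adjusted` (Bonferroni),
#'   the sample odds ratio as `effect`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(5, 33, 51, 33), 2, 2), m = 4)
fisher_exact_2x2 <- function(table, m = 1L) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2, 2)) || any(x < 0) || any(x != round(x))) {
    stop_bad_arg("`table` must be a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop_bad_arg("all margins of the 2x2 table must be positive")
  }
  m <- as.integer(m)
  if (m < 1) stop_bad_arg("`m` must be a positive integer")
  p <- fisher_p_2x2(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  new_epiq_stat(
    method = "two-sided Fisher's exact test (probability-mass)",
    p_value = p,
    p_adjusted = min(1, m * p),
    adjust_method = "bonferroni", m = m,
    effect = c(odds_ratio = unname(or))
  )
}

#' Bonferroni adjustment of a vector of p-values
#'
#' Each p-value is multiplied by the family size `m` and clipped at 1.
#' `m` may exceed the number of p-values supplied (comparisons not carried
#' through to this call still count towards the family).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' bonferroni_adjust(c(0.01, 0.5), m = 4)
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_bad_arg("p-values must lie in [0, 1]")
  }
  if (m < length(p)) {
    stop_bad_arg("`m` must be at least the number of p-values")
  }
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' One-way ANOVA followed by Tukey's honestly-significant-difference test
#'
#' Fits a one-way analysis of variance across groups and reports the
#' global F test plus all pairwise comparisons with Tukey-adjusted
#' p-values from the studentized range distribution (the comparison used
#' for per-tissue lifetime means across embryos).
#'
#' @param data Data.frame with the response and grouping columns.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @return A list of class `epiq_anova`: `anova` (an `epiq_stat` for the
#'   global F) and `pairwise` (tibble: `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adjusted`). `tidy()` returns the pairwise table.
#' @export
anova_tukey <- function(data, value = "value", group = "group") {
  y <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 2) stop_bad_arg("need at least 2 groups")
  if (any(table(g) < 2)) stop_bad_arg("need at least 2 values per group")
  note <- NA_character_
  if (isTRUE(all(y == y[1]))) {
    note <- "all values identical: F undefined"
    fit_stat <- new_epiq_stat("one-way ANOVA", statistic = NA_real_,
                              p_value = NA_real_, note = note)
    return(structure(list(anova = fit_stat, pairwise = tibble()),
                     class = "epiq_anova"))
  }
  fit <- aov(y ~ g)
  s <- summary(fit)[[1]]
  fstat <- s$`F value`[1]
  p <- s$`Pr(>F)`[1]
  tk <- TukeyHSD(fit)$g
  pairwise <- tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adjusted = tk[, "p adj"]
  )
  structure(
    list(
      anova = new_epiq_stat("one-way ANOVA", statistic = fstat,
                            df = s$Df, p_value = p, note = note),
      pairwise = pairwise
    ),
    class = "epiq_anova"
  )
}

#' @export
#' @method tidy epiq_anova
tidy.epiq_anova <- function(x, ...) x$pairwise

#' @export
#' @method glance epiq_anova
glance.epiq_anova <- function(x, ...) tidy(x$anova)

#' @export
print.epiq_anova <- function(x, ...) {
  print(x$anova)
  if (nrow(x$pairwise) > 0) {
    cat("  pairwise (Tukey):\n")
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("    %s: diff %.4g, p_adj %.4g\n",
                  x$pairwise$comparison[i], x$pairwise$diff[i],
                  x$pairwise$p_adjusted[i]))
    }
  }
  invisible(x)
}

#' Nested (two-level hierarchical) analysis of variance
#'
#' Tests a group effect against the variation among units nested within
#' groups — the correct error stratum when several measurements are taken
#' per unit (e.g. three thickness measurements per embryo, several embryos
#' per genotype). The F statistic is `MS_group / MS_unit(group)` with
#' degrees of freedom `(g - 1, total_units - g)`; the residual
#' (within-unit) stratum is never used to test the group effect, so
#' pseudo-replicated measurements cannot inflate significance.
#'
#' @param data Data.frame of individual measurements.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column (e.g. genotype).
#' @param unit Name of the unit column (e.g. embryo); units must be
#'   distinct across groups or are made so internally.
#' @return An `epiq_stat` with the nested F, df and p-value.
#' @export
#' @examples
#' d <- data.frame(
#'   genotype = rep(c("wt", "mut"), each = 6),
#'   embryo = rep(1:4, each = 3),
#'   thickness = c(rnorm(6, 50, 2), rnorm(6, 60, 2))
#' )
#' nested_anova(d, "thickness", "genotype", "embryo")
nested_anova <- function(data, value = "value", group = "group",
                         unit = "unit") {
  y <- data[[value]]
  g <- factor(data[[group]])
  u <- factor(paste(data[[group]], data[[unit]], sep = "/"))
  n_units <- tapply(as.character(u), g, function(z) length(unique(z)))
  if (any(n_units < 2)) {
    stop_bad_arg("nested ANOVA needs at least 2 units in every group")
  }
  # Sequential sums of squares: group, then unit within group.
  fit <- aov(y ~ g + u)
  s <- summary(fit)[[1]]
  ss <- s$`Sum Sq`; df <- s$Df
  ms_group <- ss[1] / df[1]
  ms_unit <- ss[2] / df[2]
  f <- ms_group / ms_unit
  p <- pf(f, df[1], df[2], lower.tail = FALSE)
  new_epiq_stat(
    method = "nested ANOVA (group tested against unit-within-group)",
    statistic = f, df = c(df[1], df[2]), p_value = p,
    effect = c(ms_group = ms_group, ms_unit = ms_unit)
  )
}

#' Unpaired two-sided t-test
#'
#' Pooled-variance Student form by default (as named in the legends), with
#' the Welch unequal-variance form available by flag. Two groups with zero
#' variance and equal means are reported with p = 1 and a note instead of
#' an error.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param welch Use the Welch unequal-variance form.
#' @return An `epiq_stat` with `statistic` (t), `df` and `p_value`; the
#'   mean difference `a - b` as `effect`.
#' @export
#' @examples
#' ttest_unpaired(rnorm(9, 4.8, 0.05), rnorm(7, 4.6, 0.05))
ttest_unpaired <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop_bad_arg("need at least 2 values per group")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_epiq_stat(
        "unpaired two-sided t-test", statistic = 0,
        df = length(a) + length(b) - 2, p_value = 1,
        effect = c(mean_diff = 0),
        note = "both groups constant with equal means: p = 1 by convention"
      ))
    }
    return(new_epiq_stat(
      "unpaired two-sided t-test", statistic = Inf,
      df = length(a) + length(b) - 2, p_value = 0,
      effect = c(mean_diff = mean(a) - mean(b)),
      note = "both groups constant with different means: p = 0 by convention"
    ))
  }
  ht <- t.test(a, b, var.equal = !welch)
  new_epiq_stat(
    method = if (welch) "unpaired two-sided t-test (Welch)" else
      "unpaired two-sided t-test (pooled variance)",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    effect = c(mean_diff = mean(a) - mean(b))
  )
}

#' Box-plot summary statistics
#'
#' Quartiles by linear interpolation, the median, and whiskers. The
#' default whisker convention is minimum-to-maximum (the convention used
#' in the tissue-comparison box plots); the `"iqr"` convention places
#' whiskers at the most extreme values within 1.5 IQR of the quartiles and
#' lists points beyond them as outliers.
#'
#' @param values Numeric vector (>= 1 value).
#' @param whiskers `"minmax"` (default) or `"iqr"`.
#' @return A list of class `box_summary`: `q25`, `median`, `q75`,
#'   `whisker_low`, `whisker_high`, `outliers` (numeric, empty for
#'   `"minmax"`). `tidy()` gives a one-row tibble.
#' @export
#' @examples
#' box_summary(c(1, 2, 3, 4, 5))
box_summary <- function(values, whiskers = c("minmax", "iqr")) {
  whiskers <- match.arg(whiskers)
  values <- values[!is.na(values)]
  if (length(values) < 1) stop_bad_arg("need at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  if (whiskers == "minmax") {
    lo <- min(values); hi <- max(values); out <- numeric(0)
  } else {
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- values >= lo_fence & values <= hi_fence
    lo <- min(values[inside]); hi <- max(values[inside])
    out <- sort(values[!inside])
  }
  structure(
    list(q25 = q[1], median = q[2], q75 = q[3],
         whisker_low = lo, whisker_high = hi,
         outliers = out, convention = whiskers, n = length(values)),
    class = "box_summary"
  )
}

#' @export
#' @method tidy box_summary
tidy.box_summary <- function(x, ...) {
  tibble(q25 = x$q25, median = x$median, q75 = x$q75,
         whisker_low = x$whisker_low, whisker_high = x$whisker_high,
         n_outliers = length(x$outliers), convention = x$convention,
         n = x$n)
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary> n = %d: [%.4g | %.4g [%.4g] %.4g | %.4g] (%s whiskers, %d outliers)\n",
    x$n, x$whisker_low, x$q25, x$median, x$q75, x$whisker_high,
    x$convention, length(x$outliers)
  ))
  invisible(x)
}
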
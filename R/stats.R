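#' Two-tailed unpaired Student's t test
#'
#' Pooled-variance (Student's, not Welch) two-sample two-tailed t test,
#' the two-group comparison used throughout the analyses. Degenerate
#' zero-variance inputs follow the convention: equal means give `p = 1`;
#' unequal means with zero pooled variance are an error.
#'
#' @param a,b numeric replicate vectors, each of length >= 2.
#' @return a list with elements `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @examples
#' students_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
students_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_data("each group needs at least 2 values")
  pooled_var <- ((length(a) - 1) * stats::var(a) +
                   (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                  mean_a = mean(a), mean_b = mean(b)))
    tcaflux_error("degenerate_variance",
                  "zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' One-way ANOVA with Tukey's multiple comparisons
#'
#' One-way analysis of variance followed by Tukey's honestly-significant-
#' difference test (studentized-range distribution) for all pairwise
#' comparisons, the three-or-more-group procedure used throughout the
#' analyses.
#'
#' @param groups a named list of >= 3 numeric vectors, each of length >= 2.
#' @param alpha significance level used to flag significant pairs.
#' @return an object of class `"group_comparison"`: `F`, `p`, a
#'   data.frame `pairs` (`pair`, `diff`, `p_adj`, `p_unadj`,
#'   `significant`) and `alpha`. `p_unadj` is the unadjusted pairwise t
#'   test on the pooled ANOVA error term.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L)
    stop_data("need >= 3 groups; use students_t_test() for 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2L))
    stop_data("each group needs at least 2 values")
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  # unadjusted pairwise t on the pooled error term (same MSE, same df)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  means <- vapply(groups, mean, 0)
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  p_unadj <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse * (1 / ns[[pr[1L]]] + 1 / ns[[pr[2L]]]))
    2 * stats::pt(abs(means[[pr[2L]]] - means[[pr[1L]]]) / se, dfe,
                  lower.tail = FALSE)
  })
  pair_names <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
  tk <- tk[match(pair_names, rownames(tk)), , drop = FALSE]
  out <- data.frame(pair = pair_names, diff = tk[, "diff"],
                    p_adj = tk[, "p adj"], p_unadj = p_unadj,
                    significant = tk[, "p adj"] < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(F = an["g", "F value"], p = an["g", "Pr(>F)"],
                 pairs = out, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g\n", x$F, x$p))
  cat(sprintf("Tukey HSD pairwise comparisons (alpha = %g):\n", x$alpha))
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1,
#' original order preserved.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop_validation("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors of equal length >= 3, both nonconstant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a list with elements `r` and `p`.
#' @export
pearson_r <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stop_data("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    tcaflux_error("undefined_correlation",
                  "correlation undefined for constant input")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p = ht$p.value)
}
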
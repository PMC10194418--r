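#' Summarize a group of repolarization-power values
#'
#' Mean, SEM (sd/sqrt(n)), quartiles and Tukey whiskers (the most extreme
#' data points within 1.5 x IQR of the quartiles), plus the values flagged as
#' outliers by that rule — the numbers behind a Tukey box plot.
#'
#' @param values numeric vector, length >= 1.
#' @param label group label.
#' @return An object of class `group_summary` with fields `label`, `n`,
#'   `mean`, `sem`, `quartiles` (q1, median, q3), `whiskers` (low, high),
#'   `outliers`.
#' @export
summarize_group <- function(values, label = "") {
  if (!is.numeric(values) || length(values) < 1L || any(!is.finite(values)))
    stop_field("values", "must be a non-empty finite numeric vector")
  n <- length(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(
    list(label = as.character(label), n = n,
         mean = mean(values),
         sem = if (n > 1L) stats::sd(values) / sqrt(n) else 0,
         quartiles = c(q1 = q[1L], median = q[2L], q3 = q[3L]),
         whiskers = c(low = min(values[inside]), high = max(values[inside])),
         outliers = values[!inside]),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "<group_summary> %s: n=%d mean=%.4g sem=%.3g median=%.4g [q1 %.4g, q3 %.4g]\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    x$n, x$mean, x$sem, x$quartiles[["median"]],
    x$quartiles[["q1"]], x$quartiles[["q3"]]))
  if (length(x$outliers))
    cat("  outliers (1.5xIQR rule):", paste(signif(x$outliers, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Compare two groups of repolarization powers
#'
#' Rank-based two-group comparison with the usual significance-star
#' convention: `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01.
#' Defaults to the Wilcoxon rank-sum (Mann--Whitney) test for independent
#' groups and the Wilcoxon signed-rank test when `paired`; Welch/paired
#' t-tests are available via `test`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 3; equal lengths
#'   required when `paired`.
#' @param paired logical.
#' @param test `"wilcoxon"` (rank-based, the default) or `"ttest"`.
#' @param label_a,label_b group labels.
#' @param alpha significance thresholds for one and two stars.
#' @return An object of class `comparison_result` with fields `group_a`,
#'   `group_b`, `p_value`, `stars` (`"ns"`, `"*"` or `"**"`), `test_name`,
#'   `paired`.
#' @export
compare_groups <- function(group_a, group_b, paired = FALSE,
                           test = c("wilcoxon", "ttest"),
                           label_a = "A", label_b = "B",
                           alpha = c(0.05, 0.01)) {
  test <- match.arg(test)
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("need at least 3 observations per group", call. = FALSE)
  if (paired && length(group_a) != length(group_b))
    stop("paired comparison requires equal group sizes", call. = FALSE)
  ht <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(group_a, group_b, paired = paired,
                                        exact = NULL))
  } else {
    stats::t.test(group_a, group_b, paired = paired)
  }
  p <- ht$p.value
  structure(
    list(group_a = label_a, group_b = label_b,
         p_value = p, stars = p_stars(p, alpha),
         test_name = ht$method, paired = paired),
    class = "comparison_result")
}

#' @rdname compare_groups
#' @param p p-value to convert to a star label.
#' @export
p_stars <- function(p, alpha = c(0.05, 0.01)) {
  if (!is.finite(p)) return("ns")
  if (p < alpha[2L]) "**" else if (p < alpha[1L]) "*" else "ns"
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s: p = %.4g (%s), %s%s\n",
              x$group_a, x$group_b, x$p_value, x$stars, x$test_name,
              if (x$paired) ", paired" else ""))
  invisible(x)
}
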
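SIGNIF_TIERS <- c(0.005, 0.01, 0.05)
SIGNIF_LABELS <- c("***", "**", "*", "ns")

#' Unpaired two-tailed t-test
#'
#' Two-sample, two-sided t-test. The default `student` variant is the
#' classical equal-variance test (pooled variance, df = n_a + n_b - 2);
#' `welch` uses the Welch-Satterthwaite degrees of freedom. The result
#' carries the significance tier label from [significance_label()].
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return object of class `test_result`: `t_stat`, `df`, `p_value`,
#'   `label`, `variant`, `n_a`, `n_b`.
#' @export
t_test_two_sample <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate variance: all values identical within both samples",
         call. = FALSE)
  fit <- stats::t.test(a, b, alternative = "two.sided",
                       var.equal = (variant == "student"))
  p <- unname(fit$p.value)
  structure(list(t_stat = unname(fit$statistic), df = unname(fit$parameter),
                 p_value = p, label = significance_label(p),
                 variant = variant, n_a = length(a), n_b = length(b)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s t = %.4g, df = %.4g, p = %.4g [%s]\n",
              x$variant, x$t_stat, x$df, x$p_value, x$label))
  invisible(x)
}

#' Significance tier label for a p-value
#'
#' Star tiering with inclusive boundaries:
#' `***` for p <= 0.005, `**` for 0.005 < p <= 0.01, `*` for
#' 0.01 < p <= 0.05, `ns` otherwise.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of labels.
#' @export
significance_label <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  vapply(p, function(pi) {
    if (pi <= SIGNIF_TIERS[1]) "***"
    else if (pi <= SIGNIF_TIERS[2]) "**"
    else if (pi <= SIGNIF_TIERS[3]) "*"
    else "ns"
  }, character(1))
}
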
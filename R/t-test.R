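#' One-sided pooled-variance two-sample t-test
#'
#' Tests H1: mean(experimental) > mean(control) with a Student (equal-variance)
#' independent-samples t-test, the appropriate choice when both arms are
#' generated with unit variance and equal size. The p-value is the upper tail
#' of the central t distribution with `n1 + n2 - 2` degrees of freedom.
#'
#' @param control,experimental Numeric vectors of raw observations, at least
#'   two per arm.
#' @return A list of class `t_test_result` with `t_statistic`,
#'   `degrees_of_freedom`, `p_one_sided` and `mean_difference`
#'   (experimental minus control).
#' @export
#' @examples
#' one_sided_t_test(c(0, 1, 2), c(1, 2, 3))
one_sided_t_test <- function(control, experimental) {
  stopifnot(is.numeric(control), is.numeric(experimental),
            length(control) >= 2, length(experimental) >= 2)
  if (var(control) + var(experimental) <= 0)
    stop("degenerate input: pooled variance is zero")
  tt <- t.test(experimental, control, alternative = "greater",
               var.equal = TRUE)
  structure(
    list(t_statistic = unname(tt$statistic),
         degrees_of_freedom = unname(tt$parameter),
         p_one_sided = unname(tt$p.value),
         mean_difference = mean(experimental) - mean(control)),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %g, one-sided p = %.4g (mean diff %.4f)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_one_sided,
              x$mean_difference))
  invisible(x)
}

#' Count trials significant at level alpha
#'
#' Number of p-values strictly below `alpha`; "at least two significant trials"
#' is `count_significant(p, alpha) >= 2`.
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Significance level in (0, 1).
#' @return Integer count.
#' @export
#' @examples
#' count_significant(c(0.01, 0.03, 0.2, 0.6, 0.9), 0.05)
count_significant <- function(p_values, alpha) {
  stopifnot(is.numeric(p_values), is.numeric(alpha), length(alpha) == 1,
            alpha > 0, alpha < 1)
  sum(p_values < alpha)
}

#' Analytic false positive rate of the two-of-five rule under the null
#'
#' With five independent trials of a truly null treatment, each one-sided test
#' rejects with probability `alpha`, so the probability that at least two
#' reject is `1 - ((1 - alpha)^5 + 5 * alpha * (1 - alpha)^4)`. This closed
#' form is the exact false positive rate of the "at least two significant of
#' five" endorsement rule at a clinically-meaningful threshold of zero, and
#' serves as a calibration oracle for the simulator.
#'
#' @param alpha Per-trial significance level in \[0, 1\].
#' @return Probability of at least two of five rejections under the null.
#' @export
#' @examples
#' analytic_fpr_five_trials(0.025)
analytic_fpr_five_trials <- function(alpha) {
  stopifnot(is.numeric(alpha), all(alpha >= 0), all(alpha <= 1))
  1 - ((1 - alpha)^5 + 5 * alpha * (1 - alpha)^4)
}
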
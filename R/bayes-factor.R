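#' Pool all trials of a dataset into two groups
#'
#' Concatenates the control arms of all trials into one group and the
#' experimental arms into the other, discarding trial structure — the "data of
#' all trials combined" on which the pooled Bayesian t-test operates. Under a
#' random-effects generation any between-trial heterogeneity is thereby
#' absorbed into the within-group variance.
#'
#' @param dataset A `trial_dataset` from [generate_dataset()].
#' @return A list with `control` and `experimental` numeric vectors.
#' @export
pool_trials <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  list(control = as.vector(dataset$control),
       experimental = as.vector(dataset$experimental))
}

.bf_result <- function(bf_10, prior_scale, t_statistic, n_control,
                       n_experimental, method) {
  structure(
    list(bf_10 = bf_10, prior_scale = prior_scale, t_statistic = t_statistic,
         n_control = n_control, n_experimental = n_experimental,
         method = method),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (%s%s)\n", x$bf_10, x$method,
              if (is.na(x$t_statistic)) ""
              else sprintf(", t = %.3f, n = %d/%d", x$t_statistic,
                           x$n_control, x$n_experimental)))
  invisible(x)
}

# Log marginal likelihood of the observed t statistic under a Cauchy(0, r)
# effect-size prior restricted to `support`, computed by adaptive quadrature
# on the noncentral-t likelihood:
#   m1 = int dt(t; df, ncp = delta * sqrt(neff)) * prior(delta) d delta.
# The integrand is evaluated on the log scale and rescaled by its maximum so
# that very large |t| (where the likelihood ratio overflows) stays finite.
.jzs_log_marginal <- function(t, df, neff, r,
                              support = c("positive", "real")) {
  support <- match.arg(support)
  sqrtN <- sqrt(neff)
  lognorm <- if (support == "positive") log(2) else 0  # truncation mass
  logf <- function(delta) {
    out <- suppressWarnings(dt(t, df, ncp = delta * sqrtN, log = TRUE)) +
      dcauchy(delta, 0, r, log = TRUE) + lognorm
    out[!is.finite(out)] <- -.Machine$double.xmax
    out
  }
  lo <- if (support == "positive") 0 else -Inf
  center <- t / sqrtN
  if (support == "positive") center <- max(center, 0)
  width <- 1 / sqrtN
  # locate the mode for rescaling (integrand is unimodal in delta)
  opt_lo <- if (support == "positive") 0 else center - 10 * width - 10 * r
  opt <- optimize(logf, lower = opt_lo, upper = center + 10 * width + 10 * r,
                  maximum = TRUE)
  M <- max(opt$objective, logf(center))
  g <- function(delta) exp(logf(delta) - M)
  cuts <- center + c(-10, -3, 3, 10) * width
  pieces <- if (support == "positive") {
    b <- sort(unique(pmax(cuts, 0)))
    edges <- c(0, b[b > 0], Inf)
    Map(c, edges[-length(edges)], edges[-1])
  } else {
    edges <- c(-Inf, cuts, Inf)
    Map(c, edges[-length(edges)], edges[-1])
  }
  total <- 0
  for (p in pieces) {
    if (p[1] >= p[2]) next
    int <- integrate(g, p[1], p[2], rel.tol = 1e-8, abs.tol = 1e-10,
                     subdivisions = 400L, stop.on.error = FALSE)
    ok <- int$message == "OK" ||
      grepl("roundoff error", int$message, fixed = TRUE)
    if (!ok || !is.finite(int$value) || int$value < 0)
      stop("Bayes factor quadrature failed on [", p[1], ", ", p[2], "]: ",
           int$message)
    total <- total + int$value
  }
  if (!is.finite(total) || total <= 0)
    stop("Bayes factor quadrature did not converge (t = ", t, ")")
  M + log(total)
}

#' JZS Bayes factor from a t statistic and group sizes
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor for a two-sample comparison
#' from its sufficient statistics: the pooled-variance t statistic and the two
#' group sizes. Under H1 the standardized effect follows a Cauchy prior with
#' scale `prior_scale` (default `sqrt(2)/2`), restricted to positive effects
#' for `alternative = "greater"`. The marginal likelihood under each
#' hypothesis is the (non)central-t density of the observed statistic with
#' effective sample size `n1 * n2 / (n1 + n2)`, integrated over the prior by
#' adaptive quadrature on a log scale (see Details in the package vignette).
#'
#' @param t Observed t statistic (experimental minus control orientation).
#' @param n1,n2 Control and experimental group sizes.
#' @param prior_scale Cauchy prior scale r.
#' @param alternative `"greater"` (one-sided, the default) or `"two.sided"`.
#' @return A `bf_result` whose `bf_10` is the evidence for the alternative
#'   over the point null.
#' @export
#' @examples
#' jzs_bf_from_t(2.5, 50, 50)
jzs_bf_from_t <- function(t, n1, n2, prior_scale = sqrt(2) / 2,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(t), length(t) == 1,
            is.numeric(n1), n1 >= 1, is.numeric(n2), n2 >= 1,
            is.numeric(prior_scale), prior_scale > 0)
  if (!is.finite(t)) stop("non-finite t statistic")
  df <- n1 + n2 - 2
  if (df <= 0) stop("at least 3 observations in total are required")
  neff <- n1 * n2 / (n1 + n2)
  support <- if (alternative == "greater") "positive" else "real"
  logm1 <- .jzs_log_marginal(t, df, neff, prior_scale, support)
  logm0 <- dt(t, df, log = TRUE)
  .bf_result(exp(logm1 - logm0), prior_scale, t, as.integer(n1),
             as.integer(n2),
             if (alternative == "greater") "jzs_one_sided" else "jzs_two_sided")
}

#' One-sided JZS Bayes factor for two groups of raw observations
#'
#' Convenience wrapper computing the pooled-variance t statistic from raw data
#' and passing it to [jzs_bf_from_t()]. This is the pooled Bayesian t-test
#' applied to the combined arms of all trials (see [pool_trials()]).
#'
#' @param control,experimental Numeric vectors (>= 2 observations each,
#'   non-degenerate).
#' @param prior_scale Cauchy prior scale r, default `sqrt(2)/2`.
#' @return A `bf_result`.
#' @export
#' @examples
#' set.seed(1)
#' jzs_bf_one_sided(rnorm(50), rnorm(50, 0.5))
jzs_bf_one_sided <- function(control, experimental,
                             prior_scale = sqrt(2) / 2) {
  stopifnot(length(control) >= 2, length(experimental) >= 2)
  if (var(control) + var(experimental) <= 0)
    stop("degenerate input: pooled variance is zero")
  tt <- t.test(experimental, control, alternative = "greater",
               var.equal = TRUE)
  jzs_bf_from_t(unname(tt$statistic), length(control), length(experimental),
                prior_scale = prior_scale, alternative = "greater")
}

#' Posterior probability of a positive effect under the JZS model
#'
#' `P(delta > 0 | data)` under the two-sided Cauchy prior, computed from the
#' marginal likelihoods of the two half-lines. Satisfies the identity
#' `BF10(one-sided) = BF10(two-sided) * P(delta > 0 | data) / 0.5`.
#'
#' @inheritParams jzs_bf_from_t
#' @return Probability in (0, 1).
#' @export
jzs_posterior_positive_mass <- function(t, n1, n2,
                                        prior_scale = sqrt(2) / 2) {
  df <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  # half-line marginals carry a log(2) truncation factor that cancels in the
  # ratio below
  logpos <- .jzs_log_marginal(t, df, neff, prior_scale, "positive")
  logneg <- .jzs_log_marginal(-t, df, neff, prior_scale, "positive")
  1 / (1 + exp(logneg - logpos))
}

#' Minimum Bayes factor from a p-value
#'
#' The largest evidence against the point null attainable by any alternative
#' in the "local" class, computed from the p-value alone: the bound on the
#' Bayes factor in favour of the null is `-e * p * log(p)` for `p < 1/e` and 1
#' otherwise; the returned `bf_10` is its reciprocal. The normal-alternative
#' bound `exp(-z^2/2)` (z the one-sided normal quantile of p) is available as
#' an option. Minimum Bayes factors are by construction more liberal than the
#' JZS Bayes factor for the same data.
#'
#' @param p_one_sided p-value in (0, 1).
#' @param calibration `"local"` (default, `-e p log p`) or `"normal"`
#'   (`exp(-z^2/2)`).
#' @return A `bf_result` with `method = "min_bf"`.
#' @export
#' @examples
#' min_bf(0.05)
min_bf <- function(p_one_sided, calibration = c("local", "normal")) {
  calibration <- match.arg(calibration)
  stopifnot(is.numeric(p_one_sided), length(p_one_sided) == 1)
  if (p_one_sided <= 0 || p_one_sided >= 1)
    stop("p-value must lie strictly between 0 and 1")
  bf01 <- switch(calibration,
    local = if (p_one_sided < exp(-1))
      -exp(1) * p_one_sided * log(p_one_sided) else 1,
    normal = {
      z <- qnorm(1 - p_one_sided)
      if (z > 0) exp(-z^2 / 2) else 1
    }
  )
  .bf_result(1 / bf01, NA_real_, NA_real_, NA_integer_, NA_integer_,
             "min_bf")
}

#' Endorse on the strength of a Bayes factor?
#'
#' Strictly-greater comparison of `bf_10` against an evidential threshold
#' (reference thresholds: 3, 10, 50).
#'
#' @param result A `bf_result`.
#' @param threshold Positive evidential threshold.
#' @return Logical: `bf_10 > threshold`.
#' @export
bf_decision <- function(result, threshold) {
  stopifnot(inherits(result, "bf_result"), is.numeric(threshold),
            threshold > 0)
  result$bf_10 > threshold
}
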
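# Independent oracles used across the suite. These deliberately share no code
# with the package: the t-test oracle evaluates the pooled-variance formula by
# hand, and the Bayes factor oracle integrates the Rouder-style marginal over
# a fine delta x g grid (Cauchy prior expanded as an inverse-gamma scale
# mixture of normals, Simpson quadrature), rather than adaptive quadrature on
# the Cauchy density itself.

hand_t_test <- function(control, experimental) {
  nc <- length(control); ne <- length(experimental)
  sp2 <- ((nc - 1) * var(control) + (ne - 1) * var(experimental)) /
    (nc + ne - 2)
  se <- sqrt(sp2 * (1 / nc + 1 / ne))
  t <- (mean(experimental) - mean(control)) / se
  list(t = t, df = nc + ne - 2, p = pt(t, nc + ne - 2, lower.tail = FALSE))
}

simpson_weights <- function(n) { # n odd
  w <- rep(c(4, 2), length.out = n - 2)
  c(1, w[-length(w)], 4, 1) / 3
}

# One-sided JZS Bayes factor by brute-force double quadrature.
oracle_jzs_bf <- function(t, n1, n2, r = sqrt(2) / 2,
                          n_delta = 4001, n_g = 801) {
  df <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  sqrtN <- sqrt(neff)
  u <- seq(1e-8, 1 - 1e-8, length.out = n_g)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  fg <- g^(-1.5) * exp(-1 / (2 * g)) / sqrt(2 * pi) # InvGamma(1/2, 1/2)
  wg <- simpson_weights(n_g) * (u[2] - u[1])
  prior_at <- function(d) 2 * sum(dnorm(d, 0, sqrt(g) * r) * fg * jac * wg)
  c1 <- max(0, t / sqrtN)
  wl <- 1 / sqrtN
  seg1 <- seq(0, c1 + 12 * wl, length.out = n_delta)
  seg2 <- seq(c1 + 12 * wl, max(200 * r, c1 + 50 * wl),
              length.out = n_delta)
  int_seg <- function(dgrid) {
    wts <- simpson_weights(length(dgrid)) * (dgrid[2] - dgrid[1])
    pr <- vapply(dgrid, prior_at, numeric(1))
    lik <- suppressWarnings(dt(t, df, ncp = dgrid * sqrtN))
    sum(lik * pr * wts)
  }
  (int_seg(seg1) + int_seg(seg2)) / dt(t, df)
}

# Build a trial_dataset from explicit matrices (one column per trial).
make_dataset <- function(control, experimental, delta = 0, is_null = FALSE,
                         trial_deltas = rep(delta, ncol(control))) {
  structure(
    list(control = control, experimental = experimental,
         iteration_delta = delta, trial_deltas = trial_deltas,
         is_null = is_null),
    class = "trial_dataset"
  )
}
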
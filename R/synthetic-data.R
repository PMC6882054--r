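#' Specify the population of true treatment effects
#'
#' An effect model describes how the latent standardized effect of a candidate
#' treatment is distributed across simulation iterations. With probability
#' `null_prevalence` the treatment is truly ineffective (effect exactly 0);
#' otherwise its effect is drawn from `N(effect_mean, effect_sd)`. Under a
#' random-effects variant, each individual trial of an iteration additionally
#' perturbs the iteration effect by `N(0, heterogeneity_sd)`.
#'
#' All quantities are standardized effects (units of the outcome's standard
#' deviation). The defaults are the study conditions used throughout the
#' package: real effects centred on 0.4 (small-to-moderate) with spread 0.13,
#' and no between-trial heterogeneity.
#'
#' @param null_prevalence Probability that an iteration's true effect is
#'   exactly zero. The reference grid uses 0.25, 0.50, 0.75 and 0.
#' @param effect_mean Mean of the non-null effect distribution.
#' @param effect_sd Standard deviation of the non-null effect distribution
#'   (must be positive). Negative draws are possible and are kept as-is.
#' @param heterogeneity_sd Standard deviation of trial-level effects around the
#'   iteration effect; 0 gives the fixed-effects model, the random-effects
#'   sensitivity variant uses 0.1.
#' @return An object of class `effect_model`.
#' @seealso [sim_config()], [draw_iteration_effect()]
#' @export
#' @examples
#' effect_model(null_prevalence = 0.5)
effect_model <- function(null_prevalence = 0.25, effect_mean = 0.4,
                         effect_sd = 0.13, heterogeneity_sd = 0) {
  stopifnot(
    is.numeric(null_prevalence), length(null_prevalence) == 1,
    null_prevalence >= 0, null_prevalence <= 1,
    is.numeric(effect_mean), length(effect_mean) == 1,
    is.numeric(effect_sd), length(effect_sd) == 1, effect_sd > 0,
    is.numeric(heterogeneity_sd), length(heterogeneity_sd) == 1,
    heterogeneity_sd >= 0
  )
  structure(
    list(null_prevalence = null_prevalence, effect_mean = effect_mean,
         effect_sd = effect_sd, heterogeneity_sd = heterogeneity_sd),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat("Effect model: P(null) =", x$null_prevalence,
      "| non-null ~ N(", x$effect_mean, ",", x$effect_sd, ")",
      if (x$heterogeneity_sd > 0)
        paste0("| trial effects ~ N(delta, ", x$heterogeneity_sd, ")")
      else "| fixed trial effects", "\n")
  invisible(x)
}

#' Configure one simulation cell
#'
#' Bundles an [effect_model()] with the design of a simulation cell: the
#' per-arm sample size, the number of trials per iteration, the number of
#' Monte-Carlo replications and the root seed.
#'
#' The root seed spawns one reproducible substream per replication: null/no-null
#' assignment uses a dedicated stream of uniforms, so that across configurations
#' differing only in `null_prevalence` the non-null iterations (and their raw
#' data) are shared, which removes Monte-Carlo noise from prevalence
#' comparisons.
#'
#' @param effect_model An [effect_model()].
#' @param n_per_arm Participants per arm per trial (>= 2). Reference grid:
#'   20, 50, 100, 400.
#' @param n_trials Number of trials per iteration (>= 1). Reference grid:
#'   2, 3, 5.
#' @param n_replications Monte-Carlo replications (the reference scale is 2000
#'   per simulation type).
#' @param seed Integer root seed.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' sim_config(effect_model(), n_per_arm = 20, n_trials = 5,
#'            n_replications = 100, seed = 1)
sim_config <- function(effect_model, n_per_arm = 20, n_trials = 5,
                       n_replications = 2000, seed = 1) {
  stopifnot(
    inherits(effect_model, "effect_model"),
    is.numeric(n_per_arm), length(n_per_arm) == 1, n_per_arm >= 2,
    n_per_arm == round(n_per_arm),
    is.numeric(n_trials), length(n_trials) == 1, n_trials >= 1,
    n_trials == round(n_trials),
    is.numeric(n_replications), length(n_replications) == 1,
    n_replications >= 1, n_replications == round(n_replications),
    is.numeric(seed), length(seed) == 1, is.finite(seed)
  )
  structure(
    list(effect_model = effect_model, n_per_arm = as.integer(n_per_arm),
         n_trials = as.integer(n_trials),
         n_replications = as.integer(n_replications), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation cell:", x$n_trials, "trials x", x$n_per_arm, "per arm,",
      x$n_replications, "replications, seed", x$seed, "\n")
  print(x$effect_model)
  invisible(x)
}

#' Draw the latent effect of one iteration
#'
#' Draws from the null/non-null mixture of an [effect_model()]: with
#' probability `null_prevalence` the effect is exactly 0 (and flagged as null),
#' otherwise it is a `N(effect_mean, effect_sd)` draw. The flag, not a
#' floating-point comparison, is what downstream truth labels use; the exact
#' zero is unambiguous because the continuous alternative has zero mass at 0.
#'
#' @param model An [effect_model()].
#' @param u Optional uniform variate deciding null vs non-null; by default one
#'   is drawn from the current RNG. Supplying it lets a caller decide the
#'   mixture component on a separate stream (see [sim_config()]).
#' @return A list with `delta` (the standardized effect) and `is_null`.
#' @export
#' @examples
#' set.seed(1)
#' draw_iteration_effect(effect_model(null_prevalence = 0.5))
draw_iteration_effect <- function(model, u = NULL) {
  stopifnot(inherits(model, "effect_model"))
  if (is.null(u)) u <- runif(1)
  if (u < model$null_prevalence) {
    list(delta = 0, is_null = TRUE)
  } else {
    list(delta = rnorm(1, model$effect_mean, model$effect_sd), is_null = FALSE)
  }
}

#' Generate the raw data of one iteration's trials
#'
#' Given the iteration-level effect, draws the trial-level effects (identical
#' to the iteration effect under fixed effects, `N(delta, heterogeneity_sd)`
#' under random effects), then for each trial `n_per_arm` control observations
#' from `N(0, 1)` and `n_per_arm` experimental observations from
#' `N(delta_i, 1)`. Uses the current RNG state; deterministic given it.
#'
#' @param config A [sim_config()].
#' @param iteration_delta Standardized effect of the iteration, as produced by
#'   [draw_iteration_effect()].
#' @param is_null Whether the iteration is a true null (carried through to
#'   truth labels).
#' @return An object of class `trial_dataset`: a list with `control` and
#'   `experimental` (`n_per_arm` x `n_trials` matrices, one column per trial),
#'   `iteration_delta`, `trial_deltas`, and `is_null`.
#' @export
#' @examples
#' cfg <- sim_config(effect_model(), n_per_arm = 20, n_trials = 5)
#' set.seed(7)
#' ds <- generate_dataset(cfg, iteration_delta = 0.4)
#' dim(ds$control)
generate_dataset <- function(config, iteration_delta, is_null = FALSE) {
  stopifnot(inherits(config, "sim_config"),
            is.numeric(iteration_delta), length(iteration_delta) == 1)
  if (config$n_per_arm < 2)
    stop("n_per_arm must be at least 2 to estimate within-trial variance")
  k <- config$n_trials
  n <- config$n_per_arm
  het <- config$effect_model$heterogeneity_sd
  trial_deltas <- if (het > 0) rnorm(k, iteration_delta, het)
                  else rep(iteration_delta, k)
  control <- matrix(rnorm(n * k), nrow = n, ncol = k)
  experimental <- matrix(rnorm(n * k, mean = rep(trial_deltas, each = n)),
                         nrow = n, ncol = k)
  structure(
    list(control = control, experimental = experimental,
         iteration_delta = iteration_delta, trial_deltas = trial_deltas,
         is_null = isTRUE(is_null)),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Trial dataset:", ncol(x$control), "trials x", nrow(x$control),
      "per arm; iteration effect", format(x$iteration_delta, digits = 4),
      if (x$is_null) "(true null)" else "", "\n")
  invisible(x)
}

# Per-replication substreams: the root seed fixes (a) a stream of uniforms
# deciding null vs non-null and (b) one sub-seed per replication driving the
# effect draw and the raw data. Configurations sharing a root seed but
# differing in null_prevalence therefore share their non-null iterations.
.iteration_streams <- function(config) {
  set.seed(config$seed)
  R <- config$n_replications
  list(u = runif(R), sub_seeds = sample.int(.Machine$integer.max, R))
}

.generate_iteration <- function(config, u, sub_seed) {
  set.seed(sub_seed)
  eff <- draw_iteration_effect(config$effect_model, u = u)
  generate_dataset(config, eff$delta, is_null = eff$is_null)
}

#' Generate a reproducible batch of simulated iterations
#'
#' Produces `n_replications` independent [trial datasets][generate_dataset]
#' under the configuration's effect model, reproducible from the root seed
#' (see [sim_config()] for the substream policy).
#'
#' @param config A [sim_config()].
#' @return A list of `trial_dataset` objects of length `n_replications`.
#' @export
#' @examples
#' cfg <- sim_config(effect_model(), n_per_arm = 20, n_trials = 2,
#'                   n_replications = 3, seed = 42)
#' batch <- generate_batch(cfg)
#' vapply(batch, function(d) d$iteration_delta, numeric(1))
generate_batch <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  streams <- .iteration_streams(config)
  lapply(seq_len(config$n_replications), function(i) {
    .generate_iteration(config, streams$u[i], streams$sub_seeds[i])
  })
}

#' Export a batch as a tidy per-trial table
#'
#' Flattens a batch into one row per trial per iteration with the latent truth
#' and per-arm summary statistics, suitable for audit or for re-analysis with
#' [meta_analyze_summaries()].
#'
#' @param batch A list of `trial_dataset` objects from [generate_batch()].
#' @param file Optional path; when given, the table is also written as
#'   tab-separated text.
#' @return A data frame with columns `iteration`, `trial`, `delta`,
#'   `trial_delta`, `is_null`, `mean_c`, `sd_c`, `n_c`, `mean_e`, `sd_e`,
#'   `n_e`, invisibly when `file` is given.
#' @export
batch_to_table <- function(batch, file = NULL) {
  rows <- lapply(seq_along(batch), function(i) {
    d <- batch[[i]]
    k <- ncol(d$control)
    data.frame(
      iteration = i, trial = seq_len(k),
      delta = d$iteration_delta, trial_delta = d$trial_deltas,
      is_null = d$is_null,
      mean_c = colMeans(d$control), sd_c = apply(d$control, 2, stats::sd),
      n_c = nrow(d$control),
      mean_e = colMeans(d$experimental),
      sd_e = apply(d$experimental, 2, stats::sd),
      n_e = nrow(d$experimental)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a simulation configuration from a YAML file
#'
#' Accepts a flat YAML mapping with any of the fields `null_prevalence`,
#' `effect_mean`, `effect_sd`, `heterogeneity_sd`, `n_per_arm`, `n_trials`,
#' `n_replications`, `seed`; missing fields fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  em <- effect_model(
    null_prevalence = y$null_prevalence %||% 0.25,
    effect_mean = y$effect_mean %||% 0.4,
    effect_sd = y$effect_sd %||% 0.13,
    heterogeneity_sd = y$heterogeneity_sd %||% 0
  )
  sim_config(em,
             n_per_arm = y$n_per_arm %||% 20,
             n_trials = y$n_trials %||% 5,
             n_replications = y$n_replications %||% 2000,
             seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
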
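#' Bundle the decision criteria to evaluate
#'
#' Collects the evidential rules applied to every simulated iteration:
#' at-least-`min_significant` individually significant trials (per one-sided
#' alpha level), a positive lower bound of each requested meta-analytic 95%
#' CI, and pooled-data Bayes factors (JZS and minimum) above each evidential
#' threshold.
#'
#' The reference settings are those of the main analysis: one-sided
#' `alpha = 0.025` (a two-sided 0.05 test followed by a direction check),
#' Bayes factor thresholds 3, 10 and 50, Cauchy prior scale `sqrt(2)/2`;
#' alphas 0.05 and 0.005 are the sensitivity variants.
#'
#' @param alphas One-sided significance levels for the trial-counting rule.
#' @param min_significant Number of individually significant trials required
#'   (the classical benchmark requires 2).
#' @param bf_thresholds Evidential thresholds applied to both Bayes factor
#'   families.
#' @param prior_scale Cauchy prior scale of the JZS Bayes factor.
#' @param families Criterion families to evaluate; any subset of
#'   `"significance"`, `"fixed_ci"`, `"dsl_ci"`, `"hksj_ci"`, `"jzs_bf"`,
#'   `"min_bf"`.
#' @param min_bf_calibration Calibration used by [min_bf()].
#' @param hedges_correction Apply Hedges' correction in trial summaries.
#' @return An object of class `endorsement_criteria`.
#' @export
endorsement_criteria <- function(alphas = 0.025, min_significant = 2,
                                 bf_thresholds = c(3, 10, 50),
                                 prior_scale = sqrt(2) / 2,
                                 families = c("significance", "fixed_ci",
                                              "dsl_ci", "hksj_ci", "jzs_bf",
                                              "min_bf"),
                                 min_bf_calibration = "local",
                                 hedges_correction = FALSE) {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(all(alphas > 0 & alphas < 1), all(bf_thresholds > 0),
            min_significant >= 1, prior_scale > 0)
  structure(
    list(alphas = alphas, min_significant = min_significant,
         bf_thresholds = bf_thresholds, prior_scale = prior_scale,
         families = families, min_bf_calibration = min_bf_calibration,
         hedges_correction = hedges_correction),
    class = "endorsement_criteria"
  )
}

.criterion_names <- function(settings) {
  out <- character(0)
  f <- settings$families
  if ("significance" %in% f)
    out <- c(out, paste0("signif_", settings$alphas))
  for (m in c("fixed_ci", "dsl_ci", "hksj_ci")) if (m %in% f)
    out <- c(out, m)
  if ("jzs_bf" %in% f)
    out <- c(out, paste0("jzs_bf_", settings$bf_thresholds))
  if ("min_bf" %in% f)
    out <- c(out, paste0("min_bf_", settings$bf_thresholds))
  out
}

#' Apply every configured criterion to one iteration
#'
#' Runs the per-trial one-sided t-tests, the requested meta-analytic CIs on
#' the trial summaries, and the pooled-data Bayes factors, then records one
#' boolean endorsement decision per criterion: significance-count positive iff
#' at least `min_significant` trials have `p < alpha`; CI criteria positive
#' iff the interval's lower bound exceeds zero; Bayes factor criteria positive
#' iff `bf_10` exceeds the threshold (all strict).
#'
#' @param dataset A `trial_dataset` (at least 2 trials for the meta-analytic
#'   criteria).
#' @param settings An [endorsement_criteria()].
#' @param iteration Optional iteration id attached to the record (and to any
#'   degenerate-input error).
#' @return A list of class `decision_record` with `iteration`, `truth_delta`,
#'   `is_null`, the named logical vector `decisions`, and `details`
#'   (p-values, meta results, Bayes factors).
#' @export
apply_criteria <- function(dataset, settings = endorsement_criteria(),
                           iteration = NA_integer_) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(settings, "endorsement_criteria"))
  k <- ncol(dataset$control)
  f <- settings$families
  needs_meta <- any(c("fixed_ci", "dsl_ci", "hksj_ci") %in% f)
  if (needs_meta && k < 2)
    stop("meta-analytic criteria need at least 2 trials (iteration ",
         iteration, ")")
  decisions <- logical(0)
  details <- list()
  res <- tryCatch({
    if ("significance" %in% f) {
      p_values <- vapply(seq_len(k), function(i)
        one_sided_t_test(dataset$control[, i],
                         dataset$experimental[, i])$p_one_sided,
        numeric(1))
      details$p_values <- p_values
      for (a in settings$alphas) {
        decisions[paste0("signif_", a)] <-
          count_significant(p_values, a) >= settings$min_significant
      }
    }
    if (needs_meta) {
      studies <- summarize_trials(dataset,
                                  hedges_correction =
                                    settings$hedges_correction)
      details$studies <- studies
      for (m in c("fixed_ci", "dsl_ci", "hksj_ci")) if (m %in% f) {
        mr <- switch(m, fixed_ci = fixed_effect_ci(studies),
                     dsl_ci = dsl_ci(studies), hksj_ci = hksj_ci(studies))
        details[[m]] <- mr
        decisions[m] <- mr$ci_lower > 0
      }
    }
    if (any(c("jzs_bf", "min_bf") %in% f)) {
      pooled <- pool_trials(dataset)
      if ("jzs_bf" %in% f) {
        bf <- jzs_bf_one_sided(pooled$control, pooled$experimental,
                               prior_scale = settings$prior_scale)
        details$jzs_bf <- bf
        for (th in settings$bf_thresholds)
          decisions[paste0("jzs_bf_", th)] <- bf_decision(bf, th)
      }
      if ("min_bf" %in% f) {
        p_pooled <- one_sided_t_test(pooled$control,
                                     pooled$experimental)$p_one_sided
        mbf <- min_bf(p_pooled, calibration = settings$min_bf_calibration)
        details$min_bf <- mbf
        for (th in settings$bf_thresholds)
          decisions[paste0("min_bf_", th)] <- bf_decision(mbf, th)
      }
    }
    list(decisions = decisions, details = details)
  }, error = function(e) {
    stop("iteration ", iteration, ": ", conditionMessage(e), call. = FALSE)
  })
  structure(
    list(iteration = iteration, truth_delta = dataset$iteration_delta,
         is_null = dataset$is_null, decisions = res$decisions,
         details = res$details),
    class = "decision_record"
  )
}

#' Classify one iteration's decisions against a clinical threshold
#'
#' The truth label is positive iff the iteration's true effect strictly
#' exceeds the clinically meaningful threshold `delta` (a true null never
#' does, for any `delta >= 0`). Each criterion's decision is then crossed with
#' the truth label into TP/FP/TN/FN. Decisions themselves do not depend on
#' `delta`; only the labels do.
#'
#' @param record A `decision_record` from [apply_criteria()].
#' @param clinical_threshold Standardized-effect threshold (reference grid:
#'   0, 0.15, 0.3, 0.45).
#' @return A named character vector over criteria with values `"TP"`, `"FP"`,
#'   `"TN"`, `"FN"`.
#' @export
classify <- function(record, clinical_threshold) {
  stopifnot(inherits(record, "decision_record"),
            is.numeric(clinical_threshold), length(clinical_threshold) == 1)
  truth_positive <- !record$is_null &&
    record$truth_delta > clinical_threshold
  dec <- record$decisions
  out <- ifelse(dec,
                ifelse(truth_positive, "TP", "FP"),
                ifelse(truth_positive, "FN", "TN"))
  names(out) <- names(dec)
  out
}

#' Aggregate decision records into TPR/FPR tables
#'
#' Counts TP/FP/TN/FN per criterion and clinical threshold over a set of
#' records, and derives the true positive rate `tp / (tp + fn)` and false
#' positive rate `fp / (fp + tn)`. A rate whose denominator is zero (e.g. the
#' TPR of an all-null batch) is reported as `NA`.
#'
#' @param records List of `decision_record`s sharing the same criteria.
#' @param clinical_thresholds Numeric vector of thresholds.
#' @return A data frame with columns `criterion`, `clinical_threshold`, `tp`,
#'   `fp`, `tn`, `fn`, `tpr`, `fpr`.
#' @export
aggregate_outcomes <- function(records,
                               clinical_thresholds = c(0, 0.15, 0.3, 0.45)) {
  if (length(records) == 0) stop("no records to aggregate")
  crit <- names(records[[1]]$decisions)
  dec <- vapply(records, function(r) r$decisions[crit],
                logical(length(crit)))
  dec <- if (is.matrix(dec)) t(dec) else matrix(dec, ncol = 1)
  colnames(dec) <- crit
  truth <- vapply(records, `[[`, numeric(1), "truth_delta")
  is_null <- vapply(records, `[[`, logical(1), "is_null")
  out <- list()
  for (delta in clinical_thresholds) {
    pos <- !is_null & truth > delta
    for (cn in crit) {
      d <- dec[, cn]
      tp <- sum(d & pos); fp <- sum(d & !pos)
      fn <- sum(!d & pos); tn <- sum(!d & !pos)
      out[[length(out) + 1L]] <- data.frame(
        criterion = cn, clinical_threshold = delta,
        tp = tp, fp = fp, tn = tn, fn = fn,
        tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate one cell and evaluate all criteria
#'
#' Generates `n_replications` iterations under `config` (using the
#' reproducible substream policy of [sim_config()]), applies the configured
#' criteria to each, and aggregates TPR/FPR over the clinical thresholds.
#'
#' @param config A [sim_config()].
#' @param settings An [endorsement_criteria()].
#' @param clinical_thresholds Thresholds passed to [aggregate_outcomes()].
#' @param keep_records Also return the per-iteration `decision_record`s.
#' @return A list with `outcomes` (data frame) and, if requested, `records`.
#' @export
run_simulation <- function(config, settings = endorsement_criteria(),
                           clinical_thresholds = c(0, 0.15, 0.3, 0.45),
                           keep_records = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  streams <- .iteration_streams(config)
  records <- lapply(seq_len(config$n_replications), function(i) {
    ds <- .generate_iteration(config, streams$u[i], streams$sub_seeds[i])
    apply_criteria(ds, settings, iteration = i)
  })
  out <- list(outcomes = aggregate_outcomes(records, clinical_thresholds),
              config = config)
  if (keep_records) out$records <- records
  out
}

#' Run the full simulation grid
#'
#' Crosses null prevalences with per-arm sample sizes (the reference grid is
#' 25/50/75/0% prevalence by n = 20/50/100/400, five trials, 2000
#' replications per cell) and returns one tidy row per criterion, clinical
#' threshold and cell. Each cell uses root seed `seed + offset` with a fixed
#' offset per cell position, so a grid is fully reproducible from one seed,
#' and cells differing only in prevalence share their non-null iterations.
#'
#' @param prevalences Null-effect prevalences.
#' @param n_per_arm Per-arm sample sizes.
#' @param n_trials Trials per iteration.
#' @param n_replications Replications per cell.
#' @param effect_mean,effect_sd,heterogeneity_sd Passed to [effect_model()].
#' @param settings An [endorsement_criteria()].
#' @param clinical_thresholds Thresholds for truth labels.
#' @param seed Root seed for the whole grid.
#' @param output_dir Optional directory; when given, writes `outcomes.csv`
#'   and a `manifest.json` recording the configuration.
#' @return A data frame of outcomes with cell columns `null_prevalence`,
#'   `n_per_arm`, `n_trials` prepended.
#' @export
run_grid <- function(prevalences = c(0.25, 0.5, 0.75, 0),
                     n_per_arm = c(20, 50, 100, 400),
                     n_trials = 5, n_replications = 2000,
                     effect_mean = 0.4, effect_sd = 0.13,
                     heterogeneity_sd = 0,
                     settings = endorsement_criteria(),
                     clinical_thresholds = c(0, 0.15, 0.3, 0.45),
                     seed = 1, output_dir = NULL) {
  cells <- expand.grid(prev = prevalences, n = n_per_arm)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    em <- effect_model(null_prevalence = cells$prev[i],
                       effect_mean = effect_mean, effect_sd = effect_sd,
                       heterogeneity_sd = heterogeneity_sd)
    # one sub-seed per n so prevalence-only cells share non-null substreams
    cell_seed <- seed + 1000L * match(cells$n[i], n_per_arm)
    cfg <- sim_config(em, n_per_arm = cells$n[i], n_trials = n_trials,
                      n_replications = n_replications, seed = cell_seed)
    res <- run_simulation(cfg, settings, clinical_thresholds)
    cbind(null_prevalence = cells$prev[i], n_per_arm = cells$n[i],
          n_trials = n_trials, res$outcomes)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(output_dir, "outcomes.csv"),
                     row.names = FALSE)
    manifest <- list(
      prevalences = prevalences, n_per_arm = n_per_arm,
      n_trials = n_trials, n_replications = n_replications,
      effect_mean = effect_mean, effect_sd = effect_sd,
      heterogeneity_sd = heterogeneity_sd,
      clinical_thresholds = clinical_thresholds, seed = seed,
      criteria = .criterion_names(settings),
      package_version = as.character(utils::packageVersion("endorsim")),
      r_version = R.version.string
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Coverage of the meta-analytic intervals across the simulation grid
#'
#' For each per-arm sample size, simulates iterations pooled over the given
#' null prevalences, computes the three meta-analytic 95% CIs per iteration,
#' and records the proportion of intervals containing the iteration's true
#' effect (a true null contributes a target of zero). Only the meta-analytic
#' machinery runs here, so the study is fast even at the reference scale.
#'
#' @param n_per_arm Per-arm sample sizes (columns of the resulting table).
#' @param n_trials Trials per iteration.
#' @param reps_per_set Replications per prevalence set (the reference scale is
#'   2000); each (n, prevalence) pair contributes this many iterations.
#' @param prevalences Null prevalences pooled into each column.
#' @param effect_mean,effect_sd,heterogeneity_sd Passed to [effect_model()].
#' @param seed Root seed.
#' @param hedges_correction Apply Hedges' correction to the trial summaries.
#' @return A data frame with columns `method`, `n_per_arm`, `coverage`,
#'   `n_iterations`.
#' @export
#' @examples
#' coverage_study(n_per_arm = 20, reps_per_set = 50, seed = 1)
coverage_study <- function(n_per_arm = c(20, 50, 100, 400), n_trials = 5,
                           reps_per_set = 2000,
                           prevalences = c(0.25, 0.5, 0.75, 0),
                           effect_mean = 0.4, effect_sd = 0.13,
                           heterogeneity_sd = 0, seed = 1,
                           hedges_correction = FALSE) {
  methods <- c("fixed", "DSL", "HKSJ")
  rows <- list()
  for (n in n_per_arm) {
    hits <- c(fixed = 0, DSL = 0, HKSJ = 0)
    total <- 0L
    for (prev in prevalences) {
      em <- effect_model(null_prevalence = prev, effect_mean = effect_mean,
                         effect_sd = effect_sd,
                         heterogeneity_sd = heterogeneity_sd)
      # every (n, prevalence) set gets its own substream so that pooling the
      # sets yields genuinely independent iterations
      cfg <- sim_config(em, n_per_arm = n, n_trials = n_trials,
                        n_replications = reps_per_set,
                        seed = seed + 1000L * match(n, n_per_arm) +
                          match(prev, prevalences))
      streams <- .iteration_streams(cfg)
      for (i in seq_len(reps_per_set)) {
        ds <- .generate_iteration(cfg, streams$u[i], streams$sub_seeds[i])
        studies <- summarize_trials(ds,
                                    hedges_correction = hedges_correction)
        truth <- ds$iteration_delta
        if (ci_covers(fixed_effect_ci(studies), truth))
          hits["fixed"] <- hits["fixed"] + 1
        if (ci_covers(dsl_ci(studies), truth))
          hits["DSL"] <- hits["DSL"] + 1
        if (ci_covers(hksj_ci(studies), truth))
          hits["HKSJ"] <- hits["HKSJ"] + 1
        total <- total + 1L
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      method = methods, n_per_arm = n, coverage = unname(hits[methods]),
      n_iterations = total
    )
    rows[[length(rows)]]$coverage <- rows[[length(rows)]]$coverage / total
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a coverage study into a method-by-n table
#'
#' @param coverage A data frame from [coverage_study()].
#' @return A matrix with one row per method and one column per sample size.
#' @export
coverage_table <- function(coverage) {
  ns <- sort(unique(coverage$n_per_arm))
  methods <- c("fixed", "DSL", "HKSJ")
  m <- matrix(NA_real_, length(methods), length(ns),
              dimnames = list(methods, paste0("n=", ns)))
  for (i in seq_len(nrow(coverage)))
    m[coverage$method[i], paste0("n=", coverage$n_per_arm[i])] <-
      coverage$coverage[i]
  m
}
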
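#' Bootstrap confidence interval for a policy value
#'
#' Nonparametric bootstrap of the whole pipeline: subjects are resampled
#' with replacement *within each cohort* (preserving the natural-history /
#' transplanted two-sample design and cohort sizes), the multistate model
#' is refitted on each replicate, and the policy value recomputed. The
#' interval is the percentile interval over successful replicates.
#'
#' @param cohorts list of [mds_cohort()] objects.
#' @param state_space a [build_state_space()] object.
#' @param policy a [transplant_policy()].
#' @param utilities an [default_utilities()] object or `NULL`.
#' @param B number of bootstrap replicates (`>= 1`).
#' @param seed integer seed; the full replicate vector is reproducible.
#' @param value one of `"gain"` (default; gain vs no transplantation),
#'   `"life_expectancy"`, `"qaly"`.
#' @param fit_options passed to [fit_model()] (the replicate refits skip
#'   the Hessian).
#' @return Object of class `bootstrap_ci`: list with `point` (full-data
#'   estimate), `replicates` (numeric vector, `NA` for failed refits),
#'   `ci` (2.5% and 97.5% percentiles), `n_failed`, `flagged` (TRUE when
#'   more than 20% of refits failed), `seed`.
#' @export
bootstrap_policy_ci <- function(cohorts, state_space, policy, utilities = NULL,
                                B = 200, seed = 1, value = c("gain",
                                "life_expectancy", "qaly"),
                                fit_options = list()) {
  if (B < 1) stop("B must be >= 1")
  value <- match.arg(value)
  if (inherits(cohorts, "mds_cohort")) cohorts <- list(cohorts)
  fit_options$hessian <- FALSE

  eval_value <- function(fit) {
    pv <- policy_expected_survival(fit, policy, utilities)
    switch(value, gain = pv$gain_vs_no_transplant,
           life_expectancy = pv$life_expectancy, qaly = pv$qaly)
  }
  full_fit <- fit_model(cohorts, state_space, options = fit_options)
  point <- eval_value(full_fit)
  # warm-start replicate refits at the full-data MLE
  init <- list(q = full_fit$q_hat, effects = full_fit$effects_hat)

  subj <- lapply(cohorts, function(co) split(seq_len(nrow(co)), co$subject_id))
  set.seed(seed)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    boot <- vector("list", length(cohorts))
    for (ci in seq_along(cohorts)) {
      ids <- sample(length(subj[[ci]]), replace = TRUE)
      pieces <- lapply(seq_along(ids), function(k) {
        df <- as.data.frame(cohorts[[ci]])[subj[[ci]][[ids[k]]], , drop = FALSE]
        df$subject_id <- sprintf("B%d_%d", ci, k)
        df
      })
      boot[[ci]] <- mds_cohort(do.call(rbind, pieces), state_space$scheme,
                               attr(cohorts[[ci]], "label"))
    }
    reps[b] <- tryCatch({
      f <- fit_model(boot, state_space, init = init, options = fit_options)
      if (!f$convergence) NA_real_ else eval_value(f)
    }, error = function(e) NA_real_)
  }
  ok <- reps[!is.na(reps)]
  if (!length(ok)) stop("all bootstrap refits failed")
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(point = point, replicates = reps,
                 ci = c(lower = ci[1], upper = ci[2]),
                 n_failed = sum(is.na(reps)),
                 flagged = sum(is.na(reps)) > 0.2 * B, seed = seed,
                 value = value),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("Bootstrap %s: point %.3f, 95%% CI (%.3f, %.3f), %d/%d replicates failed%s\n",
              x$value, x$point, x$ci[1], x$ci[2], x$n_failed,
              length(x$replicates), if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}
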
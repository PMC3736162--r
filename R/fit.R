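#' Fit the multistate model by maximum likelihood
#'
#' Maximizes the joint panel-data likelihood ([cohort_log_likelihood()])
#' over the log transition intensities and, when any subject contributes
#' post-transplant follow-up, the log hazard ratios of post-HSCT mortality.
#' Parameters live on the log scale (positivity enforced by construction);
#' optimization uses BFGS with finite-difference gradients, which is ample
#' at this dimension (at most 20 parameters). The covariance of the log
#' parameters is the inverse of the numerically evaluated Hessian at the
#' maximum.
#'
#' Transitions with no directly observed events in the data get a boundary
#' warning attached to the result (their intensities drift to the boundary
#' and are not meaningfully estimated), as do fitted intensities below
#' `1e-6`/yr.
#'
#' @param cohorts an [mds_cohort()] or list of them.
#' @param state_space a [build_state_space()] object.
#' @param init optional list with elements `q` (generator) and `effects`
#'   ([transplant_effects()]) used as the starting point; by default crude
#'   event/person-time rates seed the intensities and all hazard ratios
#'   start at 1.
#' @param options list: `maxit` (default 500), `reltol` (default 1e-8 on
#'   the objective; convergence in practice is governed by the gradient),
#'   `ndeps` (finite-difference step, default 1e-5), `hessian` (default
#'   TRUE, compute covariance).
#' @return Object of class `mds_fit` with elements `state_space`, `q_hat`,
#'   `effects_hat` (or NULL), `covariance`, `log_likelihood`, `n_subjects`,
#'   `n_transitions` (number of likelihood intervals), `convergence`
#'   (logical), `par`, `par_names`, `warnings`, `optim_details`.
#'   Non-convergence is flagged, not an error.
#' @export
fit_model <- function(cohorts, state_space, init = NULL, options = list()) {
  opts <- utils::modifyList(list(maxit = 500L, reltol = 1e-8, ndeps = 1e-5,
                          hessian = TRUE), options)
  if (inherits(cohorts, "mds_cohort")) cohorts <- list(cohorts)
  iv <- .cohort_intervals(cohorts, state_space)
  if (is.null(iv$plain) && is.null(iv$switch)) stop("no likelihood intervals in cohorts")
  has_post <- (!is.null(iv$plain) && any(iv$plain$cov == 1L)) || !is.null(iv$switch)
  cl <- .collapse_intervals(iv)

  al <- state_space$allowed
  n_q <- nrow(al)
  tp <- state_space$transplantable
  n_b <- if (has_post) length(tp) else 0L
  par_names <- c(transition_labels(state_space),
                 if (n_b) paste0("logHR:", state_space$states[tp]))

  crude <- .crude_rates(cohorts, state_space)
  if (is.null(init)) {
    start <- c(log(pmax(crude$rate, 1e-3)), rep(0, n_b))
  } else {
    start <- c(log(pmax(init$q[al], 1e-8)),
               if (n_b) {
                 if (is.null(init$effects)) rep(0, n_b)
                 else unname(init$effects$log_hr)
               })
  }

  build_q <- function(par) {
    q <- matrix(0, state_space$n_states, state_space$n_states,
                dimnames = list(state_space$states, state_space$states))
    q[al] <- exp(par[seq_len(n_q)])
    diag(q) <- -rowSums(q)
    q
  }
  build_eff <- function(par) {
    if (!n_b) return(NULL)
    transplant_effects(state_space,
                       stats::setNames(par[n_q + seq_len(n_b)], state_space$states[tp]))
  }
  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    q <- build_q(par)
    q_post <- if (n_b) apply_transplant_effects(q, state_space, build_eff(par)) else q
    -.loglik_collapsed(cl, q, q_post, state_space)
  }

  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = opts$maxit, reltol = opts$reltol,
                                     ndeps = rep(opts$ndeps, length(start))))
  cov <- NULL
  if (isTRUE(opts$hessian)) {
    h <- stats::optimHess(opt$par, negll)
    cov <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(cov)) {
      cov <- (cov + t(cov)) / 2
      if (any(!is.finite(cov)) || any(diag(cov) < 0)) cov <- NULL
    }
  }

  q_hat <- build_q(opt$par)
  warn <- character(0)
  zero_ev <- crude$events == 0
  if (any(zero_ev))
    warn <- c(warn, sprintf("no observed events for transition %s; intensity at boundary",
                            transition_labels(state_space)[zero_ev]))
  tiny <- q_hat[al] < 1e-6 & !zero_ev
  if (any(tiny))
    warn <- c(warn, sprintf("fitted intensity for %s is at the boundary (< 1e-6/yr)",
                            transition_labels(state_space)[tiny]))
  n_subj <- sum(vapply(cohorts, function(co) length(unique(co$subject_id)), 0))
  n_int <- (if (is.null(iv$plain)) 0L else nrow(iv$plain)) +
    (if (is.null(iv$switch)) 0L else nrow(iv$switch))

  structure(list(state_space = state_space, q_hat = q_hat,
                 effects_hat = build_eff(opt$par), covariance = cov,
                 log_likelihood = -opt$value, n_subjects = n_subj,
                 n_transitions = n_int, convergence = opt$convergence == 0,
                 par = stats::setNames(opt$par, par_names), par_names = par_names,
                 warnings = warn,
                 optim_details = opt[c("convergence", "counts", "message")]),
            class = "mds_fit")
}

# crude per-transition event counts and rates (events / person-time), used
# for starting values and boundary diagnostics. Person-time is attributed
# to the interval's starting state; progression events are counted from
# directly observed adjacent state pairs, deaths from the last living state.
.crude_rates <- function(cohorts, state_space) {
  al <- state_space$allowed
  events <- numeric(nrow(al))
  ptime <- numeric(state_space$n_states)
  for (co in cohorts) {
    idx <- match(co$state, state_space$states)
    sp <- split(seq_len(nrow(co)), co$subject_id)
    for (rows in sp) {
      tt <- co$time_years[rows]; st <- idx[rows]; kd <- co$kind[rows]
      for (k in seq_along(rows)[-1]) {
        ptime[st[k - 1L]] <- ptime[st[k - 1L]] + (tt[k] - tt[k - 1L])
        if (kd[k] == "death") {
          r <- which(al[, 1L] == st[k - 1L] & al[, 2L] == state_space$death)
          events[r] <- events[r] + 1
        } else if (st[k] != st[k - 1L]) {
          r <- which(al[, 1L] == st[k - 1L] & al[, 2L] == st[k])
          if (length(r)) events[r] <- events[r] + 1
        }
      }
    }
  }
  rate <- (events + 0.5) / pmax(ptime[al[, 1L]], 1)
  list(events = events, ptime = ptime, rate = rate)
}

#' @export
print.mds_fit <- function(x, ...) {
  cat(sprintf("Multistate model fit (%s): %d subjects, %d intervals\n",
              x$state_space$scheme, x$n_subjects, x$n_transitions))
  cat(sprintf("log-likelihood %.3f; %s\n", x$log_likelihood,
              if (x$convergence) "converged" else "NOT converged"))
  cat("Transition intensities (/yr):\n")
  print(round(x$q_hat, 4))
  if (!is.null(x$effects_hat)) {
    cat("Post-HSCT mortality hazard ratios:\n")
    print(round(exp(x$effects_hat$log_hr), 3))
  }
  if (length(x$warnings)) cat("Warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Hazard ratios of post-HSCT mortality with Wald confidence intervals
#'
#' @param fitted an [fit_model()] result with transplant effects.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `state`, `hr`, `lower`, `upper`
#'   (CI columns `NA` when no covariance is available).
#' @export
hazard_ratios <- function(fitted, level = 0.95) {
  stopifnot(inherits(fitted, "mds_fit"))
  if (is.null(fitted$effects_hat)) stop("model was fitted without transplant effects")
  beta <- fitted$effects_hat$log_hr
  i <- grep("^logHR:", fitted$par_names)
  se <- if (is.null(fitted$covariance)) rep(NA_real_, length(i))
        else sqrt(diag(fitted$covariance)[i])
  zc <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(state = names(beta), hr = exp(unname(beta)),
             lower = exp(unname(beta) - zc * se),
             upper = exp(unname(beta) + zc * se), row.names = NULL)
}

#' Model-based survival curve from a state
#'
#' Survival under the fitted natural-history intensities (covariate 0):
#' `S(t) = 1 - P[from, Death](t)`.
#'
#' @param fitted an [fit_model()] result, or a generator matrix (then
#'   `state_space` must be given).
#' @param from_state state label or index.
#' @param grid nonnegative increasing time grid (years).
#' @param state_space required when `fitted` is a bare generator.
#' @return data.frame with columns `time`, `surv`.
#' @export
model_survival_curve <- function(fitted, from_state, grid, state_space = NULL) {
  if (inherits(fitted, "mds_fit")) {
    q <- fitted$q_hat; ss <- fitted$state_space
  } else {
    q <- fitted; ss <- state_space
    if (is.null(ss)) stop("state_space required when passing a generator")
  }
  if (any(grid < 0) || is.unsorted(grid)) stop("grid must be nonnegative increasing")
  from <- .state_idx(from_state, ss)
  e <- .eig(q)
  s <- if (!is.null(e)) {
    coefs <- e$u[from, ] * e$uinv[, ss$death]
    1 - as.numeric(exp(outer(grid, e$lambda)) %*% coefs)
  } else {
    vapply(grid, function(t) 1 - transition_probability_matrix(q, t)[from, ss$death], 0)
  }
  data.frame(time = grid, surv = pmin(pmax(s, 0), 1))
}

#' Kaplan-Meier estimator (product-limit, right censoring)
#'
#' Thin wrapper over [survival::survfit()] returning the step curve as a
#' data.frame, for goodness-of-fit comparison against
#' [model_survival_curve()].
#'
#' @param times nonnegative follow-up times.
#' @param events logical/0-1, `TRUE` = death observed, `FALSE` = censored.
#' @return data.frame with columns `time`, `surv` (one row per event time,
#'   prepended with `time = 0, surv = 1`).
#' @export
km_estimator <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (length(events) != length(times)) stop("times and events must be aligned")
  if (any(times < 0)) stop("times must be nonnegative")
  sf <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = c(0, sf$time), surv = c(1, sf$surv))
}

#' Evaluate a step survival curve at given times
#' @param curve data.frame with `time`, `surv` (right-continuous steps).
#' @param at times to evaluate.
#' @return numeric vector of survival probabilities.
#' @export
eval_step_curve <- function(curve, at) {
  stats::approx(curve$time, curve$surv, xout = at, method = "constant",
                yleft = 1, rule = 2)$y
}

#' Serialize / restore a fitted model as structured text (YAML)
#'
#' @param fitted an [fit_model()] result.
#' @param path file path.
#' @return `read_fitted_model` returns the `mds_fit`; `write_fitted_model`
#'   returns `path` invisibly.
#' @export
write_fitted_model <- function(fitted, path) {
  stopifnot(inherits(fitted, "mds_fit"))
  obj <- list(
    scheme = fitted$state_space$scheme,
    intensities = as.list(stats::setNames(
      fitted$q_hat[fitted$state_space$allowed],
      transition_labels(fitted$state_space))),
    log_hr = if (is.null(fitted$effects_hat)) NULL
             else as.list(fitted$effects_hat$log_hr),
    covariance = if (is.null(fitted$covariance)) NULL
                 else apply(fitted$covariance, 1, as.list),
    par_names = as.list(fitted$par_names),
    log_likelihood = fitted$log_likelihood,
    n_subjects = fitted$n_subjects,
    n_transitions = fitted$n_transitions,
    convergence = fitted$convergence,
    warnings = as.list(fitted$warnings))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_fitted_model
#' @export
read_fitted_model <- function(path) {
  obj <- yaml::read_yaml(path)
  ss <- build_state_space(obj$scheme)
  q <- make_generator(ss, unlist(obj$intensities))
  eff <- if (!is.null(obj$log_hr)) transplant_effects(ss, unlist(obj$log_hr)) else NULL
  cov <- if (!is.null(obj$covariance)) {
    m <- do.call(rbind, lapply(obj$covariance, unlist)); dimnames(m) <- NULL; m
  } else NULL
  par_names <- unlist(obj$par_names)
  par <- c(log(q[ss$allowed]), if (!is.null(eff)) unname(eff$log_hr))
  structure(list(state_space = ss, q_hat = q, effects_hat = eff,
                 covariance = cov, log_likelihood = obj$log_likelihood,
                 n_subjects = obj$n_subjects, n_transitions = obj$n_transitions,
                 convergence = obj$convergence,
                 par = stats::setNames(par, par_names), par_names = par_names,
                 warnings = unlist(obj$warnings) %||% character(0),
                 optim_details = NULL),
            class = "mds_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
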
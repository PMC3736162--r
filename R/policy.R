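#' Expected (weighted) time to absorption of a phase-type distribution
#'
#' For a CTMC with transient-state subgenerator `subgen` and certain
#' absorption, the expected time spent in each transient state before
#' absorption, starting from distribution `initial`, is
#' `initial %*% solve(-subgen)`; weighting each state's occupancy by a
#' utility in `[0, 1]` gives the quality-adjusted expectation.
#'
#' @param subgen square matrix over transient states (strictly substochastic
#'   generator rows: absorption certain).
#' @param initial initial distribution over the transient states (sums to 1).
#' @param weights per-state utility vector in `[0, 1]` (default all 1).
#' @return Scalar expected weighted time to absorption.
#' @examples
#' phase_type_expected_time(matrix(-0.2, 1, 1), 1)  # 5 years
#' @export
phase_type_expected_time <- function(subgen, initial, weights = NULL) {
  subgen <- as.matrix(subgen)
  n <- nrow(subgen)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(initial) == n, length(weights) == n)
  if (abs(sum(initial) - 1) > 1e-8) stop("initial distribution must sum to 1")
  occ <- tryCatch(solve(t(-subgen), initial), error = function(e)
    stop("absorption not certain (singular subgenerator)", call. = FALSE))
  sum(occ * weights)
}

# expected weighted time to death from every living state at once:
# solve((-Q_LL) m = w) where L = living states. Returns vector over living.
.expected_times_all <- function(q, death, weights = NULL) {
  live <- setdiff(seq_len(nrow(q)), death)
  if (is.null(weights)) weights <- rep(1, length(live))
  as.numeric(solve(-q[live, live, drop = FALSE], weights))
}

#' State utilities for quality adjustment
#'
#' Default utilities: very-low WPSS risk 1; low and intermediate WPSS, or
#' low and intermediate-1 IPSS, 0.95; high and very-high WPSS, or
#' intermediate-2 and high IPSS, 0.90; AML 0.85. Post-transplant survival
#' carries a constant utility of 0.9 (average over chronic-GvHD outcomes).
#'
#' @param state_space a [build_state_space()] object.
#' @param pre optional named numeric vector overriding per-state
#'   pre-transplant utilities (living states).
#' @param post post-transplant constant utility.
#' @return Object of class `mds_utilities`: list with `pre` (named vector
#'   over living states) and `post` (scalar).
#' @export
default_utilities <- function(state_space, pre = NULL, post = 0.9) {
  if (is.null(pre)) {
    pre <- switch(state_space$scheme,
      IPSS = c("Low" = 0.95, "Int-1" = 0.95, "Int-2" = 0.90, "High" = 0.90,
               "AML" = 0.85),
      WPSS = c("Very-low" = 1, "Low" = 0.95, "Intermediate" = 0.95,
               "High" = 0.90, "Very-high" = 0.90, "AML" = 0.85))
  }
  live <- state_space$states[-state_space$death]
  miss <- setdiff(live, names(pre))
  if (length(miss)) stop("missing utility for state(s): ", paste(miss, collapse = ", "))
  pre <- pre[live]
  if (any(pre < 0 | pre > 1) || post < 0 || post > 1)
    stop("utilities must lie in [0, 1]")
  structure(list(pre = pre, post = post), class = "mds_utilities")
}

#' Delayed-transplantation policy
#'
#' A policy is defined by a threshold state `s*`: no transplant is
#' performed below `s*`; on first entry into `s*` a transplant is scheduled
#' `delay_months` later, performed if the patient is still in `s*` and
#' under the eligibility age; progression out of `s*` (or a direct jump
#' from below `s*` to any state above it, e.g. leukemic evolution) triggers
#' immediate transplantation while eligible. Eligibility is a strict age
#' cutoff: no transplant ever occurs at or after `eligibility_age`, and a
#' missed schedule is never rescheduled. Post-transplant evolution uses the
#' transplant-modified intensities permanently.
#'
#' @param state_space a [build_state_space()] object.
#' @param threshold threshold state label/index, or `"NEVER"` for the
#'   no-transplantation policy.
#' @param delay_months waiting time in the threshold state, months `>= 0`.
#' @param age_at_diagnosis years.
#' @param eligibility_age years (default 65).
#' @param initial_state state at diagnosis (default the lowest risk state).
#' @return Object of class `transplant_policy`.
#' @export
transplant_policy <- function(state_space, threshold, delay_months = 0,
                              age_at_diagnosis = 50, eligibility_age = 65,
                              initial_state = 1L) {
  never <- identical(threshold, "NEVER") || is.na(threshold)
  thr <- if (never) NA_integer_ else .state_idx(threshold, state_space)
  if (!never && thr >= state_space$death)
    stop("threshold must be a risk state, AML, or \"NEVER\"")
  if (delay_months < 0) stop("delay_months must be >= 0")
  structure(list(scheme = state_space$scheme, threshold = thr,
                 delay_months = delay_months, delay_years = delay_months / 12,
                 age_at_diagnosis = age_at_diagnosis,
                 eligibility_age = eligibility_age,
                 initial_state = .state_idx(initial_state, state_space)),
            class = "transplant_policy")
}

#' @export
print.transplant_policy <- function(x, ...) {
  ss <- build_state_space(x$scheme)
  thr <- if (is.na(x$threshold)) "NEVER" else ss$states[x$threshold]
  cat(sprintf(
    "Policy (%s): transplant in %s after %g months; diagnosis at age %g, eligibility < %g, start %s\n",
    x$scheme, thr, x$delay_months, x$age_at_diagnosis, x$eligibility_age,
    ss$states[x$initial_state]))
  invisible(x)
}

# weights over living states given utilities (or all-1)
.pre_weights <- function(state_space, utilities) {
  if (is.null(utilities)) rep(1, state_space$n_states - 1L)
  else unname(utilities$pre)
}

#' Life expectancy without transplantation
#'
#' Expected (optionally utility-weighted) time to death from a state under
#' the natural-history intensities.
#'
#' @param fitted an [fit_model()] result (or list with `q_hat`,
#'   `state_space`).
#' @param from_state state label or index.
#' @param utilities an [default_utilities()] object or `NULL` (weights 1).
#' @return Scalar years (or QALYs).
#' @export
no_transplant_value <- function(fitted, from_state, utilities = NULL) {
  ss <- fitted$state_space
  from <- .state_idx(from_state, ss)
  w <- .pre_weights(ss, utilities)
  m <- .expected_times_all(fitted$q_hat, ss$death, w)
  m[from]
}

#' Expected survival after transplantation in a given state
#'
#' Phase-type expectation under the transplant-modified intensities,
#' starting in the state at transplantation; when utilities are supplied,
#' all post-transplant time carries the constant post-transplant utility.
#'
#' @inheritParams no_transplant_value
#' @param state_at_transplant transplantable state label or index.
#' @return Scalar years (or QALYs).
#' @export
posttransplant_value <- function(fitted, state_at_transplant, utilities = NULL) {
  ss <- fitted$state_space
  st <- .state_idx(state_at_transplant, ss)
  if (!(st %in% ss$transplantable))
    stop("state ", ss$states[st], " is not transplantable")
  if (is.null(fitted$effects_hat)) stop("fitted model has no transplant effects")
  q_post <- apply_transplant_effects(fitted$q_hat, ss, fitted$effects_hat)
  w <- if (is.null(utilities)) NULL else rep(utilities$post, ss$n_states - 1L)
  m <- .expected_times_all(q_post, ss$death, w)
  m[st]
}

# --- policy value ------------------------------------------------------

# Expected weighted remaining lifetime on first entry into the threshold
# state s*, given r = years until eligibility is lost and delay d (years).
# The sojourn in s* is exponential(lam); the effective deadline is
# delta = d if d < r (scheduled transplant) else r (eligibility lost),
# with continuation value cont at the deadline. Progression to state j
# before the deadline transplants immediately (value w_trans[j]).
.threshold_entry_value <- function(r, d, lam, w_star, prog_idx, prog_rate,
                                   w_trans, v_star_trans, v_star_nat) {
  if (r <= 0) return(v_star_nat + 0)  # never eligible: but caller handles
  sched <- d < r
  delta <- if (sched) d else r
  cont <- if (sched) v_star_trans else v_star_nat
  if (lam <= 0) return(w_star * delta + cont)
  em <- exp(-lam * delta)
  pw <- if (length(prog_idx)) sum((prog_rate / lam) * w_trans[prog_idx]) else 0
  w_star * (1 - em) / lam + em * cont + (1 - em) * pw
}

#' Expected survival under a delayed-transplantation policy
#'
#' Computes the expected time (and, with utilities, the quality-adjusted
#' time) from diagnosis to death under a [transplant_policy()], by
#' phase-type algebra. The pre-threshold phase, the exponential sojourn in
#' the threshold state against its deadlines, and all post-transplant and
#' never-eligible regimes are closed form; only the entry-time integral
#' over the window where the eligibility deadline interacts with the delay
#' requires quadrature (composite Simpson, default step 0.01 yr, with a
#' half-step Richardson error estimate reported as `numeric_tolerance`).
#'
#' @param fitted an [fit_model()] result.
#' @param policy a [transplant_policy()] (same scheme).
#' @param utilities an [default_utilities()] object or `NULL`.
#' @param grid_step quadrature step in years (default 0.01).
#' @return Object of class `policy_value`: list with `life_expectancy`,
#'   `qaly` (`NA` without utilities), `gain_vs_no_transplant` (on the
#'   reported scale: QALY when utilities are supplied), `method`
#'   (`"algebraic"`), `numeric_tolerance`.
#' @export
policy_expected_survival <- function(fitted, policy, utilities = NULL,
                                     grid_step = 0.01) {
  ss <- fitted$state_space
  if (policy$scheme != ss$scheme)
    stop("policy scheme ", policy$scheme, " does not match fitted model ", ss$scheme)
  le <- .policy_value(fitted, policy, NULL, grid_step)
  qa <- if (!is.null(utilities)) .policy_value(fitted, policy, utilities, grid_step)
        else list(value = NA_real_, tol = 0)
  ref <- no_transplant_value(fitted, policy$initial_state, utilities)
  val <- if (is.null(utilities)) le$value else qa$value
  structure(list(life_expectancy = le$value, qaly = qa$value,
                 gain_vs_no_transplant = val - ref, method = "algebraic",
                 numeric_tolerance = max(le$tol, qa$tol)),
            class = "policy_value")
}

#' @export
print.policy_value <- function(x, ...) {
  cat(sprintf("Policy value (%s): life expectancy %.3f yr", x$method,
              x$life_expectancy))
  if (!is.na(x$qaly)) cat(sprintf(", %.3f QALY", x$qaly))
  cat(sprintf("; gain vs no transplant %+.3f (numeric tol %.2g)\n",
              x$gain_vs_no_transplant, x$numeric_tolerance))
  invisible(x)
}

# core algebraic computation for one weighting; returns list(value, tol)
.policy_value <- function(fitted, policy, utilities, grid_step) {
  ss <- fitted$state_space
  q <- fitted$q_hat
  death <- ss$death
  w_pre <- .pre_weights(ss, utilities)           # over living states
  i0 <- policy$initial_state
  te <- max(policy$eligibility_age - policy$age_at_diagnosis, 0)
  d <- policy$delay_years

  nat <- .expected_times_all(q, death, w_pre)    # natural values, living states
  if (is.na(policy$threshold) || te <= 0)
    return(list(value = nat[i0], tol = 0))

  if (is.null(fitted$effects_hat))
    stop("fitted model has no transplant effects; only NEVER policies are possible")
  q_post <- apply_transplant_effects(q, ss, fitted$effects_hat)
  w_post <- if (is.null(utilities)) rep(1, ss$n_states - 1L)
            else rep(utilities$post, ss$n_states - 1L)
  wtr <- .expected_times_all(q_post, death, w_post)  # post-transplant values

  s_star <- policy$threshold
  if (i0 > s_star) return(list(value = wtr[i0], tol = 0))

  lam <- -q[s_star, s_star]
  prog_idx <- setdiff(ss$allowed[ss$allowed[, 1L] == s_star, 2L], death)
  prog_rate <- q[s_star, prog_idx]
  entry_val <- function(r) .threshold_entry_value(
    r, d, lam, w_pre[s_star], prog_idx, prog_rate, wtr, wtr[s_star], nat[s_star])

  if (i0 == s_star) return(list(value = entry_val(te), tol = 0))

  # pre-threshold phase over B = states below s*
  B <- seq_len(s_star - 1L)
  qb <- q[B, B, drop = FALSE]
  e0 <- numeric(length(B)); e0[i0] <- 1
  expb <- function(t) as.matrix(Matrix::expm(qb * t))
  # M(T) = int_0^T exp(qb u) du = qb^{-1} (exp(qb T) - I)
  Mfun <- function(t) solve(qb, expb(t) - diag(length(B)))

  eT <- expb(te); MT <- Mfun(te)
  a1 <- sum((e0 %*% MT) * w_pre[B])              # weighted time in B before te
  a2 <- sum((e0 %*% eT) * nat[B])                # still in B at te: natural
  a3 <- 0
  if (s_star <= max(ss$risk_states) && ss$aml > s_star) {
    # bypass jumps B -> AML before te transplant immediately in AML
    a3 <- as.numeric(e0 %*% MT %*% q[B, ss$aml]) * wtr[ss$aml]
  }
  s_col <- q[B, s_star]
  u_star <- max(te - d, 0)
  a4 <- if (u_star > 0) {
    as.numeric(e0 %*% Mfun(u_star) %*% s_col) * entry_val(te)  # r > d: scheduled regime
  } else 0
  # note: for u < te - d, r = te - u > d so entry value is the scheduled-
  # regime constant; entry_val(te) equals it since te - 0 > d there. Guard:
  if (u_star > 0 && !(te > d)) a4 <- 0

  # window [u_star, te): deadline structure depends on entry time
  res <- .simpson_window(qb, as.numeric(e0 %*% expb(u_star)), s_col,
                         function(u) entry_val(te - u), u_star, te, grid_step)

  list(value = a1 + a2 + a3 + a4 + res$value, tol = res$tol)
}

# composite Simpson of f(u) = (e0' exp(qb u) s_col) * g(u) over [a, b],
# with the occupancy row vector propagated along the grid (one matrix
# exponential per step size); a half-step refinement gives a Richardson
# error estimate.
.simpson_window <- function(qb, v_a, s_col, g, a, b, h) {
  if (b - a <= 0) return(list(value = 0, tol = 0))
  simp <- function(n) {
    hh <- (b - a) / n
    ph <- as.matrix(Matrix::expm(qb * hh))
    y <- numeric(n + 1L)
    v <- v_a
    for (j in 0:n) {
      y[j + 1L] <- sum(v * s_col) * g(a + j * hh)
      if (j < n) v <- as.numeric(v %*% ph)
    }
    hh / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, by = 2)]) +
              2 * (if (n > 2) sum(y[seq(3, n - 1, by = 2)]) else 0))
  }
  n <- max(2L, 2L * ceiling((b - a) / h / 2))
  v1 <- simp(n); v2 <- simp(2L * n)
  list(value = v2, tol = max(abs(v2 - v1) / 15, 1e-12))
}

#' Gain in expected survival of a policy over no transplantation
#'
#' @inheritParams policy_expected_survival
#' @return Scalar gain in years (or QALYs when utilities are supplied);
#'   negative when the policy is harmful.
#' @export
policy_gain <- function(fitted, policy, utilities = NULL, grid_step = 0.01) {
  policy_expected_survival(fitted, policy, utilities, grid_step)$gain_vs_no_transplant
}

#' Policy comparison table (gains in life expectancy)
#'
#' Evaluates [policy_gain()] over a grid of threshold policies, delays and
#' ages at diagnosis, mirroring the layout of published delayed-
#' transplantation gain/loss tables: rows are (policy, delay), columns are
#' ages.
#'
#' @param fitted an [fit_model()] result.
#' @param ages ages at diagnosis (default `seq(30, 65, by = 5)`).
#' @param delays delays in months (default `c(0, 12, 24, 48, 60)`).
#' @param thresholds threshold state labels; by default the scheme's three
#'   standard policies (IPSS: Low, Int-1, Int-2; WPSS: Low, Intermediate,
#'   High).
#' @param utilities an [default_utilities()] object or `NULL`.
#' @param eligibility_age years (default 65).
#' @param initial_state state at diagnosis (default lowest risk state).
#' @param grid_step quadrature step (years).
#' @return data.frame in long form: `policy`, `threshold`, `delay_months`,
#'   `age`, `gain` (plus `qaly_gain` when utilities are supplied).
#' @export
policy_table <- function(fitted, ages = seq(30, 65, by = 5),
                         delays = c(0, 12, 24, 48, 60), thresholds = NULL,
                         utilities = NULL, eligibility_age = 65,
                         initial_state = 1L, grid_step = 0.01) {
  ss <- fitted$state_space
  if (!length(ages) || !length(delays)) stop("age and delay grids must be nonempty")
  if (is.null(thresholds))
    thresholds <- switch(ss$scheme,
      IPSS = c("Low", "Int-1", "Int-2"),
      WPSS = c("Low", "Intermediate", "High"))
  rows <- list()
  for (pi in seq_along(thresholds)) for (dm in delays) for (a in ages) {
    pol <- transplant_policy(ss, thresholds[pi], dm, a, eligibility_age,
                             initial_state)
    pv <- policy_expected_survival(fitted, pol, utilities, grid_step)
    rows[[length(rows) + 1L]] <- data.frame(
      policy = sprintf("Policy %d: transplantation in %s", pi, thresholds[pi]),
      threshold = thresholds[pi], delay_months = dm, age = a,
      gain = pv$life_expectancy -
        no_transplant_value(fitted, initial_state, NULL),
      qaly_gain = if (is.null(utilities)) NA_real_
                  else pv$qaly - no_transplant_value(fitted, initial_state, utilities))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pivot a policy table to the published wide layout
#'
#' @param tab result of [policy_table()].
#' @param value `"gain"` or `"qaly_gain"`.
#' @return data.frame with one row per (policy, delay) and one column per age.
#' @export
policy_table_wide <- function(tab, value = "gain") {
  ages <- sort(unique(tab$age))
  keys <- unique(tab[c("policy", "delay_months")])
  out <- keys
  for (a in ages) {
    col <- vapply(seq_len(nrow(keys)), function(i) {
      r <- tab$policy == keys$policy[i] & tab$delay_months == keys$delay_months[i] &
        tab$age == a
      tab[[value]][r][1]
    }, 0)
    out[[sprintf("age_%d", a)]] <- round(col, 2)
  }
  rownames(out) <- NULL
  out
}
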
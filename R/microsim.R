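# Single-trajectory simulation under a delayed-transplantation policy.
# One implementation serves both the recorded-path API and the bulk
# Monte-Carlo estimator, so the policy semantics cannot drift between them.
# Competing risks are sampled as a total-rate exponential sojourn plus a
# categorical destination (same law as per-transition exponentials, fewer
# draws). Deterministic interrupts: the scheduled transplant time; triggers
# are checked against the strict eligibility cutoff at event time.
.sim_path <- function(q, q_post, policy, w_pre, w_post, horizon, record = FALSE) {
  death <- nrow(q)
  s_star <- policy$threshold          # NA = never transplant
  te <- max(policy$eligibility_age - policy$age_at_diagnosis, 0)
  d <- policy$delay_years
  t <- 0; state <- policy$initial_state
  post <- FALSE; sched <- NA_real_; tx_time <- NA_real_
  value <- 0
  if (record) { ev_t <- 0; ev_s <- state }

  enter <- function(s, now) {
    # returns list(post?, sched?) decisions on entering state s at time now
    if (post || is.na(s_star)) return(NULL)
    if (s > s_star && now < te) return("transplant")
    if (s == s_star && is.na(sched) && now + d < te) return("schedule")
    NULL
  }
  a <- enter(state, 0)
  if (identical(a, "transplant")) { post <- TRUE; tx_time <- 0 }
  if (identical(a, "schedule")) sched <- d

  repeat {
    qq <- if (post) q_post else q
    lam <- -qq[state, state]
    jump <- if (lam > 0) t + stats::rexp(1, lam) else Inf
    if (!post && !is.na(sched) && sched <= jump) {
      # scheduled transplant fires (sched < te by construction)
      value <- value + w_pre[state] * (sched - t)
      if (record) { ev_t <- c(ev_t, sched); ev_s <- c(ev_s, state) }
      t <- sched; tx_time <- sched; post <- TRUE; sched <- NA_real_
      next
    }
    if (jump > horizon) {
      value <- value + (if (post) w_post else w_pre[state]) * (horizon - t)
      return(list(times = if (record) ev_t else NULL,
                  states = if (record) ev_s else NULL,
                  transplant_time = tx_time, death_time = NA_real_,
                  value = value, truncated = TRUE))
    }
    value <- value + (if (post) w_post else w_pre[state]) * (jump - t)
    t <- jump
    dest <- sample.int(death, 1L, prob = pmax(qq[state, ], 0))
    state <- dest
    if (record) { ev_t <- c(ev_t, t); ev_s <- c(ev_s, state) }
    if (state == death)
      return(list(times = if (record) ev_t else NULL,
                  states = if (record) ev_s else NULL,
                  transplant_time = tx_time, death_time = t,
                  value = value, truncated = FALSE))
    a <- enter(state, t)
    if (identical(a, "transplant")) { post <- TRUE; tx_time <- t }
    else if (identical(a, "schedule")) sched <- t + d
  }
}

#' Simulate one patient trajectory under a policy
#'
#' Exact-event continuous-time simulation from diagnosis under the policy
#' semantics of [policy_expected_survival()]: no transplant below the
#' threshold state, scheduled transplant after the delay on first entry
#' into it, immediate transplant on progression past it while under the
#' eligibility age, transplant-modified intensities permanently after
#' transplantation.
#'
#' @param q baseline generator matrix.
#' @param state_space a [build_state_space()] object.
#' @param effects a [transplant_effects()] object (may be `NULL` for
#'   NEVER policies).
#' @param policy a [transplant_policy()].
#' @param seed integer seed; the same seed reproduces the path exactly.
#' @param horizon censoring horizon in years (default 120; absorption is
#'   near-certain long before this for any plausible generator).
#' @return Object of class `sim_path`: list with `times`/`states` (the
#'   jump chain, including the transplant interrupt), `transplant_time`
#'   (`NA` if never), `death_time` (`NA` if truncated at the horizon),
#'   `survival` (years lived, truncated at horizon), `seed`.
#' @export
simulate_path <- function(q, state_space, effects, policy, seed,
                          horizon = 120) {
  set.seed(seed)
  q_post <- if (!is.null(effects))
    apply_transplant_effects(q, state_space, effects) else q
  if (is.null(effects) && !is.na(policy$threshold))
    stop("policy transplants but no transplant effects supplied")
  w1 <- rep(1, state_space$n_states)
  p <- .sim_path(q, q_post, policy, w1, 1, horizon, record = TRUE)
  structure(list(times = p$times, states = p$states,
                 transplant_time = p$transplant_time,
                 death_time = p$death_time, survival = p$value,
                 seed = seed), class = "sim_path")
}

#' Monte-Carlo policy value by microsimulation
#'
#' Mean (optionally utility-weighted) survival over `n` independent
#' simulated trajectories, with its standard error. Used to validate the
#' algebraic policy values.
#'
#' @inheritParams simulate_path
#' @param utilities an [default_utilities()] object or `NULL`.
#' @param n number of paths (`>= 1`).
#' @return List with `mean`, `se` (`NA` for `n = 1`), `n`, `truncated`
#'   (count of paths alive at the horizon; a warning is issued if more than
#'   0.1% of paths are truncated).
#' @export
microsim_value <- function(q, state_space, effects, policy, utilities = NULL,
                           n, seed, horizon = 120) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  q_post <- if (!is.null(effects))
    apply_transplant_effects(q, state_space, effects) else q
  w_pre <- c(.pre_weights(state_space, utilities), 0)
  w_post <- if (is.null(utilities)) 1 else utilities$post
  vals <- numeric(n); trunc <- 0L
  for (i in seq_len(n)) {
    p <- .sim_path(q, q_post, policy, w_pre, w_post, horizon)
    vals[i] <- p$value
    if (p$truncated) trunc <- trunc + 1L
  }
  if (trunc > 0.001 * n)
    warning(sprintf("%d of %d paths truncated at horizon %g yr", trunc, n, horizon))
  list(mean = mean(vals),
       se = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
       n = n, truncated = trunc)
}
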
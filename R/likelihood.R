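#' Log-likelihood contribution of one observation interval
#'
#' Panel-data likelihood for a time-homogeneous continuous-time Markov
#' model. Over an interval of length `dt` starting in `from_state`, the
#' contribution depends on how the interval ends:
#' \describe{
#'   \item{panel}{state observed exactly: `log P[from, to](dt)`.}
#'   \item{death}{death time exactly observed, state just before death
#'     unknown: `log sum_m P[from, m](dt) * q[m, Death]` over living `m`.}
#'   \item{censor}{alive at `dt`, state unknown:
#'     `log sum_{m != Death} P[from, m](dt)`.}
#' }
#' If `post_hsct` is `TRUE` the transplant-modified generator
#' ([apply_transplant_effects()]) is used for the interval.
#'
#' @param from_state state label or index at the start of the interval.
#' @param to_state state label or index observed at the end (ignored for
#'   `kind = "censor"`).
#' @param kind `"panel"`, `"death"` or `"censor"`.
#' @param dt interval length in years, `> 0`.
#' @param q baseline generator matrix.
#' @param state_space a [build_state_space()] object.
#' @param post_hsct logical covariate value over the interval.
#' @param effects a [transplant_effects()] object (required if `post_hsct`).
#' @return Scalar log-likelihood; `-Inf` (with a warning naming the
#'   observation) for a zero-probability observation.
#' @export
interval_log_likelihood <- function(from_state, to_state, kind, dt, q,
                                    state_space, post_hsct = FALSE,
                                    effects = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("dt must be a single positive number of years")
  from <- .state_idx(from_state, state_space)
  q_eff <- if (isTRUE(post_hsct)) {
    if (is.null(effects)) stop("post_hsct interval requires transplant effects")
    apply_transplant_effects(q, state_space, effects)
  } else q
  p <- transition_probability_matrix(q_eff, dt)
  death <- state_space$death
  val <- switch(match.arg(kind, c("panel", "death", "censor")),
    panel = p[from, .state_idx(to_state, state_space)],
    death = sum(p[from, -death] * q_eff[-death, death]),
    censor = sum(p[from, -death]))
  if (val <= 0) {
    warning(sprintf("zero-probability observation (from %s, kind %s, dt %g)",
                    state_space$states[from], kind, dt))
    return(-Inf)
  }
  log(val)
}

.state_idx <- function(s, state_space) {
  if (is.numeric(s)) {
    s <- as.integer(s)
    if (s < 1L || s > state_space$n_states) stop("state index out of range: ", s)
    return(s)
  }
  i <- match(s, state_space$states)
  if (is.na(i)) stop("unknown state label '", s, "'")
  i
}

# Decompose each subject's history into likelihood intervals.
# Returns a list: `plain` data.frame(from, to, kind, dt, cov) for
# constant-covariate intervals and `switch` data.frame(from, to, kind,
# dt0, dt1) for intervals containing the 0 -> 1 covariate switch (split at
# the subject's hsct_time, covariate constant on each piece).
.cohort_intervals <- function(cohorts, state_space) {
  if (inherits(cohorts, "mds_cohort")) cohorts <- list(cohorts)
  plain <- vector("list", length(cohorts))
  sw <- vector("list", length(cohorts))
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    stopifnot(inherits(co, "mds_cohort"))
    if (attr(co, "scheme") != state_space$scheme)
      stop("cohort scheme does not match state space")
    idx <- match(co$state, state_space$states)
    sp <- split(seq_len(nrow(co)), co$subject_id)
    pl <- list(); sl <- list()
    for (rows in sp) {
      n <- length(rows)
      if (n < 2L) next
      tt <- co$time_years[rows]; st <- idx[rows]
      kd <- co$kind[rows]; post <- co$post_hsct[rows]
      h <- if ("hsct_time" %in% names(co)) co$hsct_time[rows[1L]] else NA_real_
      if (is.na(h) && any(post == 1L)) h <- min(tt[post == 1L])
      for (k in seq_len(n - 1L)) {
        dt <- tt[k + 1L] - tt[k]
        if (!is.na(h) && post[k] == 0L && h > tt[k] && h < tt[k + 1L]) {
          sl[[length(sl) + 1L]] <- c(st[k], st[k + 1L],
                                     match(kd[k + 1L], c("panel", "death", "censor")),
                                     h - tt[k], tt[k + 1L] - h)
        } else {
          pl[[length(pl) + 1L]] <- c(st[k], st[k + 1L],
                                     match(kd[k + 1L], c("panel", "death", "censor")),
                                     dt, post[k])
        }
      }
    }
    if (length(pl)) {
      m <- do.call(rbind, pl)
      plain[[ci]] <- data.frame(from = m[, 1], to = m[, 2], kind = m[, 3],
                                dt = m[, 4], cov = m[, 5])
    }
    if (length(sl)) {
      m <- do.call(rbind, sl)
      sw[[ci]] <- data.frame(from = m[, 1], to = m[, 2], kind = m[, 3],
                             dt0 = m[, 4], dt1 = m[, 5])
    }
  }
  list(plain = do.call(rbind, plain), switch = do.call(rbind, sw))
}

# Eigendecomposition of a generator; NULL if defective/ill-conditioned
# (falls back to expm). The generators here are upper triangular, so the
# eigenvalues are the diagonal entries and are real.
.eig <- function(q) {
  e <- tryCatch(eigen(q), error = function(e) NULL)
  if (is.null(e) || is.complex(e$values)) return(NULL)
  if (min(dist(e$values)) < 1e-9) return(NULL)
  uinv <- tryCatch(solve(e$vectors), error = function(e) NULL)
  if (is.null(uinv) || !all(is.finite(uinv)) || max(abs(uinv)) > 1e12) return(NULL)
  list(u = e$vectors, uinv = uinv, lambda = e$values)
}

# P-entry sums for a batch of intervals with a common generator.
# iv: data.frame(from, to, kind, dt). Returns the probability-scale terms.
.interval_probs <- function(iv, q_eff, state_space, eig = NULL) {
  death <- state_space$death
  n <- state_space$n_states
  if (is.null(eig)) eig <- .eig(q_eff)
  qd <- q_eff[, death]; qd[death] <- 0
  live <- rep(1, n); live[death] <- 0
  if (!is.null(eig)) {
    # coefficient matrix: row r, col k of U[from_r, k] * a[k, target_r]
    amat <- t(eig$uinv)                          # panel: a[to, k]
    amat_d <- as.numeric(eig$uinv %*% qd)        # death coefficients
    amat_c <- as.numeric(eig$uinv %*% live)      # censor coefficients
    tgt <- matrix(0, nrow(iv), n)
    is_p <- iv$kind == 1L
    if (any(is_p)) tgt[is_p, ] <- amat[iv$to[is_p], , drop = FALSE]
    is_d <- iv$kind == 2L
    if (any(is_d)) tgt[is_d, ] <- matrix(amat_d, sum(is_d), n, byrow = TRUE)
    is_c <- iv$kind == 3L
    if (any(is_c)) tgt[is_c, ] <- matrix(amat_c, sum(is_c), n, byrow = TRUE)
    cmat <- eig$u[iv$from, , drop = FALSE] * tgt
    emat <- exp(outer(iv$dt, eig$lambda))
    return(rowSums(emat * cmat))
  }
  # fallback: dense expm per unique dt
  p <- numeric(nrow(iv))
  for (d in unique(iv$dt)) {
    pm <- transition_probability_matrix(q_eff, d)
    rr <- which(iv$dt == d)
    for (r in rr) {
      k <- iv$kind[r]
      p[r] <- if (k == 1L) pm[iv$from[r], iv$to[r]]
      else if (k == 2L) sum(pm[iv$from[r], -death] * q_eff[-death, death])
      else sum(pm[iv$from[r], -death])
    }
  }
  p
}

# Collapse intervals to unique (from, to, kind, dt) rows with counts, per
# covariate level; regular visit grids collapse heavily. Done once per fit.
.collapse_intervals <- function(iv) {
  out <- list()
  if (!is.null(iv$plain)) {
    for (cv in unique(iv$plain$cov)) {
      sub <- iv$plain[iv$plain$cov == cv, , drop = FALSE]
      key <- paste(sub$from, sub$to, sub$kind, sub$dt)
      first <- !duplicated(key)
      u <- sub[first, , drop = FALSE]
      u$wt <- as.numeric(table(key)[key[first]])
      u$cov <- NULL
      out[[as.character(cv)]] <- u
    }
  }
  out$switch <- iv$switch
  out
}

# Total log-likelihood from collapsed intervals (fit hot path).
# Probabilities are floored at 1e-300 so the optimizer sees finite values.
.loglik_collapsed <- function(cl, q, q_post, state_space) {
  ll <- 0
  for (cv in intersect(c("0", "1"), names(cl))) {
    u <- cl[[cv]]
    qq <- if (cv == "1") q_post else q
    p <- .interval_probs(u, qq, state_space)
    ll <- ll + sum(u$wt * log(pmax(p, 1e-300)))
  }
  if (!is.null(cl$switch)) {
    death <- state_space$death
    for (r in seq_len(nrow(cl$switch))) {
      s <- cl$switch[r, ]
      m <- transition_probability_matrix(q, s$dt0) %*%
        transition_probability_matrix(q_post, s$dt1)
      p <- if (s$kind == 1L) m[s$from, s$to]
      else if (s$kind == 2L) sum(m[s$from, -death] * q_post[-death, death])
      else sum(m[s$from, -death])
      ll <- ll + log(max(p, 1e-300))
    }
  }
  ll
}

.loglik_intervals <- function(iv, q, q_post, state_space) {
  ll <- .loglik_collapsed(.collapse_intervals(iv["plain"]), q, q_post, state_space)
  if (!is.null(iv$switch)) {
    death <- state_space$death
    for (r in seq_len(nrow(iv$switch))) {
      s <- iv$switch[r, ]
      m <- transition_probability_matrix(q, s$dt0) %*%
        transition_probability_matrix(q_post, s$dt1)
      p <- if (s$kind == 1L) m[s$from, s$to]
      else if (s$kind == 2L) sum(m[s$from, -death] * q_post[-death, death])
      else sum(m[s$from, -death])
      ll <- ll + log(max(p, 1e-300))
    }
  }
  ll
}

#' Joint log-likelihood of one or more cohorts
#'
#' Sums [interval_log_likelihood()] over consecutive observation pairs of
#' every subject in every cohort. Intervals containing a transplant switch
#' (the subject's `hsct_time` strictly inside the interval) are split at the
#' switch with the covariate constant on each piece.
#'
#' @param cohorts an [mds_cohort()] or list of them (consistent scheme).
#' @param q baseline generator matrix.
#' @param state_space a [build_state_space()] object.
#' @param effects a [transplant_effects()] object, or `NULL` when no
#'   interval has covariate 1.
#' @return Scalar log-likelihood (0 for an empty cohort list).
#' @export
cohort_log_likelihood <- function(cohorts, q, state_space, effects = NULL) {
  if (inherits(cohorts, "mds_cohort")) cohorts <- list(cohorts)
  if (!length(cohorts)) return(0)
  iv <- .cohort_intervals(cohorts, state_space)
  needs_post <- (!is.null(iv$plain) && any(iv$plain$cov == 1L)) || !is.null(iv$switch)
  q_post <- if (needs_post) {
    if (is.null(effects)) stop("cohorts contain post-HSCT intervals but no effects given")
    apply_transplant_effects(q, state_space, effects)
  } else q
  .loglik_intervals(iv, q, q_post, state_space)
}
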
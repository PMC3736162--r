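test_that("interval contributions match closed forms", {
  ss2 <- two_state_space()
  q <- two_state_q(0.5)
  # survive one year: log e^{-0.5}
  expect_equal(interval_log_likelihood("Alive", "Alive", "panel", 1, q, ss2),
               -0.5, tolerance = 1e-10)
  # exactly observed death at one year: log(e^{-0.5} * 0.5)
  expect_equal(interval_log_likelihood("Alive", "Death", "death", 1, q, ss2),
               log(exp(-0.5) * 0.5), tolerance = 1e-10)
  # censored alive at one year: same survival probability
  expect_equal(interval_log_likelihood("Alive", "Alive", "censor", 1, q, ss2),
               -0.5, tolerance = 1e-10)

  ssc <- chain_space()
  qc <- chain_q(1, 0, 2)
  expect_equal(interval_log_likelihood("A", "B", "panel", 1, qc, ssc),
               log(exp(-1) - exp(-2)), tolerance = 1e-10)

  expect_error(interval_log_likelihood("Alive", "Alive", "panel", 0, q, ss2),
               "positive")
  # impossible observation: B cannot go back to A
  expect_warning(
    val <- interval_log_likelihood("B", "A", "panel", 1, qc, ssc),
    "zero-probability")
  expect_identical(val, -Inf)
})

test_that("post-HSCT intervals use the modified generator", {
  ssc <- chain_space()
  qc <- chain_q(1, 0.1, 2)
  eff <- transplant_effects(ssc, c(A = log(3), B = log(0.5)))
  qp <- apply_transplant_effects(qc, ssc, eff)
  expect_equal(
    interval_log_likelihood("A", "A", "panel", 2, qc, ssc, post_hsct = TRUE,
                            effects = eff),
    log(transition_probability_matrix(qp, 2)[1, 1]), tolerance = 1e-12)
  expect_error(interval_log_likelihood("A", "A", "panel", 2, qc, ssc,
                                       post_hsct = TRUE), "effects")
})

test_that("cohort log-likelihood sums subject intervals and is order-invariant", {
  ssc <- chain_space()
  qc <- chain_q(1, 0.05, 2)
  expect_identical(cohort_log_likelihood(list(), qc, ssc), 0)

  one <- mds_cohort(obs_df("s", c(0, 1), c("A", "B"), c("panel", "panel")), ssc)
  expect_equal(cohort_log_likelihood(one, qc, ssc),
               interval_log_likelihood("A", "B", "panel", 1, qc, ssc),
               tolerance = 1e-12)

  co <- chain_cohort()
  ll <- cohort_log_likelihood(co, qc, ssc)
  # reorder subjects (relabel so the sort order flips)
  df <- as.data.frame(co)
  df$subject_id <- c(s1 = "s9", s2 = "s8", s3 = "s7", s4 = "s6",
                     s5 = "s5")[df$subject_id]
  co2 <- mds_cohort(df, ssc)
  expect_equal(cohort_log_likelihood(co2, qc, ssc), ll, tolerance = 1e-10)

  # manual sum over subjects equals the cohort value
  by_hand <- interval_log_likelihood("A", "B", "panel", 1, qc, ssc) +
    interval_log_likelihood("A", "Death", "death", 1.5, qc, ssc) +
    interval_log_likelihood("A", "A", "panel", 0.5, qc, ssc) +
    interval_log_likelihood("A", "Death", "death", 1.5, qc, ssc) +
    interval_log_likelihood("A", "B", "panel", 1, qc, ssc) +
    interval_log_likelihood("B", "B", "censor", 1.5, qc, ssc) +
    interval_log_likelihood("B", "Death", "death", 0.75, qc, ssc)
  expect_equal(ll, by_hand, tolerance = 1e-10)
})

test_that("an HSCT switch inside an interval splits it at the switch time", {
  ssc <- chain_space()
  qc <- chain_q(1, 0.05, 2)
  eff0 <- transplant_effects(ssc, c(A = 0, B = 0))
  eff <- transplant_effects(ssc, c(A = log(2), B = log(0.5)))

  df <- obs_df("s", c(0, 2), c("A", "B"), c("panel", "panel"),
               post = c(0L, 1L))
  df$hsct_time <- 0.75
  co <- mds_cohort(df, ssc)

  # with null effects the split must reproduce the unsplit likelihood
  expect_equal(cohort_log_likelihood(co, qc, ssc, eff0),
               interval_log_likelihood("A", "B", "panel", 2, qc, ssc),
               tolerance = 1e-10)

  # with real effects it must equal the two-piece matrix product
  qp <- apply_transplant_effects(qc, ssc, eff)
  manual <- log((transition_probability_matrix(qc, 0.75) %*%
                 transition_probability_matrix(qp, 1.25))[1, 2])
  expect_equal(cohort_log_likelihood(co, qc, ssc, eff), manual,
               tolerance = 1e-10)
})

test_that("likelihood oracle: discretized-chain path sum matches on the 3-state fixture", {
  # Independent oracle: approximate the CTMC by a discrete-time chain with
  # step h (P ~ I + Qh) and sum path probabilities under the observation
  # constraints; error is O(h).
  ssc <- chain_space()
  qc <- chain_q(0.8, 0.1, 1.5)
  co <- chain_cohort()
  h <- 1e-3
  ph <- diag(3) + qc * h
  pmat_h <- function(t) {
    # matrix power by repeated squaring on the step count
    n <- round(t / h)
    out <- diag(3); b <- ph
    while (n > 0) {
      if (n %% 2 == 1) out <- out %*% b
      b <- b %*% b
      n <- n %/% 2
    }
    out
  }
  oracle_interval <- function(from, to, kind, dt) {
    p <- pmat_h(dt)
    f <- match(from, ssc$states); tt <- match(to, ssc$states)
    if (kind == "panel") log(p[f, tt])
    else if (kind == "death") log(sum(p[f, -3] * qc[-3, 3]))
    else log(sum(p[f, -3]))
  }
  oracle <- oracle_interval("A", "B", "panel", 1) +
    oracle_interval("A", "Death", "death", 1.5) +
    oracle_interval("A", "A", "panel", 0.5) +
    oracle_interval("A", "Death", "death", 1.5) +
    oracle_interval("A", "B", "panel", 1) +
    oracle_interval("B", "B", "censor", 1.5) +
    oracle_interval("B", "Death", "death", 0.75)
  expect_equal(cohort_log_likelihood(co, qc, ssc), unname(oracle),
               tolerance = 1e-3)
})
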
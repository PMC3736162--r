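test_that("IPSS and WPSS state spaces have the canonical structure", {
  ss <- build_state_space("IPSS")
  expect_equal(ss$states, c("Low", "Int-1", "Int-2", "High", "AML", "Death"))
  expect_equal(nrow(ss$allowed), 12L)
  expect_equal(ss$death, 6L)
  expect_equal(ss$aml, 5L)
  # exact allowed set: next risk state, AML and death from each risk state
  want <- rbind(c(1, 2), c(1, 5), c(1, 6), c(2, 3), c(2, 5), c(2, 6),
                c(3, 4), c(3, 5), c(3, 6), c(4, 5), c(4, 6), c(5, 6))
  expect_equal(unname(ss$allowed), want[order(want[, 1], want[, 2]), ],
               ignore_attr = TRUE)
  expect_equal(ss$transplantable, c(1:4, 5L))  # all risk states plus AML

  ws <- build_state_space("WPSS")
  expect_length(ws$states, 7L)
  expect_equal(nrow(ws$allowed), 15L)
  # Very-low is not transplantable
  expect_false(1L %in% ws$transplantable)
  expect_setequal(ws$transplantable, c(2:5, 6L))

  expect_error(build_state_space("FAB"), "IPSS.*WPSS|valid schemes")
})

test_that("no allowed transition lowers the risk ordering", {
  for (sch in c("IPSS", "WPSS")) {
    ss <- build_state_space(sch)
    expect_true(all(ss$allowed[, 2] > ss$allowed[, 1]))
    expect_false(any(ss$allowed[, 1] == ss$death))
  }
})

test_that("validate_generator flags the invariant violations", {
  ss <- build_state_space("IPSS")
  q <- make_generator(ss, setNames(rep(0.1, 12), transition_labels(ss)))
  expect_length(validate_generator(q, ss), 0L)

  q_neg <- q; q_neg[1, 5] <- -0.05; diag(q_neg) <- 0; diag(q_neg) <- -rowSums(q_neg)
  expect_match(validate_generator(q_neg, ss), "negative intensity", all = FALSE)

  q_skip <- q; q_skip[1, 4] <- 0.1   # Low -> High is not allowed
  expect_match(validate_generator(q_skip, ss), "disallowed transition", all = FALSE)
  expect_match(validate_generator(q_skip, ss), "row 1 does not sum", all = FALSE)

  q_abs <- q; q_abs[6, 5] <- 0.1
  expect_match(validate_generator(q_abs, ss), "death", all = FALSE)

  expect_error(validate_generator(q[1:5, 1:5], ss), "6x6")
})

test_that("transplant effects multiply only the death intensities", {
  ss <- build_state_space("IPSS")
  q <- make_generator(ss, setNames(c(0.2, 0.05, 0.1, 0.2, 0.05, 0.1, 0.2, 0.05,
                                     0.1, 0.3, 0.2, 0.9),
                                   transition_labels(ss)))
  zero <- transplant_effects(ss, setNames(rep(0, 5), ss$states[ss$transplantable]))
  expect_equal(apply_transplant_effects(q, ss, zero), q)

  eff <- transplant_effects(ss, setNames(c(log(2), 0, 0, 0, 0),
                                         ss$states[ss$transplantable]))
  q2 <- apply_transplant_effects(q, ss, eff)
  expect_equal(q2[1, 6], 2 * q[1, 6])
  expect_equal(q2[1, 1], q[1, 1] - q[1, 6])  # diagonal absorbs the extra death rate
  expect_equal(q2[-1, ], q[-1, ])            # other rows untouched
  expect_equal(q, make_generator(ss, setNames(q[ss$allowed],
                                              transition_labels(ss))))  # input unchanged
  expect_length(validate_generator(q2, ss), 0L)

  # reapplying beta = 0 is the identity; death column composes multiplicatively
  expect_equal(apply_transplant_effects(q2, ss, zero), q2)
  q4 <- apply_transplant_effects(q2, ss, eff)
  expect_equal(q4[1, 6], 4 * q[1, 6])

  ws <- build_state_space("WPSS")
  expect_error(transplant_effects(ws, setNames(rep(0, 6), ws$states[1:6])),
               "non-transplantable.*Very-low")
})

test_that("transition probabilities solve the forward equations", {
  q <- two_state_q(0.5)
  expect_equal(transition_probability_matrix(q, 0), diag(2), ignore_attr = TRUE)
  p <- transition_probability_matrix(q, 2)
  expect_equal(p[1, 1], exp(-1), tolerance = 1e-10)
  expect_error(transition_probability_matrix(q, -1), "nonnegative")

  # bidiagonal chain: closed form P[A,B](t) = e^{-t} - e^{-2t} checked both
  # against the analytic value and an RK4 integration of the forward ODEs
  qc <- chain_q(ab = 1, ad = 0, bd = 2)
  p1 <- transition_probability_matrix(qc, 1)
  expect_equal(p1[1, 2], exp(-1) - exp(-2), tolerance = 1e-10)
  rk4 <- function(q, t, n = 2000) {
    h <- t / n; p <- diag(nrow(q))
    for (i in seq_len(n)) {
      k1 <- p %*% q; k2 <- (p + h / 2 * k1) %*% q
      k3 <- (p + h / 2 * k2) %*% q; k4 <- (p + h * k3) %*% q
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    p
  }
  expect_equal(p1, rk4(qc, 1), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(rowSums(p1)), rep(1, 3), tolerance = 1e-10)
})

test_that("Chapman-Kolmogorov and absorption monotonicity hold for random generators", {
  set.seed(42)
  ss <- build_state_space("IPSS")
  for (rep in 1:5) {
    q <- make_generator(ss, setNames(runif(12, 0.01, 1), transition_labels(ss)))
    s <- runif(1, 0.1, 3); t <- runif(1, 0.1, 3)
    pst <- transition_probability_matrix(q, s + t)
    ps_pt <- transition_probability_matrix(q, s) %*% transition_probability_matrix(q, t)
    expect_lt(max(abs(pst - ps_pt)), 1e-8)
    # death column nondecreasing in time; death row stays the unit vector
    grid <- seq(0, 10, by = 0.5)
    dcol <- vapply(grid, function(u) transition_probability_matrix(q, u)[1, 6], 0)
    expect_true(all(diff(dcol) >= -1e-12))
    expect_equal(pst[6, ], c(0, 0, 0, 0, 0, 1), ignore_attr = TRUE)
  }
})
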
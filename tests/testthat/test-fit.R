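test_that("exponential MLE is recovered from exact death data", {
  # 10 deaths over 50 person-years: qhat = 10/50 = 0.2 in closed form
  ss2 <- two_state_space()
  times <- c(2, 3, 4, 5, 6, 7, 3, 8, 6, 6)  # sums to 50
  df <- do.call(rbind, lapply(seq_along(times), function(i)
    obs_df(sprintf("d%02d", i), c(0, times[i]), c("Alive", "Death"),
           c("panel", "death"))))
  f <- fit_model(mds_cohort(df, ss2), ss2,
                 options = list(reltol = 1e-14, hessian = FALSE))
  expect_true(f$convergence)
  expect_equal(f$q_hat[1, 2], 0.2, tolerance = 1e-6)
  expect_equal(f$log_likelihood, 10 * log(0.2) - 0.2 * 50, tolerance = 1e-8)
})

test_that("transitions without observed events get a boundary warning", {
  true <- default_fixture_parameters("IPSS")
  ss <- true$state_space
  # short follow-up keeps everyone in the first two states
  co <- generate_natural_history_cohort(true, 120, visit_interval = 0.25,
                                        admin_censor = 1, seed = 3)
  f <- fit_model(co, ss, options = list(hessian = FALSE, maxit = 200))
  expect_true(any(grepl("Int-2->High", f$warnings)))
})

test_that("hazard_ratios exponentiates with Wald intervals", {
  ssc <- chain_space()
  base <- fit_from_truth(list(state_space = ssc, q = chain_q(1, 0.1, 2),
                              effects = transplant_effects(ssc, c(A = 0, B = log(2)))))
  base$par_names <- c("A->B", "A->Death", "B->Death", "logHR:A", "logHR:B")
  base$covariance <- diag(c(1, 1, 1, 0.1^2, 0))
  hr <- hazard_ratios(base)
  expect_equal(hr$hr, c(1, 2))
  zc <- qnorm(0.975)
  expect_equal(hr$lower[1], exp(-zc * 0.1), tolerance = 1e-10)
  expect_equal(hr$upper[1], exp(zc * 0.1), tolerance = 1e-10)
  expect_equal(hr$lower[2], 2)  # degenerate interval at SE = 0
  base$covariance <- NULL
  hr2 <- hazard_ratios(base)
  expect_true(all(is.na(hr2$lower)))
  expect_equal(hr2$hr, c(1, 2))
})

test_that("model survival curves are proper and match the closed form", {
  ss2 <- two_state_space()
  f <- fit_from_truth(list(state_space = ss2, q = two_state_q(0.5),
                           effects = NULL))
  s <- model_survival_curve(f, "Alive", c(0, 1, 2, 5))
  expect_equal(s$surv[1], 1)
  expect_equal(s$surv[3], exp(-1), tolerance = 1e-8)
  expect_true(all(diff(s$surv) <= 0))
  expect_error(model_survival_curve(f, "Alive", c(2, 1)), "increasing")
})

test_that("Kaplan-Meier wrapper matches hand computation", {
  km <- km_estimator(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(eval_step_curve(km, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(eval_step_curve(km, 3), 0, tolerance = 1e-12)
  expect_equal(eval_step_curve(km, 0.5), 1)

  allc <- km_estimator(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(allc$surv == 1))
  expect_error(km_estimator(numeric(0), logical(0)), "empty")

  # large uncensored exponential sample: S(1) close to e^{-0.5}
  set.seed(99)
  x <- rexp(20000, 0.5)
  km2 <- km_estimator(x, rep(TRUE, length(x)))
  expect_lt(abs(eval_step_curve(km2, 1) - exp(-0.5)), 0.012)
})

test_that("model-based curve matches a Kaplan-Meier of simulated death times", {
  true <- default_fixture_parameters("IPSS")
  ss <- true$state_space
  f <- fit_from_truth(true)
  set.seed(17)
  n <- 50000
  # exact death times from the natural-history model, starting in Low
  dts <- numeric(n)
  for (i in seq_len(n)) {
    t <- 0; s <- 1L
    repeat {
      lam <- -true$q[s, s]
      t <- t + rexp(1, lam)
      s <- sample.int(6, 1, prob = pmax(true$q[s, ], 0))
      if (s == ss$death) break
    }
    dts[i] <- t
  }
  km <- km_estimator(dts, rep(TRUE, n))
  grid <- seq(0, 25, by = 0.25)
  mod <- model_survival_curve(f, "Low", grid)
  expect_lt(max(abs(mod$surv - eval_step_curve(km, grid))), 0.01)
})

test_that("fitted models serialize to YAML and back", {
  true <- default_fixture_parameters("WPSS")
  ss <- true$state_space
  nat <- generate_natural_history_cohort(true, 150, seed = 5)
  tx <- generate_transplant_cohort(true, 100, seed = 6)
  f <- fit_model(list(nat, tx), ss, options = list(maxit = 150))
  path <- tempfile(fileext = ".yaml")
  write_fitted_model(f, path)
  g <- read_fitted_model(path)
  expect_equal(g$q_hat, f$q_hat, tolerance = 1e-12)
  expect_equal(g$effects_hat$log_hr, f$effects_hat$log_hr, tolerance = 1e-12)
  expect_equal(g$log_likelihood, f$log_likelihood, tolerance = 1e-9)
  expect_equal(g$covariance, f$covariance, tolerance = 1e-9)
})

test_that("the fitted likelihood is at least the truth's on the same data", {
  true <- default_fixture_parameters("IPSS")
  ss <- true$state_space
  nat <- generate_natural_history_cohort(true, 400, seed = 8)
  f <- fit_model(nat, ss, options = list(hessian = FALSE))
  ll_truth <- cohort_log_likelihood(nat, true$q, ss)
  expect_gte(f$log_likelihood, ll_truth - 1e-6)
})
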
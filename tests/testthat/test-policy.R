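test_that("phase-type expectations match closed forms", {
  expect_equal(phase_type_expected_time(matrix(-0.2, 1, 1), 1), 5,
               tolerance = 1e-12)
  # chain A -> B (0.5), B -> absorption (0.25): 1/0.5 + 1/0.25 = 6
  sub <- matrix(c(-0.5, 0.5, 0, -0.25), 2, 2, byrow = TRUE)
  expect_equal(phase_type_expected_time(sub, c(1, 0)), 6, tolerance = 1e-12)
  expect_equal(phase_type_expected_time(sub, c(1, 0), c(1, 0.85)), 5.4,
               tolerance = 1e-12)
  # absorption impossible: conservative generator row
  bad <- matrix(c(-0.5, 0.5, 0, 0), 2, 2, byrow = TRUE)
  expect_error(phase_type_expected_time(bad, c(1, 0)), "absorption")
  expect_error(phase_type_expected_time(sub, c(0.5, 0.4)), "sum to 1")
})

test_that("no-transplant and post-transplant values are phase-type expectations", {
  ss2 <- two_state_space()
  f2 <- fit_from_truth(list(state_space = ss2, q = two_state_q(0.2),
                            effects = NULL))
  expect_equal(no_transplant_value(f2, "Alive"), 5, tolerance = 1e-12)

  # single transient state with death rate 0.25 and HR 2 -> 2 years
  f3 <- fit_from_truth(list(state_space = ss2, q = two_state_q(0.25),
                            effects = transplant_effects(ss2, c(Alive = log(2)))))
  expect_equal(posttransplant_value(f3, "Alive"), 2, tolerance = 1e-12)
  u <- structure(list(pre = c(Alive = 1), post = 0.9), class = "mds_utilities")
  expect_equal(posttransplant_value(f3, "Alive", u), 1.8, tolerance = 1e-12)

  ws <- build_state_space("WPSS")
  fw <- fit_from_truth(default_fixture_parameters("WPSS"))
  expect_error(posttransplant_value(fw, "Very-low"), "not transplantable")

  # utilities identically 1 reproduce the unweighted value
  true <- default_fixture_parameters("IPSS")
  fi <- fit_from_truth(true)
  ones <- default_utilities(true$state_space,
                            pre = setNames(rep(1, 5), true$state_space$states[1:5]),
                            post = 1)
  expect_equal(no_transplant_value(fi, "Low", ones),
               no_transplant_value(fi, "Low"), tolerance = 1e-12)
})

test_that("policy value reduces to no-transplant in the null cases", {
  true <- default_fixture_parameters("IPSS")
  ss <- true$state_space
  f <- fit_from_truth(true)
  base <- no_transplant_value(f, "Low")

  never <- policy_expected_survival(f, transplant_policy(ss, "NEVER", 0, 40))
  expect_equal(never$life_expectancy, base, tolerance = 1e-12)

  at65 <- policy_expected_survival(f, transplant_policy(ss, "Int-1", 12, 65))
  expect_equal(at65$life_expectancy, base, tolerance = 1e-12)

  # HR = 1 everywhere: transplantation changes nothing
  f1 <- f
  f1$effects_hat <- transplant_effects(ss, setNames(rep(0, 5),
                                                    ss$states[ss$transplantable]))
  for (thr in c("Low", "Int-1", "Int-2")) {
    pv <- policy_expected_survival(f1, transplant_policy(ss, thr, 12, 40))
    expect_equal(pv$life_expectancy, base, tolerance = 1e-3)
  }
})

test_that("policy values agree with microsimulation across the policy grid", {
  true <- default_fixture_parameters("IPSS")
  ss <- true$state_space
  f <- fit_from_truth(true)
  configs <- list(c("Low", 0, 40), c("Int-1", 12, 40), c("Int-2", 60, 60))
  for (cf in configs) {
    pol <- transplant_policy(ss, cf[1], as.numeric(cf[2]), as.numeric(cf[3]))
    alg <- policy_expected_survival(f, pol)$life_expectancy
    mc <- microsim_value(true$q, ss, true$effects, pol, NULL, n = 30000,
                         seed = 1234)
    expect_lt(abs(alg - mc$mean), 4 * mc$se)
  }
})

test_that("QALY values are dominated by life expectancy and gains can be negative", {
  true <- default_fixture_parameters("IPSS")
  ss <- true$state_space
  f <- fit_from_truth(true)
  u <- default_utilities(ss)
  for (thr in c("Low", "Int-1")) for (a in c(40, 64)) {
    pv <- policy_expected_survival(f, transplant_policy(ss, thr, 6, a), u)
    expect_lte(pv$qaly, pv$life_expectancy)
    expect_gt(pv$qaly, 0)
  }
  # transplanting immediately in the lowest state is harmful on this fixture
  expect_lt(policy_gain(f, transplant_policy(ss, "Low", 0, 40)), 0)
})

test_that("raising every hazard ratio never increases the policy value", {
  true <- default_fixture_parameters("IPSS")
  ss <- true$state_space
  pol <- transplant_policy(ss, "Int-1", 12, 45)
  vals <- sapply(c(-0.3, 0, 0.3, 0.8), function(shift) {
    f <- fit_from_truth(true)
    f$effects_hat <- transplant_effects(ss, true$effects$log_hr + shift)
    policy_expected_survival(f, pol)$life_expectancy
  })
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("policy value is continuous in the delay", {
  true <- default_fixture_parameters("IPSS")
  ss <- true$state_space
  f <- fit_from_truth(true)
  delays <- seq(0, 36, by = 1.5)
  v <- sapply(delays, function(d)
    policy_expected_survival(f, transplant_policy(ss, "Int-1", d, 58))$life_expectancy)
  expect_true(all(abs(diff(v)) < 0.06))  # no jumps on a 1.5-month grid
})

test_that("policy tables have the published layout", {
  true <- default_fixture_parameters("IPSS")
  f <- fit_from_truth(true)
  tab <- policy_table(f, ages = c(40, 65), delays = c(0, 12),
                      utilities = default_utilities(true$state_space))
  expect_equal(nrow(tab), 3 * 2 * 2)
  expect_setequal(unique(tab$threshold), c("Low", "Int-1", "Int-2"))
  # no one is eligible at 65: all gains vanish
  expect_equal(tab$gain[tab$age == 65], rep(0, 6), tolerance = 1e-9)
  expect_true(all(is.finite(tab$qaly_gain)))
  wide <- policy_table_wide(tab)
  expect_equal(names(wide), c("policy", "delay_months", "age_40", "age_65"))
  expect_equal(nrow(wide), 6)
})
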
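# Small hand-checkable state spaces and cohorts used across tests.

# A two-state world {Alive, Death}: one exponential clock.
two_state_space <- function() {
  structure(list(scheme = "toy2", states = c("Alive", "Death"), n_states = 2L,
                 aml = 1L, death = 2L, risk_states = integer(0),
                 transplantable = 1L,
                 allowed = matrix(c(1L, 2L), 1, 2,
                                  dimnames = list(NULL, c("from", "to")))),
            class = "state_space")
}

two_state_q <- function(rate) {
  matrix(c(-rate, rate, 0, 0), 2, 2, byrow = TRUE,
         dimnames = list(c("Alive", "Death"), c("Alive", "Death")))
}

# A three-state chain A -> B -> Death (A -> Death also allowed, rate may be 0).
chain_space <- function() {
  structure(list(scheme = "chain3", states = c("A", "B", "Death"), n_states = 3L,
                 aml = 2L, death = 3L, risk_states = 1L,
                 transplantable = c(1L, 2L),
                 allowed = matrix(c(1L, 2L, 1L, 3L, 2L, 3L), 3, 2, byrow = TRUE,
                                  dimnames = list(NULL, c("from", "to")))),
            class = "state_space")
}

chain_q <- function(ab = 1, ad = 0, bd = 2) {
  q <- matrix(0, 3, 3, dimnames = list(c("A", "B", "Death"), c("A", "B", "Death")))
  q[1, 2] <- ab; q[1, 3] <- ad; q[2, 3] <- bd
  diag(q) <- -rowSums(q)
  q
}

# one-subject observation frame
obs_df <- function(id, times, states, kinds, post = 0L, age = 50) {
  data.frame(subject_id = id, age_at_entry = age, time_years = times,
             state = states, kind = kinds, post_hsct = post)
}

# wrap true fixture parameters as a fitted-model object (known truth)
fit_from_truth <- function(true) {
  structure(list(state_space = true$state_space, q_hat = true$q,
                 effects_hat = true$effects, covariance = NULL,
                 log_likelihood = NA_real_, n_subjects = 0L,
                 n_transitions = 0L, convergence = TRUE,
                 par = numeric(0), par_names = character(0),
                 warnings = character(0), optim_details = NULL),
            class = "mds_fit")
}

# five-subject panel cohort on the 3-state chain, mixing panel / death /
# censor endings; used for the likelihood oracle tests
chain_cohort <- function() {
  ssc <- chain_space()
  df <- rbind(
    obs_df("s1", c(0, 1), c("A", "B"), c("panel", "panel")),
    obs_df("s2", c(0, 1.5), c("A", "Death"), c("panel", "death")),
    obs_df("s3", c(0, 0.5, 2), c("A", "A", "Death"), c("panel", "panel", "death")),
    obs_df("s4", c(0, 1, 2.5), c("A", "B", "B"), c("panel", "panel", "censor")),
    obs_df("s5", c(0, 0.75), c("B", "Death"), c("panel", "death")))
  mds_cohort(df, ssc)
}
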
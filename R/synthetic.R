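#' Documented fixture parameters for synthetic cohorts
#'
#' Returns a set of *invented* true transition intensities and transplant
#' hazard ratios used to generate synthetic cohorts. These are fixture
#' values, not estimates from any real cohort. They are chosen so that the
#' generated data carry the qualitative structure the analysis assumes:
#' death intensities strictly increase along the risk ordering (AML
#' highest); post-HSCT mortality hazard ratios are well above 1 in the
#' low-risk states (transplant-related mortality dwarfs the low baseline
#' mortality) and near or below the mortality-equalizing level at high
#' risk, so that policy sweeps show the expected pattern: transplantation
#' at diagnosis in the lowest state loses life expectancy, delaying until
#' progression to intermediate risk maximizes the gain, and delaying
#' beyond that loses ground.
#'
#' @param scheme `"IPSS"` or `"WPSS"`.
#' @return Object of class `true_parameters`: list with `state_space`,
#'   `q` (true generator), `effects` (true [transplant_effects()]).
#' @export
default_fixture_parameters <- function(scheme = c("IPSS", "WPSS")) {
  ss <- build_state_space(scheme)
  scheme <- ss$scheme
  if (scheme == "IPSS") {
    q <- make_generator(ss, c(
      "Low->Int-1" = 0.23, "Low->AML" = 0.02, "Low->Death" = 0.025,
      "Int-1->Int-2" = 0.22, "Int-1->AML" = 0.08, "Int-1->Death" = 0.12,
      "Int-2->High" = 0.25, "Int-2->AML" = 0.10, "Int-2->Death" = 0.22,
      "High->AML" = 0.45, "High->Death" = 0.40,
      "AML->Death" = 0.95))
    hr <- c("Low" = 5.0, "Int-1" = 0.85, "Int-2" = 0.70, "High" = 0.55,
            "AML" = 0.40)
  } else {
    q <- make_generator(ss, c(
      "Very-low->Low" = 0.20, "Very-low->AML" = 0.01, "Very-low->Death" = 0.015,
      "Low->Intermediate" = 0.22, "Low->AML" = 0.03, "Low->Death" = 0.035,
      "Intermediate->High" = 0.22, "Intermediate->AML" = 0.08,
      "Intermediate->Death" = 0.12,
      "High->Very-high" = 0.25, "High->AML" = 0.12, "High->Death" = 0.22,
      "Very-high->AML" = 0.45, "Very-high->Death" = 0.40,
      "AML->Death" = 0.95))
    hr <- c("Low" = 4.0, "Intermediate" = 0.85, "High" = 0.70,
            "Very-high" = 0.55, "AML" = 0.40)
  }
  structure(list(state_space = ss, q = q,
                 effects = transplant_effects(ss, log(hr))),
            class = "true_parameters")
}

#' @export
print.true_parameters <- function(x, ...) {
  cat(sprintf("Synthetic fixture parameters (%s; invented values)\n",
              x$state_space$scheme))
  print(round(x$q, 3))
  print(x$effects)
  invisible(x)
}

#' Default transplant-cohort entry-state mix
#'
#' Proportions of transplantable entry states shaped like a registry
#' transplant cohort (heavier at intermediate/high risk, with a share of
#' AML evolved from MDS).
#'
#' @param state_space a [build_state_space()] object.
#' @return Named probability vector over transplantable state labels.
#' @export
default_transplant_mix <- function(state_space) {
  m <- switch(state_space$scheme,
    IPSS = c("Low" = 23, "Int-1" = 118, "Int-2" = 139, "High" = 57, "AML" = 140),
    WPSS = c("Low" = 34, "Intermediate" = 74, "High" = 185, "Very-high" = 44,
             "AML" = 140))
  m / sum(m)
}

#' Generate a synthetic natural-history (supportive-care) cohort
#'
#' Each subject starts in the lowest risk state at diagnosis and evolves
#' under the true intensities. The disease state is recorded at scheduled
#' visits (`0, visit_interval, 2*visit_interval, ...`); the death time is
#' recorded exactly if it occurs before administrative censoring, otherwise
#' a censor row marks end of follow-up alive. The transplant covariate is 0
#' throughout.
#'
#' @param true a [default_fixture_parameters()] object (or any
#'   `true_parameters`).
#' @param n number of subjects.
#' @param visit_interval years between visits (default 0.5).
#' @param admin_censor administrative censoring time in years (default 15).
#' @param age_dist function of `n` returning ages at diagnosis (default
#'   uniform on 35--80).
#' @param seed integer seed.
#' @return An [mds_cohort()] labeled `"natural-history"`.
#' @export
generate_natural_history_cohort <- function(true, n, visit_interval = 0.5,
                                            admin_censor = 15,
                                            age_dist = function(n) stats::runif(n, 35, 80),
                                            seed = 1) {
  stopifnot(n >= 1, visit_interval > 0)
  ss <- true$state_space
  set.seed(seed)
  ages <- age_dist(n)
  all_visits <- seq(0, admin_censor, by = visit_interval)
  id <- st <- kd <- vector("list", n)
  tm <- ag <- vector("list", n)
  for (i in seq_len(n)) {
    path <- .raw_ctmc_path(true$q, 1L, ss$death, admin_censor)
    visits <- all_visits[all_visits < min(path$end_time, admin_censor)]
    nv <- length(visits)
    id[[i]] <- rep.int(sprintf("NH%05d", i), nv + 1L)
    ag[[i]] <- rep.int(ages[i], nv + 1L)
    tm[[i]] <- c(visits, if (path$died) path$end_time else admin_censor)
    vst <- path$state_at(visits)
    st[[i]] <- ss$states[c(vst, if (path$died) ss$death
                           else path$state_at(admin_censor))]
    kd[[i]] <- c(rep.int("panel", nv), if (path$died) "death" else "censor")
  }
  mds_cohort(data.frame(subject_id = unlist(id), age_at_entry = unlist(ag),
                        time_years = unlist(tm), state = unlist(st),
                        kind = unlist(kd), post_hsct = 0L),
             ss$scheme, "natural-history")
}

#' Generate a synthetic transplanted cohort
#'
#' Each subject enters the study at transplantation (time origin 0) in a
#' transplantable state drawn from `state_mix`, and evolves under the
#' transplant-modified intensities; the covariate is 1 on every row. Death
#' is exactly observed if before `followup`, else a censor row is written.
#'
#' @inheritParams generate_natural_history_cohort
#' @param state_mix named probability vector over transplantable state
#'   labels (default [default_transplant_mix()]).
#' @param followup administrative censoring after transplantation, years
#'   (default 10).
#' @return An [mds_cohort()] labeled `"transplanted"`.
#' @export
generate_transplant_cohort <- function(true, n, state_mix = NULL,
                                       followup = 10,
                                       age_dist = function(n) stats::runif(n, 20, 65),
                                       seed = 1) {
  stopifnot(n >= 1, followup > 0)
  ss <- true$state_space
  if (is.null(state_mix)) state_mix <- default_transplant_mix(ss)
  bad <- setdiff(names(state_mix), ss$states[ss$transplantable])
  if (length(bad))
    stop("state_mix has mass on non-transplantable state(s): ",
         paste(bad, collapse = ", "))
  q_post <- apply_transplant_effects(true$q, ss, true$effects)
  set.seed(seed)
  ages <- age_dist(n)
  entry <- match(names(state_mix), ss$states)[
    sample.int(length(state_mix), n, replace = TRUE, prob = state_mix)]
  end_t <- end_s <- numeric(n); died <- logical(n)
  for (i in seq_len(n)) {
    path <- .raw_ctmc_path(q_post, entry[i], ss$death, followup)
    died[i] <- path$died
    end_t[i] <- if (path$died) path$end_time else followup
    end_s[i] <- if (path$died) ss$death else path$state_at(followup)
  }
  ids <- sprintf("TX%05d", seq_len(n))
  mds_cohort(data.frame(
    subject_id = rep(ids, each = 2L), age_at_entry = rep(ages, each = 2L),
    time_years = as.numeric(rbind(0, end_t)),
    state = ss$states[as.integer(rbind(entry, end_s))],
    kind = as.character(rbind("panel", ifelse(died, "death", "censor"))),
    post_hsct = 1L), ss$scheme, "transplanted")
}

# exact CTMC jump path from `start` until death or `horizon`; returns the
# jump times/states, whether death occurred before horizon, and a lookup
# closure state_at(t) (right-continuous).
.raw_ctmc_path <- function(q, start, death, horizon) {
  t <- 0; s <- start
  times <- 0; states <- s
  repeat {
    lam <- -q[s, s]
    if (lam <= 0) break
    t <- t + stats::rexp(1, lam)
    if (t >= horizon) break  # jump lands beyond follow-up: censored
    s <- sample.int(nrow(q), 1L, prob = pmax(q[s, ], 0))
    times <- c(times, t); states <- c(states, s)
    if (s == death) break
  }
  died <- states[length(states)] == death && times[length(states)] < horizon
  list(times = times, states = states, died = died,
       end_time = if (died) times[length(states)] else Inf,
       state_at = function(tt) {
         idx <- findInterval(tt, times)
         states[idx]
       })
}
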
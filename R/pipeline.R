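#' Run the full decision-analysis pipeline
#'
#' Executes fit, goodness of fit, policy tables (plain and QALY-adjusted),
#' microsimulation cross-check and optional bootstrap, writing CSV tables
#' and a text summary to an output directory. Every output embeds the
#' config hash and seed in a leading comment line; reruns with identical
#' config are byte-identical.
#'
#' @param config a list, or path to a YAML file, with entries:
#' \describe{
#'   \item{scheme}{`"IPSS"` or `"WPSS"`.}
#'   \item{cohorts}{list with `natural_history` and/or `transplanted` CSV
#'     paths; if absent, synthetic cohorts are generated from
#'     [default_fixture_parameters()] using `synthetic` sizes.}
#'   \item{synthetic}{list `n_natural` (default 660), `n_transplanted`
#'     (default 477), `visit_interval` (0.5), `admin_censor` (15),
#'     `followup` (10).}
#'   \item{ages, delays, thresholds}{policy grids (defaults as in
#'     [policy_table()]).}
#'   \item{eligibility_age}{default 65.}
#'   \item{use_utilities}{default TRUE: also produce QALY-adjusted values.}
#'   \item{microsim_n}{paths per cross-checked cell (default 20000;
#'     0 skips the validation stage).}
#'   \item{bootstrap_B}{replicates (default 0 = skip).}
#'   \item{seed}{integer, drives all randomness.}
#'   \item{output_dir}{directory (created if needed).}
#' }
#' @return Invisibly, a list with the fitted model, policy table,
#'   microsim check and bootstrap results, plus the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    scheme = "IPSS", cohorts = NULL,
    synthetic = list(n_natural = 660, n_transplanted = 477,
                     visit_interval = 0.5, admin_censor = 15, followup = 10),
    ages = seq(30, 65, by = 5), delays = c(0, 12, 24, 48, 60),
    thresholds = NULL, eligibility_age = 65, use_utilities = TRUE,
    microsim_n = 20000, bootstrap_B = 0, seed = 1, output_dir = "mdshsct-out"),
    config)
  hash <- .cfg_hash(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# mdshsct run config=%s seed=%d", hash, as.integer(cfg$seed))
  logf <- file.path(cfg$output_dir, "run_log.txt")
  logcon <- file(logf, "w")
  logmsg <- function(...) {
    writeLines(sprintf(...), logcon)
    message(sprintf(...))
  }
  on.exit(close(logcon))
  logmsg("mdshsct pipeline; config hash %s; seed %d; R %s", hash,
         as.integer(cfg$seed), as.character(getRversion()))

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    logmsg("stage %-14s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    r
  }

  ss <- build_state_space(cfg$scheme)
  cohorts <- stage("data", {
    if (!is.null(cfg$cohorts)) {
      lapply(seq_along(cfg$cohorts), function(i)
        read_cohort(cfg$cohorts[[i]], cfg$scheme, names(cfg$cohorts)[i]))
    } else {
      true <- default_fixture_parameters(cfg$scheme)
      list(generate_natural_history_cohort(true, cfg$synthetic$n_natural,
             cfg$synthetic$visit_interval, cfg$synthetic$admin_censor,
             seed = cfg$seed),
           generate_transplant_cohort(true, cfg$synthetic$n_transplanted,
             followup = cfg$synthetic$followup, seed = cfg$seed + 1))
    }
  })
  fit <- stage("fit", fit_model(cohorts, ss))
  write_fitted_model(fit, file.path(cfg$output_dir, "fitted_model.yaml"))

  wout <- function(df, name) {
    path <- file.path(cfg$output_dir, name)
    con <- file(path, "wb")
    writeLines(stamp, con)
    utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, quote = FALSE)
    close(con)
    path
  }

  gof <- stage("gof", {
    nat <- Filter(function(co) all(co$post_hsct == 0L), cohorts)
    grid <- seq(0, 15, by = 0.25)
    out <- list()
    for (co in nat) {
      sj <- cohort_subjects(co)
      sj$entry_state <- factor(sj$entry_state, levels = ss$states)
      for (st in levels(droplevels(sj$entry_state))) {
        sub <- sj[sj$entry_state == st, ]
        if (nrow(sub) < 10) next
        km <- km_estimator(sub$followup, sub$died)
        mod <- model_survival_curve(fit, st, grid)
        out[[length(out) + 1L]] <- data.frame(
          from_state = st, time = grid, model_surv = mod$surv,
          km_surv = eval_step_curve(km, grid))
      }
    }
    do.call(rbind, out)
  })
  if (!is.null(gof)) wout(gof, "gof_curves.csv")

  util <- if (isTRUE(cfg$use_utilities)) default_utilities(ss) else NULL
  tab <- stage("policy-table",
    policy_table(fit, cfg$ages, cfg$delays, cfg$thresholds, util,
                 cfg$eligibility_age))
  wout(tab, "policy_table.csv")
  wout(policy_table_wide(tab), "policy_table_wide.csv")

  msim <- NULL
  if (cfg$microsim_n > 0) {
    msim <- stage("microsim", {
      cells <- tab[tab$age %in% range(tab$age) &
                   tab$delay_months %in% range(tab$delay_months), ]
      base <- no_transplant_value(fit, 1L)
      out <- list()
      for (r in seq_len(nrow(cells))) {
        pol <- transplant_policy(ss, cells$threshold[r], cells$delay_months[r],
                                 cells$age[r], cfg$eligibility_age)
        mc <- microsim_value(fit$q_hat, ss, fit$effects_hat, pol, NULL,
                             n = cfg$microsim_n, seed = cfg$seed + 100 + r)
        out[[r]] <- data.frame(
          threshold = cells$threshold[r], delay_months = cells$delay_months[r],
          age = cells$age[r], algebraic_gain = cells$gain[r],
          microsim_gain = mc$mean - base, se = mc$se,
          within_3se = abs(cells$gain[r] - (mc$mean - base)) <= 3 * mc$se)
      }
      do.call(rbind, out)
    })
    wout(msim, "microsim_check.csv")
  } else logmsg("stage %-14s skipped (microsim_n = 0)", "microsim")

  boot <- NULL
  if (cfg$bootstrap_B > 0) {
    boot <- stage("bootstrap", {
      thr <- (cfg$thresholds %||%
        switch(cfg$scheme, IPSS = "Int-1", WPSS = "Intermediate"))[1]
      pol <- transplant_policy(ss, thr, 0, 50, cfg$eligibility_age)
      bootstrap_policy_ci(cohorts, ss, pol, util, B = cfg$bootstrap_B,
                          seed = cfg$seed + 999)
    })
    wout(data.frame(value = boot$value, point = boot$point,
                    lower = boot$ci["lower"], upper = boot$ci["upper"],
                    n_failed = boot$n_failed, B = length(boot$replicates)),
         "bootstrap.csv")
  } else logmsg("stage %-14s skipped (bootstrap_B = 0)", "bootstrap")

  summ <- c(stamp,
    sprintf("Fitted %s model: logLik %.2f, %d subjects, converged: %s",
            cfg$scheme, fit$log_likelihood, fit$n_subjects, fit$convergence),
    if (length(fit$warnings)) paste("warning:", fit$warnings),
    sprintf("Best gain in table: %.2f yr (%s, delay %d mo, age %d)",
            max(tab$gain), tab$threshold[which.max(tab$gain)],
            tab$delay_months[which.max(tab$gain)], tab$age[which.max(tab$gain)]),
    if (!is.null(msim) && any(!msim$within_3se))
      sprintf("FLAG: %d microsim cells beyond 3 SE of algebraic value",
              sum(!msim$within_3se))
    else if (!is.null(msim))
      "Microsim cross-check: all cells within 3 SE of algebraic values")
  writeLines(summ, file.path(cfg$output_dir, "summary.txt"))
  logmsg("pipeline complete")
  invisible(list(fit = fit, policy_table = tab, microsim_check = msim,
                 bootstrap = boot, output_dir = cfg$output_dir,
                 config_hash = hash))
}

# FNV-1a hash of the deparsed config (stable across runs of same R version).
# The output directory is not part of the hash: it does not affect results.
.cfg_hash <- function(cfg) {
  cfg$output_dir <- NULL
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Plot goodness of fit: model vs Kaplan-Meier survival curves
#'
#' @param gof data.frame as produced by the pipeline's gof stage
#'   (columns `from_state`, `time`, `model_surv`, `km_surv`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot_gof <- function(gof, ...) {
  states <- unique(gof$from_state)
  old <- graphics::par(mfrow = c(1, length(states)))
  on.exit(graphics::par(old))
  for (st in states) {
    d <- gof[gof$from_state == st, ]
    graphics::matplot(d$time, cbind(d$model_surv, d$km_surv), type = "l",
                      lty = c(1, 2), col = c("black", "red3"), ylim = c(0, 1),
                      xlab = "Years since diagnosis", ylab = "Survival",
                      main = st, ...)
    graphics::legend("topright", c("model", "Kaplan-Meier"), lty = c(1, 2),
                     col = c("black", "red3"), bty = "n")
  }
  invisible(NULL)
}

#' Plot policy gains against delay, one panel per policy
#'
#' @param tab a [policy_table()] result.
#' @param value column to plot (default `"gain"`).
#' @export
plot_policy_gains <- function(tab, value = "gain") {
  pols <- unique(tab$policy)
  old <- graphics::par(mfrow = c(1, length(pols)))
  on.exit(graphics::par(old))
  ages <- sort(unique(tab$age))
  cols <- grDevices::hcl.colors(length(ages), "viridis")
  for (p in pols) {
    d <- tab[tab$policy == p, ]
    graphics::plot(NULL, xlim = range(d$delay_months), ylim = range(tab[[value]]),
                   xlab = "Delay (months)", ylab = "Gain vs no transplant (yr)",
                   main = p)
    graphics::abline(h = 0, col = "grey70")
    for (i in seq_along(ages)) {
      dd <- d[d$age == ages[i], ]
      graphics::lines(dd$delay_months, dd[[value]], col = cols[i], type = "b",
                      pch = 16)
    }
    graphics::legend("topright", legend = ages, col = cols, lty = 1, pch = 16,
                     bty = "n", title = "Age", cex = 0.7)
  }
  invisible(NULL)
}
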
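#' Panel-observed cohort objects
#'
#' A cohort is a set of subjects observed longitudinally under a panel
#' scheme: the disease state is recorded exactly at scheduled visits
#' (`kind = "panel"`), death times are exactly observed (`kind = "death"`),
#' and end of follow-up alive is marked by a censor row (`kind = "censor"`,
#' whose `state` records the last known living state and is not used by the
#' likelihood). Times are decimal years since subject entry -- diagnosis for
#' natural-history subjects, transplantation for transplanted-cohort
#' subjects. The `post_hsct` flag is the transplant covariate value at that
#' time (0 before transplantation, 1 at or after it).
#'
#' @param df data.frame with columns `subject_id`, `age_at_entry`,
#'   `time_years`, `state` (state label), `kind`, `post_hsct`.
#' @param scheme `"IPSS"` or `"WPSS"`, or a [build_state_space()]-shaped
#'   `state_space` object (custom spaces are useful for small worked
#'   examples with closed-form answers).
#' @param label free-text cohort label (e.g. `"natural-history"`).
#' @return An object of class `mds_cohort`: the observation data.frame with
#'   `scheme` and `label` attributes, rows ordered by subject then time.
#' @export
mds_cohort <- function(df, scheme, label = "") {
  ss <- if (inherits(scheme, "state_space")) scheme else build_state_space(scheme)
  scheme <- ss$scheme
  need <- c("subject_id", "age_at_entry", "time_years", "state", "kind", "post_hsct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[c(need, intersect("hsct_time", names(df)))]
  df$subject_id <- as.character(df$subject_id)
  df$state <- as.character(df$state)
  df$kind <- as.character(df$kind)
  df$post_hsct <- as.integer(df$post_hsct)
  df <- df[order(df$subject_id, df$time_years, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, scheme = scheme, label = label,
                   class = c("mds_cohort", "data.frame"))
  err <- .cohort_errors(out, ss)
  if (length(err)) stop(paste(err, collapse = "\n"))
  out
}

# hard errors: malformed data that no downstream code should see
.cohort_errors <- function(cohort, ss) {
  err <- character(0)
  bad_state <- !(cohort$state %in% ss$states)
  if (any(bad_state))
    err <- c(err, sprintf("subject %s, row %d: unknown state label '%s'",
                          cohort$subject_id[bad_state], which(bad_state),
                          cohort$state[bad_state]))
  bad_kind <- !(cohort$kind %in% c("panel", "death", "censor"))
  if (any(bad_kind))
    err <- c(err, sprintf("subject %s, row %d: unknown kind '%s'",
                          cohort$subject_id[bad_kind], which(bad_kind),
                          cohort$kind[bad_kind]))
  if (length(err)) return(err)
  death_lab <- ss$states[ss$death]
  i <- which(cohort$kind == "death" & cohort$state != death_lab)
  if (length(i))
    err <- c(err, sprintf("subject %s, row %d: kind 'death' requires state '%s'",
                          cohort$subject_id[i], i, death_lab))
  i <- which(cohort$kind != "death" & cohort$state == death_lab)
  if (length(i))
    err <- c(err, sprintf("subject %s, row %d: living observation in state '%s'",
                          cohort$subject_id[i], i, death_lab))
  sp <- split(seq_len(nrow(cohort)), cohort$subject_id)
  for (sid in names(sp)) {
    rows <- sp[[sid]]
    tt <- cohort$time_years[rows]
    if (any(tt < 0))
      err <- c(err, sprintf("subject %s: negative observation time", sid))
    if (any(diff(tt) <= 0))
      err <- c(err, sprintf("subject %s: observation times not strictly increasing", sid))
    term <- cohort$kind[rows] %in% c("death", "censor")
    if (any(term & seq_along(rows) < length(rows)))
      err <- c(err, sprintf("subject %s: observation after death/censor", sid))
    if (sum(term) > 1L)
      err <- c(err, sprintf("subject %s: multiple death/censor observations", sid))
  }
  err
}

#' @export
print.mds_cohort <- function(x, ...) {
  cat(sprintf("mds_cohort (%s%s): %d subjects, %d observations\n",
              attr(x, "scheme"),
              if (nzchar(attr(x, "label"))) paste0(", ", attr(x, "label")) else "",
              length(unique(x$subject_id)), nrow(x)))
  invisible(x)
}

# shortest decimal representation that round-trips exactly
.num2str <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    for (d in 1:17) {
      s <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Read / write a cohort CSV
#'
#' The cohort CSV dialect has one row per observation and columns
#' `subject_id, age_at_entry, time_years, state, kind, post_hsct` with
#' `kind` in `panel`/`death`/`censor` and `post_hsct` in 0/1. State labels
#' (not indices) are used; decimal point, UTF-8. Writing is deterministic
#' (rows ordered by subject then time; numerics in shortest exact decimal
#' form) so write–read–write is byte-identical.
#'
#' @param path file path.
#' @param scheme `"IPSS"` or `"WPSS"`.
#' @param label cohort label attached on read.
#' @return `read_cohort` returns an [mds_cohort()]; `write_cohort` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path, scheme, label = "") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  if (!nrow(df)) df$post_hsct <- integer(0)
  mds_cohort(df, scheme, label)
}

#' @rdname read_cohort
#' @param cohort an [mds_cohort()] object.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mds_cohort"))
  df <- as.data.frame(cohort)
  df$age_at_entry <- .num2str(df$age_at_entry)
  df$time_years <- .num2str(df$time_years)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("subject_id,age_at_entry,time_years,state,kind,post_hsct", con)
  if (nrow(df))
    writeLines(paste(df$subject_id, df$age_at_entry, df$time_years,
                     df$state, df$kind, df$post_hsct, sep = ","), con)
  invisible(path)
}

#' Validate a cohort against the transition structure
#'
#' Flags subject histories that are impossible or inconsistent under the
#' model: observed risk regression (states never decrease in the risk
#' ordering), duplicate observation times, and transplant-covariate flags
#' inconsistent with the subject's transplantation time (first time with
#' `post_hsct = 1`). Pure check, no mutation.
#'
#' @param cohort an [mds_cohort()] object.
#' @param state_space a [build_state_space()] object for the same scheme.
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_cohort <- function(cohort, state_space) {
  stopifnot(inherits(cohort, "mds_cohort"))
  if (attr(cohort, "scheme") != state_space$scheme)
    stop("cohort scheme ", attr(cohort, "scheme"), " does not match state space ",
         state_space$scheme)
  v <- character(0)
  idx <- match(cohort$state, state_space$states)
  sp <- split(seq_len(nrow(cohort)), cohort$subject_id)
  for (sid in names(sp)) {
    rows <- sp[[sid]]
    live <- rows[cohort$kind[rows] == "panel"]
    if (length(live) > 1L && any(diff(idx[live]) < 0))
      v <- c(v, sprintf("subject %s: risk regression in observed state sequence", sid))
    if (anyDuplicated(cohort$time_years[rows]))
      v <- c(v, sprintf("subject %s: duplicate observation times", sid))
    post <- cohort$post_hsct[rows]
    if (any(post == 1L)) {
      h <- min(cohort$time_years[rows][post == 1L])
      bad <- (cohort$time_years[rows] >= h) != (post == 1L)
      if (any(bad))
        v <- c(v, sprintf("subject %s: post_hsct flags inconsistent with hsct time %g",
                          sid, h))
    }
  }
  v
}

#' Per-subject summaries of a cohort
#'
#' @param cohort an [mds_cohort()] object.
#' @return data.frame with one row per subject: id, age at entry, entry
#'   state, transplantation time (`NA` if never), follow-up span, and
#'   whether death was observed.
#' @export
cohort_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "mds_cohort"))
  sp <- split(seq_len(nrow(cohort)), cohort$subject_id)
  out <- lapply(names(sp), function(sid) {
    rows <- sp[[sid]]
    post <- cohort$post_hsct[rows] == 1L
    data.frame(subject_id = sid,
               age_at_entry = cohort$age_at_entry[rows[1L]],
               entry_state = cohort$state[rows[1L]],
               hsct_time = if (any(post)) min(cohort$time_years[rows][post]) else NA_real_,
               followup = max(cohort$time_years[rows]),
               died = any(cohort$kind[rows] == "death"))
  })
  do.call(rbind, out)
}
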
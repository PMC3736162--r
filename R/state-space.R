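#' Canonical disease state spaces
#'
#' Builds the ordered state space and allowed-transition structure for a
#' risk-scoring scheme. Disease states are ordered by increasing risk,
#' followed by AML (leukemic evolution) and then death, which is absorbing.
#' From every risk state the allowed moves are: to the next risk state (if
#' any), to AML, and to death; AML can only move to death.
#'
#' The set of transplantable states contains every state in which an
#' allogeneic HSCT may be performed. For WPSS the very-low risk state is
#' excluded (transplantation is not an option there, so no hazard ratio is
#' modeled for it); for IPSS all risk states plus AML are transplantable.
#'
#' @param scheme `"IPSS"` or `"WPSS"`.
#' @return An object of class `state_space`: a list with elements
#'   `scheme`, `states` (character vector of labels), `n_states`,
#'   `aml` and `death` (indices), `risk_states` (indices),
#'   `transplantable` (indices), and `allowed` (two-column integer matrix
#'   of allowed from/to index pairs).
#' @examples
#' ss <- build_state_space("IPSS")
#' ss$states
#' nrow(ss$allowed)  # 12 allowed transitions
#' @export
build_state_space <- function(scheme = c("IPSS", "WPSS")) {
  if (!is.character(scheme) || !(scheme[1] %in% c("IPSS", "WPSS")))
    stop("unknown scheme '", scheme[1], "'; valid schemes are \"IPSS\", \"WPSS\"")
  scheme <- scheme[1]
  states <- switch(scheme,
    IPSS = c("Low", "Int-1", "Int-2", "High", "AML", "Death"),
    WPSS = c("Very-low", "Low", "Intermediate", "High", "Very-high", "AML", "Death"))
  n <- length(states)
  aml <- n - 1L
  death <- n
  risk <- seq_len(n - 2L)
  transplantable <- if (scheme == "WPSS") c(risk[-1L], aml) else c(risk, aml)
  allowed <- NULL
  for (k in risk) {
    if (k < aml - 1L) allowed <- rbind(allowed, c(k, k + 1L))
    allowed <- rbind(allowed, c(k, aml), c(k, death))
  }
  allowed <- rbind(allowed, c(aml, death))
  allowed <- allowed[order(allowed[, 1L], allowed[, 2L]), , drop = FALSE]
  storage.mode(allowed) <- "integer"
  colnames(allowed) <- c("from", "to")
  structure(list(scheme = scheme, states = states, n_states = n,
                 aml = aml, death = death, risk_states = risk,
                 transplantable = transplantable, allowed = allowed),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("%s state space: %s\n", x$scheme, paste(x$states, collapse = " -> ")))
  cat(sprintf("%d allowed transitions; transplantable states: %s\n",
              nrow(x$allowed), paste(x$states[x$transplantable], collapse = ", ")))
  invisible(x)
}

#' Assemble a transition intensity (generator) matrix
#'
#' Fills a generator matrix from per-transition intensities. Off-diagonal
#' entries are the instantaneous rates (per year) of the allowed
#' transitions; each diagonal entry is minus the row sum of the
#' off-diagonals, and the death row is identically zero.
#'
#' @param state_space a [build_state_space()] object.
#' @param intensities named numeric vector, one entry per allowed transition,
#'   named `"from->to"` with state labels (e.g. `"Low->AML"`), or an
#'   unnamed vector in the row order of `state_space$allowed`.
#' @return A square numeric matrix with state labels as dimnames.
#' @examples
#' ss <- build_state_space("IPSS")
#' q <- make_generator(ss, setNames(rep(0.1, nrow(ss$allowed)),
#'   transition_labels(ss)))
#' @export
make_generator <- function(state_space, intensities) {
  al <- state_space$allowed
  labs <- transition_labels(state_space)
  if (!is.null(names(intensities))) {
    miss <- setdiff(labs, names(intensities))
    if (length(miss))
      stop("missing intensities for transitions: ", paste(miss, collapse = ", "))
    intensities <- intensities[labs]
  } else if (length(intensities) != nrow(al)) {
    stop("need ", nrow(al), " intensities, got ", length(intensities))
  }
  if (any(intensities < 0)) stop("transition intensities must be nonnegative")
  n <- state_space$n_states
  q <- matrix(0, n, n, dimnames = list(state_space$states, state_space$states))
  q[al] <- as.numeric(intensities)
  diag(q) <- -rowSums(q)
  q
}

#' Transition labels of a state space
#'
#' @param state_space a [build_state_space()] object.
#' @return Character vector `"from->to"` in the order of `state_space$allowed`.
#' @export
transition_labels <- function(state_space) {
  paste0(state_space$states[state_space$allowed[, 1L]], "->",
         state_space$states[state_space$allowed[, 2L]])
}

#' Check generator-matrix invariants
#'
#' Verifies that a square matrix is a valid transition intensity matrix for
#' a given transition structure: nonnegative off-diagonal intensities, zero
#' intensities on disallowed pairs, rows summing to zero, and an absorbing
#' death row.
#'
#' @param q square numeric matrix.
#' @param state_space a [build_state_space()] object (its `allowed` matrix
#'   is the transition structure).
#' @param tol numeric tolerance for the zero checks.
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_generator <- function(q, state_space, tol = 1e-8) {
  n <- state_space$n_states
  if (!is.matrix(q) || nrow(q) != n || ncol(q) != n)
    stop("q must be a ", n, "x", n, " matrix for the ", state_space$scheme,
         " state space")
  v <- character(0)
  allowed <- matrix(FALSE, n, n)
  allowed[state_space$allowed] <- TRUE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (allowed[i, j] && q[i, j] < -tol)
      v <- c(v, sprintf("negative intensity at (%d,%d)", i, j))
    if (!allowed[i, j] && abs(q[i, j]) > tol)
      v <- c(v, sprintf("disallowed transition (%d,%d) has nonzero intensity", i, j))
  }
  if (any(abs(rowSums(q)) > tol))
    v <- c(v, sprintf("row %d does not sum to zero",
                      which(abs(rowSums(q)) > tol)))
  if (any(abs(q[state_space$death, ]) > tol))
    v <- c(v, "death row is not identically zero (death must be absorbing)")
  v
}

#' Transplant effects on state-specific mortality
#'
#' Post-HSCT mortality in each disease state is modeled as a proportional
#' effect on that state's death intensity: a hazard ratio `exp(beta)` per
#' transplantable state. Progression intensities are unchanged.
#'
#' @param state_space a [build_state_space()] object.
#' @param log_hr named numeric vector of log hazard ratios; names are the
#'   labels of the transplantable states. All transplantable states must be
#'   supplied; no other state may appear.
#' @return Object of class `transplant_effects`.
#' @examples
#' ss <- build_state_space("IPSS")
#' eff <- transplant_effects(ss, setNames(log(c(4, 2.5, 1.2, 0.8, 0.5)),
#'   ss$states[ss$transplantable]))
#' @export
transplant_effects <- function(state_space, log_hr) {
  want <- state_space$states[state_space$transplantable]
  if (is.null(names(log_hr)))
    stop("log_hr must be named by state label")
  extra <- setdiff(names(log_hr), want)
  if (length(extra))
    stop("transplant effect supplied for non-transplantable state(s): ",
         paste(extra, collapse = ", "))
  miss <- setdiff(want, names(log_hr))
  if (length(miss))
    stop("missing transplant effect for state(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(log_hr))) stop("log hazard ratios must be finite")
  structure(list(scheme = state_space$scheme,
                 log_hr = log_hr[want]), class = "transplant_effects")
}

#' @export
print.transplant_effects <- function(x, ...) {
  cat(sprintf("Post-HSCT mortality hazard ratios (%s):\n", x$scheme))
  print(round(exp(x$log_hr), 4))
  invisible(x)
}

#' Apply transplant effects to a generator
#'
#' Returns the post-transplant generator: each transplantable state's death
#' intensity is multiplied by its hazard ratio, all other off-diagonal
#' intensities are unchanged, and the diagonal is recomputed. The input is
#' not modified.
#'
#' @param q generator matrix (baseline, no-HSCT).
#' @param state_space a [build_state_space()] object.
#' @param effects a [transplant_effects()] object (same scheme).
#' @return The modified generator matrix.
#' @export
apply_transplant_effects <- function(q, state_space, effects) {
  stopifnot(inherits(effects, "transplant_effects"))
  if (effects$scheme != state_space$scheme)
    stop("effects are for scheme ", effects$scheme, ", state space is ",
         state_space$scheme)
  idx <- match(names(effects$log_hr), state_space$states)
  q2 <- q
  q2[idx, state_space$death] <- q[idx, state_space$death] * exp(effects$log_hr)
  diag(q2) <- 0
  diag(q2) <- -rowSums(q2)
  q2
}

#' Transition probability matrix over an interval
#'
#' Solves the Kolmogorov forward equations for a time-homogeneous generator:
#' `P(dt) = expm(q * dt)`, computed by dense scaling-and-squaring
#' ([Matrix::expm()]).
#'
#' @param q generator matrix.
#' @param dt interval length in years, `>= 0`.
#' @return Probability matrix with rows summing to 1.
#' @examples
#' q <- matrix(c(-0.5, 0.5, 0, 0), 2, 2, byrow = TRUE)
#' transition_probability_matrix(q, 2)[1, 1]  # exp(-1)
#' @export
transition_probability_matrix <- function(q, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0)
    stop("dt must be a single nonnegative number of years")
  p <- as.matrix(Matrix::expm(q * dt))
  dimnames(p) <- dimnames(q)
  # clip tiny negative round-off
  p[p < 0] <- 0
  p
}

#' Write or read a labeled generator matrix as CSV (debugging aid)
#' @param q generator matrix with dimnames.
#' @param path file path.
#' @return `read_generator_csv` returns the matrix; `write_generator_csv`
#'   returns `path` invisibly.
#' @export
write_generator_csv <- function(q, path) {
  utils::write.csv(as.data.frame(q), path)
  invisible(path)
}

#' @rdname write_generator_csv
#' @export
read_generator_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}
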
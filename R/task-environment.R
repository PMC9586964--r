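#' Task configuration for the two-step task
#'
#' The two-step task starts every trial in a single initial-stage state with
#' two actions. Each initial action leads with probability 0.7 to one
#' final-stage state ("common" transition) and with probability 0.3 to the
#' other ("rare"); the mapping for the second action mirrors the first. Each
#' final-stage state offers two actions with binary outcomes whose success
#' probabilities drift as independent reflecting Gaussian random walks.
#'
#' @param n_trials number of trials per session (default 201, the length
#'   typical of this task family).
#' @param walk_sd standard deviation of the Gaussian random-walk increment
#'   in probability units. The two conventional regimes are 0.025 with
#'   bounds c(0.25, 0.75), and 0.2 with bounds c(0, 1).
#' @param walk_bounds length-2 numeric, reflecting lower/upper bounds on the
#'   outcome probabilities.
#' @param structure_true 1 if initial action 1 commonly (p = 0.7) leads to
#'   final state 1, 2 if it commonly leads to final state 2.
#' @param walk_init "uniform" to draw initial outcome probabilities
#'   uniformly within the bounds, or "center" to start all four at the
#'   bounds' midpoint.
#' @param outcome_valence TRUE when outcome 1 codes the preferred event
#'   (reward obtained, or shock absent in aversive variants).
#' @param seed optional integer seed applied at the start of
#'   [run_session()].
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_trials = 201L,
                        walk_sd = 0.025,
                        walk_bounds = c(0.25, 0.75),
                        structure_true = 1L,
                        walk_init = c("uniform", "center"),
                        outcome_valence = TRUE,
                        seed = NULL) {
  walk_init <- match.arg(walk_init)
  if (length(walk_bounds) != 2 || !is.numeric(walk_bounds) ||
      walk_bounds[1] < 0 || walk_bounds[2] > 1 ||
      walk_bounds[1] > walk_bounds[2]) {
    stop("walk_bounds must satisfy 0 <= lo <= hi <= 1", call. = FALSE)
  }
  if (walk_sd <= 0) stop("walk_sd must be > 0", call. = FALSE)
  if (!structure_true %in% c(1L, 2L)) {
    stop("structure_true must be 1 or 2", call. = FALSE)
  }
  structure(
    list(
      n_trials = as.integer(n_trials),
      walk_sd = walk_sd,
      walk_bounds = walk_bounds,
      structure_true = as.integer(structure_true),
      walk_init = walk_init,
      outcome_valence = isTRUE(outcome_valence),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "task_config"
  )
}

#' True transition matrix implied by a task configuration
#'
#' @param config a [task_config()].
#' @param p_common probability of the common transition (fixed at 0.7 in the
#'   task).
#' @return 2x2 matrix, rows = initial action, columns = final state.
#' @export
true_transition_matrix <- function(config, p_common = 0.7) {
  transition_matrix(config$structure_true, p_common)
}

transition_matrix <- function(structure_id, p_common = 0.7) {
  if (structure_id == 1L) {
    m <- rbind(c(p_common, 1 - p_common), c(1 - p_common, p_common))
  } else if (structure_id == 2L) {
    m <- rbind(c(1 - p_common, p_common), c(p_common, 1 - p_common))
  } else {                                   # flat
    m <- matrix(0.5, 2, 2)
  }
  dimnames(m) <- list(action = c("a1", "a2"), state = c("sB", "sC"))
  m
}

#' Initialise the generative outcome-probability walks
#'
#' @param config a [task_config()].
#' @return 2x2 matrix of Bernoulli success probabilities, rows = final state,
#'   columns = final action.
#' @export
init_walks <- function(config) {
  lo <- config$walk_bounds[1]
  hi <- config$walk_bounds[2]
  v <- if (config$walk_init == "uniform") {
    stats::runif(4, lo, hi)
  } else {
    rep((lo + hi) / 2, 4)
  }
  matrix(v, 2, 2, dimnames = list(state = c("sB", "sC"),
                                  action = c("a1", "a2")))
}

#' Advance the outcome-probability walks by one step
#'
#' Each probability is perturbed by a zero-mean Gaussian increment of sd
#' `walk_sd` and reflected into the bounds (v' = 2*hi - v above, 2*lo - v
#' below, iterated until inside).
#'
#' @param walks matrix from [init_walks()].
#' @param config a [task_config()].
#' @return perturbed walk matrix, all values within the bounds.
#' @export
step_walks <- function(walks, config) {
  v <- walks + stats::rnorm(length(walks), 0, config$walk_sd)
  v[] <- vapply(v, reflect_into, numeric(1),
                lo = config$walk_bounds[1], hi = config$walk_bounds[2])
  v
}

reflect_into <- function(v, lo, hi) {
  if (lo == hi) return(lo)
  while (v < lo || v > hi) {
    if (v > hi) v <- 2 * hi - v
    if (v < lo) v <- 2 * lo - v
  }
  v
}

#' Sample a final-stage state given an initial action
#'
#' @param structure 2x2 transition matrix (rows = initial action).
#' @param a1 initial action, 1 or 2.
#' @return final state, 1 or 2.
#' @export
sample_transition <- function(structure, a1) {
  if (!a1 %in% c(1L, 2L)) stop("unknown action id", call. = FALSE)
  if (stats::runif(1) < structure[a1, 1]) 1L else 2L
}

#' Run one closed-loop session of the two-step task
#'
#' The agent chooses the initial action, the environment samples the
#' transition, the agent chooses the final action, the environment samples
#' the binary outcome from the current walk value, the agent updates, and
#' the walks drift. Agents are lists exposing `act(stage, state)` (returning
#' a length-2 probability vector), `learn(trial)` and `reset()`; see
#' [make_agent()].
#'
#' @param agent an agent object.
#' @param config a [task_config()]. If `config$seed` is non-NULL the RNG is
#'   seeded on entry, making the session exactly reproducible.
#' @param reset whether to reset the agent's internal state first.
#' @return an object of class `twostep_session`: list with elements
#'   `config`, `trials` (data frame with columns t, a1, s2, transition, a2,
#'   o) and `walks` (n_trials x 4 matrix of the generative probabilities).
#' @export
run_session <- function(agent, config, reset = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (reset) agent$reset()
  n <- config$n_trials
  p_true <- true_transition_matrix(config)
  common_state <- apply(p_true, 1, which.max)
  walks <- init_walks(config)
  a1 <- s2 <- a2 <- o <- tr <- integer(n)
  walk_log <- matrix(NA_real_, n, 4)
  for (t in seq_len(n)) {
    walk_log[t, ] <- as.vector(walks)
    p1 <- agent$act(1L, 1L)
    if (length(p1) != 2 || any(!is.finite(p1)) || abs(sum(p1) - 1) > 1e-8) {
      stop("agent returned invalid initial-stage action probabilities",
           call. = FALSE)
    }
    a1[t] <- if (stats::runif(1) < p1[1]) 1L else 2L
    s2[t] <- sample_transition(p_true, a1[t])
    tr[t] <- as.integer(s2[t] == common_state[a1[t]])
    p2 <- agent$act(2L, s2[t])
    if (length(p2) != 2 || any(!is.finite(p2)) || abs(sum(p2) - 1) > 1e-8) {
      stop("agent returned invalid final-stage action probabilities",
           call. = FALSE)
    }
    a2[t] <- if (stats::runif(1) < p2[1]) 1L else 2L
    o[t] <- as.integer(stats::runif(1) < walks[s2[t], a2[t]])
    agent$learn(list(t = t, a1 = a1[t], s2 = s2[t], a2 = a2[t], o = o[t],
                     transition = tr[t]))
    walks <- step_walks(walks, config)
  }
  new_session(config,
              data.frame(t = seq_len(n), a1 = a1, s2 = s2, transition = tr,
                         a2 = a2, o = o),
              walks = walk_log)
}

new_session <- function(config, trials, walks = NULL, subject_id = NA) {
  structure(list(config = config, trials = trials, walks = walks,
                 subject_id = subject_id),
            class = "twostep_session")
}

#' @export
print.twostep_session <- function(x, ...) {
  cat("Two-step task session:", nrow(x$trials), "trials\n")
  if (nrow(x$trials) > 0) {
    cat("  common transitions:",
        sprintf("%.3f", mean(x$trials$transition)), "\n")
    cat("  outcome rate:      ", sprintf("%.3f", mean(x$trials$o)), "\n")
  }
  invisible(x)
}

#' Agent choosing uniformly at random
#'
#' Useful as a baseline and for generating task-consistency checks.
#' @return an agent object (see [run_session()]).
#' @export
agent_random <- function() {
  list(
    act = function(stage, state) c(0.5, 0.5),
    learn = function(trial) invisible(NULL),
    reset = function() invisible(NULL)
  )
}
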
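#' Parameters of the hybrid model-free/model-based agent
#'
#' The hybrid agent combines SARSA(lambda) model-free values with
#' model-based values planned through the inferred transition structure,
#' weighted by `w` at the initial stage.
#'
#' @param alpha1,alpha2 learning rates per stage, in \[0, 1\].
#' @param elig_lambda eligibility parameter in \[0, 1\], scaling the effect
#'   of the final-stage prediction error on initial-stage values.
#' @param w model-based weight in \[0, 1\]; w = 0 is pure model-free, w = 1
#'   pure model-based.
#' @param beta1,beta2 inverse temperatures (>= 0) per stage.
#' @param rho initial-stage choice stickiness (log-odds bonus for repeating
#'   the previous initial action).
#' @return named numeric vector of class `hybrid_params`.
#' @export
hybrid_params <- function(alpha1 = 0.5, alpha2 = 0.5, elig_lambda = 0.5,
                          w = 0.5, beta1 = 5, beta2 = 5, rho = 0) {
  p <- c(alpha1 = alpha1, alpha2 = alpha2, elig_lambda = elig_lambda,
         w = w, beta1 = beta1, beta2 = beta2, rho = rho)
  if (any(p[c("alpha1", "alpha2", "elig_lambda", "w")] < 0) ||
      any(p[c("alpha1", "alpha2", "elig_lambda", "w")] > 1)) {
    stop("alpha1, alpha2, elig_lambda and w must lie in [0, 1]",
         call. = FALSE)
  }
  if (p["beta1"] < 0 || p["beta2"] < 0) {
    stop("inverse temperatures must be >= 0", call. = FALSE)
  }
  structure(p, class = "hybrid_params")
}

#' Empty model-free value table
#'
#' @return list with `q1` (length-2, initial stage) and `q2` (2x2, final
#'   states x actions), all zero.
#' @export
q_table <- function() {
  list(q1 = c(0, 0),
       q2 = matrix(0, 2, 2, dimnames = list(state = c("sB", "sC"),
                                            action = c("a1", "a2"))))
}

#' SARSA prediction errors for a completed trial
#'
#' The initial stage has no outcome, so its error is driven by the value of
#' the selected final-stage action; the final-stage error is driven by the
#' binary outcome.
#'
#' @param q value table from [q_table()].
#' @param trial list with elements a1, s2, a2, o.
#' @return c(delta1, delta2).
#' @export
mf_prediction_errors <- function(q, trial) {
  d1 <- q$q2[trial$s2, trial$a2] - q$q1[trial$a1]
  d2 <- trial$o - q$q2[trial$s2, trial$a2]
  c(delta1 = unname(d1), delta2 = unname(d2))
}

#' Apply the SARSA(lambda) update for one trial
#'
#' The visited final-stage pair moves by `alpha2 * delta2`; the visited
#' initial-stage action moves by `alpha1 * delta1` plus the
#' eligibility-weighted final-stage error `alpha1 * elig_lambda * delta2`.
#' Unvisited pairs never change.
#'
#' @param q value table.
#' @param trial completed trial (a1, s2, a2, o).
#' @param deltas from [mf_prediction_errors()].
#' @param params a [hybrid_params()] vector.
#' @return updated value table.
#' @export
mf_update <- function(q, trial, deltas, params) {
  q$q1[trial$a1] <- q$q1[trial$a1] +
    params[["alpha1"]] * deltas[["delta1"]] +
    params[["alpha1"]] * params[["elig_lambda"]] * deltas[["delta2"]]
  q$q2[trial$s2, trial$a2] <- q$q2[trial$s2, trial$a2] +
    params[["alpha2"]] * deltas[["delta2"]]
  q
}

#' Model-based initial-stage values
#'
#' Plans through the inferred transition structure: each initial action's
#' value is the transition-probability-weighted best final-stage value in
#' each state.
#'
#' @param q2 2x2 final-stage value matrix.
#' @param structure 2x2 transition matrix (e.g. from [infer_structure()]).
#' @return length-2 vector of model-based values.
#' @export
mb_values <- function(q2, structure) {
  best <- apply(q2, 1, max)
  as.vector(structure %*% best)
}

#' Convex combination of model-based and model-free values
#'
#' @param q_mb,q_mf length-2 value vectors (initial stage).
#' @param w model-based weight in \[0, 1\].
#' @return length-2 net values.
#' @export
hybrid_combine <- function(q_mb, q_mf, w) {
  stopifnot(w >= 0, w <= 1)
  w * q_mb + (1 - w) * q_mf
}

#' Softmax choice rule with initial-stage stickiness
#'
#' p(a) proportional to exp(beta * value(a) + rho * rep(a)), where rep(a) is
#' 1 iff `a` repeats the previous initial-stage choice. Stickiness applies
#' at stage 1 only; on the first trial (no previous choice) it is inactive.
#'
#' @param values length-2 value vector.
#' @param beta inverse temperature.
#' @param rho stickiness weight.
#' @param prev_a1 previous initial action (1, 2, or NA).
#' @param stage 1 or 2.
#' @return length-2 probability vector.
#' @export
softmax_policy <- function(values, beta, rho = 0, prev_a1 = NA, stage = 1) {
  u <- beta * values
  if (stage == 1 && !is.na(prev_a1)) {
    u <- u + rho * (seq_len(2) == prev_a1)
  }
  softmax(u)
}

#' Construct a hybrid RL agent
#'
#' @param params a [hybrid_params()] vector.
#' @param pure "none" for the full hybrid; "mf" or "mb" build pure
#'   model-free / model-based agents whose initial-stage values bypass the
#'   hybrid combination entirely (used for degeneracy checks against
#'   w = 0 / w = 1).
#' @return an agent object for [run_session()]; exposes `state()` for
#'   inspection.
#' @export
agent_hybrid <- function(params = hybrid_params(), pure = c("none", "mf", "mb")) {
  pure <- match.arg(pure)
  e <- new.env(parent = emptyenv())
  reset <- function() {
    e$q <- q_table()
    e$counts <- transition_counts()
    e$prev_a1 <- NA_integer_
  }
  reset()
  act <- function(stage, state) {
    if (stage == 1L) {
      structure_hat <- infer_structure(e$counts)
      q_net <- switch(pure,
        none = hybrid_combine(mb_values(e$q$q2, structure_hat), e$q$q1,
                              params[["w"]]),
        mf = e$q$q1,
        mb = mb_values(e$q$q2, structure_hat))
      softmax_policy(q_net, params[["beta1"]], params[["rho"]], e$prev_a1,
                     stage = 1)
    } else {
      softmax_policy(e$q$q2[state, ], params[["beta2"]], stage = 2)
    }
  }
  learn <- function(trial) {
    deltas <- mf_prediction_errors(e$q, trial)
    e$q <- mf_update(e$q, trial, deltas, params)
    e$counts <- update_counts(e$counts, trial$a1, trial$s2)
    e$prev_a1 <- trial$a1
    invisible(NULL)
  }
  list(act = act, learn = learn, reset = reset,
       state = function() as.list(e), params = params, model_id = "hybrid")
}
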
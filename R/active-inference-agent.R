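#' Parameters of the active-inference agent
#'
#' The agent holds Beta-Bernoulli beliefs over the four final-stage outcome
#' probabilities and selects actions by softmax over negative expected free
#' energy, which decomposes into an extrinsic term (expected log preference
#' probability of outcomes) and an intrinsic term (expected KL information
#' gain about the outcome probabilities). Four learning variants differ in
#' their forgetting kinetics: the Full model combines surprise-modulated
#' updating of the sampled pair (rate set by `nu_ps`), static decay of the
#' sampled pair toward the prior (`nu_sd`), and decay of the three unsampled
#' pairs toward the prior (`nu_ud`); the NPS, NSD and NUD variants fix the
#' corresponding rate to zero.
#'
#' @param pref_lambda preference precision in \[0, 10\]; 0 values both
#'   outcomes equally (pure information seeking), large values make the
#'   agent purely preference-driven.
#' @param kappa habit precision: static bias toward repeating the previous
#'   initial-stage action.
#' @param gamma1,gamma2 inverse temperatures (>= 0) per stage.
#' @param prior_mean mean of the prior Beta belief, in (0, 1). The prior
#'   total concentration is fixed at 2 (unit-information prior), so
#'   alpha0 = 2 * prior_mean.
#' @param l learning rate scaling the concentration increment of observed
#'   outcomes.
#' @param nu_ps,nu_sd,nu_ud prior volatility parameters in \[0, 1).
#' @param variant one of "full", "nud", "nsd", "nps"; forces the
#'   corresponding nu to 0.
#' @return named numeric vector of class `ai_params` with attribute
#'   `variant`.
#' @export
ai_params <- function(pref_lambda = 1, kappa = 0, gamma1 = 5, gamma2 = 5,
                      prior_mean = 0.5, l = 1,
                      nu_ps = 0, nu_sd = 0, nu_ud = 0,
                      variant = c("full", "nud", "nsd", "nps")) {
  variant <- match.arg(variant)
  if (prior_mean <= 0 || prior_mean >= 1) {
    stop("prior_mean must lie in (0, 1)", call. = FALSE)
  }
  if (gamma1 < 0 || gamma2 < 0) {
    stop("inverse temperatures must be >= 0", call. = FALSE)
  }
  p <- c(pref_lambda = pref_lambda, kappa = kappa, gamma1 = gamma1,
         gamma2 = gamma2, prior_mean = prior_mean, l = l,
         nu_ps = nu_ps, nu_sd = nu_sd, nu_ud = nu_ud)
  fixed <- switch(variant, full = NULL, nud = "nu_ud", nsd = "nu_sd",
                  nps = "nu_ps")
  if (!is.null(fixed)) p[fixed] <- 0
  if (any(p[c("nu_ps", "nu_sd", "nu_ud")] < 0) ||
      any(p[c("nu_ps", "nu_sd", "nu_ud")] >= 1)) {
    stop("volatility parameters nu must lie in [0, 1)", call. = FALSE)
  }
  structure(p, variant = variant, class = "ai_params")
}

#' Beta-Bernoulli belief state over final-stage outcome probabilities
#'
#' @param prior_mean mean of the prior Beta, in (0, 1).
#' @param prior_total total prior concentration alpha0 + beta0 (default 2).
#' @return object of class `belief_state`: 2x2 matrices `alpha`, `beta`
#'   (state x action) plus scalars `alpha0`, `beta0`.
#' @export
belief_state <- function(prior_mean = 0.5, prior_total = 2) {
  a0 <- prior_total * prior_mean
  b0 <- prior_total * (1 - prior_mean)
  dn <- list(state = c("sB", "sC"), action = c("a1", "a2"))
  structure(list(alpha = matrix(a0, 2, 2, dimnames = dn),
                 beta = matrix(b0, 2, 2, dimnames = dn),
                 alpha0 = a0, beta0 = b0),
            class = "belief_state")
}

#' Predictive probability of a positive outcome
#'
#' Mean of the Beta belief for the given final-stage pair: p(o = 1) =
#' alpha / (alpha + beta), consistent with alpha counting positive
#' outcomes.
#'
#' @param belief a [belief_state()].
#' @param s final state, 1 or 2.
#' @param a final action, 1 or 2.
#' @return probability of o = 1.
#' @export
predictive_outcome_prob <- function(belief, s, a) {
  belief$alpha[s, a] / (belief$alpha[s, a] + belief$beta[s, a])
}

#' Log preference probabilities over outcomes
#'
#' Bernoulli preference distribution p(o | C) proportional to
#' exp(o * lambda) * exp(-(1 - o) * lambda); lambda = 0 values both
#' outcomes equally.
#'
#' @param pref_lambda preference precision (>= 0).
#' @return c(ln p(o = 0 | C), ln p(o = 1 | C)).
#' @export
preference_log_prob <- function(pref_lambda) {
  log(bernoulli_kernel(pref_lambda))
}

#' Kullback-Leibler divergence between Beta distributions
#'
#' Closed form via log-Beta and digamma functions:
#' KL(Beta(a1, b1) || Beta(a2, b2)).
#'
#' @param post_alpha,post_beta parameters of the first (posterior) Beta.
#' @param prior_alpha,prior_beta parameters of the second (prior) Beta.
#' @return divergence in nats (>= 0).
#' @export
beta_kl <- function(post_alpha, post_beta, prior_alpha, prior_beta) {
  if (any(c(post_alpha, post_beta, prior_alpha, prior_beta) <= 0)) {
    stop("Beta parameters must be positive", call. = FALSE)
  }
  lbeta(prior_alpha, prior_beta) - lbeta(post_alpha, post_beta) +
    (post_alpha - prior_alpha) * digamma(post_alpha) +
    (post_beta - prior_beta) * digamma(post_beta) +
    (prior_alpha - post_alpha + prior_beta - post_beta) *
      digamma(post_alpha + post_beta)
}

#' Expected free energy of the final-stage actions in a state
#'
#' G(a) = -E\[ln p(o | C)\] - E\[KL(belief after o || current belief)\],
#' with the expectation under the predictive outcome distribution and the
#' hypothetical posterior taken as the one-step conjugate update
#' (increment `hyp_increment`, default 1, independent of the learning
#' kinetics so the exploration incentive is isolated).
#'
#' @param belief a [belief_state()].
#' @param s final state, 1 or 2.
#' @param pref_lambda preference precision.
#' @param hyp_increment concentration increment of the hypothetical update.
#' @return length-2 vector G(a1), G(a2); lower is better.
#' @export
efe_final <- function(belief, s, pref_lambda, hyp_increment = 1) {
  lp <- preference_log_prob(pref_lambda)
  vapply(1:2, function(a) {
    al <- belief$alpha[s, a]
    be <- belief$beta[s, a]
    q1 <- al / (al + be)
    extrinsic <- -(q1 * lp[2] + (1 - q1) * lp[1])
    intrinsic <- q1 * beta_kl(al + hyp_increment, be, al, be) +
      (1 - q1) * beta_kl(al, be + hyp_increment, al, be)
    extrinsic - intrinsic
  }, numeric(1))
}

#' Expected free energy of the initial-stage actions
#'
#' Propagates final-stage expected free energies through the inferred
#' transition structure: G(a_j) = p(sB | a_j) * sum of G over actions in sB
#' + p(sC | a_j) * sum of G over actions in sC (unweighted sums over the
#' two actions per state).
#'
#' @param G_final 2x2 matrix of final-stage G values (state x action).
#' @param structure 2x2 transition matrix.
#' @return length-2 vector of initial-stage G values.
#' @export
efe_initial <- function(G_final, structure) {
  as.vector(structure %*% rowSums(G_final))
}

#' Habit bias toward repeating the previous initial action
#'
#' Static Bernoulli habit with precision kappa; returns the normalised
#' habit strengths added inside the softmax of [ai_policy()]. Zero for both
#' actions on the first trial (no previous choice); always zero at the
#' final stage.
#'
#' @param kappa habit precision.
#' @param prev_a1 previous initial action (1, 2, or NA).
#' @return length-2 vector.
#' @export
habit_bias <- function(kappa, prev_a1 = NA) {
  if (is.na(prev_a1)) return(c(0, 0))
  k <- bernoulli_kernel(kappa)
  if (prev_a1 == 1L) c(k[2], k[1]) else c(k[1], k[2])
}

#' Action probabilities from expected free energies
#'
#' p(a) = softmax(-gamma * G(a) + E_a(a)).
#'
#' @param G expected free energies (lower preferred).
#' @param gamma inverse temperature (>= 0).
#' @param E_a habit bias vector (default none).
#' @return probability vector.
#' @export
ai_policy <- function(G, gamma, E_a = 0) {
  softmax(-gamma * G + E_a)
}

#' Predictive surprise of an observed outcome
#'
#' PS = -ln p(o; current belief).
#'
#' @param belief a [belief_state()].
#' @param s,a final state and action.
#' @param o observed outcome, 0 or 1.
#' @return surprise in nats (>= 0).
#' @export
predictive_surprise <- function(belief, s, a, o) {
  p1 <- predictive_outcome_prob(belief, s, a)
  -log(max(if (o == 1) p1 else 1 - p1, 1e-12))
}

#' Bayes-factor surprise of an observed outcome
#'
#' Ratio of the prior-predictive to the current-predictive probability of
#' the observation; 1 when beliefs equal the prior, > 1 when the outcome is
#' better explained by the prior.
#'
#' @param belief current [belief_state()].
#' @param prior prior [belief_state()].
#' @param s,a final state and action.
#' @param o observed outcome, 0 or 1.
#' @return positive surprise ratio.
#' @export
bayes_factor_surprise <- function(belief, prior, s, a, o) {
  p_cur <- predictive_outcome_prob(belief, s, a)
  p_pri <- predictive_outcome_prob(prior, s, a)
  if (o != 1) {
    p_cur <- 1 - p_cur
    p_pri <- 1 - p_pri
  }
  p_pri / max(p_cur, 1e-12)
}

#' Surprise-modulated adaptation rate
#'
#' chi(S, m) = m S / (1 + m S) with m = nu / (1 - nu); the fraction by
#' which belief concentrations are shrunk on a surprising trial.
#'
#' @param S surprise (>= 0).
#' @param nu prior volatility in \[0, 1).
#' @return adaptation rate in \[0, 1).
#' @export
adaptation_rate <- function(S, nu) {
  if (nu < 0 || nu >= 1) stop("nu must lie in [0, 1)", call. = FALSE)
  stopifnot(S >= 0)
  m <- nu / (1 - nu)
  m * S / (1 + m * S)
}

#' Update beliefs after a completed trial
#'
#' The sampled final-stage pair receives a surprise-modulated conjugate
#' update: alpha <- (1 - chi) alpha + o * l and beta <- (1 - chi) beta +
#' (1 - o) * l, with chi driven by the predictive surprise through
#' `nu_ps` (chi = 0 in the NPS variant), followed by static decay toward
#' the prior at rate `nu_sd` (skipped in NSD). The three unsampled pairs
#' decay toward the prior at rate `nu_ud` (skipped in NUD). All
#' concentrations are floored at 1e-6.
#'
#' @param belief a [belief_state()].
#' @param trial completed trial (s2, a2, o).
#' @param params an [ai_params()] vector.
#' @param prior_pull if TRUE, the surprise-modulated update also pulls the
#'   sampled pair toward the prior (adds chi * alpha0 / chi * beta0), the
#'   changepoint-style form of the update.
#' @return updated [belief_state()].
#' @export
update_beliefs <- function(belief, trial, params, prior_pull = FALSE) {
  s <- trial$s2
  a <- trial$a2
  o <- trial$o
  ps <- predictive_surprise(belief, s, a, o)
  chi <- adaptation_rate(ps, params[["nu_ps"]])
  l <- params[["l"]]
  al <- (1 - chi) * belief$alpha[s, a] + o * l
  be <- (1 - chi) * belief$beta[s, a] + (1 - o) * l
  if (prior_pull) {
    al <- al + chi * belief$alpha0
    be <- be + chi * belief$beta0
  }
  nu_sd <- params[["nu_sd"]]
  al <- (1 - nu_sd) * al + nu_sd * belief$alpha0
  be <- (1 - nu_sd) * be + nu_sd * belief$beta0
  nu_ud <- params[["nu_ud"]]
  belief$alpha <- (1 - nu_ud) * belief$alpha + nu_ud * belief$alpha0
  belief$beta <- (1 - nu_ud) * belief$beta + nu_ud * belief$beta0
  belief$alpha[s, a] <- al
  belief$beta[s, a] <- be
  belief$alpha <- pmax(belief$alpha, 1e-6)
  belief$beta <- pmax(belief$beta, 1e-6)
  belief
}

#' Construct an active-inference agent
#'
#' @param params an [ai_params()] vector.
#' @param prior_pull see [update_beliefs()].
#' @param hyp_increment see [efe_final()].
#' @return an agent object for [run_session()]; exposes `state()` for
#'   inspection.
#' @export
agent_active_inference <- function(params = ai_params(), prior_pull = FALSE,
                                   hyp_increment = 1) {
  e <- new.env(parent = emptyenv())
  reset <- function() {
    e$belief <- belief_state(params[["prior_mean"]])
    e$counts <- transition_counts()
    e$prev_a1 <- NA_integer_
  }
  reset()
  G2 <- function() {
    rbind(efe_final(e$belief, 1, params[["pref_lambda"]], hyp_increment),
          efe_final(e$belief, 2, params[["pref_lambda"]], hyp_increment))
  }
  act <- function(stage, state) {
    if (stage == 1L) {
      structure_hat <- infer_structure(e$counts)
      G1 <- efe_initial(G2(), structure_hat)
      ai_policy(G1, params[["gamma1"]],
                habit_bias(params[["kappa"]], e$prev_a1))
    } else {
      g <- efe_final(e$belief, state, params[["pref_lambda"]], hyp_increment)
      ai_policy(g, params[["gamma2"]])
    }
  }
  learn <- function(trial) {
    e$belief <- update_beliefs(e$belief, trial, params,
                               prior_pull = prior_pull)
    e$counts <- update_counts(e$counts, trial$a1, trial$s2)
    e$prev_a1 <- trial$a1
    invisible(NULL)
  }
  list(act = act, learn = learn, reset = reset,
       state = function() as.list(e), params = params,
       model_id = paste0("ai_", attr(params, "variant")))
}

#' Build an agent from a model id and parameter vector
#'
#' @param model_id one of "hybrid", "mf", "mb", "ai_full", "ai_nud",
#'   "ai_nsd", "ai_nps".
#' @param params named numeric vector matching the model's parameters (see
#'   [parameter_spec()]); missing entries take defaults.
#' @param ... passed to the agent constructor.
#' @return an agent object.
#' @export
make_agent <- function(model_id, params, ...) {
  params <- as.list(params)
  if (model_id %in% c("hybrid", "mf", "mb")) {
    p <- do.call(hybrid_params, params[names(params) %in%
                                         names(formals(hybrid_params))])
    agent_hybrid(p, pure = if (model_id == "hybrid") "none" else model_id)
  } else if (model_id %in% c("ai_full", "ai_nud", "ai_nsd", "ai_nps")) {
    params$variant <- sub("^ai_", "", model_id)
    p <- do.call(ai_params, params[names(params) %in%
                                     names(formals(ai_params))])
    agent_active_inference(p, ...)
  } else {
    stop("unknown model_id: ", model_id, call. = FALSE)
  }
}
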
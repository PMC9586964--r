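# Shared fixtures, built in code.

# A reproducible session generated by a hybrid agent.
make_hybrid_session <- function(n_trials = 201, seed = 101,
                                params = hybrid_params(w = 0.5, rho = 0.2)) {
  cfg <- task_config(n_trials = n_trials, seed = seed)
  run_session(agent_hybrid(params), cfg)
}

# A session of pure-random behaviour.
make_random_session <- function(n_trials = 201, seed = 202) {
  cfg <- task_config(n_trials = n_trials, seed = seed)
  run_session(agent_random(), cfg)
}

# Hand-built trial list (forced history) as a trials data frame.
forced_trials <- function(a1, s2, a2, o) {
  tr <- data.frame(t = seq_along(a1), a1 = a1, s2 = s2,
                   transition = rep(1L, length(a1)), a2 = a2, o = o)
  twostepAI:::new_session(task_config(n_trials = nrow(tr)), tr)
}

# Random parameter draw within a model's bounds.
draw_params <- function(model_id) {
  spec <- parameter_spec(model_id)
  stats::setNames(stats::runif(nrow(spec), spec$lower, spec$upper),
                  spec$name)
}

# Brute-force KL between Beta densities by adaptive quadrature: the
# expectation of the log-density ratio under Beta(a1, b1), written in the
# probability domain via quantiles (the mirrored upper-tail quantile keeps
# log(1 - x) finite when the mass piles onto 1) and integrated under the
# smoothstep substitution p = 3u^2 - 2u^3, whose vanishing endpoint
# derivative tames the logarithmic endpoint spikes.
beta_kl_quadrature <- function(a1, b1, a2, b2) {
  const <- lbeta(a2, b2) - lbeta(a1, b1)
  g <- function(p) {
    x <- pmax(stats::qbeta(p, a1, b1), .Machine$double.xmin)
    xc <- pmax(stats::qbeta(p, b1, a1, lower.tail = FALSE),
               .Machine$double.xmin)
    (a1 - a2) * log(x) + (b1 - b2) * log(xc) + const
  }
  h <- function(u) g(3 * u^2 - 2 * u^3) * 6 * u * (1 - u)
  stats::integrate(h, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 1000L)$value
}
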
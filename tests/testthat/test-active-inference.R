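test_that("predictive outcome probabilities are Beta means", {
  b <- belief_state(0.5)
  expect_equal(predictive_outcome_prob(b, 1, 1), 0.5)
  b$alpha[1, 1] <- 3
  b$beta[1, 1] <- 1
  expect_equal(predictive_outcome_prob(b, 1, 1), 0.75)
})

test_that("outcome preferences follow the Bernoulli kernel", {
  expect_equal(preference_log_prob(0), log(c(0.5, 0.5)))
  lp <- preference_log_prob(1)
  expect_equal(exp(lp[2]), exp(1) / (exp(1) + exp(-1)))
  expect_equal(round(exp(lp[2]), 4), 0.8808)
  expect_lt(abs(exp(preference_log_prob(10)[2]) - 1), 1e-8)
  expect_equal(sum(exp(lp)), 1)
})

test_that("Beta KL matches closed form, quadrature, and is a divergence", {
  expect_equal(beta_kl(1, 1, 1, 1), 0)
  expect_equal(beta_kl(2, 1, 1, 1), log(2) - 0.5)
  expect_error(beta_kl(0, 1, 1, 1), "positive")
  set.seed(5)
  for (i in 1:25) {
    pars <- runif(4, 0.3, 20)
    kl <- beta_kl(pars[1], pars[2], pars[3], pars[4])
    expect_gte(kl, 0)
    expect_equal(kl, beta_kl_quadrature(pars[1], pars[2], pars[3], pars[4]),
                 tolerance = 1e-6)
  }
})

test_that("expected free energy decomposes into extrinsic and intrinsic value", {
  b <- belief_state(0.5)  # Beta(1,1) everywhere
  # flat preferences: extrinsic value is ln 2, differences purely informational
  g0 <- efe_final(b, 1, pref_lambda = 0)
  expect_equal(g0, rep(log(2) - (log(2) - 0.5), 2))
  # lambda = 1: hand-computed value
  g1 <- efe_final(b, 1, pref_lambda = 1)
  expect_equal(g1, rep(1.1269 - 0.1931, 2), tolerance = 1e-4)
  # concentrated beliefs carry less to learn
  bc <- belief_state(0.5)
  bc$alpha[1, 1] <- bc$beta[1, 1] <- 100
  gc <- efe_final(bc, 1, pref_lambda = 0)
  expect_gt(gc[1], gc[2])  # less intrinsic value => larger G at lambda = 0
})

test_that("initial-stage free energy propagates through the structure", {
  G2 <- rbind(c(0.4, 0.6), c(0.9, 1.1))  # row sums 1.0 and 2.0
  m <- twostepAI:::transition_matrix(1L)
  expect_equal(efe_initial(G2, m), c(0.7 * 1 + 0.3 * 2, 0.3 * 1 + 0.7 * 2))
  # all equal G: both actions get twice the common value
  expect_equal(efe_initial(matrix(0.5, 2, 2), m), c(1, 1))
  expect_equal(diff(efe_initial(G2, twostepAI:::transition_matrix(3L))), 0)
})

test_that("habit bias repeats the previous initial action", {
  expect_equal(habit_bias(1, NA), c(0, 0))
  h <- habit_bias(1, prev_a1 = 1)
  expect_equal(round(h, 4), c(0.8808, 0.1192))
  expect_equal(sum(h), 1)
  expect_equal(habit_bias(1, prev_a1 = 2), rev(h))
  # kappa = 0: constant shift, policy unaffected
  expect_equal(ai_policy(c(1, 2), 3, habit_bias(0, 1)),
               ai_policy(c(1, 2), 3))
})

test_that("policy prefers low expected free energy", {
  expect_equal(ai_policy(c(0.9, 1.1), gamma = 0), c(0.5, 0.5))
  p <- ai_policy(c(0.9, 1.1), gamma = 5)
  expect_equal(round(p, 4), c(0.7311, 0.2689))
  expect_gt(p[1], p[2])
  expect_equal(ai_policy(c(1.9, 2.1), 5), p)  # shift invariance
  expect_equal(sum(p), 1)
})

test_that("surprise measures behave as required", {
  b <- belief_state(0.5)
  expect_equal(predictive_surprise(b, 1, 1, 1), log(2))
  b$alpha[1, 1] <- 9
  b$beta[1, 1] <- 1
  expect_equal(predictive_surprise(b, 1, 1, 0), -log(0.1))
  expect_lt(predictive_surprise(b, 1, 1, 1), predictive_surprise(b, 1, 1, 0))

  prior <- belief_state(0.5)
  expect_equal(bayes_factor_surprise(prior, prior, 1, 1, 1), 1)
  expect_equal(bayes_factor_surprise(b, prior, 1, 1, 0), 0.5 / 0.1)
  expect_gt(bayes_factor_surprise(b, prior, 1, 1, 1), 0)
})

test_that("adaptation rate is the odds-scaled surprise fraction", {
  expect_equal(adaptation_rate(0, 0.5), 0)
  expect_equal(adaptation_rate(log(2), 0.5), log(2) / (1 + log(2)))
  expect_error(adaptation_rate(1, 1), "nu")
  s <- seq(0, 5, length.out = 10)
  expect_true(all(diff(vapply(s, adaptation_rate, numeric(1),
                              nu = 0.3)) > 0))
  nus <- seq(0, 0.9, length.out = 10)
  expect_true(all(diff(vapply(nus, adaptation_rate, numeric(1),
                              S = 1)) > 0))
})

test_that("belief updates reduce to conjugate counting when kinetics are off", {
  p <- ai_params(l = 1, nu_ps = 0, nu_sd = 0, nu_ud = 0)
  b <- belief_state(0.5)
  sess <- make_random_session(n_trials = 60, seed = 31)
  counts1 <- matrix(0, 2, 2)
  counts0 <- matrix(0, 2, 2)
  for (i in seq_len(60)) {
    tr <- as.list(sess$trials[i, ])
    b <- update_beliefs(b, tr, p)
    counts1[tr$s2, tr$a2] <- counts1[tr$s2, tr$a2] + tr$o
    counts0[tr$s2, tr$a2] <- counts0[tr$s2, tr$a2] + (1 - tr$o)
  }
  expect_equal(unname(b$alpha), 1 + counts1)
  expect_equal(unname(b$beta), 1 + counts0)
})

test_that("unsampled-pair decay pulls beliefs toward the prior", {
  p <- ai_params(nu_ud = 0.1, variant = "full")
  b <- belief_state(0.5)
  b$alpha[2, 2] <- 5  # unsampled pair, Beta(5, 1)
  trial <- list(s2 = 1L, a2 = 1L, o = 1L)
  b2 <- update_beliefs(b, trial, p)
  expect_equal(b2$alpha[2, 2], 0.9 * 5 + 0.1 * 1)
  expect_equal(b2$beta[2, 2], 1)
  # mean moves strictly toward the prior mean each trial
  m1 <- b$alpha[2, 2] / (b$alpha[2, 2] + b$beta[2, 2])
  m2 <- b2$alpha[2, 2] / (b2$alpha[2, 2] + b2$beta[2, 2])
  expect_lt(m2, m1)
  expect_gt(m2, 0.5)
})

test_that("variants force their volatility parameter to zero", {
  p <- ai_params(nu_ps = 0.5, nu_sd = 0.5, nu_ud = 0.5, variant = "nps")
  expect_equal(p[["nu_ps"]], 0)
  expect_equal(p[["nu_sd"]], 0.5)
  p2 <- ai_params(nu_ud = 0.3, variant = "nud")
  expect_equal(p2[["nu_ud"]], 0)
  p3 <- ai_params(nu_sd = 0.3, variant = "nsd")
  expect_equal(p3[["nu_sd"]], 0)
})

test_that("intrinsic value shrinks with concentration at fixed mean", {
  lam <- 0
  g <- vapply(c(2, 4, 8, 16, 64), function(total) {
    b <- belief_state(0.5, prior_total = total)
    efe_final(b, 1, lam)[1]
  }, numeric(1))
  # G = const - intrinsic at lambda 0, so G must increase with concentration
  expect_true(all(diff(g) > 0))
})

test_that("a preference-free agent seeks the rarely sampled action", {
  p <- ai_params(pref_lambda = 0, gamma2 = 5, l = 1)
  b <- belief_state(0.5)
  # forced history: action 1 in state 1 sampled 20 times, action 2 once
  outcomes <- rep(c(1L, 0L), 10)
  for (o in outcomes) {
    b <- update_beliefs(b, list(s2 = 1L, a2 = 1L, o = o), p)
  }
  b <- update_beliefs(b, list(s2 = 1L, a2 = 2L, o = 1L), p)
  probs <- ai_policy(efe_final(b, 1, 0), gamma = 5)
  expect_gt(probs[2], 0.5)
})
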
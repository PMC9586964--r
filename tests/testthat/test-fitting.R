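test_that("replay likelihood matches hand-computable cases", {
  sess <- make_random_session(n_trials = 40, seed = 41)
  # zero inverse temperatures: uniform policy at both stages
  p0 <- c(beta1 = 0, beta2 = 0, rho = 0)
  expect_equal(session_neg_log_likelihood("hybrid", p0, sess),
               2 * 40 * log(2))
  a0 <- c(gamma1 = 0, gamma2 = 0, kappa = 0)
  expect_equal(session_neg_log_likelihood("ai_full", a0, sess),
               2 * 40 * log(2))
  # replay is deterministic under truncation and re-append
  p <- draw_params("hybrid")
  full <- session_neg_log_likelihood("hybrid", p, sess)
  expect_equal(session_neg_log_likelihood("hybrid", p, sess), full)
})

test_that("compiled and reference replay engines agree exactly", {
  sess <- make_hybrid_session(n_trials = 120, seed = 42)
  set.seed(43)
  for (i in 1:4) {
    ph <- draw_params("hybrid")
    expect_equal(session_neg_log_likelihood("hybrid", ph, sess, "cpp"),
                 session_neg_log_likelihood("hybrid", ph, sess, "r"),
                 tolerance = 1e-12)
  }
  for (m in c("ai_full", "ai_nud", "ai_nsd", "ai_nps")) {
    pa <- draw_params(m)
    expect_equal(session_neg_log_likelihood(m, pa, sess, "cpp"),
                 session_neg_log_likelihood(m, pa, sess, "r"),
                 tolerance = 1e-12)
  }
  # alternative kinetics flags propagate to both engines
  pa <- draw_params("ai_full")
  expect_equal(
    session_neg_log_likelihood("ai_full", pa, sess, "cpp",
                               prior_pull = TRUE, hyp_increment = 0.5),
    session_neg_log_likelihood("ai_full", pa, sess, "r",
                               prior_pull = TRUE, hyp_increment = 0.5),
    tolerance = 1e-12)
})

test_that("hybrid weight limits reproduce the pure agents exactly", {
  sess <- make_hybrid_session(n_trials = 150, seed = 44)
  base <- c(alpha1 = 0.4, alpha2 = 0.6, elig_lambda = 0.7,
            beta1 = 4, beta2 = 3, rho = 0.4)
  for (engine in c("cpp", "r")) {
    expect_identical(
      session_neg_log_likelihood("hybrid", c(base, w = 0), sess, engine),
      session_neg_log_likelihood("mf", base, sess, engine))
    expect_identical(
      session_neg_log_likelihood("hybrid", c(base, w = 1), sess, engine),
      session_neg_log_likelihood("mb", base, sess, engine))
  }
})

test_that("information criteria match their definitions", {
  ic <- information_criteria(-150, 7, 200)
  expect_equal(ic[["aic"]], 314)
  expect_equal(ic[["bic"]], 7 * log(200) + 300)
  expect_equal(round(ic[["bic"]], 3), 337.088)
  expect_equal(information_criteria(-10, 0, 50),
               c(aic = 20, bic = 20))
})

test_that("multi-restart fitting is deterministic and restart-monotone", {
  sess <- make_hybrid_session(n_trials = 120, seed = 45)
  f1 <- fit_twostep(sess, "hybrid", n_restarts = 3, seed = 7)
  f2 <- fit_twostep(sess, "hybrid", n_restarts = 3, seed = 7)
  expect_identical(f1$free_params, f2$free_params)
  expect_identical(f1$logLik, f2$logLik)
  # nested restart sets: more restarts can only improve the best result
  f5 <- fit_twostep(sess, "hybrid", n_restarts = 6, seed = 7)
  expect_gte(f5$logLik, f1$logLik)
  expect_equal(f5$restarts$nll[1:3], f1$restarts$nll)
  # bookkeeping
  expect_equal(f1$k, 7)
  expect_equal(f1$aic, information_criteria(f1$logLik, 7, 120)[["aic"]])
  expect_gte(f1$logLik, -min(f1$restarts$nll) - 1e-10)
})

test_that("fitting recovers a strongly model-based agent", {
  cfg <- task_config(n_trials = 1000, seed = 46)
  gen <- hybrid_params(alpha1 = 0.5, alpha2 = 0.5, elig_lambda = 0.5,
                       w = 1, beta1 = 5, beta2 = 5, rho = 0)
  sess <- run_session(agent_hybrid(gen), cfg)
  fit <- fit_twostep(sess, "hybrid", n_restarts = 8, seed = 8)
  expect_gte(coef(fit)[["w"]], 0.8)
  # MLE beats the generating parameters on its own data
  nll_true <- session_neg_log_likelihood("hybrid", unclass(gen), sess)
  expect_lte(-fit$logLik, nll_true)
})

test_that("fit objects expose standard methods", {
  sess <- make_hybrid_session(n_trials = 80, seed = 47)
  fit <- fit_twostep(sess, "hybrid", n_restarts = 2, seed = 9)
  expect_s3_class(fit, "twostep_fit")
  expect_named(coef(fit),
               c("alpha1", "alpha2", "elig_lambda", "w", "beta1", "beta2",
                 "rho"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 7)
  expect_output(print(fit), "hybrid")
  sims <- simulate(fit, nsim = 2, seed = 5, config = task_config(50))
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]$trials), 50)
  sims2 <- simulate(fit, nsim = 2, seed = 5, config = task_config(50))
  expect_identical(sims[[1]]$trials, sims2[[1]]$trials)
})

test_that("parameter specs encode the documented bounds", {
  sh <- parameter_spec("hybrid")
  expect_equal(nrow(sh), 7)
  sf <- parameter_spec("ai_full")
  expect_equal(nrow(sf), 9)
  expect_equal(sf$upper[sf$name == "pref_lambda"], 10)
  for (m in c("ai_nud", "ai_nsd", "ai_nps")) {
    expect_equal(nrow(parameter_spec(m)), 8)
  }
  expect_false("nu_ps" %in% parameter_spec("ai_nps")$name)
})
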
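fake_fit <- function(model_id, params) {
  structure(list(model_id = model_id,
                 params = full_params_for(model_id, params)),
            class = "twostep_fit")
}
full_params_for <- function(model_id, params) {
  twostepAI:::full_param_vector(model_id, params)
}

test_that("simulation from fits is deterministic and correctly sized", {
  fits <- list(fake_fit("hybrid", c(w = 0.8, beta1 = 4, beta2 = 4)),
               fake_fit("ai_nps", c(pref_lambda = 2, gamma1 = 5)))
  cfg <- task_config(n_trials = 40)
  sims <- simulate_from_fits(fits, cfg, n_runs = 3, seed = 61)
  expect_length(sims, 2)
  expect_length(sims[[1]], 3)
  expect_equal(nrow(sims[[2]][[1]]$trials), 40)
  sims2 <- simulate_from_fits(fits, cfg, n_runs = 3, seed = 61)
  expect_identical(sims[[1]][[2]]$trials, sims2[[1]][[2]]$trials)
  sims3 <- simulate_from_fits(fits, cfg, n_runs = 3, seed = 62)
  expect_false(identical(sims[[1]][[1]]$trials, sims3[[1]][[1]]$trials))
})

test_that("lambda stratification splits at the threshold", {
  fits <- lapply(c(0.3, 1.5, 10, 1.49), function(l)
    fake_fit("ai_full", c(pref_lambda = l)))
  groups <- stratify_by_lambda(fits, threshold = 1.5)
  lam <- function(g) vapply(g, function(f) f$params[["pref_lambda"]],
                            numeric(1))
  expect_equal(lam(groups$low), c(0.3, 1.49))
  expect_equal(lam(groups$high), c(1.5, 10))  # boundary joins high group
})

test_that("the group reward comparison is a Welch t-test", {
  make_reward_session <- function(rate, n = 50) {
    forced_trials(rep(1L, n), rep(1L, n), rep(1L, n),
                  as.integer(seq_len(n) <= round(rate * n)))
  }
  g <- lapply(c(0.4, 0.5, 0.6), make_reward_session)
  same <- group_reward_welch(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$mean_diff_pct, 0)

  low <- lapply(c(0.40, 0.45, 0.50, 0.55), make_reward_session)
  high <- lapply(c(0.50, 0.55, 0.60, 0.65), make_reward_session)
  res <- group_reward_welch(low, high)
  x <- vapply(low, function(s) mean(s$trials$o), numeric(1))
  y <- vapply(high, function(s) mean(s$trials$o), numeric(1))
  t_hand <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(res$t, t_hand)
  expect_lt(res$t, 0)  # high group earns more => negative statistic
  expect_equal(res$mean_diff_pct, 100 * (mean(y) - mean(x)) / mean(x))
  rev <- group_reward_welch(high, low)
  expect_equal(rev$t, -res$t)
  expect_error(group_reward_welch(low[1], high), "2 subjects")
})

test_that("correlation measures handle skew and degeneracy", {
  set.seed(63)
  x <- rexp(40)
  y <- 2 * x + rnorm(40, 0, 0.1)
  cm <- corr_measures(x, y)
  expect_gt(cm[["pearson_log"]], 0.9)
  expect_gt(cm[["spearman"]], 0.9)
  # negative values are handled by the offset
  cm2 <- corr_measures(x - 10, y)
  expect_gt(cm2[["pearson_log"]], 0.9)
  expect_true(is.na(corr_measures(rep(1, 5), 1:5)[["spearman"]]))
})

test_that("parameter recovery refits simulated subjects", {
  set.seed(64)
  true <- data.frame(alpha1 = c(0.3, 0.5, 0.7, 0.4, 0.6),
                     alpha2 = 0.5, elig_lambda = 0.5,
                     w = c(0.1, 0.9, 0.5, 0.95, 0.05),
                     beta1 = 6, beta2 = 6, rho = 0)
  sessions <- lapply(seq_len(nrow(true)), function(i) {
    cfg <- task_config(n_trials = 250, seed = 640 + i)
    run_session(agent_hybrid(do.call(hybrid_params, as.list(true[i, ]))),
                cfg)
  })
  rep <- parameter_recovery("hybrid", true, sessions, n_restarts = 4,
                            seed = 65)
  expect_s3_class(rep, "recovery_report")
  expect_equal(dim(rep$recovered), c(5, 7))
  spec <- parameter_spec("hybrid")
  for (p in spec$name) {
    expect_true(all(rep$recovered[[p]] >= spec$lower[spec$name == p] - 1e-9))
    expect_true(all(rep$recovered[[p]] <= spec$upper[spec$name == p] + 1e-9))
  }
  # the strongly varied weight parameter must show a positive association
  expect_gt(cor(true$w, rep$recovered$w, method = "spearman"), 0.5)
  expect_error(parameter_recovery("hybrid", true,
                                  replicate(5, forced_trials(integer(0),
                                                             integer(0),
                                                             integer(0),
                                                             integer(0)),
                                            simplify = FALSE)),
               "at least one trial")
})

test_that("relative-fit correlation machinery runs end to end", {
  set.seed(66)
  n <- 12
  mk <- function(model_id, ll, lam = NA) {
    p <- if (is.na(lam)) c(w = 0.5) else c(pref_lambda = lam)
    f <- fake_fit(model_id, p)
    f$logLik <- ll
    f
  }
  lam <- runif(n, 0, 10)
  dll <- -0.5 * lam + rnorm(n, 0, 0.5)  # low lambda -> AI fits better
  ai <- lapply(seq_len(n), function(i) mk("ai_full", dll[i], lam[i]))
  hy <- lapply(seq_len(n), function(i) mk("hybrid", 0))
  beta_int <- 0.3 * dll + rnorm(n, 0, 0.2)
  res <- relative_fit_correlations(ai, hy, beta_int)
  expect_equal(res$delta_loglik, dll)
  expect_lt(res$lambda_vs_fit[["spearman"]], 0)
  expect_gt(res$interaction_vs_fit[["spearman"]], 0)
  expect_true(all(abs(c(res$lambda_vs_fit, res$interaction_vs_fit)) <= 1))
})

test_that("low-preference agents show stronger transition aversion at lags 2-3", {
  n_per_group <- 50
  sim_group <- function(lambda, seed0) {
    coefs <- lapply(seq_len(n_per_group), function(i) {
      cfg <- task_config(n_trials = 201, seed = seed0 + i)
      p <- ai_params(pref_lambda = lambda, gamma1 = 8, gamma2 = 8,
                     l = 1, nu_ud = 0.2, variant = "full")
      history_regression(run_session(agent_active_inference(p), cfg))
    })
    average_coefficients(coefs)
  }
  low <- sim_group(0.1, 6700)
  high <- sim_group(8, 6900)
  expect_lt(mean(low[2:3, "transition"]), mean(high[2:3, "transition"]))
})
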
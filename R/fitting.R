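MODEL_IDS <- c("hybrid", "ai_full", "ai_nud", "ai_nsd", "ai_nps")

#' Parameter specification for a model
#'
#' Names, box bounds and free-parameter count used by the bounded
#' multi-restart optimiser. The preference precision is capped at 10 so a
#' pure preference-realisation strategy is representable; volatility
#' parameters are bounded just below 1 where their odds transform
#' diverges.
#'
#' @param model_id one of `r paste(MODEL_IDS, collapse = ", ")`.
#' @return data frame with columns name, lower, upper.
#' @export
parameter_spec <- function(model_id) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (model_id == "hybrid") {
    data.frame(
      name = c("alpha1", "alpha2", "elig_lambda", "w", "beta1", "beta2",
               "rho"),
      lower = c(0, 0, 0, 0, 0, 0, -5),
      upper = c(1, 1, 1, 1, 20, 20, 5)
    )
  } else {
    spec <- data.frame(
      name = c("pref_lambda", "kappa", "gamma1", "gamma2", "prior_mean",
               "l", "nu_ps", "nu_sd", "nu_ud"),
      lower = c(0, -5, 0, 0, 0.05, 0.01, 0, 0, 0),
      upper = c(10, 5, 20, 20, 0.95, 2, 0.999, 0.999, 0.999)
    )
    fixed <- switch(model_id, ai_full = NULL, ai_nud = "nu_ud",
                    ai_nsd = "nu_sd", ai_nps = "nu_ps")
    spec[!spec$name %in% fixed, , drop = FALSE]
  }
}

# Full ordered parameter vector for the replay engines, with variant-fixed
# volatilities zeroed and unspecified entries defaulted.
full_param_vector <- function(model_id, params) {
  params <- unlist(params)
  if (model_id %in% c("hybrid", "mf", "mb")) {
    full <- c(alpha1 = 0.5, alpha2 = 0.5, elig_lambda = 0.5, w = 0.5,
              beta1 = 5, beta2 = 5, rho = 0)
  } else {
    full <- c(pref_lambda = 1, kappa = 0, gamma1 = 5, gamma2 = 5,
              prior_mean = 0.5, l = 1, nu_ps = 0, nu_sd = 0, nu_ud = 0)
  }
  keep <- intersect(names(params), names(full))
  full[keep] <- params[keep]
  fixed <- switch(model_id, ai_nud = "nu_ud", ai_nsd = "nu_sd",
                  ai_nps = "nu_ps", NULL)
  if (!is.null(fixed)) full[fixed] <- 0
  full
}

#' Negative log-likelihood of a session under a model
#'
#' Replays the session trial by trial: at each trial the model's
#' probability of the subject's actual initial- and final-stage choices is
#' computed with all internal state (values, beliefs, transition counts,
#' stickiness/habit on the previous actual choice) conditioned on the
#' subject's actual history; choice probabilities are floored at 1e-12.
#'
#' @param model_id "hybrid", an "ai_*" variant, or "mf"/"mb" for the pure
#'   model-free / model-based agents.
#' @param params named parameter vector (missing entries take defaults).
#' @param session a `twostep_session`.
#' @param engine "cpp" (compiled replay, used by the fitter) or "r"
#'   (reference replay built from the exported per-step operations).
#' @param prior_pull,hyp_increment see [update_beliefs()] and
#'   [efe_final()]; active-inference models only.
#' @return negative log-likelihood in nats (sum over both stages).
#' @export
session_neg_log_likelihood <- function(model_id, params, session,
                                       engine = c("cpp", "r"),
                                       prior_pull = FALSE,
                                       hyp_increment = 1) {
  engine <- match.arg(engine)
  tr <- session$trials
  full <- full_param_vector(model_id, params)
  if (engine == "cpp") {
    if (model_id %in% c("hybrid", "mf", "mb")) {
      pure <- switch(model_id, hybrid = 0L, mf = 1L, mb = 2L)
      nll_hybrid_cpp(unname(full), tr$a1, tr$s2, tr$a2, tr$o, pure)
    } else {
      nll_ai_cpp(unname(full), tr$a1, tr$s2, tr$a2, tr$o,
                 prior_pull, hyp_increment)
    }
  } else {
    agent <- if (model_id %in% c("hybrid", "mf", "mb")) {
      make_agent(model_id, full)
    } else {
      make_agent(model_id, full, prior_pull = prior_pull,
                 hyp_increment = hyp_increment)
    }
    agent$reset()
    nll <- 0
    for (i in seq_len(nrow(tr))) {
      p1 <- agent$act(1L, 1L)
      nll <- nll - log(max(p1[tr$a1[i]], 1e-12))
      p2 <- agent$act(2L, tr$s2[i])
      nll <- nll - log(max(p2[tr$a2[i]], 1e-12))
      agent$learn(list(t = tr$t[i], a1 = tr$a1[i], s2 = tr$s2[i],
                       a2 = tr$a2[i], o = tr$o[i]))
    }
    nll
  }
}

#' Fit a two-step task model to one subject's session
#'
#' Maximum-likelihood estimation by session replay: bounded L-BFGS-B
#' minimisation of [session_neg_log_likelihood()] from `n_restarts`
#' uniform-random starting points within the parameter bounds; the restart
#' with the highest log-likelihood wins.
#'
#' @param session a `twostep_session` (or a trials data frame with columns
#'   a1, s2, a2, o).
#' @param model one of `r paste(MODEL_IDS, collapse = ", ")`.
#' @param n_restarts number of random restarts (default 25).
#' @param seed integer seed for the restart draws.
#' @param subject_id optional label carried into the result.
#' @param ... passed to [session_neg_log_likelihood()] (e.g. `prior_pull`).
#' @return an object of class `twostep_fit` with components `params` (full
#'   named vector), `logLik`, `aic`, `bic`, `k`, `n_trials`, and per-restart
#'   diagnostics. Methods: print, coef, logLik, summary, simulate.
#' @examples
#' cfg <- task_config(n_trials = 60, seed = 42)
#' sess <- run_session(agent_hybrid(hybrid_params(w = 1)), cfg)
#' fit <- fit_twostep(sess, "hybrid", n_restarts = 3, seed = 1)
#' coef(fit)
#' @export
fit_twostep <- function(session, model = "hybrid", n_restarts = 25,
                        seed = 1L, subject_id = NULL, ...) {
  model <- match.arg(model, MODEL_IDS)
  if (is.data.frame(session)) session <- new_session(NULL, session)
  stopifnot(n_restarts >= 1)
  spec <- parameter_spec(model)
  k <- nrow(spec)
  n <- nrow(session$trials)
  if (n < 1) stop("session has no trials", call. = FALSE)
  objective <- function(x) {
    names(x) <- spec$name
    v <- session_neg_log_likelihood(model, x, session, engine = "cpp", ...)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  # draw restart r's start as the r-th block of the seeded stream, so the
  # restart sets are nested across n_restarts
  starts <- t(vapply(seq_len(n_restarts), function(r)
    stats::runif(k, spec$lower, spec$upper), numeric(k)))
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    runs[[r]] <- tryCatch(
      stats::optim(starts[r, ], objective, method = "L-BFGS-B",
                   lower = spec$lower, upper = spec$upper,
                   control = list(maxit = 500, pgtol = 1e-6)),
      error = function(e) list(value = Inf, par = starts[r, ],
                               convergence = 99L, message = conditionMessage(e))
    )
  }
  values <- vapply(runs, function(x) x$value, numeric(1))
  if (all(!is.finite(values))) {
    stop("all optimisation restarts failed", call. = FALSE)
  }
  best <- which.min(values)
  par <- runs[[best]]$par
  names(par) <- spec$name
  ll <- -values[best]
  ic <- information_criteria(ll, k, n)
  structure(
    list(model_id = model,
         subject_id = subject_id %||% session$subject_id,
         params = full_param_vector(model, par),
         free_params = par,
         logLik = ll, aic = ic[["aic"]], bic = ic[["bic"]],
         k = k, n_trials = n, n_restarts = n_restarts, seed = seed,
         restarts = data.frame(restart = seq_len(n_restarts),
                               nll = values,
                               convergence = vapply(runs, function(x)
                                 as.integer(x$convergence), integer(1)))),
    class = "twostep_fit"
  )
}

#' @rdname fit_twostep
#' @param model_id model identifier (first argument order used by the
#'   batch-processing helpers).
#' @export
fit_subject <- function(model_id, session, n_restarts = 25, seed = 1L,
                        subject_id = NULL, ...) {
  fit_twostep(session, model = model_id, n_restarts = n_restarts,
              seed = seed, subject_id = subject_id, ...)
}

#' Akaike and Bayesian information criteria
#'
#' AIC = 2k - 2 ln L; BIC = k ln(n) - 2 ln L.
#'
#' @param max_loglik maximised log-likelihood (nats).
#' @param k number of free parameters.
#' @param n number of trials.
#' @return c(aic, bic).
#' @export
information_criteria <- function(max_loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  c(aic = 2 * k - 2 * max_loglik,
    bic = k * log(n) - 2 * max_loglik)
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat("Two-step task model fit (", x$model_id, ")\n", sep = "")
  if (!is.null(x$subject_id) && !is.na(x$subject_id)) {
    cat("  subject:", x$subject_id, "\n")
  }
  cat("  trials: ", x$n_trials, ",  restarts: ", x$n_restarts, "\n", sep = "")
  cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f  (k = %d)\n",
              x$logLik, x$aic, x$bic, x$k))
  cat("  parameters:\n")
  print(round(x$free_params, 4))
  invisible(x)
}

#' @export
coef.twostep_fit <- function(object, ...) object$params

#' @export
logLik.twostep_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_trials,
            class = "logLik")
}

#' @export
summary.twostep_fit <- function(object, ...) {
  conv <- sum(object$restarts$convergence == 0)
  cat(sprintf("%s fit: logLik %.3f (best of %d restarts, %d converged)\n",
              object$model_id, object$logLik, object$n_restarts, conv))
  print(object)
  invisible(object)
}

#' Simulate fresh sessions from a fitted model
#'
#' @param object a `twostep_fit`.
#' @param nsim number of sessions.
#' @param seed master seed; per-session seeds are derived from it.
#' @param config a [task_config()] for the simulated environment.
#' @param ... unused.
#' @return a list of `twostep_session` objects (a single session if
#'   `nsim = 1`).
#' @export
simulate.twostep_fit <- function(object, nsim = 1, seed = NULL,
                                 config = task_config(), ...) {
  agent <- make_agent(object$model_id, object$params)
  seeds <- if (is.null(seed)) rep(list(NULL), nsim) else
    as.list(derive_seeds(seed, nsim))
  out <- lapply(seq_len(nsim), function(i) {
    cfg <- config
    cfg$seed <- seeds[[i]]
    run_session(agent, cfg)
  })
  if (nsim == 1) out[[1]] else out
}
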
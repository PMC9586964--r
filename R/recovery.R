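#' Simulate sessions from fitted parameters
#'
#' Posterior-predictive style simulation: each subject's fitted parameters
#' drive `n_runs` fresh closed-loop sessions (default 20), with per-run
#' seeds derived deterministically from the master seed.
#'
#' @param fits list of `twostep_fit` objects (one per subject).
#' @param config a [task_config()] for the simulated environment.
#' @param n_runs sessions per subject.
#' @param seed master integer seed.
#' @return list (per subject) of lists of `twostep_session` objects.
#' @export
simulate_from_fits <- function(fits, config = task_config(), n_runs = 20,
                               seed = 1L) {
  seeds <- derive_seeds(seed, length(fits))
  lapply(seq_along(fits), function(i) {
    out <- simulate(fits[[i]], nsim = n_runs, seed = seeds[i],
                    config = config)
    if (n_runs == 1) list(out) else out
  })
}

#' Offset-log Pearson and Spearman correlations
#'
#' Pearson's r on log-transformed values after offsetting both variables so
#' their minimum is 1 (the standard treatment for the strongly skewed
#' preference-precision estimates), together with Spearman's rank
#' correlation on the untransformed values.
#'
#' @param x,y numeric vectors.
#' @return c(pearson_log, spearman); entries are NA when a variable is
#'   constant.
#' @export
corr_measures <- function(x, y) {
  log_offset <- function(v) log(v - min(v) + 1)
  safe_cor <- function(a, b, method) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = method)
  }
  c(pearson_log = safe_cor(log_offset(x), log_offset(y), "pearson"),
    spearman = safe_cor(x, y, "spearman"))
}

#' Parameter recovery from simulated sessions
#'
#' Refits each synthetic subject's session(s) and correlates true with
#' recovered parameter values (offset-log Pearson and Spearman, per
#' parameter). When a subject has several sessions the recovered value is
#' the mean across per-session fits.
#'
#' @param model_id model to refit.
#' @param true_params data frame of generating parameters, one row per
#'   subject, columns named as in [parameter_spec()].
#' @param sessions list (per subject) of a `twostep_session` or list of
#'   sessions simulated from those parameters.
#' @param n_restarts restarts per refit (default 25, matching primary
#'   fits).
#' @param seed master seed for the refits.
#' @return object of class `recovery_report`: `true`, `recovered` (data
#'   frames) and `correlations` (parameter x measure matrix).
#' @export
parameter_recovery <- function(model_id, true_params, sessions,
                               n_restarts = 25, seed = 1L) {
  stopifnot(nrow(true_params) == length(sessions))
  if (any(vapply(sessions, function(s) {
    ss <- if (inherits(s, "twostep_session")) list(s) else s
    any(vapply(ss, function(x) nrow(x$trials) == 0, logical(1)))
  }, logical(1)))) {
    stop("sessions must contain at least one trial", call. = FALSE)
  }
  spec <- parameter_spec(model_id)
  seeds <- derive_seeds(seed, length(sessions))
  recovered <- lapply(seq_along(sessions), function(i) {
    ss <- sessions[[i]]
    if (inherits(ss, "twostep_session")) ss <- list(ss)
    fits <- lapply(seq_along(ss), function(j) {
      fit_twostep(ss[[j]], model = model_id, n_restarts = n_restarts,
                  seed = seeds[i] + j - 1L)
    })
    colMeans(do.call(rbind, lapply(fits, function(f) f$free_params)))
  })
  recovered <- as.data.frame(do.call(rbind, recovered))
  true_params <- true_params[, spec$name, drop = FALSE]
  correlations <- t(vapply(spec$name, function(p) {
    corr_measures(true_params[[p]], recovered[[p]])
  }, numeric(2)))
  structure(list(model_id = model_id, true = true_params,
                 recovered = recovered, correlations = correlations),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery (", x$model_id, "), ",
      nrow(x$true), " synthetic subjects\n", sep = "")
  print(round(x$correlations, 3))
  invisible(x)
}

#' Stratify fits by preference precision
#'
#' Splits active-inference fits into a low group (pref_lambda <
#' `threshold`) and a high group (>= threshold; the boundary goes to the
#' high group).
#'
#' @param fits list of `twostep_fit` objects for active-inference models.
#' @param threshold split point (default 1.5).
#' @return list with elements `low` and `high` (lists of fits).
#' @export
stratify_by_lambda <- function(fits, threshold = 1.5) {
  lam <- vapply(fits, function(f) f$params[["pref_lambda"]], numeric(1))
  list(low = fits[lam < threshold], high = fits[lam >= threshold])
}

#' Welch's t-test on per-subject mean obtained reward
#'
#' Compares average obtained reward between a low and a high
#' preference-precision group (unequal variances and sizes). The statistic
#' is signed as low minus high, so a better-performing high group yields a
#' negative t.
#'
#' @param low_sessions,high_sessions lists with one element per subject: a
#'   `twostep_session` or a list of sessions (averaged within subject).
#' @return list with `t`, `p`, `mean_diff_pct` (100 * (high - low) / low),
#'   and per-group mean rewards.
#' @export
group_reward_welch <- function(low_sessions, high_sessions) {
  subject_reward <- function(s) {
    ss <- if (inherits(s, "twostep_session")) list(s) else s
    mean(vapply(ss, function(x) mean(x$trials$o), numeric(1)))
  }
  low <- vapply(low_sessions, subject_reward, numeric(1))
  high <- vapply(high_sessions, subject_reward, numeric(1))
  if (length(low) < 2 || length(high) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  tt <- stats::t.test(low, high, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff_pct = 100 * (mean(high) - mean(low)) / mean(low),
       mean_low = mean(low), mean_high = mean(high))
}

#' Correlations between relative model fit and behavioural markers
#'
#' Relative fit is delta logLik = logLik(best active-inference model) -
#' logLik(hybrid), per subject. Returns its correlation (offset-log
#' Pearson and Spearman) with the lag-1 outcome-by-transition interaction
#' coefficient (a model-based-inference proxy) and with the fitted
#' preference precision.
#'
#' @param ai_fits list of active-inference `twostep_fit`s (the subject's
#'   best AI model).
#' @param hybrid_fits list of hybrid `twostep_fit`s, same subject order.
#' @param lag1_interaction numeric vector of lag-1 interaction regression
#'   coefficients, same order.
#' @return list with `delta_loglik` and matrices of correlation measures.
#' @export
relative_fit_correlations <- function(ai_fits, hybrid_fits,
                                      lag1_interaction) {
  stopifnot(length(ai_fits) == length(hybrid_fits),
            length(ai_fits) == length(lag1_interaction))
  dll <- vapply(ai_fits, function(f) f$logLik, numeric(1)) -
    vapply(hybrid_fits, function(f) f$logLik, numeric(1))
  lam <- vapply(ai_fits, function(f) f$params[["pref_lambda"]], numeric(1))
  list(delta_loglik = dll,
       interaction_vs_fit = corr_measures(lag1_interaction, dll),
       lambda_vs_fit = corr_measures(lam, dll))
}
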
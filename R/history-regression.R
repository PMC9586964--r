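#' Recode a session for the trial-history regression
#'
#' Codes the initial-stage choice, outcome and transition of each trial as
#' +1/-1: choices action1 -> -1 and action2 -> +1, outcomes +1 for the
#' preferred event (reward obtained, or shock absent when
#' `config$outcome_valence` is FALSE), transitions +1 for common and -1
#' for rare.
#'
#' @param session a `twostep_session`.
#' @return list with elements `y` (choice codes, also used as the lagged
#'   regressor), `o` and `tau`.
#' @export
encode_session <- function(session) {
  tr <- session$trials
  if (is.null(tr$a1) || is.null(tr$o) || is.null(tr$transition)) {
    stop("session is missing required trial fields", call. = FALSE)
  }
  pos_is_one <- is.null(session$config) ||
    isTRUE(session$config$outcome_valence)
  o_pref <- if (pos_is_one) tr$o else 1L - tr$o
  list(y = ifelse(tr$a1 == 2L, 1, -1),
       o = ifelse(o_pref == 1L, 1, -1),
       tau = ifelse(tr$transition == 1L, 1, -1))
}

#' Build the lagged design matrix for the history regression
#'
#' One row per trial with a complete T-trial history; for each lag j the
#' four columns are the lagged choice x, outcome-by-choice o*x,
#' transition-by-choice tau*x, and the three-way interaction o*tau*x. The
#' lagged-choice terms play the role of the intercept, so no separate
#' intercept column is included.
#'
#' @param coded output of [encode_session()].
#' @param T number of preceding trials (default 4).
#' @return list with `X` ((n - T) x 4T design matrix) and `y` (responses in
#'   -1/+1).
#' @export
build_design <- function(coded, T = 4) {
  n <- length(coded$y)
  if (n <= T) stop("session too short for ", T, " lags", call. = FALSE)
  rows <- (T + 1):n
  cols <- lapply(seq_len(T), function(j) {
    x <- coded$y[rows - j]
    o <- coded$o[rows - j]
    tau <- coded$tau[rows - j]
    m <- cbind(x, o * x, tau * x, o * tau * x)
    colnames(m) <- paste0(c("choice", "outcome", "transition",
                            "interaction"), "_lag", j)
    m
  })
  X <- do.call(cbind, cols)
  constant <- apply(X, 2, function(col) length(unique(col)) == 1)
  if (any(constant)) {
    attr(X, "constant_columns") <- colnames(X)[constant]
  }
  list(X = X, y = coded$y[rows])
}

#' Fit the penalised trial-history logistic regression
#'
#' Logistic regression of the initial-stage choice on the lagged history
#' regressors, without an intercept, with a light L2 penalty (objective:
#' sum of log-losses + penalty/2 * ||beta||^2; the default penalty of 1
#' mirrors the common general-purpose default and guarantees a finite
#' solution under separation). Deterministic BFGS optimisation with
#' analytic gradients.
#'
#' @param X design matrix from [build_design()].
#' @param y responses in -1/+1.
#' @param penalty L2 penalty strength (0 for unpenalised).
#' @return named coefficient vector (log-odds units).
#' @export
fit_history_regression <- function(X, y, penalty = 1) {
  stopifnot(length(unique(y)) >= 2)
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-y * eta))) + penalty / 2 * sum(b^2)
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    -drop(crossprod(X, y * stats::plogis(-y * eta))) + penalty * b
  }
  fit <- stats::optim(rep(0, ncol(X)), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  stats::setNames(fit$par, colnames(X))
}

#' Trial-history regression of a session
#'
#' Convenience wrapper: encode, build the lagged design, fit, and reshape
#' the 4T coefficients into a lag x term matrix.
#'
#' @param session a `twostep_session`.
#' @param T number of lags.
#' @param penalty L2 penalty (see [fit_history_regression()]).
#' @return T x 4 matrix, rows lag1..lagT, columns choice, outcome,
#'   transition, interaction.
#' @export
history_regression <- function(session, T = 4, penalty = 1) {
  d <- build_design(encode_session(session), T = T)
  b <- fit_history_regression(d$X, d$y, penalty = penalty)
  matrix(b, nrow = T, ncol = 4, byrow = TRUE,
         dimnames = list(paste0("lag", seq_len(T)),
                         c("choice", "outcome", "transition",
                           "interaction")))
}

#' Average history-regression coefficients across simulation runs
#'
#' @param coeff_list nonempty list of coefficient matrices (or vectors) of
#'   identical shape.
#' @return elementwise mean.
#' @export
average_coefficients <- function(coeff_list) {
  if (length(coeff_list) == 0) stop("empty coefficient list", call. = FALSE)
  Reduce(`+`, coeff_list) / length(coeff_list)
}

#' Coefficients as a tidy table
#'
#' @param coefs lag x term coefficient matrix (possibly averaged).
#' @param subject_id label for the subject column.
#' @return data frame with columns subject_id, lag, term, estimate.
#' @export
coefficients_table <- function(coefs, subject_id = NA) {
  data.frame(subject_id = subject_id,
             lag = rep(seq_len(nrow(coefs)), times = ncol(coefs)),
             term = rep(colnames(coefs), each = nrow(coefs)),
             estimate = as.vector(coefs),
             stringsAsFactors = FALSE)
}
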
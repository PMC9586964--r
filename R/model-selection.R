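#' Assemble a log-evidence matrix from per-subject fits
#'
#' Approximates each subject-model log evidence as -AIC/2 or -BIC/2.
#'
#' @param fit_results list of lists of `twostep_fit` objects: one inner
#'   list per subject, one fit per model; or a subjects x models matrix of
#'   criterion values.
#' @param criterion "aic" or "bic".
#' @return subjects x models numeric matrix of log evidences, with model
#'   ids as column names where available.
#' @export
evidence_from_criteria <- function(fit_results, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (is.matrix(fit_results)) {
    ev <- -fit_results / 2
  } else {
    rows <- lapply(fit_results, function(subject_fits) {
      vals <- vapply(subject_fits, function(f) f[[criterion]], numeric(1))
      names(vals) <- vapply(subject_fits, function(f) f$model_id,
                            character(1))
      vals
    })
    model_ids <- names(rows[[1]])
    if (!all(vapply(rows, function(r) identical(names(r), model_ids),
                    logical(1)))) {
      stop("all subjects must have fits for the same models in the same order",
           call. = FALSE)
    }
    ev <- -do.call(rbind, rows) / 2
  }
  if (any(!is.finite(ev))) stop("non-finite evidence", call. = FALSE)
  attr(ev, "criterion") <- criterion
  ev
}

#' Random-effects Bayesian model selection
#'
#' Variational inference on a Dirichlet-multinomial hierarchy over model
#' frequencies in the population: per-subject model posteriors are
#' proportional to exp(log-evidence + digamma(alpha_k) - digamma(sum
#' alpha)), and the Dirichlet concentrations accumulate the posteriors,
#' iterated to convergence. Exceedance probabilities (probability that each
#' model is the most frequent) are estimated by Monte-Carlo Dirichlet
#' sampling; protected exceedance probabilities additionally account for
#' the chance that all models are equally frequent (see [protected_xp()]).
#'
#' @param evidence subjects x models matrix of log evidences (see
#'   [evidence_from_criteria()]).
#' @param prior_alpha Dirichlet prior concentrations (scalar or per-model
#'   vector; default uniform 1).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @param seed seed for the Monte-Carlo draws.
#' @param tol convergence threshold on max |delta alpha|.
#' @param max_iter iteration cap.
#' @param responsibilities "digamma" for the standard variational update
#'   (subject posteriors weighted by exp(digamma(alpha_k) - digamma(sum
#'   alpha))), or "mean" to weight by the expected frequencies
#'   alpha_k / sum(alpha). The two coincide for uniform priors and strong
#'   evidence; the mean form reproduces the exact posterior under
#'   uninformative evidence with non-uniform priors and is used for
#'   family-level inference.
#' @return object of class `bms_result`: `alpha` (posterior Dirichlet
#'   concentrations), `expected_r` (expected posterior model frequencies),
#'   `xp`, `pxp`, `bor` (Bayesian omnibus risk), `subject_posteriors`
#'   (subjects x models), and the free energies of the random-effects and
#'   null models.
#' @export
rfx_bms <- function(evidence, prior_alpha = 1, n_samples = 1e6,
                    seed = 1L, tol = 1e-6, max_iter = 10000,
                    responsibilities = c("digamma", "mean")) {
  responsibilities <- match.arg(responsibilities)
  if (any(!is.finite(evidence))) stop("non-finite evidence", call. = FALSE)
  n <- nrow(evidence)
  K <- ncol(evidence)
  stopifnot(n >= 1, K >= 2)
  alpha0 <- rep_len(prior_alpha, K)
  alpha <- alpha0
  u <- matrix(0, n, K)
  for (it in seq_len(max_iter)) {
    wk <- if (responsibilities == "digamma") {
      digamma(alpha) - digamma(sum(alpha))
    } else {
      log(alpha / sum(alpha))
    }
    lu <- sweep(evidence, 2, wk, "+")
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  expected_r <- alpha / sum(alpha)
  xp <- exceedance_probabilities(alpha, n_samples = n_samples, seed = seed)
  names(alpha) <- names(expected_r) <- names(xp) <- colnames(evidence)
  res <- structure(
    list(alpha = alpha, prior_alpha = alpha0, expected_r = expected_r,
         xp = xp, pxp = NULL, bor = NULL,
         subject_posteriors = u, evidence = evidence),
    class = "bms_result"
  )
  pr <- protected_xp(evidence, res, seed = seed)
  res$pxp <- pr$pxp
  res$bor <- pr$bor
  res$F_rfx <- pr$F_rfx
  res$F_null <- pr$F_null
  res
}

#' Monte-Carlo exceedance probabilities of a Dirichlet posterior
#'
#' Estimates P(r_k > r_j for all j != k) from Dirichlet samples.
#'
#' @param dirichlet_alpha positive concentration vector.
#' @param n_samples number of draws (default 1e6).
#' @param seed RNG seed.
#' @return probability vector summing to 1.
#' @export
exceedance_probabilities <- function(dirichlet_alpha, n_samples = 1e6,
                                     seed = 1L) {
  stopifnot(all(dirichlet_alpha > 0))
  K <- length(dirichlet_alpha)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  # Dirichlet draws via independent gammas; winner = argmax of the gammas
  wins <- integer(K)
  block <- 250000L
  done <- 0L
  while (done < n_samples) {
    m <- min(block, as.integer(n_samples - done))
    g <- matrix(stats::rgamma(m * K, shape = rep(dirichlet_alpha, each = m)),
                nrow = m)
    idx <- max.col(g, ties.method = "first")
    wins <- wins + tabulate(idx, nbins = K)
    done <- done + m
  }
  wins / sum(wins)
}

# Variational free energy of the random-effects model at its optimum.
rfx_free_energy <- function(evidence, alpha, alpha0, u) {
  psi_diff <- digamma(alpha) - digamma(sum(alpha))
  e_lik <- sum(u * sweep(evidence, 2, psi_diff, "+"))
  ent_z <- -sum(u[u > 0] * log(u[u > 0]))
  e_prior <- lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum((alpha0 - 1) * psi_diff)
  ent_q <- -(lgamma(sum(alpha)) - sum(lgamma(alpha)) +
               sum((alpha - 1) * psi_diff))
  e_lik + ent_z + e_prior + ent_q
}

#' Protected exceedance probabilities and Bayesian omnibus risk
#'
#' Compares the random-effects model against the null hypothesis that all
#' models are equally frequent in the population. The Bayesian omnibus risk
#' (BOR) is the posterior probability of the null given equal prior odds,
#' computed from the two models' (free) energies; protected exceedance
#' probabilities mix the exceedance probabilities with chance:
#' pxp = xp * (1 - BOR) + BOR / K.
#'
#' @param evidence subjects x models log-evidence matrix.
#' @param bms_result result of [rfx_bms()].
#' @param seed unused placeholder for interface stability.
#' @return list with `pxp`, `bor`, `F_rfx`, `F_null`.
#' @export
protected_xp <- function(evidence, bms_result, seed = 1L) {
  K <- ncol(evidence)
  # null: every subject's data marginalised over a fixed uniform frequency
  lse <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  F_null <- sum(apply(evidence, 1, function(e) lse(e - log(K))))
  F_rfx <- rfx_free_energy(evidence, bms_result$alpha,
                           bms_result$prior_alpha,
                           bms_result$subject_posteriors)
  bor <- 1 / (1 + exp(F_rfx - F_null))
  pxp <- bms_result$xp * (1 - bor) + bor / K
  list(pxp = pxp, bor = bor, F_rfx = F_rfx, F_null = F_null)
}

#' Family-level Bayesian model selection
#'
#' Partitions models into disjoint families and reruns [rfx_bms()] with
#' "F-unity" priors: each model's prior concentration is 1 divided by its
#' family's size, so every family carries unit prior mass. Family
#' frequencies are the summed member frequencies; family exceedance
#' probabilities are computed from family-aggregated Dirichlet draws.
#' (Protected exceedance probabilities are not defined at the family
#' level.)
#'
#' @param evidence subjects x models log-evidence matrix with column names.
#' @param families named list of character vectors partitioning the model
#'   (column) names.
#' @param n_samples,seed Monte-Carlo settings for the family exceedance
#'   probabilities.
#' @return object of class `bms_family_result`: the underlying model-level
#'   `bms_result` plus `family_expected_r` and `family_xp`.
#' @export
family_comparison <- function(evidence, families, n_samples = 1e6,
                              seed = 1L) {
  model_ids <- colnames(evidence)
  members <- unlist(families, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, model_ids)) {
    stop("families must partition the models exactly", call. = FALSE)
  }
  fam_of <- rep(names(families), lengths(families))
  names(fam_of) <- members
  fam_of <- fam_of[model_ids]
  prior <- 1 / lengths(families)[fam_of]
  bms <- rfx_bms(evidence, prior_alpha = unname(prior),
                 n_samples = n_samples, seed = seed,
                 responsibilities = "mean")
  fam_r <- c(tapply(bms$expected_r, fam_of, sum)[names(families)])
  # family exceedance: aggregate Dirichlet draws by family
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  K <- length(bms$alpha)
  nf <- length(families)
  agg <- outer(names(families), fam_of, "==") * 1  # nf x K indicator
  wins <- integer(nf)
  block <- 250000L
  done <- 0L
  while (done < n_samples) {
    m <- min(block, as.integer(n_samples - done))
    g <- matrix(stats::rgamma(m * K, shape = rep(bms$alpha, each = m)),
                nrow = m)
    fg <- g %*% t(agg)
    idx <- max.col(fg, ties.method = "first")
    wins <- wins + tabulate(idx, nbins = nf)
    done <- done + m
  }
  fam_xp <- wins / sum(wins)
  names(fam_xp) <- names(families)
  structure(c(unclass(bms),
              list(families = families,
                   family_expected_r = fam_r,
                   family_xp = fam_xp)),
            class = c("bms_family_result", "bms_result"))
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  cat("  subjects:", nrow(x$subject_posteriors),
      " models:", length(x$alpha), "\n")
  tab <- rbind(alpha = x$alpha, expected_r = x$expected_r, xp = x$xp,
               pxp = x$pxp)
  print(round(tab, 4))
  cat(sprintf("  Bayesian omnibus risk: %.4f\n", x$bor))
  if (!is.null(x$family_xp)) {
    cat("  family expected_r:",
        paste(sprintf("%s=%.3f", names(x$family_expected_r),
                      x$family_expected_r), collapse = ", "), "\n")
    cat("  family xp:        ",
        paste(sprintf("%s=%.3f", names(x$family_xp), x$family_xp),
              collapse = ", "), "\n")
  }
  invisible(x)
}
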
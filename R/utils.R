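#' Numerically stable softmax
#'
#' @param x numeric vector of (finite) scores.
#' @return probabilities summing to 1.
#' @keywords internal
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Bernoulli kernel of the preference/habit form
#'
#' Normalised two-point distribution `exp(d*k) * exp(-(1-d)*k) / Z(k)` over
#' d in {0, 1}, used for both the outcome preference and the habit bias.
#'
#' @param k precision parameter.
#' @return c(p(d = 0), p(d = 1)).
#' @keywords internal
bernoulli_kernel <- function(k) {
  # log weights -k and +k; normalised
  softmax(c(-k, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive sub-seeds from a master seed
#'
#' Deterministically expands one integer seed into `n` distinct seeds,
#' all below 2^31, so nested simulations stay reproducible.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  # capped at 2^30 so small additive offsets cannot overflow 32-bit ints
  sample.int(1073741824L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}
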
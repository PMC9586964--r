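#' Empty transition-count table
#'
#' Agents learn which initial action commonly leads to which final state by
#' counting observed transitions.
#'
#' @return 2x2 integer matrix of zeros, rows = initial action, columns =
#'   final state.
#' @export
transition_counts <- function() {
  matrix(0L, 2, 2, dimnames = list(action = c("a1", "a2"),
                                   state = c("sB", "sC")))
}

#' Record one observed transition
#'
#' @param counts matrix from [transition_counts()].
#' @param a1 initial action, 1 or 2.
#' @param s2 final state, 1 or 2.
#' @return updated count matrix.
#' @export
update_counts <- function(counts, a1, s2) {
  stopifnot(a1 %in% c(1L, 2L), s2 %in% c(1L, 2L))
  counts[a1, s2] <- counts[a1, s2] + 1L
  counts
}

#' Infer the most likely transition structure from counts
#'
#' Scores the three candidate structures -- action 1 commonly to state 1,
#' action 1 commonly to state 2 (both with the task's fixed 0.7/0.3
#' probabilities), and flat 0.5 -- by the product-Bernoulli likelihood of
#' the observed counts, and returns the maximiser. Ties (in particular zero
#' counts) resolve to the flat structure, representing ignorance before
#' evidence.
#'
#' @param counts matrix from [transition_counts()].
#' @param p_common common-transition probability of the non-flat candidates.
#' @return 2x2 transition probability matrix with attribute `structure_id`
#'   (1, 2, or 3 for flat).
#' @export
infer_structure <- function(counts, p_common = 0.7) {
  n_diag <- counts[1, 1] + counts[2, 2]
  n_off <- counts[1, 2] + counts[2, 1]
  ll <- c(n_diag * log(p_common) + n_off * log(1 - p_common),
          n_diag * log(1 - p_common) + n_off * log(p_common),
          (n_diag + n_off) * log(0.5))
  best <- which.max(ll)
  if (ll[3] >= max(ll[1], ll[2]) - 1e-12) best <- 3L
  m <- transition_matrix(best, p_common)
  attr(m, "structure_id") <- best
  m
}
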
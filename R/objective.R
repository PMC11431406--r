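#' Class decomposition of a histogram by a threshold set
#'
#' `m` strictly increasing integer thresholds `t_1 < ... < t_m` (each in
#' `[0, L-2]`) partition the gray axis into `m + 1` classes with inclusive
#' bounds: class 0 covers `[0, t_1]`, class `j` covers `[t_j + 1, t_{j+1}]`
#' and the last class covers `[t_m + 1, L-1]`.  Each class gets its
#' cumulative probability `P_j` and its renormalised within-class
#' distribution `p_i / P_j`.  A class with `P_j = 0` is flagged empty and
#' its within-class vector is all-zero.
#'
#' @param hist A `gray_histogram`.
#' @param t Integer vector of thresholds, strictly increasing.
#' @return A `class_decomposition`: list with `m`, `t`, `bounds` (tibble of
#'   inclusive `lower`/`upper` gray levels), `P` (cumulative probabilities,
#'   summing to 1), `within` (list of within-class vectors) and `empty`
#'   (logical).
#' @examples
#' h <- gen_histogram(rep(0.25, 4), 100)
#' class_probabilities(h, t = 1)
#' @export
class_probabilities <- function(hist, t) {
  stopifnot(inherits(hist, "gray_histogram"))
  t <- validate_thresholds(t, hist$L)
  lower <- c(0L, t + 1L)
  upper <- c(t, hist$L - 1L)
  P <- vapply(seq_along(lower),
              function(j) sum(hist$probs[(lower[j] + 1L):(upper[j] + 1L)]),
              numeric(1))
  within <- lapply(seq_along(lower), function(j) {
    p <- hist$probs[(lower[j] + 1L):(upper[j] + 1L)]
    if (P[j] > 0) p / P[j] else p * 0
  })
  structure(
    list(m = length(t), t = t,
         bounds = tibble(class = seq_along(lower) - 1L, lower = lower, upper = upper),
         P = P, within = within, empty = P == 0),
    class = "class_decomposition"
  )
}

validate_thresholds <- function(t, L) {
  if (length(t) < 1L || anyNA(t) || any(t != round(t))) {
    abort("`t` must be one or more integer thresholds.")
  }
  t <- as.integer(t)
  if (any(diff(t) <= 0)) abort("Thresholds must be strictly increasing.")
  if (t[1] < 0 || t[length(t)] > L - 2) {
    abort(sprintf("Thresholds must lie in [0, %d].", L - 2))
  }
  t
}

#' Per-class Tsallis entropies
#'
#' The Tsallis entropy of each within-class renormalised distribution.
#' Empty classes contribute 0, the limit of a vanishing class, keeping
#' every threshold set feasible.
#'
#' @param decomp A `class_decomposition`.
#' @inheritParams tsallis_entropy
#' @return Numeric vector of `m + 1` non-negative entropies.
#' @export
class_entropies <- function(decomp, q) {
  stopifnot(inherits(decomp, "class_decomposition"))
  check_number(q, "q", lower = 0, strict = TRUE)
  vapply(seq_along(decomp$P), function(j) {
    if (decomp$empty[j]) return(0)
    tsallis_entropy(decomp$within[[j]], q)
  }, numeric(1))
}

#' Pseudo-additive Tsallis thresholding objective
#'
#' The joint Tsallis entropy of the `m + 1` classes under the
#' pseudo-additive composition rule, expanded over all interaction orders:
#' \deqn{S_q(t_1,\dots,t_m) = \sum_j S_q^j + (1-q)\sum_{j<k} S_q^j S_q^k +
#'   \dots + (1-q)^m \prod_j S_q^j.}
#' Computed in closed form via
#' \eqn{1 + (1-q) S_q^{tot} = \prod_j \left(1 + (1-q) S_q^j\right)},
#' which is algebraically identical to the explicit expansion.  Maximising
#' this objective over threshold sets selects the segmentation.
#'
#' At `|q - 1| < 1e-9` all cross terms vanish and the Kapur (Shannon)
#' objective is returned.
#'
#' @inheritParams class_probabilities
#' @inheritParams tsallis_entropy
#' @return Scalar objective value.
#' @export
tsallis_objective <- function(hist, t, q) {
  decomp <- class_probabilities(hist, t)
  s <- class_entropies(decomp, q)
  compose_pseudo_additive(s, q)
}

compose_pseudo_additive <- function(s, q) {
  if (abs(q - 1) < 1e-9) return(sum(s))
  (prod(1 + (1 - q) * s) - 1) / (1 - q)
}

#' Kapur (maximum Shannon entropy) thresholding objective
#'
#' Sum of the Shannon entropies of the within-class distributions; the
#' extensive baseline, equal to the `q -> 1` limit of
#' [tsallis_objective()].  Empty classes contribute 0.
#'
#' @inheritParams class_probabilities
#' @return Scalar objective value.
#' @export
kapur_objective <- function(hist, t) {
  decomp <- class_probabilities(hist, t)
  sum(vapply(seq_along(decomp$P), function(j) {
    if (decomp$empty[j]) return(0)
    shannon_entropy(decomp$within[[j]])
  }, numeric(1)))
}

# ---- fast batch evaluation -------------------------------------------------
#
# Evaluates the objective for a matrix of candidate threshold sets (one row
# per candidate) using prefix sums of p, p^q and p*log(p), so each class
# entropy costs O(1).  Backbone of both the exhaustive and the DE search.

objective_prefix <- function(hist, type, q) {
  p <- hist$probs
  pre <- list(type = type, q = q, L = hist$L, cp = c(0, cumsum(p)))
  if (type == "tsallis" && abs(q - 1) >= 1e-9) {
    pre$cpq <- c(0, cumsum(p^q))
  } else {
    pre$type <- "kapur"
    plp <- ifelse(p > 0, p * log(p), 0)
    pre$cplp <- c(0, cumsum(plp))
  }
  pre
}

# tmat: n x m integer matrix of strictly increasing thresholds in [0, L-2]
objective_batch <- function(pre, tmat) {
  n <- nrow(tmat)
  L <- pre$L
  upper <- cbind(tmat, L - 1L)               # inclusive class upper bounds
  lower <- cbind(matrix(-1L, n, 1L), tmat)   # exclusive class lower bounds
  P <- matrix(pre$cp[upper + 2L] - pre$cp[lower + 2L], n)
  if (pre$type == "kapur") {
    S <- matrix(0, n, ncol(P))
    ok <- P > 0
    slp <- matrix(pre$cplp[upper + 2L] - pre$cplp[lower + 2L], n)
    S[ok] <- log(P[ok]) - slp[ok] / P[ok]
    rowSums(S)
  } else {
    q <- pre$q
    A <- matrix(pre$cpq[upper + 2L] - pre$cpq[lower + 2L], n)
    S <- matrix(0, n, ncol(P))
    ok <- P > 0
    S[ok] <- (1 - A[ok] / P[ok]^q) / (q - 1)
    fac <- 1 + (1 - q) * S
    (exp(rowSums(log(fac))) - 1) / (1 - q)
  }
}
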
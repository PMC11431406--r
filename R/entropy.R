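#' Tsallis entropy of a probability distribution
#'
#' Non-extensive generalisation of Shannon entropy,
#' \deqn{S_q = \frac{1 - \sum_i p_i^q}{q - 1},}
#' which recovers the Shannon entropy (natural log) as \eqn{q \to 1}.
#' The entropic index `q` governs the deviation from additivity: for two
#' independent systems, \eqn{S_q(A \otimes B) = S_q(A) + S_q(B) +
#' (1-q) S_q(A) S_q(B)} (pseudo-additivity).  The convention `0^q := 0`
#' applies, so zero-probability bins contribute nothing.
#'
#' @param probs Probability vector (non-negative, summing to 1).
#' @param q Entropic index, `q > 0`.  Values within `1e-9` of 1 return the
#'   Shannon entropy.
#' @return Non-negative scalar entropy (nats at `q = 1`).
#' @examples
#' tsallis_entropy(c(0.5, 0.5), q = 2) # (1 - 0.5) / 1 = 0.5
#' @export
tsallis_entropy <- function(probs, q) {
  validate_probs(probs)
  check_number(q, "q", lower = 0, strict = TRUE)
  if (abs(q - 1) < 1e-9) return(shannon_entropy(probs))
  (1 - sum(probs^q)) / (q - 1)
}

#' Shannon entropy (natural log)
#'
#' \eqn{-\sum_i p_i \ln p_i} with the continuity convention
#' `0 * ln 0 := 0`.  The extensive baseline the Tsallis family generalises.
#'
#' @inheritParams tsallis_entropy
#' @return Non-negative scalar in nats.
#' @export
shannon_entropy <- function(probs) {
  validate_probs(probs)
  p <- probs[probs > 0]
  -sum(p * log(p))
}

#' Maximum attainable Tsallis entropy over L levels
#'
#' Attained by the equiprobable distribution `p_i = 1/L`:
#' \eqn{S_q^{max} = (1 - L^{1-q})/(q - 1)}, with limit `ln L` at `q = 1`.
#'
#' @param L Number of gray levels, `L >= 2`.
#' @inheritParams tsallis_entropy
#' @return Positive scalar.
#' @export
max_tsallis_entropy <- function(L, q) {
  check_number(L, "L", lower = 2)
  check_number(q, "q", lower = 0, strict = TRUE)
  if (abs(q - 1) < 1e-9) return(log(L))
  (1 - L^(1 - q)) / (q - 1)
}

#' q-redundancy of a distribution
#'
#' The normalised shortfall of the Tsallis entropy from its equiprobable
#' maximum, \eqn{R_T = 1 - S_q / S_q^{max}}.  Always in `[0, 1]`: 0 for the
#' uniform distribution, 1 for a delta.
#'
#' @inheritParams tsallis_entropy
#' @param L Number of levels; defaults to `length(probs)`.
#' @return Scalar in `[0, 1]`.
#' @export
q_redundancy <- function(probs, q, L = length(probs)) {
  1 - tsallis_entropy(probs, q) / max_tsallis_entropy(L, q)
}

#' Default q search grid
#'
#' 0.01 to 2.00 in steps of 0.01, excluding the extensive point `q = 1`;
#' covers both the sub-extensive (`q < 1`) and super-extensive (`q > 1`)
#' regimes.
#'
#' @return Numeric vector of 199 candidate q values.
#' @export
q_grid_default <- function() {
  g <- round(seq(0.01, 2, by = 0.01), 2)
  g[g != 1]
}

#' Self-adaptive estimation of the entropic index q
#'
#' Scans a grid of q values and selects \eqn{q^* = \arg\max_q R_T(q)}, the
#' index at which the histogram's q-redundancy is maximal.  The idea: the
#' gray-level histogram carries the imprint of long-range correlations
#' among pixels, and the q that pushes the re-normalised histogram furthest
#' from equiprobability is the one matching that correlation strength.
#' Ties are broken towards the smallest q.
#'
#' For degenerate histograms the redundancy curve is constant (identically
#' 1 for a delta, 0 for the uniform), every q is equally good, and the
#' result carries `degenerate = TRUE` plus a warning.
#'
#' @param probs Histogram probability vector (length `L`).
#' @param grid Ordered vector of candidate q values (positive, != 1).
#' @return A `q_estimate`: list with `q_star`, `r_max`, `grid`,
#'   `redundancy` (the full curve, exportable via [tidy()]), `degenerate`.
#' @examples
#' h <- gen_histogram(c(0.7, 0.1, 0.1, 0.1), 1000)
#' estimate_q(h$probs)
#' @export
estimate_q <- function(probs, grid = q_grid_default()) {
  validate_probs(probs)
  if (length(grid) < 1L || any(grid <= 0) || any(grid == 1)) {
    abort("`grid` must be non-empty with all entries > 0 and != 1.")
  }
  L <- length(probs)
  nz <- probs[probs > 0]
  # R_T(q) = 1 - (1 - sum p^q) / (1 - L^(1-q)); the (q-1) factors cancel
  pq <- colSums(outer(nz, grid, `^`))
  redundancy <- 1 - (1 - pq) / (1 - L^(1 - grid))
  degenerate <- sum(probs > 0) == 1L ||
    (length(grid) > 1L && diff(range(redundancy)) < 1e-12)
  if (degenerate) {
    warn("Degenerate histogram: q-redundancy is constant across the grid; q* is arbitrary.")
  }
  i <- which.max(redundancy)          # first maximum = smallest q on ties
  structure(
    list(q_star = grid[i], r_max = redundancy[i], grid = grid,
         redundancy = redundancy, degenerate = degenerate),
    class = "q_estimate"
  )
}

#' @export
print.q_estimate <- function(x, ...) {
  cat(sprintf("<q_estimate> q* = %.4g (R_T = %.4f) over %d grid points%s\n",
              x$q_star, x$r_max, length(x$grid),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @describeIn estimate_q One row per grid point: columns `q`, `redundancy`.
#' @param x A `q_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.q_estimate <- function(x, ...) {
  tibble(q = x$grid, redundancy = x$redundancy)
}

#' @describeIn estimate_q One-row summary: `q_star`, `r_max`, `degenerate`.
#' @exportS3Method generics::glance
glance.q_estimate <- function(x, ...) {
  tibble(q_star = x$q_star, r_max = x$r_max, degenerate = x$degenerate)
}

#' @describeIn estimate_q Plot the redundancy curve with q* marked.
#' @param object A `q_estimate`.
#' @exportS3Method ggplot2::autoplot
autoplot.q_estimate <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$q, y = .data$redundancy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$q_star, linetype = "dashed") +
    ggplot2::labs(x = "q", y = expression(R[T]),
                  title = sprintf("q-redundancy curve (q* = %.3g)", object$q_star))
}
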
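# Independent oracles, deliberately implemented by different routes than
# the package internals they check.

# Explicit pseudo-additive expansion over all interaction orders:
# sum_k (1-q)^(k-1) * e_k(s), with e_k the elementary symmetric polynomial
# enumerated by brute force over subsets.
oracle_pseudo_expansion <- function(s, q) {
  n <- length(s)
  total <- 0
  for (k in seq_len(n)) {
    ek <- sum(utils::combn(s, k, prod))
    total <- total + (1 - q)^(k - 1) * ek
  }
  total
}

# Naive exhaustive threshold search via combn and the public objective
# functions (class_probabilities route, no prefix sums).
oracle_exhaustive_naive <- function(hist, m, type = "tsallis", q = NULL) {
  combos <- utils::combn(0:(hist$L - 2), m)
  vals <- apply(combos, 2, function(t) {
    if (type == "tsallis") tsallis_objective(hist, t, q) else kapur_objective(hist, t)
  })
  i <- which.max(vals)
  list(t = as.integer(combos[, i]), value = vals[i])
}

# Single-pass global SSIM written out directly.
oracle_ssim <- function(x, y, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  vx <- sum(x^2) / n - mx^2
  vy <- sum(y^2) / n - my^2
  cxy <- sum(x * y) / n - mx * my
  (2 * mx * my + c1) * (2 * cxy + c2) / ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# Random probability vector over L levels.
rand_probs <- function(L, seed) {
  withr::with_seed(seed, {
    p <- stats::runif(L)
    p / sum(p)
  })
}

# Sparse random histogram: a few occupied bins, uneven mass.
rand_hist <- function(L, seed, total = 2048) {
  withr::with_seed(seed, {
    k <- sample(3:L, 1)
    idx <- sort(sample.int(L, k))
    w <- stats::rexp(k)
    p <- numeric(L)
    p[idx] <- w / sum(w)
  })
  gen_histogram(p, total)
}
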
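#' Optimizer configuration for threshold search
#'
#' Settings for the differential-evolution search used when exhaustive
#' enumeration exceeds its budget.  Defaults: rand/1/bin DE with population
#' `10 * m` (resolved at call time), 200 iterations, `F = 0.5`, `CR = 0.9`.
#'
#' @param population Population size (`NULL` = `10 * m`, minimum 4).
#' @param iterations Number of DE generations.
#' @param F Differential weight in `(0, 2]`.
#' @param CR Crossover rate in `[0, 1]`.
#' @param seed Integer seed; the search is fully reproducible given it.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(population = NULL, iterations = 200,
                             F = 0.5, CR = 0.9, seed = 1L) {
  if (!is.null(population)) check_number(population, "population", lower = 2)
  check_number(iterations, "iterations", lower = 1)
  check_number(F, "F", lower = 0, strict = TRUE)
  check_number(CR, "CR", lower = 0)
  check_number(seed, "seed", lower = -Inf)
  structure(list(population = population, iterations = as.integer(iterations),
                 F = F, CR = CR, seed = as.integer(seed)),
            class = "optimizer_config")
}

resolve_objective <- function(objective, q) {
  objective <- match.arg(objective, c("tsallis", "kapur"))
  if (objective == "tsallis") {
    if (is.null(q)) abort("`q` is required for the tsallis objective.")
    check_number(q, "q", lower = 0, strict = TRUE)
  }
  list(type = objective, q = q)
}

new_threshold_search <- function(t, value, method, objective, q, evaluations) {
  structure(
    list(t = as.integer(t), value = value, method = method,
         objective = objective, q = q, evaluations = evaluations),
    class = "threshold_search"
  )
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("<threshold_search> t = [%s], %s objective = %.6f (%s)\n",
              paste(x$t, collapse = ", "),
              if (x$objective == "tsallis") sprintf("Tsallis(q=%.3g)", x$q) else "Kapur",
              x$value, x$method))
  invisible(x)
}

#' Exhaustive (globally optimal) threshold search
#'
#' Enumerates every strictly increasing set of `m` thresholds in
#' `[0, L-2]` and returns the global maximiser of the chosen objective.
#' Class entropies are evaluated from prefix sums of `p_i` and `p_i^q`, so
#' each candidate costs O(m); enumeration is lexicographic with the last
#' threshold vectorised, and ties are resolved to the lexicographically
#' smallest threshold vector.
#'
#' Serves as the exact oracle against which [swarm_optimize()] is checked.
#'
#' @inheritParams class_probabilities
#' @param m Number of thresholds, `>= 1`.
#' @param objective `"tsallis"` or `"kapur"`.
#' @param q Entropic index (required for `"tsallis"`).
#' @param budget Maximum number of candidate evaluations; combination
#'   counts above it raise an error directing the caller to
#'   [swarm_optimize()].  Default `5e6` (covers `m <= 3` at `L = 256`).
#' @return A `threshold_search`: list with integer `t`, objective `value`,
#'   `method = "exhaustive"`, and the evaluation count.
#' @export
exhaustive_search <- function(hist, m, objective = c("tsallis", "kapur"),
                              q = NULL, budget = 5e6) {
  stopifnot(inherits(hist, "gray_histogram"))
  check_number(m, "m", lower = 1)
  m <- as.integer(m)
  L <- hist$L
  if (m > L - 1) abort("`m` cannot exceed L - 1.")
  n_comb <- choose(L - 1, m)
  if (n_comb > budget) {
    abort(sprintf(
      "Exhaustive search needs %.3g evaluations (> budget %.3g); use swarm_optimize().",
      n_comb, budget), class = "qthresh_budget_error")
  }
  obj <- resolve_objective(objective, q)
  pre <- objective_prefix(hist, obj$type, obj$q)

  best_val <- -Inf
  best_t <- NULL
  eval_block <- function(prefix, start) {
    last <- start:(L - 2L)
    tmat <- cbind(matrix(rep(prefix, each = length(last)), nrow = length(last)), last)
    vals <- objective_batch(pre, tmat)
    i <- which.max(vals)                  # first max = smallest last threshold
    if (vals[i] > best_val) {             # strict: keeps lexicographically first
      best_val <<- vals[i]
      best_t <<- tmat[i, ]
    }
  }
  recurse <- function(prefix, start, depth) {
    if (depth == m - 1L) {
      eval_block(prefix, start)
    } else {
      for (v in start:(L - 2L - (m - 1L - depth))) {
        recurse(c(prefix, v), v + 1L, depth + 1L)
      }
    }
  }
  if (m == 1L) eval_block(integer(0), 0L) else recurse(integer(0), 0L, 0L)
  new_threshold_search(best_t, best_val, "exhaustive", obj$type, obj$q, n_comb)
}

# Repair continuous DE positions into feasible strictly increasing integer
# thresholds: clamp, round, sort, then push duplicates apart.
repair_thresholds <- function(X, L) {
  m <- ncol(X)
  X <- pmin(pmax(round(X), 0L), L - 2L)
  X <- matrix(as.integer(X), nrow(X), m)
  if (m > 1L) X <- t(apply(X, 1L, sort))
  for (j in seq_len(m)[-1]) {
    X[, j] <- pmax(X[, j], X[, j - 1L] + 1L)
  }
  over <- X[, m] > L - 2L
  if (any(over)) {
    for (j in rev(seq_len(m))) {
      X[over, j] <- pmin(X[over, j], L - 2L - (m - j))
    }
    for (j in seq_len(m)[-1]) {          # re-assert increase after clamping
      X[, j] <- pmax(X[, j], X[, j - 1L] + 1L)
    }
  }
  X
}

# Variable-neighborhood descent on integer thresholds: alternate sweeps of
# (a) single-threshold moves over the full feasible range and (b) joint
# exhaustive re-optimisation of each adjacent threshold pair, until neither
# improves.  Deterministic; every accepted move strictly increases the
# objective, so it terminates.  Pair moves matter: neighbouring local
# optima of the pseudo-additive objective often differ in two adjacent
# thresholds at once, where single-coordinate ascent stalls.
refine_local <- function(pre, t, L) {
  m <- length(t)
  val <- objective_batch(pre, matrix(t, 1L))
  lex_less <- function(a, b) {
    d <- a - b
    nz <- which(d != 0)
    length(nz) > 0L && d[nz[1]] < 0
  }
  try_move <- function(tmat) {
    vals <- objective_batch(pre, tmat)
    top <- which(vals == max(vals))
    # among exact ties take the lexicographically smallest row, so the
    # polished result agrees with the exhaustive oracle on flat plateaus
    i <- top[do.call(order, as.data.frame(tmat[top, , drop = FALSE]))[1]]
    if (vals[i] > val || (vals[i] == val && lex_less(tmat[i, ], t))) {
      val <<- vals[i]
      t <<- tmat[i, ]
      TRUE
    } else FALSE
  }
  repeat {
    improved <- FALSE
    for (j in seq_len(m)) {
      lo <- if (j == 1L) 0L else t[j - 1L] + 1L
      hi <- if (j == m) L - 2L else t[j + 1L] - 1L
      cand <- lo:hi
      tmat <- matrix(rep(t, each = length(cand)), length(cand), m)
      tmat[, j] <- cand
      improved <- try_move(tmat) || improved
    }
    if (m > 1L) {
      for (j in seq_len(m - 1L)) for (k in (j + 1L):m) {
        lo_j <- if (j == 1L) 0L else t[j - 1L] + 1L
        hi_j <- if (j + 1L == k) Inf else t[j + 1L] - 1L   # joint when adjacent
        lo_k <- if (k - 1L == j) -Inf else t[k - 1L] + 1L
        hi_k <- if (k == m) L - 2L else t[k + 1L] - 1L
        cj <- lo_j:min(hi_j, hi_k - 1L)
        ck <- max(lo_k, lo_j + 1L):hi_k
        grid <- expand.grid(a = cj, b = ck)
        grid <- grid[grid$a < grid$b, , drop = FALSE]
        if (nrow(grid) == 0L) next
        tmat <- matrix(rep(t, each = nrow(grid)), nrow(grid), m)
        tmat[, j] <- grid$a
        tmat[, k] <- grid$b
        improved <- try_move(tmat) || improved
      }
    }
    if (!improved) break
  }
  list(t = t, value = val)
}

#' Differential-evolution threshold search
#'
#' Maximises the chosen objective with rand/1/bin differential evolution
#' over continuous positions in `[0, L-2]^m`; every candidate is repaired
#' (rounded, sorted, duplicates pushed apart) before evaluation, so fitness
#' always refers to a feasible integer threshold set.  The best individual
#' is then polished by deterministic coordinate-wise hill climbing on the
#' integer lattice (a memetic step, standard in multilevel-thresholding
#' optimisers), which snaps runs started from different seeds onto the
#' same discrete optimum.  Fully reproducible given `cfg$seed`.
#'
#' Multi-level entropy thresholding has a combinatorial search space, so
#' stochastic population search is the standard tool once exhaustive
#' enumeration becomes infeasible; on instances where enumeration is
#' feasible the DE result should (and, in the test suite, does) match the
#' exhaustive optimum almost always.
#'
#' @inheritParams exhaustive_search
#' @param cfg An [optimizer_config()].
#' @return A `threshold_search` with `method = "de"`.
#' @export
swarm_optimize <- function(hist, m, objective = c("tsallis", "kapur"),
                           q = NULL, cfg = optimizer_config()) {
  stopifnot(inherits(hist, "gray_histogram"), inherits(cfg, "optimizer_config"))
  check_number(m, "m", lower = 1)
  m <- as.integer(m)
  L <- hist$L
  if (m > L - 1) abort("`m` cannot exceed L - 1: no feasible threshold set.")
  obj <- resolve_objective(objective, q)
  pre <- objective_prefix(hist, obj$type, obj$q)
  np <- as.integer(cfg$population %||% max(4L, 10L * m))
  evals <- 0L

  withr::with_seed(cfg$seed, {
    X <- matrix(runif(np * m, 0, L - 2), np, m)
    f <- objective_batch(pre, repair_thresholds(X, L))
    evals <- evals + np
    for (iter in seq_len(cfg$iterations)) {
      r <- t(vapply(seq_len(np),
                    function(i) sample(seq_len(np)[-i], 3L),
                    integer(3)))
      V <- X[r[, 1], , drop = FALSE] +
        cfg$F * (X[r[, 2], , drop = FALSE] - X[r[, 3], , drop = FALSE])
      mask <- matrix(runif(np * m) < cfg$CR, np, m)
      jrand <- cbind(seq_len(np), sample.int(m, np, replace = TRUE))
      mask[jrand] <- TRUE
      U <- ifelse(mask, V, X)
      U <- pmin(pmax(U, 0), L - 2)
      fu <- objective_batch(pre, repair_thresholds(U, L))
      evals <- evals + np
      acc <- fu >= f
      X[acc, ] <- U[acc, , drop = FALSE]
      f[acc] <- fu[acc]
    }
  })
  Ti <- repair_thresholds(X, L)
  # polish the best few individuals: distinct survivors often sit in
  # different basins, and the descent decides between them deterministically
  top <- utils::head(order(f, decreasing = TRUE), 3L)
  top <- top[!duplicated(lapply(top, function(i) Ti[i, ]))]
  polished <- lapply(top, function(i) refine_local(pre, Ti[i, ], L))
  best <- polished[[which.max(vapply(polished, `[[`, numeric(1), "value"))]]
  new_threshold_search(best$t, best$value, "de", obj$type, obj$q, evals)
}
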
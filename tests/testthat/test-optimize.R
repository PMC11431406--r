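test_that("exhaustive search matches naive enumeration on small instances", {
  for (seed in 1:5) {
    h <- rand_hist(16, seed)
    for (type in c("tsallis", "kapur")) {
      q <- if (type == "tsallis") 0.8 else NULL
      ex <- exhaustive_search(h, 2, type, q)
      naive <- oracle_exhaustive_naive(h, 2, type, q)
      expect_equal(ex$value, naive$value)
      expect_identical(ex$t, naive$t)
    }
  }
})

test_that("plateau ties resolve to the lexicographically smallest thresholds", {
  # two uniform blocks with an empty gap: any threshold in [7, 23] fully
  # separates them and the objective is bit-identical across the gap, so
  # the tie rule returns the smallest such threshold
  p <- numeric(32)
  p[(0:7) + 1] <- 0.5 / 8
  p[(24:31) + 1] <- 0.5 / 8
  h <- gen_histogram(p, 1600)
  for (spec in list(list("tsallis", 0.8), list("kapur", NULL))) {
    ex <- exhaustive_search(h, 1, spec[[1]], spec[[2]])
    vals <- vapply(0:30, function(t) {
      if (spec[[1]] == "tsallis") tsallis_objective(h, t, 0.8) else kapur_objective(h, t)
    }, numeric(1))
    expect_equal(ex$value, max(vals))
    expect_identical(ex$t, 7L)          # left edge of the optimal plateau
  }
})

test_that("empty classes are feasible and can carry the optimum", {
  # two isolated delta spikes: separated classes each have zero entropy,
  # while leaving one class empty keeps the two-spike distribution (and
  # its positive entropy) intact — the objective prefers the empty class,
  # and the tie rule picks the smallest threshold of that plateau
  p <- numeric(32)
  p[c(5, 25) + 1] <- 0.5
  h <- gen_histogram(p, 1000)
  expect_equal(tsallis_objective(h, 10, 0.8), 0)   # separation scores zero
  ex <- exhaustive_search(h, 1, "kapur")
  expect_identical(ex$t, 0L)
  expect_equal(ex$value, shannon_entropy(c(0.5, 0.5)))
})

test_that("full split (m = L-1) gives single-level classes and zero objective", {
  h <- rand_hist(8, 2)
  ex <- exhaustive_search(h, 7, "tsallis", 0.6)
  expect_identical(ex$t, 0:6)
  expect_equal(ex$value, 0)
})

test_that("over-budget instances raise a budget error", {
  h <- rand_hist(256, 1)
  expect_error(exhaustive_search(h, 5, "tsallis", 0.8),
               class = "qthresh_budget_error")
  expect_error(swarm_optimize(h, 256, "tsallis", 0.8), "feasible")
})

test_that("threshold repair yields feasible strictly increasing sets", {
  L <- 32L
  for (seed in 1:10) {
    X <- withr::with_seed(seed, matrix(stats::runif(40 * 4, -5, L + 5), 40, 4))
    R <- qthresh:::repair_thresholds(X, L)
    expect_true(all(R >= 0 & R <= L - 2))
    expect_true(all(apply(R, 1, function(r) all(diff(r) > 0))))
  }
})

test_that("DE search is deterministic under a fixed seed", {
  h <- trimodal_hist64(4)
  a <- swarm_optimize(h, 3, "tsallis", 0.8, optimizer_config(seed = 42))
  b <- swarm_optimize(h, 3, "tsallis", 0.8, optimizer_config(seed = 42))
  expect_identical(a$t, b$t)
  expect_identical(a$value, b$value)
  c <- swarm_optimize(h, 3, "tsallis", 0.8, optimizer_config(seed = 43))
  expect_s3_class(c, "threshold_search")   # different seed still feasible
  expect_true(all(diff(c$t) > 0))
})

test_that("DE with m = 1 equals the exhaustive scan", {
  for (seed in c(1, 5, 9)) {
    h <- rand_hist(256, seed)
    ex <- exhaustive_search(h, 1, "kapur")
    sw <- swarm_optimize(h, 1, "kapur", cfg = optimizer_config(seed = seed))
    expect_identical(sw$t, ex$t)
  }
})

test_that("DE matches the exhaustive optimum on trimodal instances", {
  hits <- 0
  for (seed in 1:20) {
    h <- trimodal_hist64(seed)
    ex <- exhaustive_search(h, 2, "tsallis", 0.8)
    sw <- swarm_optimize(h, 2, "tsallis", 0.8,
                         optimizer_config(seed = seed + 1000))
    if (identical(sw$t, ex$t)) hits <- hits + 1
    expect_gte(sw$value, 0.99 * ex$value)
  }
  expect_gte(hits, 19)
})

test_that("minimum reconstruction error is non-increasing in m", {
  # enumerate the MSE-optimal class-mean reconstruction at small L: adding
  # a threshold refines the partition and can only reduce the error
  recon_mse <- function(img, t, L) {
    ap <- apply_thresholds(img, t, L)
    img_mse(img, ap$reconstruction)
  }
  for (seed in 1:3) {
    h <- rand_hist(12, seed, total = 144)
    img <- image_from_histogram(h)
    best <- vapply(1:3, function(m) {
      combos <- utils::combn(0:10, m)
      min(apply(combos, 2, function(t) recon_mse(img, t, 12)))
    }, numeric(1))
    expect_true(all(diff(best) <= 1e-12))
  }
})
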
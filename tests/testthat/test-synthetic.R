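test_that("mixture image generation is deterministic and respects the spec", {
  spec <- mixture_spec(c(60, 180), c(5, 5))
  a <- gen_mixture_image(spec, 32, 32, seed = 5)
  b <- gen_mixture_image(spec, 32, 32, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, gen_mixture_image(spec, 32, 32, seed = 6)))
  expect_true(all(a >= 0 & a <= 255))

  const <- gen_mixture_image(mixture_spec(100, 0), 8, 8, seed = 1)
  expect_true(all(const == 100L))
})

test_that("mixture valley lies between separated modes and is recovered", {
  spec <- mixture_spec(c(60, 180), c(5, 5))
  v <- mixture_valleys(spec)
  expect_gt(v, 100)
  expect_lt(v, 140)
  # widely separated modes leave a zero-count gap where the objective is
  # exactly flat; the optimal threshold separates the modes and the tie
  # rule parks it at the left edge of that gap
  img <- gen_mixture_image(spec, 128, 128, seed = 2)
  h <- compute_histogram(img)
  ex <- exhaustive_search(h, 1, "tsallis", 0.8)
  expect_gt(ex$t, 60)
  expect_lt(ex$t, 180)
  # the threshold cleanly separates the two modes' mass
  expect_gt(sum(h$probs[1:(ex$t + 1)]), 0.49)
  expect_gt(sum(h$probs[(ex$t + 2):256]), 0.49)

  # at 6-sd separation the valley region keeps mass and the threshold sits
  # in the valley interior
  spec6 <- mixture_spec(c(100, 130), c(5, 5))
  img6 <- gen_mixture_image(spec6, 256, 256, seed = 2)
  t6 <- exhaustive_search(compute_histogram(img6), 1, "tsallis", 0.8)$t
  expect_lte(abs(t6 - mixture_valleys(spec6)), 2)
})

test_that("sampled histograms converge to the specified mixture", {
  spec <- mixture_spec(c(80, 170), c(12, 10), weights = c(0.4, 0.6))
  x <- 0:255
  target <- 0.4 * stats::dnorm(x, 80, 12) + 0.6 * stats::dnorm(x, 170, 10)
  target <- target / sum(target)
  tv <- vapply(c(32, 128), function(side) {
    h <- compute_histogram(gen_mixture_image(spec, side, side, seed = 9))
    0.5 * sum(abs(h$probs - target))
  }, numeric(1))
  expect_lt(tv[2], tv[1])
  expect_lt(tv[2], 0.05)
})

test_that("mixture_spec validates its fields", {
  expect_error(mixture_spec(c(100, 50), c(5, 5)), "increasing")
  expect_error(mixture_spec(c(50, 100), c(5, -1)), "non-negative")
  expect_error(mixture_spec(c(50, 100), c(5, 5), weights = c(1, -1)), "positive")
  expect_error(mixture_valleys(mixture_spec(100, 5)), "two modes")
})

test_that("scene series shares its background and bounds the perturbation", {
  ss <- scene_series_default(n_frames = 6, seed = 21)
  frames <- gen_scene_series(ss, 100, 100)
  bg <- attr(frames, "background")
  cap <- 0.05 * length(bg)
  h_bg <- compute_histogram(bg)$counts
  for (f in frames) {
    changed <- sum(f != bg)
    expect_lte(changed, cap)
    # histogram count mass moves by at most 2 per changed pixel
    expect_lte(sum(abs(compute_histogram(f)$counts - h_bg)), 2 * changed)
  }
  # element-wise reproducibility
  again <- gen_scene_series(ss, 100, 100)
  expect_identical(frames[[4]], again[[4]])
})

test_that("zero foreground objects leave every frame equal to the background", {
  ss <- scene_series_spec(scene_background_spec(), n_frames = 3, n_objects = 0,
                          seed = 4)
  frames <- gen_scene_series(ss, 40, 40)
  bg <- attr(frames, "background")
  for (f in frames) expect_identical(f, bg)
})

test_that("scene series rejects infeasible foregrounds", {
  expect_error(
    gen_scene_series(scene_series_spec(matrix(0L, 10, 10), n_objects = 1,
                                       size_range = c(20, 30), seed = 1)),
    "larger than the image")
  expect_error(
    gen_scene_series(scene_series_spec(matrix(0L, 20, 20), n_objects = 20,
                                       size_range = c(4, 6), seed = 1)),
    "cap")
  expect_error(scene_series_spec(matrix(0L, 5, 5), max_fg_frac = 0.5), "0.25")
})

test_that("q* stays in a narrow band across a fixed-background series", {
  frames <- gen_scene_series(scene_series_default(12, seed = 33), 120, 120)
  qs <- vapply(frames, function(f) {
    estimate_q(compute_histogram(f)$probs)$q_star
  }, numeric(1))
  span <- diff(range(q_grid_default()))
  expect_lt(max(qs) - min(qs), 0.1 * span)
})

test_that("disk-shaped foregrounds are supported", {
  ss <- scene_series_spec(scene_background_spec(), n_frames = 2, n_objects = 2,
                          shape = "disk", size_range = c(2, 4), seed = 8)
  frames <- gen_scene_series(ss, 60, 60)
  bg <- attr(frames, "background")
  expect_gt(sum(frames[[1]] != bg), 0)
})
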
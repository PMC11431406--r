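test_that("apply_thresholds labels classes and reconstructs exactly when lossless", {
  const <- matrix(100L, 6, 6)
  ap <- apply_thresholds(const, c(50, 150))
  expect_equal(ap$reconstruction, const)
  expect_true(all(ap$labels == 1L))

  # m = L-1: every class one gray level, reconstruction is the identity
  img <- matrix(sample(0:7, 64, TRUE), 8, 8)
  ap2 <- apply_thresholds(img, 0:6, L = 8)
  expect_equal(ap2$reconstruction, img)

  two <- matrix(c(40L, 200L), 4, 4)
  ap3 <- apply_thresholds(two, 100)
  expect_equal(sort(unique(as.vector(ap3$reconstruction))), c(40, 200))
  expect_identical(img_psnr(two, ap3$reconstruction), Inf)
})

test_that("midpoint reconstruction uses class gray ranges", {
  img <- matrix(c(10L, 20L, 240L, 250L), 2, 2)
  ap <- apply_thresholds(img, 127, reconstruction = "midpoint")
  expect_equal(sort(unique(as.vector(ap$reconstruction))),
               c(round(127 / 2), round((128 + 255) / 2)))
})

test_that("segmentation recovers mixture valleys with all three methods", {
  spec <- mixture_spec(c(90, 120, 150), c(5, 5, 5))
  img <- gen_mixture_image(spec, 128, 128, seed = 6)
  valleys <- mixture_valleys(spec)
  for (method in c("shannon", "tsallis_fixed", "adaptive")) {
    seg <- segment_image(img, m = 2, method = method)
    expect_true(all(abs(seg$thresholds - valleys) <= 2),
                info = sprintf("%s: t = %s vs valleys %s", method,
                               paste(seg$thresholds, collapse = ","),
                               paste(round(valleys, 1), collapse = ",")))
  }
})

test_that("adaptive with a one-point q grid reduces to fixed-q Tsallis", {
  img <- gen_mixture_image(mixture_spec(c(60, 140, 200), c(10, 12, 9)),
                           96, 96, seed = 3)
  fixed <- segment_image(img, m = 2, method = "tsallis_fixed", q = 0.55)
  adapt <- segment_image(img, m = 2, method = "adaptive", q_grid = 0.55)
  expect_identical(adapt$thresholds, fixed$thresholds)
  expect_equal(adapt$objective, fixed$objective)
  expect_equal(adapt$q_used, 0.55)
})

test_that("constant images segment with a warning and lossless reconstruction", {
  img <- matrix(77L, 16, 16)
  expect_warning(seg <- segment_image(img, m = 2, method = "adaptive"),
                 "[Dd]egenerate")
  expect_equal(seg$reconstruction, img)
  expect_true(all(diff(seg$thresholds) > 0))
  # deterministic: rerun gives identical thresholds
  expect_warning(seg2 <- segment_image(img, m = 2, method = "adaptive"))
  expect_identical(seg$thresholds, seg2$thresholds)
})

test_that("color images are segmented per channel and merged", {
  img <- array(0L, c(32, 32, 3))
  img[, , 1] <- gen_mixture_image(mixture_spec(c(50, 180), c(8, 8)), 32, 32, seed = 1)
  img[, , 2] <- gen_mixture_image(mixture_spec(c(80, 200), c(8, 8)), 32, 32, seed = 2)
  img[, , 3] <- gen_mixture_image(mixture_spec(c(30, 120), c(8, 8)), 32, 32, seed = 3)
  seg <- segment_image(img, m = 1, method = "adaptive")
  expect_named(seg$thresholds, c("red", "green", "blue"))
  expect_equal(dim(seg$reconstruction), dim(img))
  expect_equal(length(seg$q_used), 3L)
  g <- glance(seg)
  expect_true(g$ssim > 0 && g$ssim <= 1)
  td <- tidy(seg)
  expect_setequal(unique(td$channel), c("red", "green", "blue"))

  shared <- segment_image(img, m = 1, method = "adaptive", shared_q = TRUE)
  expect_equal(length(unique(shared$q_used)), 1L)
})

test_that("glance and tidy summarise a gray segmentation consistently", {
  img <- gen_mixture_image(mixture_spec(c(70, 190), c(9, 9)), 64, 64, seed = 8)
  seg <- segment_image(img, m = 1, method = "shannon")
  g <- glance(seg)
  expect_true(is.na(g$q_used))
  expect_equal(g$objective, kapur_objective(compute_histogram(img), seg$thresholds))
  td <- tidy(seg)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$pixel_share), 1)
  expect_s3_class(autoplot(seg), "ggplot")
})

test_that("stored objective equals re-evaluation at the stored thresholds", {
  img <- gen_mixture_image(mixture_spec(c(60, 120, 200), c(10, 14, 8)),
                           80, 80, seed = 12)
  h <- compute_histogram(img)
  fixed <- segment_image(img, m = 3, method = "tsallis_fixed", q = 0.8,
                         cfg = optimizer_config(seed = 5))
  expect_equal(fixed$objective, tsallis_objective(h, fixed$thresholds, 0.8))
  sh <- segment_image(img, m = 2, method = "shannon")
  expect_equal(sh$objective, kapur_objective(h, sh$thresholds))
})

test_that("fitness_robustness returns a sorted profile with max multiplicity", {
  img <- image_from_histogram(trimodal_hist64(7))
  one <- fitness_robustness(img, m = 2, runs = 1, base_seed = 2,
                            method = "tsallis_fixed", L = 64)
  expect_length(one$values, 1)
  expect_equal(one$max_multiplicity, 1L)

  prof <- fitness_robustness(img, m = 2, runs = 100, base_seed = 2,
                             method = "tsallis_fixed", L = 64)
  expect_true(all(diff(prof$values) >= 0))
  ex <- exhaustive_search(compute_histogram(img, 64), 2, "tsallis", 0.8)
  hits <- sum(abs(prof$values - ex$value) < 1e-9)
  expect_gte(hits, 90)
  td <- tidy(prof)
  expect_equal(nrow(td), 100)
  expect_s3_class(autoplot(prof), "ggplot")
})
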
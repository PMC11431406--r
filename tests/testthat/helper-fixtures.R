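# Seeded synthetic fixtures shared across tests.

# Trimodal histogram on L = 64 with jittered modes, discretised analytically.
trimodal_hist64 <- function(seed, total = 4096) {
  withr::with_seed(seed, {
    means <- c(12, 30, 50) + sample(-2:2, 3, TRUE)
    sds <- stats::runif(3, 2.5, 4)
    w <- stats::runif(3, 0.5, 1.5)
  })
  x <- 0:63
  p <- colSums(t(sapply(1:3, function(k) w[k] * stats::dnorm(x, means[k], sds[k]))))
  gen_histogram(p / sum(p), total)
}

# Broad three-mode background spec used for scene series (occupies almost
# every gray level, like a textured scene).
scene_background_spec <- function() {
  mixture_spec(c(50, 110, 170), c(22, 28, 24))
}

scene_series_default <- function(n_frames, seed) {
  scene_series_spec(scene_background_spec(), n_frames = n_frames,
                    n_objects = 3, size_range = c(4, 9),
                    intensity_range = c(230, 250), max_fg_frac = 0.05,
                    seed = seed)
}
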
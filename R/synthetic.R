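#' Specification of a Gaussian gray-level mixture
#'
#' Describes a multimodal gray-level distribution: `K` modes at strictly
#' increasing mean gray levels, each with its own spread and weight.
#' Sampled pixel values are rounded and clipped (not wrapped) to
#' `[0, L-1]`; clipping slightly inflates the boundary bins, which is
#' documented behaviour.
#'
#' @param means Strictly increasing mode centres (gray levels).
#' @param sds Non-negative spreads, one per mode (0 = degenerate mode).
#' @param weights Positive mode weights; normalised to sum to 1.  Default
#'   equal.
#' @param L Gray-level count.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(means, sds, weights = NULL, L = 256) {
  if (length(means) < 1L || any(diff(means) <= 0)) {
    abort("`means` must be strictly increasing.")
  }
  if (length(sds) != length(means) || any(sds < 0)) {
    abort("`sds` must be non-negative, one per mode.")
  }
  weights <- weights %||% rep(1, length(means))
  if (length(weights) != length(means) || any(weights <= 0)) {
    abort("`weights` must be positive, one per mode.")
  }
  structure(list(K = length(means), means = means, sds = sds,
                 weights = weights / sum(weights), L = as.integer(L)),
            class = "mixture_spec")
}

#' Generate an image with a multimodal gray-level mixture
#'
#' Pixels are drawn independently from the Gaussian mixture, rounded and
#' clipped to `[0, L-1]`.  Deterministic for a fixed seed.  Emulates the
#' histogram structure of multimodal scenes (several objects against a
#' background at distinct characteristic intensities) that multi-level
#' thresholding targets.
#'
#' @param spec A [mixture_spec()].
#' @param rows,cols Image dimensions.
#' @param seed Integer seed.
#' @return Integer matrix.
#' @export
gen_mixture_image <- function(spec, rows, cols, seed = 1L) {
  stopifnot(inherits(spec, "mixture_spec"))
  check_number(rows, "rows", lower = 1)
  check_number(cols, "cols", lower = 1)
  n <- rows * cols
  withr::with_seed(seed, {
    comp <- sample.int(spec$K, n, replace = TRUE, prob = spec$weights)
    vals <- rnorm(n, spec$means[comp], spec$sds[comp])
  })
  matrix(as.integer(pmin(pmax(round(vals), 0), spec$L - 1)), rows, cols)
}

#' Mixture density and its inter-mode valleys
#'
#' `mixture_density()` evaluates the continuous mixture density;
#' `mixture_valleys()` locates the density minimum between each pair of
#' adjacent modes — the analytic reference against which recovered
#' thresholds are judged.
#'
#' @param spec A [mixture_spec()] with all `sds > 0`.
#' @param x Gray-level coordinates.
#' @return `mixture_density()`: density values; `mixture_valleys()`:
#'   `K - 1` valley locations.
#' @export
mixture_density <- function(spec, x) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (any(spec$sds <= 0)) abort("Density requires all `sds` > 0.")
  vapply(x, function(xi) sum(spec$weights * dnorm(xi, spec$means, spec$sds)),
         numeric(1))
}

#' @rdname mixture_density
#' @export
mixture_valleys <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (spec$K < 2L) abort("Valleys need at least two modes.")
  vapply(seq_len(spec$K - 1L), function(k) {
    optimize(function(x) mixture_density(spec, x),
             c(spec$means[k], spec$means[k + 1L]))$minimum
  }, numeric(1))
}

#' Specification of a fixed-background scene series
#'
#' Describes a series of frames sharing one static background on which a
#' few small, bright foreground objects are freshly placed per frame —
#' the structure of image series from a fixed camera (e.g. infrared
#' surveillance frames), where the foreground occupies a small fraction
#' of the pixels and the gray-level histogram barely moves from frame to
#' frame.
#'
#' @param background A background image (integer matrix) or a
#'   [mixture_spec()] to generate one from.
#' @param n_frames Number of frames.
#' @param n_objects Foreground objects per frame.
#' @param shape `"rect"` or `"disk"`.
#' @param size_range Min/max object side (rect) or radius (disk), pixels.
#' @param intensity_range Min/max object intensity (gray levels).
#' @param max_fg_frac Hard cap on total foreground area per frame as a
#'   fraction of the image (default 0.05; values above 0.25 are
#'   rejected).
#' @param seed Master seed; each frame uses a derived child seed.
#' @return A `scene_series_spec` list.
#' @export
scene_series_spec <- function(background, n_frames = 50, n_objects = 3,
                              shape = c("rect", "disk"), size_range = c(4, 10),
                              intensity_range = c(200, 250),
                              max_fg_frac = 0.05, seed = 1L) {
  shape <- match.arg(shape)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(n_objects, "n_objects", lower = 0)
  if (max_fg_frac <= 0 || max_fg_frac >= 0.25) {
    abort("`max_fg_frac` must be in (0, 0.25).")
  }
  structure(list(background = background, n_frames = as.integer(n_frames),
                 n_objects = as.integer(n_objects), shape = shape,
                 size_range = size_range, intensity_range = intensity_range,
                 max_fg_frac = max_fg_frac, seed = as.integer(seed)),
            class = "scene_series_spec")
}

#' Generate a fixed-background scene series
#'
#' Background pixels are identical across frames; only the foreground
#' objects move.  Frame `i` uses the child seed `derive_seed(seed, i)`, so
#' the series is reproducible element-wise.  Objects whose requested area
#' would push a frame past `max_fg_frac` raise an error at generation.
#'
#' @param spec A [scene_series_spec()].
#' @param rows,cols Image dimensions (required when the background is a
#'   [mixture_spec()]; ignored otherwise).
#' @param L Gray-level count.
#' @return List of `n_frames` integer matrices, with the rendered
#'   background as attribute `"background"`.
#' @export
gen_scene_series <- function(spec, rows = NULL, cols = NULL, L = 256) {
  stopifnot(inherits(spec, "scene_series_spec"))
  bg <- spec$background
  if (inherits(bg, "mixture_spec")) {
    if (is.null(rows) || is.null(cols)) abort("`rows`/`cols` required for a mixture background.")
    bg <- gen_mixture_image(bg, rows, cols, seed = derive_seed(spec$seed, 0L))
  }
  validate_image(bg, L)
  nr <- nrow(bg); nc <- ncol(bg)
  max_size <- spec$size_range[2]
  if (max_size > min(nr, nc)) abort("Foreground objects larger than the image.")
  per_obj_area <- if (spec$shape == "rect") max_size^2 else pi * max_size^2
  if (spec$n_objects * per_obj_area > spec$max_fg_frac * nr * nc) {
    abort(sprintf(
      "Up to %d objects of area %.0f exceed the foreground cap of %.0f pixels.",
      spec$n_objects, per_obj_area, spec$max_fg_frac * nr * nc))
  }
  frames <- lapply(seq_len(spec$n_frames), function(i) {
    withr::with_seed(derive_seed(spec$seed, i), place_objects(bg, spec, L))
  })
  attr(frames, "background") <- bg
  frames
}

place_objects <- function(bg, spec, L) {
  nr <- nrow(bg); nc <- ncol(bg)
  frame <- bg
  for (k in seq_len(spec$n_objects)) {
    size <- if (spec$size_range[1] == spec$size_range[2]) spec$size_range[1] else
      sample(spec$size_range[1]:spec$size_range[2], 1L)
    val <- sample(spec$intensity_range[1]:spec$intensity_range[2], 1L)
    val <- min(val, L - 1L)
    if (spec$shape == "rect") {
      r0 <- sample.int(nr - size + 1L, 1L)
      c0 <- sample.int(nc - size + 1L, 1L)
      frame[r0:(r0 + size - 1L), c0:(c0 + size - 1L)] <- val
    } else {
      rc <- sample.int(nr, 1L); cc <- sample.int(nc, 1L)
      rr <- matrix(seq_len(nr), nr, nc)
      ccm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      frame[(rr - rc)^2 + (ccm - cc)^2 <= size^2] <- val
    }
  }
  frame
}
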
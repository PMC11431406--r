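#' Apply a threshold set to an image
#'
#' Labels each pixel with its class index (0..m) and renders a
#' reconstructed image with one intensity per class.  Reconstruction
#' modes:
#' * `"mean"` (default): the mean original intensity of the pixels in the
#'   class, rounded to the nearest integer — the rendering used for
#'   PSNR/SSIM scoring;
#' * `"midpoint"`: the midpoint of the class's gray-level range,
#'   independent of the image content (sensitivity-check alternative).
#'
#' A class empty in this particular image falls back to its gray-range
#' midpoint under `"mean"`.
#'
#' @param image Grayscale integer matrix.
#' @param t Integer thresholds (strictly increasing, in `[0, L-2]`).
#' @param L Gray-level count.
#' @param reconstruction `"mean"` or `"midpoint"`.
#' @return List with `labels` (integer matrix, values 0..m),
#'   `reconstruction` (integer matrix) and `levels` (intensity assigned to
#'   each class).
#' @export
apply_thresholds <- function(image, t, L = 256, reconstruction = c("mean", "midpoint")) {
  validate_image(image, L)
  if (is_color_image(image)) abort("`image` must be grayscale; apply per channel.")
  reconstruction <- match.arg(reconstruction)
  t <- validate_thresholds(t, L)
  m <- length(t)
  # class j holds gray levels in [t_j + 1, t_{j+1}]; label = #(t_j < value)
  labels <- matrix(findInterval(image - 0.5, t), nrow(image), ncol(image))
  lower <- c(0L, t + 1L)
  upper <- c(t, L - 1L)
  mid <- as.integer(round((lower + upper) / 2))
  levels <- mid
  if (reconstruction == "mean") {
    for (j in seq_len(m + 1L)) {
      px <- image[labels == j - 1L]
      if (length(px) > 0) levels[j] <- as.integer(round(mean(px)))
    }
  }
  recon <- matrix(levels[labels + 1L], nrow(image), ncol(image))
  list(labels = labels, reconstruction = recon, levels = levels)
}

#' Segment an image by entropy-maximising multi-level thresholding
#'
#' The full pipeline: gray-level histogram, entropic index selection,
#' threshold optimisation, and reconstruction with quality scoring.
#' Three methods are provided:
#' * `"adaptive"` — Tsallis objective at the self-adaptive `q*` from
#'   [estimate_q()] (q-redundancy maximisation);
#' * `"tsallis_fixed"` — Tsallis objective at a fixed `q` (default 0.8,
#'   the conventional empirical choice);
#' * `"shannon"` — Kapur's maximum-Shannon-entropy objective.
#'
#' Thresholds are found exhaustively when the combination count fits the
#' budget, otherwise by differential evolution.  Color images are
#' processed per channel (red, green, blue) with per-channel thresholds
#' and — for `"adaptive"` — a per-channel `q*` by default; `shared_q = TRUE`
#' instead estimates one `q*` from the mean of the three channel
#' histograms.
#'
#' @param image Integer matrix or `M x N x 3` array.
#' @param m Number of thresholds (`m + 1` classes).
#' @param method `"adaptive"`, `"tsallis_fixed"` or `"shannon"`.
#' @param q Fixed entropic index for `"tsallis_fixed"`.
#' @param L Gray-level count.
#' @param q_grid Candidate grid for `"adaptive"` (default [q_grid_default()]).
#' @param cfg [optimizer_config()] for the DE fallback.
#' @param reconstruction Rendering mode, see [apply_thresholds()].
#' @param budget Exhaustive-search evaluation budget.
#' @param shared_q For color + `"adaptive"`: estimate a single q across
#'   channels.
#' @return A `qthresh_segmentation`: thresholds, `q_used`, objective
#'   value(s), label map, reconstructed image and a quality report.
#'   Summarise with [glance()], inspect classes with [tidy()], render with
#'   [autoplot()].
#' @examples
#' img <- gen_mixture_image(mixture_spec(c(60, 180), c(8, 8)), 64, 64, seed = 1)
#' seg <- segment_image(img, m = 1, method = "adaptive")
#' glance(seg)
#' @export
segment_image <- function(image, m, method = c("adaptive", "tsallis_fixed", "shannon"),
                          q = 0.8, L = 256, q_grid = q_grid_default(),
                          cfg = optimizer_config(), reconstruction = c("mean", "midpoint"),
                          budget = 5e6, shared_q = FALSE) {
  method <- match.arg(method)
  reconstruction <- match.arg(reconstruction)
  validate_image(image, L)

  if (is_color_image(image)) {
    chans <- split_channels(image, L)
    shared <- NULL
    if (shared_q && method == "adaptive") {
      probs <- Reduce(`+`, lapply(chans, function(ch) compute_histogram(ch, L)$probs)) / 3
      shared <- estimate_q(probs, q_grid)$q_star
    }
    per_channel <- lapply(chans, function(ch) {
      segment_gray(ch, m, method, q, L, q_grid, cfg, reconstruction, budget,
                   q_override = shared)
    })
    recon <- stack_channels(per_channel$red$reconstruction,
                            per_channel$green$reconstruction,
                            per_channel$blue$reconstruction)
    labels <- stack_channels(per_channel$red$labels,
                             per_channel$green$labels,
                             per_channel$blue$labels)
    res <- structure(
      list(method = method, m = m,
           thresholds = lapply(per_channel, `[[`, "thresholds"),
           q_used = vapply(per_channel, function(x) x$q_used %||% NA_real_, numeric(1)),
           objective = vapply(per_channel, `[[`, numeric(1), "objective"),
           optimizer = per_channel$red$optimizer,
           labels = labels, reconstruction = recon,
           quality = quality_report(image, recon),
           channels = per_channel, L = L),
      class = "qthresh_segmentation"
    )
    return(res)
  }

  res <- segment_gray(image, m, method, q, L, q_grid, cfg, reconstruction, budget)
  res$quality <- quality_report(image, res$reconstruction)
  res$L <- L
  structure(res, class = "qthresh_segmentation")
}

segment_gray <- function(image, m, method, q, L, q_grid, cfg, reconstruction,
                         budget, q_override = NULL) {
  hist <- compute_histogram(image, L)
  q_used <- NULL
  q_est <- NULL
  if (method == "adaptive") {
    if (!is.null(q_override)) {
      q_used <- q_override
    } else {
      q_est <- withCallingHandlers(
        estimate_q(hist$probs, q_grid),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (q_est$degenerate) {
        warn("Degenerate histogram: q* is arbitrary; thresholds chosen deterministically.")
      }
      q_used <- q_est$q_star
    }
  } else if (method == "tsallis_fixed") {
    q_used <- q
  }
  obj_type <- if (method == "shannon") "kapur" else "tsallis"
  search <- if (choose(L - 1, m) <= budget) {
    exhaustive_search(hist, m, obj_type, q_used, budget)
  } else {
    swarm_optimize(hist, m, obj_type, q_used, cfg)
  }
  ap <- apply_thresholds(image, search$t, L, reconstruction)
  list(method = method, m = as.integer(m), thresholds = search$t,
       q_used = q_used, q_estimate = q_est, objective = search$value,
       optimizer = search$method, labels = ap$labels,
       reconstruction = ap$reconstruction, levels = ap$levels,
       histogram = hist)
}

#' @export
print.qthresh_segmentation <- function(x, ...) {
  cat(sprintf("<qthresh_segmentation> method = %s, m = %d (%s search)\n",
              x$method, x$m, x$optimizer))
  if (is.list(x$thresholds)) {
    for (ch in names(x$thresholds)) {
      cat(sprintf("  %s: t = [%s], q = %s\n", ch,
                  paste(x$thresholds[[ch]], collapse = ", "),
                  format(x$q_used[[ch]])))
    }
  } else {
    cat(sprintf("  t = [%s], q = %s, objective = %.6f\n",
                paste(x$thresholds, collapse = ", "),
                if (is.null(x$q_used)) "-" else format(x$q_used), x$objective))
  }
  print(x$quality)
  invisible(x)
}

#' @describeIn segment_image One-row summary: method, m, q, objective and
#'   quality scores.
#' @param x,object A `qthresh_segmentation`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.qthresh_segmentation <- function(x, ...) {
  q_used <- if (is.null(x$q_used)) NA_real_ else mean(unlist(x$q_used))
  dplyr::bind_cols(
    tibble(method = x$method, m = x$m, q_used = q_used,
           objective = mean(unlist(x$objective)), optimizer = x$optimizer),
    x$quality
  )
}

#' @describeIn segment_image One row per class (and channel, for color):
#'   gray-level bounds, pixel share and rendered level.
#' @exportS3Method generics::tidy
tidy.qthresh_segmentation <- function(x, ...) {
  one <- function(res, channel) {
    t <- res$thresholds
    lower <- c(0L, t + 1L)
    upper <- c(t, x$L - 1L)
    share <- vapply(seq_along(lower), function(j) {
      mean(res$labels == j - 1L)
    }, numeric(1))
    tibble(channel = channel, class = seq_along(lower) - 1L,
           lower = lower, upper = upper, pixel_share = share,
           level = res$levels)
  }
  if (is.list(x$thresholds)) {
    dplyr::bind_rows(lapply(names(x$channels), function(ch) one(x$channels[[ch]], ch)))
  } else {
    one(x, "gray")
  }
}

#' @describeIn segment_image Raster plot of the reconstructed image.
#' @exportS3Method ggplot2::autoplot
autoplot.qthresh_segmentation <- function(object, ...) {
  img <- object$reconstruction
  if (is_color_image(img)) {
    df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
    df$fill <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3],
                              maxColorValue = object$L - 1)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$fill)) +
      ggplot2::geom_raster() + ggplot2::scale_fill_identity()
  } else {
    df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
    df$value <- as.vector(img)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   limits = c(0, object$L - 1))
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s segmentation, m = %d", object$method, object$m),
                  x = NULL, y = NULL, fill = "level")
}

#' Repeated-run robustness profile of the stochastic search
#'
#' Runs the DE search `runs` times with seeds derived from `base_seed`,
#' sorts the attained objective values in ascending order, and reports how
#' many runs attain the maximal value — a flat, long tail in the sorted
#' curve means the best fitness is reproduced in most runs and the
#' stochastic optimiser is reliable for this image.
#'
#' @inheritParams segment_image
#' @param runs Number of independent optimisations.
#' @param base_seed Master seed; run `i` uses a derived child seed.
#' @param tol Absolute tolerance for counting a run as attaining the max.
#' @return A `fitness_profile`: sorted `values`, `max_multiplicity`,
#'   `best`, plus run metadata.  [tidy()] gives the sorted curve,
#'   [autoplot()] plots it.
#' @export
fitness_robustness <- function(image, m, runs = 100, base_seed = 1L,
                               method = c("adaptive", "tsallis_fixed", "shannon"),
                               q = 0.8, L = 256, q_grid = q_grid_default(),
                               cfg = optimizer_config(), tol = 1e-9) {
  method <- match.arg(method)
  check_number(runs, "runs", lower = 1)
  hist <- compute_histogram(image, L)
  q_used <- switch(method,
    adaptive = estimate_q(hist$probs, q_grid)$q_star,
    tsallis_fixed = q,
    shannon = NULL
  )
  obj_type <- if (method == "shannon") "kapur" else "tsallis"
  values <- vapply(seq_len(runs), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(base_seed, i)
    swarm_optimize(hist, m, obj_type, q_used, cfg_i)$value
  }, numeric(1))
  sorted <- sort(values)
  best <- sorted[length(sorted)]
  structure(
    list(values = sorted, best = best,
         max_multiplicity = sum(sorted >= best - tol),
         runs = as.integer(runs), m = as.integer(m), method = method,
         q_used = q_used, base_seed = base_seed),
    class = "fitness_profile"
  )
}

#' @export
print.fitness_profile <- function(x, ...) {
  cat(sprintf(
    "<fitness_profile> %s, m = %d: best = %.6f attained in %d/%d runs\n",
    x$method, x$m, x$best, x$max_multiplicity, x$runs))
  invisible(x)
}

#' @describeIn fitness_robustness Sorted fitness curve as a tibble
#'   (`rank`, `fitness`).
#' @param x,object A `fitness_profile`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fitness_profile <- function(x, ...) {
  tibble(rank = seq_along(x$values), fitness = x$values)
}

#' @describeIn fitness_robustness Plot of the ascending fitness curve.
#' @exportS3Method ggplot2::autoplot
autoplot.fitness_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rank, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "run (sorted)", y = "objective",
                  title = sprintf("%s, m = %d: max attained in %d/%d runs",
                                  object$method, object$m,
                                  object$max_multiplicity, object$runs))
}
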
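#' Batch segmentation over an image set
#'
#' Runs each method at each threshold count on every image and collects
#' one record per (image, method, m): thresholds, the q actually used,
#' the attained objective and the PSNR/SSIM quality scores.  Failures on
#' individual images are logged as warnings and skipped, never fatal.
#'
#' @param images Named list of images, or a character vector of file
#'   paths (read via [read_image()]; unreadable files are skipped with a
#'   warning).
#' @param methods Subset of `c("shannon", "tsallis_fixed", "adaptive")`.
#' @param m_values Threshold counts to evaluate.
#' @param q Fixed index for `"tsallis_fixed"` (default 0.8).
#' @inheritParams segment_image
#' @return Tibble with columns `image_id`, `method`, `m`, `q_used`,
#'   `thresholds` (list column), `objective`, `mse`, `psnr_db`, `ssim`.
#' @export
run_batch <- function(images, methods = c("shannon", "tsallis_fixed", "adaptive"),
                      m_values = 4, q = 0.8, L = 256,
                      q_grid = q_grid_default(), cfg = optimizer_config(),
                      budget = 5e6) {
  methods <- match.arg(methods, c("shannon", "tsallis_fixed", "adaptive"),
                       several.ok = TRUE)
  if (is.character(images)) {
    paths <- images
    images <- list()
    for (p in paths) {
      img <- tryCatch(read_image(p, L), error = function(e) {
        warn(sprintf("Skipping unreadable image '%s': %s", p, conditionMessage(e)))
        NULL
      })
      if (!is.null(img)) images[[tools::file_path_sans_ext(basename(p))]] <- img
    }
  }
  if (length(images) == 0L) abort("`images` is empty.")
  ids <- names(images) %||% as.character(seq_along(images))
  if (is.null(names(images))) names(images) <- ids

  grid <- tidyr::expand_grid(image_id = ids, method = methods, m = m_values)
  rows <- purrr::pmap(grid, function(image_id, method, m) {
    res <- tryCatch(
      segment_image(images[[image_id]], m = m, method = method, q = q, L = L,
                    q_grid = q_grid, cfg = cfg, budget = budget),
      error = function(e) {
        warn(sprintf("Segmentation failed for '%s' (%s, m=%d): %s",
                     image_id, method, m, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) return(NULL)
    g <- glance(res)
    tibble(image_id = image_id, method = method, m = as.integer(m),
           q_used = if (method == "shannon") NA_real_ else g$q_used,
           thresholds = list(res$thresholds),
           objective = g$objective, mse = g$mse, psnr_db = g$psnr_db,
           ssim = g$ssim)
  })
  dplyr::bind_rows(rows)
}

#' Most-suitable rates across methods
#'
#' For each method, the fraction of images on which its score equals the
#' per-image maximum at the given `m` — the statistic used to compare
#' segmentation algorithms over a dataset.  Ties (within `tol`) are
#' credited to every tied method, so the rates can sum to slightly more
#' than 1.
#'
#' @param records Output of [run_batch()].
#' @param score `"psnr"` or `"ssim"`.
#' @param m Threshold count to evaluate at (default: the single m present).
#' @param tol Score-equality tolerance for crediting ties.
#' @return Tibble with columns `method`, `n_images`, `n_best`, `rate`
#'   (fraction in `[0, 1]`).
#' @export
suitability <- function(records, score = c("psnr", "ssim"), m = NULL, tol = 1e-6) {
  score <- match.arg(score)
  col <- if (score == "psnr") "psnr_db" else "ssim"
  m <- m %||% unique(records$m)
  if (length(m) != 1L) abort("Pick a single `m` (records contain several).")
  recs <- dplyr::filter(records, .data$m == !!m)
  methods <- unique(recs$method)
  cover <- dplyr::count(recs, .data$image_id)
  if (any(cover$n != length(methods))) {
    abort("Every image must have a record for every method at the chosen m.")
  }
  recs <- dplyr::mutate(
    dplyr::group_by(recs, .data$image_id),
    best = {
      s <- .data[[col]]
      top <- max(s)
      # identical images make every PSNR infinite; credit all methods
      if (is.infinite(top)) is.infinite(s) else s >= top - tol
    })
  recs <- dplyr::ungroup(recs)
  out <- dplyr::summarise(
    dplyr::group_by(recs, .data$method),
    n_images = dplyr::n(), n_best = sum(.data$best),
    rate = mean(.data$best), .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$rate))
}
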
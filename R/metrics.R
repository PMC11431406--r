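#' Mean squared error between two images
#'
#' Mean of squared intensity differences over all pixels; for color
#' images the mean is taken jointly over all channels.
#'
#' @param original,segmented Images of identical dimension and channels.
#' @return Non-negative scalar.
#' @export
img_mse <- function(original, segmented) {
  check_same_shape(original, segmented)
  mean((as.numeric(original) - as.numeric(segmented))^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' \eqn{PSNR = 10 \log_{10}(255^2 / MSE)} with the peak fixed at 255
#' (8-bit convention) regardless of the observed maximum.  Identical
#' images have `MSE = 0` and return `Inf`.  Typical segmentation
#' reconstructions land between 10 and 50 dB; above 30 dB differences are
#' hard to see by eye.
#'
#' @inheritParams img_mse
#' @param peak Peak signal value (default 255).
#' @return PSNR in dB, or `Inf` for identical images.
#' @export
img_psnr <- function(original, segmented, peak = 255) {
  m <- img_mse(original, segmented)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Structural similarity index (global form)
#'
#' \deqn{SSIM(x, y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)},}
#' computed from whole-image means, variances (population convention) and
#' covariance.  The stabilizers default to the standard
#' \eqn{C_1 = (0.01 \cdot 255)^2}, \eqn{C_2 = (0.03 \cdot 255)^2}.
#' For color images the index is computed per channel and averaged.
#'
#' A sliding-window variant (mean of local SSIM over square windows) is
#' available via `window`; it is an extension beyond the global form and
#' is off by default.
#'
#' @inheritParams img_mse
#' @param c1,c2 Positive stabilizing constants.
#' @param window `NULL` (global, default) or an odd window side length for
#'   the local-window extension.
#' @return Scalar in `[-1, 1]`; 1 for identical images.
#' @export
img_ssim <- function(original, segmented, c1 = (0.01 * 255)^2,
                     c2 = (0.03 * 255)^2, window = NULL) {
  check_same_shape(original, segmented)
  check_number(c1, "c1", lower = 0, strict = TRUE)
  check_number(c2, "c2", lower = 0, strict = TRUE)
  if (is_color_image(original)) {
    vals <- vapply(1:3, function(ch) {
      img_ssim(original[, , ch], segmented[, , ch], c1, c2, window)
    }, numeric(1))
    return(mean(vals))
  }
  if (is.null(window)) {
    ssim_global(as.numeric(original), as.numeric(segmented), c1, c2)
  } else {
    ssim_windowed(original, segmented, c1, c2, as.integer(window))
  }
}

ssim_global <- function(x, y, c1, c2) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# Local-mean SSIM over all fully interior w x w windows, via integral images.
ssim_windowed <- function(x, y, c1, c2, w) {
  if (w < 2 || w > min(dim(x))) abort("`window` must be between 2 and min(dim).")
  box <- function(z) {
    cs <- apply(apply(z, 2, cumsum), 1, cumsum)   # transposed integral image
    cs <- t(cs)
    pad <- matrix(0, nrow(z) + 1, ncol(z) + 1)
    pad[-1, -1] <- cs
    nr <- nrow(z) - w + 1; nc <- ncol(z) - w + 1
    pad[(w + 1):(nrow(z) + 1), (w + 1):(ncol(z) + 1)] -
      pad[1:nr, (w + 1):(ncol(z) + 1)] -
      pad[(w + 1):(nrow(z) + 1), 1:nc] + pad[1:nr, 1:nc]
  }
  n <- w * w
  mx <- box(x) / n; my <- box(y) / n
  vx <- box(x^2) / n - mx^2
  vy <- box(y^2) / n - my^2
  cxy <- box(x * y) / n - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("Images must share dimensions and channel count.")
  invisible(NULL)
}

#' Quality report for a segmentation reconstruction
#'
#' One-row tibble with joint-channel MSE, PSNR (dB) and SSIM (per-channel
#' mean for color).
#'
#' @inheritParams img_mse
#' @return Tibble with columns `mse`, `psnr_db`, `ssim`.
#' @export
quality_report <- function(original, segmented) {
  tibble(
    mse = img_mse(original, segmented),
    psnr_db = img_psnr(original, segmented),
    ssim = img_ssim(original, segmented)
  )
}
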
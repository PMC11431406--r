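#' Gray-level histogram of an image
#'
#' Counts pixels at each of the `L` gray levels and normalises by the pixel
#' count, giving the probability distribution `p_i = h_i / (M*N)` that every
#' entropy in the package operates on.  Zero-count bins are kept (with
#' probability 0), never dropped.
#'
#' @param image Integer matrix (grayscale); for color images compute one
#'   histogram per channel via [split_channels()].
#' @param L Number of gray levels (bins), default 256.
#' @return A `gray_histogram`: list with `L`, integer `counts` (length `L`),
#'   `probs` (summing to 1) and `n_pixels`.
#' @examples
#' img <- matrix(c(0, 0, 1, 2), 2, 2)
#' h <- compute_histogram(img, L = 4)
#' h$probs
#' @export
compute_histogram <- function(image, L = 256) {
  if (L < 2) abort("`L` must be at least 2.")
  validate_image(image, L)
  if (is_color_image(image)) {
    abort("`image` has 3 channels; use split_channels() and compute per-channel histograms.")
  }
  counts <- tabulate(as.integer(image) + 1L, nbins = L)
  n <- length(image)
  new_gray_histogram(counts, n, L)
}

new_gray_histogram <- function(counts, n_pixels, L) {
  structure(
    list(L = as.integer(L), counts = as.integer(counts),
         probs = counts / n_pixels, n_pixels = as.integer(n_pixels)),
    class = "gray_histogram"
  )
}

#' Build a histogram with counts matching an explicit probability vector
#'
#' Counts are `probs * total` rounded with largest-remainder correction, so
#' they always sum exactly to `total`.  Used to construct test histograms
#' with known analytic structure.
#'
#' @param probs Probability vector over gray levels (length = `L`).
#' @param total Total pixel count the counts must sum to.
#' @return A `gray_histogram`.
#' @examples
#' gen_histogram(c(0.5, 0.3, 0.2), total = 10)$counts
#' @export
gen_histogram <- function(probs, total) {
  validate_probs(probs)
  check_number(total, "total", lower = 1)
  target <- probs / sum(probs) * total
  base <- floor(target)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    frac_order <- order(target - base, decreasing = TRUE)
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  }
  new_gray_histogram(as.integer(base), total, length(probs))
}

#' Synthesize a grayscale image realising a histogram exactly
#'
#' Deterministic arrangement (levels in ascending raster order); the
#' histogram of the result reproduces `hist` bit-exactly.
#'
#' @param hist A `gray_histogram`.
#' @param ncol Number of columns of the output (rows inferred); default a
#'   near-square layout.
#' @return Integer matrix.
#' @export
image_from_histogram <- function(hist, ncol = NULL) {
  stopifnot(inherits(hist, "gray_histogram"))
  n <- hist$n_pixels
  ncol <- ncol %||% max(1L, floor(sqrt(n)))
  while (n %% ncol != 0L) ncol <- ncol - 1L
  vals <- rep(seq_len(hist$L) - 1L, times = hist$counts)
  matrix(vals, ncol = ncol)
}

validate_probs <- function(probs, tol = 1e-6) {
  if (!is.numeric(probs) || length(probs) < 1L || anyNA(probs)) {
    abort("`probs` must be a numeric probability vector.")
  }
  if (any(probs < -1e-12)) abort("`probs` contains negative entries.")
  if (abs(sum(probs) - 1) > tol) {
    abort(sprintf("`probs` sums to %.8f, not 1.", sum(probs)))
  }
  invisible(probs)
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat(sprintf("<gray_histogram> L = %d bins, %d pixels, %d non-empty bins\n",
              x$L, x$n_pixels, nz))
  invisible(x)
}

#' @describeIn compute_histogram Tidy a histogram into a tibble with one row
#'   per gray level (`gray`, `count`, `prob`).
#' @param x A `gray_histogram`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gray_histogram <- function(x, ...) {
  tibble(gray = seq_len(x$L) - 1L, count = x$counts, prob = x$probs)
}
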
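# ---- internal helpers -------------------------------------------------------

# Reflect padding (edge-inclusive, scipy 'reflect' / cv2 BORDER_REFLECT):
# for a row a b c d padded by 2 -> b a | a b c d | d c.
# Held fixed so blur/morphology determinism is bit-exact.
pad_reflect_idx <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  if (r > n) stop("padding radius exceeds image extent", call. = FALSE)
  c(rev(seq_len(r)), seq_len(n), seq(n, n - r + 1L))
}

check_gray <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("%s must be a single-channel numeric matrix", what), call. = FALSE)
  if (length(image) == 0L) stop(sprintf("%s is empty", what), call. = FALSE)
  invisible(image)
}

check_odd_kernel <- function(kernel) {
  if (length(kernel) != 1L || is.na(kernel) || kernel < 1 || kernel %% 2 == 0)
    stop("kernel must be a positive odd integer", call. = FALSE)
  as.integer(kernel)
}

# Keys bicubic kernel, a = -0.5 (the standard photographic convention).
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# Interpolation matrix mapping n_in samples to n_out, pixel-centre aligned:
# src = (dst + 0.5) * n_in / n_out - 0.5 (0-based), border taps clamped.
cubic_interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 1 + 0.5) * scale - 0.5
    base <- floor(src)
    taps <- base + (-1:2)
    w <- cubic_kernel(src - taps)
    taps <- pmin(pmax(taps, 0), n_in - 1) + 1L  # clamp to border
    for (k in 1:4) A[i, taps[k]] <- A[i, taps[k]] + w[k]
  }
  A
}

# ---- pipeline parameter container ------------------------------------------

#' Stimulus pipeline parameters
#'
#' Bundles the tunable knobs of the two-tone stimulus pipeline. Defaults follow
#' the published recipe: 500x500 bicubic resize, a 1x1 opening kernel
#' (mathematically the identity; exposed because a larger kernel is the only
#' way the opening step can denoise) and a 9x9 Gaussian blur.
#'
#' @param target_size side length in pixels of the square output (default 500).
#' @param opening_kernel odd side of the square opening structuring element.
#' @param blur_kernel odd side of the Gaussian blur kernel.
#' @param blur_sigma positive standard deviation in pixels, or `"auto"` for
#'   the OpenCV convention `0.3 * ((kernel - 1)/2 - 1) + 0.8` (1.7 for a 9x9
#'   kernel).
#' @return A list of class `"stimulus_params"`.
#' @export
stimulus_params <- function(target_size = 500L, opening_kernel = 1L,
                            blur_kernel = 9L, blur_sigma = "auto") {
  opening_kernel <- check_odd_kernel(opening_kernel)
  blur_kernel <- check_odd_kernel(blur_kernel)
  if (!identical(blur_sigma, "auto")) {
    if (!is.numeric(blur_sigma) || length(blur_sigma) != 1L || blur_sigma <= 0)
      stop("blur_sigma must be positive or \"auto\"", call. = FALSE)
  }
  if (target_size < blur_kernel)
    stop("target_size must be at least blur_kernel", call. = FALSE)
  structure(list(target_size = as.integer(target_size),
                 opening_kernel = opening_kernel,
                 blur_kernel = blur_kernel,
                 blur_sigma = blur_sigma),
            class = "stimulus_params")
}

auto_sigma <- function(kernel) 0.3 * ((kernel - 1) / 2 - 1) + 0.8

# ---- stage operations -------------------------------------------------------

#' Bicubic resize of an intensity image
#'
#' Resizes a grayscale matrix or RGB array (values 0-255) to `size` x `size`
#' using separable Keys bicubic interpolation (a = -0.5), pixel-centre
#' alignment and clamped borders. Output is clipped to [0, 255].
#'
#' @param image numeric matrix (H x W) or array (H x W x 3).
#' @param size target side length, at least 2.
#' @return Resized image of the same kind as the input.
#' @export
resize_cubic <- function(image, size) {
  if (length(image) == 0L) stop("image is empty", call. = FALSE)
  if (length(size) != 1L || size < 2) stop("size must be >= 2", call. = FALSE)
  size <- as.integer(size)
  resize_plane <- function(m) {
    A <- cubic_interp_matrix(nrow(m), size)
    B <- cubic_interp_matrix(ncol(m), size)
    out <- A %*% m %*% t(B)
    pmin(pmax(out, 0), 255)
  }
  if (is.matrix(image)) return(resize_plane(image))
  if (is.array(image) && length(dim(image)) == 3L) {
    out <- array(0, c(size, size, dim(image)[3]))
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- resize_plane(image[, , ch])
    return(out)
  }
  stop("image must be a 2-D matrix or 3-D array", call. = FALSE)
}

#' Convert an RGB image to grayscale luminance
#'
#' Uses the ITU-R BT.601 weights (0.299, 0.587, 0.114) and rounds to integer
#' intensity, matching 8-bit image-library behaviour. A single-channel input
#' is returned unchanged.
#'
#' @param image numeric matrix (already grayscale) or H x W x 3 array.
#' @return Numeric matrix of rounded intensities in [0, 255].
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    if (nc == 1L)
      return(matrix(image[, , 1], dim(image)[1], dim(image)[2]))
    if (nc != 3L) stop("image must have 1 or 3 channels", call. = FALSE)
    g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    return(matrix(round(g), dim(image)[1], dim(image)[2]))
  }
  stop("image must have 1 or 3 channels", call. = FALSE)
}

# Sliding-window extremum filter with reflect padding.
local_extremum <- function(image, kernel, fun) {
  r <- (kernel - 1L) %/% 2L
  if (r == 0L) return(image)
  ri <- pad_reflect_idx(nrow(image), r)
  ci <- pad_reflect_idx(ncol(image), r)
  padded <- image[ri, ci, drop = FALSE]
  out <- NULL
  for (dy in 0:(kernel - 1L)) for (dx in 0:(kernel - 1L)) {
    block <- padded[dy + seq_len(nrow(image)), dx + seq_len(ncol(image)), drop = FALSE]
    out <- if (is.null(out)) block else fun(out, block)
  }
  out
}

#' Grayscale morphological opening
#'
#' Erosion (local minimum) followed by dilation (local maximum) with a square
#' structuring element, using reflect padding at the borders. A 1x1 element is
#' the identity transform.
#'
#' @param image single-channel numeric matrix.
#' @param kernel odd side length of the square structuring element.
#' @return Opened image, same dimensions.
#' @export
morphological_open <- function(image, kernel = 1L) {
  check_gray(image)
  kernel <- check_odd_kernel(kernel)
  eroded <- local_extremum(image, kernel, pmin)
  local_extremum(eroded, kernel, pmax)
}

#' Separable Gaussian blur
#'
#' Convolves with a normalized Gaussian kernel (rows then columns), reflect
#' padding at the borders. With `sigma = "auto"` the standard deviation
#' follows the kernel-size convention `0.3 * ((kernel - 1)/2 - 1) + 0.8`.
#'
#' @param image single-channel numeric matrix.
#' @param kernel odd kernel side length.
#' @param sigma positive real or `"auto"`.
#' @return Blurred image (real-valued; not rounded).
#' @export
gaussian_blur <- function(image, kernel = 9L, sigma = "auto") {
  check_gray(image)
  kernel <- check_odd_kernel(kernel)
  if (identical(sigma, "auto")) sigma <- auto_sigma(kernel)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive", call. = FALSE)
  r <- (kernel - 1L) %/% 2L
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  if (r == 0L) return(image)
  ri <- pad_reflect_idx(nrow(image), r)
  tmp <- image[ri, , drop = FALSE]
  # convolve down columns
  rows <- vapply(seq_len(nrow(image)), function(i) {
    drop(g %*% tmp[i:(i + 2L * r), , drop = FALSE])
  }, numeric(ncol(image)))
  tmp <- if (is.matrix(rows)) t(rows) else matrix(rows, nrow = nrow(image))
  ci <- pad_reflect_idx(ncol(image), r)
  tmp2 <- tmp[, ci, drop = FALSE]
  cols <- vapply(seq_len(ncol(image)), function(j) {
    drop(tmp2[, j:(j + 2L * r), drop = FALSE] %*% g)
  }, numeric(nrow(image)))
  matrix(cols, nrow = nrow(image))
}

#' Otsu threshold and binarization
#'
#' Selects the global threshold maximizing between-class variance over the
#' 256-bin intensity histogram (intensities rounded and clipped to 0-255),
#' then assigns 255 where intensity exceeds the threshold and 0 elsewhere.
#' Ties are broken toward the lowest threshold.
#'
#' @param image single-channel numeric matrix with at least two distinct
#'   intensity values.
#' @return List with `threshold` (integer in 0-254) and `binary` (matrix of
#'   0/255).
#' @export
otsu_threshold <- function(image) {
  check_gray(image)
  v <- pmin(pmax(round(image), 0), 255)
  if (length(unique(as.vector(v))) < 2L)
    stop("constant image: no threshold separates a single class", call. = FALSE)
  counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)                      # class 0: intensity <= t
  mu <- cumsum(p * levels)
  mu_total <- mu[256]
  w1 <- 1 - w0
  # between-class variance at each candidate threshold t = 0..254
  num <- (mu_total * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)[1:255]
  threshold <- which.max(sigma_b) - 1L
  binary <- ifelse(v > threshold, 255, 0)
  list(threshold = threshold, binary = binary)
}

#' Build a two-tone stimulus from a colour template
#'
#' Runs the full deterministic pipeline: bicubic resize to the target size,
#' grayscale conversion, morphological opening, Gaussian blur (result rounded
#' back to integer intensities before thresholding), and Otsu binarization.
#'
#' @param template numeric matrix or H x W x 3 array of intensities in 0-255.
#' @param params a [stimulus_params()] object.
#' @param id identifier for the resulting stimulus.
#' @param template_id identifier of the source template.
#' @param is_test logical; `TRUE` if the template contains a person.
#' @return Object of class `"two_tone"`: list with `pixels` (0/255 matrix),
#'   `id`, `template_id`, `is_test` and `otsu_threshold`.
#' @export
make_two_tone <- function(template, params = stimulus_params(), id = "stim",
                          template_id = id, is_test = NA) {
  if (length(template) == 0L) stop("template is empty", call. = FALSE)
  x <- resize_cubic(template, params$target_size)
  x <- to_grayscale(x)
  x <- morphological_open(x, params$opening_kernel)
  x <- gaussian_blur(x, params$blur_kernel, params$blur_sigma)
  x <- pmin(pmax(round(x), 0), 255)
  ot <- otsu_threshold(x)
  structure(list(pixels = ot$binary, id = id, template_id = template_id,
                 is_test = is_test, otsu_threshold = ot$threshold),
            class = "two_tone")
}

#' @export
print.two_tone <- function(x, ...) {
  vals <- sort(unique(as.vector(x$pixels)))
  cat(sprintf("Two-tone stimulus '%s' (template '%s', %s)\n", x$id,
              x$template_id,
              if (isTRUE(x$is_test)) "test" else if (isFALSE(x$is_test)) "control" else "unlabelled"))
  cat(sprintf("  %d x %d, Otsu threshold %d, tones {%s}\n",
              nrow(x$pixels), ncol(x$pixels), x$otsu_threshold,
              paste(vals, collapse = ", ")))
  invisible(x)
}

#' Pilot screening of stimulus difficulty
#'
#' Keeps stimuli that are hard enough before template viewing and easy enough
#' after: those that are too easy to disambiguate before seeing the template,
#' or still too hard after, are excluded. Scores may be on any common
#' discrimination scale (proportion correct or d-prime) as long as the rule's
#' cut-offs are on the same scale.
#'
#' @param pilot_scores data frame with columns `stimulus_id`, `before`,
#'   `after` (per-stimulus pilot discrimination scores).
#' @param max_before keep only stimuli with `before <= max_before`.
#' @param min_after keep only stimuli with `after >= min_after`.
#' @return Character vector of kept stimulus ids.
#' @export
screen_stimuli <- function(pilot_scores, max_before = 0.80, min_after = 0.65) {
  req <- c("stimulus_id", "before", "after")
  if (!all(req %in% names(pilot_scores)))
    stop("pilot_scores needs columns stimulus_id, before, after", call. = FALSE)
  if (anyNA(pilot_scores$before) || anyNA(pilot_scores$after))
    stop("missing before or after pilot score", call. = FALSE)
  keep <- pilot_scores$before <= max_before & pilot_scores$after >= min_after
  as.character(pilot_scores$stimulus_id[keep])
}

#' Read a PNG template image as 0-255 intensities
#'
#' @param path path to a PNG file.
#' @return Numeric matrix (grayscale) or H x W x 3 array (colour) in 0-255.
#' @export
read_template_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  img * 255
}

#' Write a two-tone stimulus to PNG
#'
#' @param stimulus a `"two_tone"` object.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_two_tone_png <- function(stimulus, path) {
  png::writePNG(stimulus$pixels / 255, path)
  invisible(path)
}
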
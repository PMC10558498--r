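#' Load a raster image as an 8-bit grayscale matrix
#'
#' Reads PNG/JPEG/TIFF via EBImage; multi-channel input is averaged to
#' one channel. Values are returned on the \[0, 255\] scale.
#'
#' @param path Image file path.
#' @return Numeric matrix in \[0, 255\].
#' @export
load_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) == 3L) apply(img, c(1, 2), mean) else as.matrix(img)
  m * 255
}

#' Chest X-ray style preprocessing
#'
#' Min-max normalises pixel values to \[0, 255\], inverts the image when
#' the border-region mean exceeds the centre-region mean (the cue that
#' air is rendered dark and the photometric interpretation is flipped),
#' then applies global histogram equalization over 256 levels and
#' returns an 8-bit image. A constant image is returned unchanged —
#' normalisation and equalization are undefined on a degenerate
#' histogram. The whole chain is idempotent up to one intensity level.
#'
#' @param img Single-channel numeric matrix.
#' @return Integer-valued matrix in \[0, 255\] with attributes
#'   `inverted` and `equalized`.
#' @export
preprocess_cxr <- function(img) {
  if (is.null(dim(img)) || any(dim(img) == 0L) || length(img) == 0L)
    abort("empty image", class = "fairdx_spec_error")
  if (length(dim(img)) != 2L)
    abort("preprocess_cxr expects a single-channel image", class = "fairdx_spec_error")
  rng <- range(img)
  if (rng[1] == rng[2]) {
    out <- img
    attr(out, "inverted") <- FALSE; attr(out, "equalized") <- FALSE
    return(out)
  }
  v <- (img - rng[1]) / (rng[2] - rng[1]) * 255
  inverted <- FALSE
  if (border_mean(v) > center_mean(v)) { v <- 255 - v; inverted <- TRUE }
  v <- equalize_hist(v)
  attr(v, "inverted") <- inverted; attr(v, "equalized") <- TRUE
  v
}

# border = outer 10% frame of the image, centre = the rest
border_mask <- function(d) {
  bi <- pmax(1L, round(d * 0.1))
  m <- matrix(TRUE, d[1], d[2])
  m[(bi[1] + 1):(d[1] - bi[1]), (bi[2] + 1):(d[2] - bi[2])] <- FALSE
  m
}
border_mean <- function(v) mean(v[border_mask(dim(v))])
center_mean <- function(v) mean(v[!border_mask(dim(v))])

# classic global histogram equalization to a uniform 256-level target:
# map each level through the normalised empirical CDF
equalize_hist <- function(v) {
  q <- floor(pmin(pmax(v, 0), 255))
  h <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(q)
  if (n == cdf_min) return(matrix(q, nrow(v)))   # single occupied level
  lut <- round((cdf - cdf_min) / (n - cdf_min) * 255)
  matrix(lut[q + 1L], nrow(v))
}

#' Random rotation and flip augmentation
#'
#' Draws a rotation angle uniformly from \[0, 10\] degrees with a random
#' sign, and independent fair coin flips for horizontal and vertical
#' mirroring. Rotation uses bilinear interpolation with a black (0)
#' background fill and preserves the image shape. Deterministic under
#' `seed`.
#'
#' @param img Numeric matrix (preprocessed image).
#' @param seed Integer seed.
#' @return Augmented matrix, same dimensions and intensity domain.
#' @export
augment_image <- function(img, seed = 1L) {
  stopifnot(length(dim(img)) == 2L)
  with_seed_(seed, {
    angle <- runif(1, 0, 10) * sample(c(-1, 1), 1)
    do_h <- runif(1) < 0.5
    do_v <- runif(1) < 0.5
    out <- img
    if (abs(angle) > 0) {
      e <- EBImage::rotate(EBImage::Image(out / 255), angle,
                           filter = "bilinear", output.dim = dim(out),
                           bg.col = 0)
      out <- as.matrix(EBImage::imageData(e)) * 255
    }
    if (do_h) out <- out[nrow(out):1, , drop = FALSE]
    if (do_v) out <- out[, ncol(out):1, drop = FALSE]
    out
  })
}

#' Resize to the scorer input shape
#'
#' Bilinear resize to `side` x `side`; grayscale input is replicated to
#' the requested channel count (models pretrained on RGB expect 3).
#'
#' @param img Numeric matrix or h x w x 3 array.
#' @param side Output side length (default 224).
#' @param channels 1 or 3 output channels.
#' @return Matrix (`channels = 1`) or `side x side x channels` array.
#' @export
resize_to_input <- function(img, side = 224L, channels = 3L) {
  d <- dim(img)
  if (is.null(d) || any(d == 0L))
    abort("zero-dimension image", class = "fairdx_spec_error")
  m <- if (length(d) == 3L) apply(img, c(1, 2), mean) else img
  if (!all(dim(m) == c(side, side))) {
    e <- EBImage::resize(EBImage::Image(m / 255), w = side, h = side,
                         filter = "bilinear")
    m <- as.matrix(EBImage::imageData(e)) * 255
  }
  if (channels == 1L) return(m)
  array(rep(m, channels), dim = c(side, side, channels))
}
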
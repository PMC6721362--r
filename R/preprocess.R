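#' Median denoising
#'
#' Square median filter applied before binarization to suppress shot and
#' line noise from the infrared camera.
#'
#' @param img Grayscale image matrix (0-255).
#' @param window Odd window side length; `1` is the identity.
#' @return Filtered image, same shape, integer 0-255.
#' @export
denoise <- function(img, window = 3L) {
  assert_gray_image(img)
  if (window %% 2 == 0 || window < 1)
    stop_pupiltrack("window must be odd and >= 1", "invalid_parameter")
  if (window == 1L) return(matrix(as.integer(img), nrow(img), ncol(img)))
  r <- as.integer((window - 1L) / 2L)
  median_filter_int(matrix(as.integer(img), nrow(img), ncol(img)), r)
}

#' Expected pupil percentile from a radius estimate
#'
#' The adaptive quantitative binarization keys its threshold to the fraction
#' of image pixels expected to belong to the pupil. For a circular pupil of
#' radius `r_pupil` that percentage is
#' `t0 = 100 * pi * r_pupil^2 / (width * height)`.
#'
#' @param r_pupil Pupil radius estimate in pixels (> 0), typically obtained
#'   with [estimate_pupil_radius()] during calibration.
#' @param width,height Image size in pixels.
#' @return Percentile `t0` in percent.
#' @export
#' @examples
#' percentile_from_radius(25, 640, 480) # ~0.64 %
percentile_from_radius <- function(r_pupil, width, height) {
  if (r_pupil <= 0)
    stop_pupiltrack("r_pupil must be positive", "invalid_parameter")
  if (width * height <= 0)
    stop_pupiltrack("image area must be positive", "invalid_parameter")
  100 * pi * r_pupil^2 / (width * height)
}

#' Adaptive quantitative threshold
#'
#' Computes the global threshold `T` as the smallest grey level whose
#' cumulative pixel fraction (in percent) reaches the target percentile
#' `t0`; the pupil mask is then `intensity <= T`. Because the threshold is
#' tied to a pixel *quantile* rather than an absolute level, it is invariant
#' to global illumination changes that preserve the intensity ordering.
#'
#' @param img Grayscale image (0-255).
#' @param t0 Target percentile in percent, `0 < t0 < 100`.
#' @return Integer threshold `T` in 0-255, with attribute `"degenerate"`
#'   set to `TRUE` when the mask would cover the whole image (e.g. constant
#'   input).
#' @export
quantitative_threshold <- function(img, t0) {
  assert_gray_image(img)
  if (t0 <= 0 || t0 >= 100)
    stop_pupiltrack("t0 must lie strictly between 0 and 100",
                    "invalid_parameter")
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  cum <- cumsum(counts) / length(img) * 100
  T_ <- which(cum >= t0)[1] - 1L
  structure(as.integer(T_), degenerate = cum[T_ + 1L] >= 100)
}

#' Binarize a dark-pupil image
#'
#' @param img Grayscale image.
#' @param T Threshold intensity (0-255); object pixels are those with
#'   `intensity <= T` (dark-pupil polarity).
#' @return Logical mask, `TRUE` = object.
#' @export
binarize <- function(img, T) {
  assert_gray_image(img)
  if (T < 0 || T > 255)
    stop_pupiltrack("T must lie in [0, 255]", "invalid_parameter")
  img <= T
}

#' Keep the largest connected component
#'
#' After binarization the pupil is taken to be the object of maximum area;
#' smaller noise blobs are discarded. Components use 8-connectivity. Area
#' ties are broken in favor of the component containing the smallest pixel
#' index in row-major (top-to-bottom, then left-to-right) order.
#'
#' @param mask Logical mask.
#' @return Logical mask retaining only the largest component.
#' @export
largest_component <- function(mask) {
  assert_mask(mask)
  if (!any(mask))
    stop_pupiltrack("empty mask: no pupil candidate", "no_pupil")
  lab <- label_components8(mask)
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # row-major scan order on [y, x]: row index changes fastest per column
    # in R storage, so rank pixels explicitly by (y - 1) * width + x
    h <- nrow(mask); w <- ncol(mask)
    first_rowmajor <- vapply(best, function(l) {
      idx <- which(lab == l)
      y <- ((idx - 1L) %% h) + 1L; x <- ((idx - 1L) %/% h) + 1L
      min((y - 1L) * w + x)
    }, numeric(1))
    best <- best[which.min(first_rowmajor)]
  }
  lab == best[1]
}

disc_kernel <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Morphological pupil reconstruction
#'
#' Removes the corneal-reflection artifacts from the binarized pupil:
#' dilation with a disc structuring element, hole filling (flood fill of the
#' complement from the image border), then erosion with the same disc.
#' Interior glint holes disappear; boundary glint notches of half-width up
#' to `se_radius` are closed.
#'
#' @param mask Logical pupil mask (non-empty).
#' @param se_radius Disc structuring-element radius in pixels (>= 1). A
#'   practical default is `max(3, round(0.2 * r_pupil))`, scaling with the
#'   typical glint-to-pupil size ratio.
#' @return Reconstructed logical mask.
#' @export
reconstruct_pupil <- function(mask, se_radius = 3L) {
  assert_mask(mask)
  if (!any(mask))
    stop_pupiltrack("empty mask: nothing to reconstruct", "no_pupil")
  if (se_radius < 1)
    stop_pupiltrack("se_radius must be >= 1", "invalid_parameter")
  kern <- disc_kernel(se_radius)
  m <- EBImage::dilate(mask * 1L, kern)
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, kern)
  matrix(m > 0, nrow(mask), ncol(mask))
}

#' Default structuring-element radius from a pupil radius estimate
#' @param r_pupil Pupil radius estimate (pixels).
#' @return Integer disc radius.
#' @export
default_se_radius <- function(r_pupil) max(3L, as.integer(round(0.2 * r_pupil)))

log_kernel <- function(sigma) {
  half <- max(2L, ceiling(4 * sigma))
  g <- seq(-half, half)
  xx <- matrix(rep(g, each = length(g)), length(g))
  yy <- t(xx)
  k <- ((xx^2 + yy^2 - 2 * sigma^2) / sigma^4) *
    exp(-(xx^2 + yy^2) / (2 * sigma^2))
  k - mean(k)  # zero-sum so flat regions give exactly zero response
}

#' Laplacian-of-Gaussian edge detection
#'
#' Convolves with a LoG kernel and marks zero-crossing pixels: a pixel is an
#' edge when a 4-neighbor has opposite response sign, the pixel is the one
#' closer to zero, and the local response swing exceeds `threshold`
#' (rejecting the numerically-zero oscillations of flat regions). Used to
#' feed the Hough-transform detectors.
#'
#' @param x Logical mask or grayscale image (the latter rescaled to 0-1
#'   before filtering).
#' @param sigma Gaussian scale in pixels (> 0).
#' @param threshold Minimum `|response| + |neighbor response|` for a zero
#'   crossing to count as an edge, in 0-1 intensity units; rejects the
#'   numerically-zero oscillations of flat regions and the faint ripples of
#'   kernel truncation.
#' @return Logical edge mask (may be empty for blank input).
#' @export
log_edges <- function(x, sigma = 2, threshold = 0.03) {
  if (sigma <= 0)
    stop_pupiltrack("sigma must be positive", "invalid_parameter")
  img <- if (is.logical(x)) x * 1 else { assert_gray_image(x); x / 255 }
  r <- EBImage::filter2(img, log_kernel(sigma), boundary = "replicate")
  h <- nrow(r); w <- ncol(r)
  edge <- matrix(FALSE, h, w)
  shift <- function(m, dy, dx) {
    out <- matrix(NA_real_, h, w)
    out[max(1, 1 + dy):min(h, h + dy), max(1, 1 + dx):min(w, w + dx)] <-
      m[max(1, 1 - dy):min(h, h - dy), max(1, 1 - dx):min(w, w - dx)]
    out
  }
  for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    nb <- shift(r, d[1], d[2])
    hit <- !is.na(nb) & (r * nb < 0) & (abs(r) <= abs(nb)) &
      (abs(r) + abs(nb) > threshold)
    hit[is.na(hit)] <- FALSE
    edge <- edge | hit
  }
  edge
}
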
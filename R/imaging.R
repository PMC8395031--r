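## ADC map computation and ROI intensity normalisation / quantisation.

#' Compute an apparent diffusion coefficient (ADC) map from two b-values
#'
#' Applies the mono-exponential diffusion model pixel by pixel:
#' \deqn{ADC = (\ln SI_0 - \ln SI) / (b - b_0)}
#' where \eqn{SI_0} and \eqn{SI} are the signal intensities at the low and
#' high b-value. Non-positive intensities (possible after noise clipping)
#' are floored at the smallest positive value present in the corresponding
#' image before taking logarithms; the number of floored pixels is recorded
#' in the \code{"n_floored"} attribute.
#'
#' @param b0_image Matrix of signal intensities at the low b-value.
#' @param b800_image Matrix of signal intensities at the high b-value.
#' @param b_low Low b-value in s/mm^2 (default 0).
#' @param b_high High b-value in s/mm^2 (default 800).
#' @return Matrix of ADC values in mm^2/s, same shape as the inputs.
#' @examples
#' b0 <- matrix(1000, 4, 4)
#' adc <- compute_adc(b0, b0 * exp(-0.8), 0, 800)  # 0.001 mm^2/s everywhere
#' @export
compute_adc <- function(b0_image, b800_image, b_low = 0, b_high = 800) {
  assert_same_shape(b0_image, b800_image, "b0/b800 images")
  if (b_high <= b_low) stop_dwr("b_high must exceed b_low")
  floor_pos <- function(x) {
    bad <- x <= 0
    if (any(bad)) {
      pos <- x[!bad]
      if (!length(pos)) stop_dwr("image contains no positive intensities")
      x[bad] <- min(pos)
    }
    list(x = x, n = sum(bad))
  }
  f0 <- floor_pos(b0_image)
  f1 <- floor_pos(b800_image)
  adc <- (log(f0$x) - log(f1$x)) / (b_high - b_low)
  attr(adc, "n_floored") <- f0$n + f1$n
  adc
}

#' Normalise ROI intensities to mu +/- 3 sigma and quantise to 8 bits
#'
#' The mean \eqn{\mu} and standard deviation \eqn{\sigma} are computed over
#' the masked pixels only. Intensities are clipped to
#' \eqn{[\mu - 3\sigma, \mu + 3\sigma]} and mapped linearly onto that range.
#' The continuous normalised image (scaled to \code{[0, 255]}) feeds the
#' Laws/Gabor filters; the integer-quantised image (half-open equal-width
#' bins, right edge inclusive at level 255) feeds co-occurrence counting.
#'
#' @param image Real-valued matrix.
#' @param mask Logical/binary matrix selecting the ROI; must be nonempty.
#' @return List with elements \code{quantized} (integer matrix, levels
#'   0--255 inside the mask, \code{NA} outside), \code{normalized}
#'   (continuous matrix mapped by the same affine clip, defined everywhere
#'   so that filters see coherent neighbourhoods), and \code{params}
#'   (list \code{mu}, \code{sigma}, \code{n_levels}, \code{degenerate}).
#' @export
normalize_and_quantize <- function(image, mask) {
  m <- assert_mask(mask)
  assert_same_shape(image, mask, "image and mask")
  vals <- image[m]
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  n_levels <- 256L
  degenerate <- sigma == 0
  if (degenerate) {
    warn_dwr("zero-variance ROI: all masked pixels map to level 0")
    q <- matrix(NA_integer_, nrow(image), ncol(image))
    q[m] <- 0L
    norm <- matrix(0, nrow(image), ncol(image))
    return(list(quantized = q, normalized = norm,
                params = list(mu = mu, sigma = sigma,
                              n_levels = n_levels, degenerate = TRUE)))
  }
  lo <- mu - 3 * sigma
  hi <- mu + 3 * sigma
  clip <- function(x) pmin(pmax(x, lo), hi)
  norm <- matrix(255 * (clip(image) - lo) / (hi - lo),
                 nrow(image), ncol(image))
  ## half-open bins [lo + k*w, lo + (k+1)*w), right edge -> 255
  lev <- floor(256 * (clip(vals) - lo) / (hi - lo))
  lev[lev > 255L] <- 255L
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  q[m] <- as.integer(lev)
  list(quantized = q, normalized = norm,
       params = list(mu = mu, sigma = sigma,
                     n_levels = n_levels, degenerate = FALSE))
}
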
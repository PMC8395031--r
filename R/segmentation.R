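## Semi-automatic lesion segmentation: Otsu threshold inside a seed region,
## morphological opening with the 4x4 square element, largest 8-connected
## component; plus the 4-mm peritumoral ring and contour propagation.

#' Otsu threshold (maximum between-class variance)
#'
#' Builds a 256-bin histogram over the observed min--max of the values and
#' returns the bin-edge threshold maximising the between-class variance.
#' Ties are broken towards the lowest qualifying threshold.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Histogram resolution (default 256).
#' @return Scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || rng[1] == rng[2])
    stop_dwr("Otsu threshold undefined: all values identical")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)[-n_bins]
  mu0 <- cumsum(p * centers)[-n_bins]
  mu_t <- sum(p * centers)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)   # which.max returns the first (lowest) maximiser
  edges[k + 1L]
}

#' Segment the intratumoral region from a seed box
#'
#' Reproduces the five-step semi-automatic procedure: threshold the seed
#' region by maximum between-class variance, binarise, erode with a 4x4
#' square element, keep the largest 8-connected component, and dilate the
#' unique region with the same element.
#'
#' @param b800_image High-b-value image (lesions appear hyperintense).
#' @param seed_region Logical matrix: a rough region drawn around the lesion.
#' @param se_size Structuring-element side (default 4).
#' @return Logical lesion mask (single 8-connected component).
#' @export
segment_intratumoral <- function(b800_image, seed_region, se_size = 4L) {
  seed <- assert_mask(seed_region)
  assert_same_shape(b800_image, seed_region, "image and seed region")
  vals <- b800_image[seed]
  thr <- otsu_threshold(vals)
  fg <- seed & (b800_image > thr)
  if (!any(fg)) stop_dwr("no foreground pixels above the Otsu threshold")
  er <- binary_erode(fg, se_size)
  if (!any(er))
    stop_dwr("erosion emptied the candidate mask: lesion too small for a %dx%d element",
             se_size, se_size)
  core <- largest_component(er)
  out <- binary_dilate(core, se_size)
  largest_component(out)
}

#' Build the peritumoral ring around an intratumoral mask
#'
#' The ring extends a fixed physical distance (default 4 mm) outward from
#' the lesion boundary, using a Euclidean distance transform so that the
#' expansion is isotropic, then excludes the lesion itself and clips to an
#' optional breast mask.
#'
#' @param intratumoral Logical lesion mask (nonempty).
#' @param ring_width_mm Ring width in mm (default 4).
#' @param pixel_spacing_mm Physical size of one pixel in mm.
#' @param breast_mask Optional logical matrix bounding the breast region.
#' @return Logical ring mask.
#' @export
peritumoral_ring <- function(intratumoral, ring_width_mm = 4,
                             pixel_spacing_mm = 340 / 256,
                             breast_mask = NULL) {
  m <- assert_mask(intratumoral)
  if (pixel_spacing_mm <= 0) stop_dwr("pixel spacing must be positive")
  r_px <- round(ring_width_mm / pixel_spacing_mm)
  d <- distance_to_mask(m, r_px + 1)
  ring <- d > 0 & d <= r_px
  if (!is.null(breast_mask)) {
    assert_same_shape(m, breast_mask, "mask and breast mask")
    ring <- ring & (breast_mask != 0)
    if (!any(ring)) warn_dwr("breast-mask clipping left an empty peritumoral ring")
  }
  ring
}

#' Assemble an ROI set
#'
#' @param intratumoral Logical lesion mask (single 8-connected component).
#' @param peritumoral Logical ring mask (disjoint from the lesion).
#' @param breast_mask Optional logical breast mask.
#' @param ring_width_mm Ring width used, for provenance.
#' @return Object of class \code{roi_set}.
#' @export
roi_set <- function(intratumoral, peritumoral, breast_mask = NULL,
                    ring_width_mm = 4) {
  intr <- assert_mask(intratumoral)
  peri <- assert_mask(peritumoral, allow_empty = TRUE)
  assert_same_shape(intr, peri, "intratumoral and peritumoral masks")
  if (any(intr & peri))
    stop_dwr("intratumoral and peritumoral masks overlap")
  lab <- label_components(intr)
  if (attr(lab, "n") != 1L)
    stop_dwr("intratumoral mask must be a single 8-connected component")
  structure(list(intratumoral = intr, peritumoral = peri,
                 breast_mask = breast_mask, ring_width_mm = ring_width_mm),
            class = "roi_set")
}

#' Propagate ROI masks to every channel of an image stack
#'
#' The contours drawn on the b800 image are copied unchanged to the exact
#' same pixel locations of the b0 and ADC channels.
#'
#' @param roi An \code{roi_set}.
#' @param stack List with matrices \code{b0}, \code{b800}, \code{adc}.
#' @return Named list (b0, b800, adc) of identical \code{roi_set} objects.
#' @export
propagate_rois <- function(roi, stack) {
  stopifnot(inherits(roi, "roi_set"))
  for (ch in c("b0", "b800", "adc"))
    assert_same_shape(roi$intratumoral, stack[[ch]],
                      sprintf("mask and %s channel", ch))
  list(b0 = roi, b800 = roi, adc = roi)
}
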
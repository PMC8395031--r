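## Feature registry, whole-bank extraction per case, z-score normalisation.

CHANNELS <- c("b0", "b800", "adc")
REGIONS <- c("intra", "peri")
STATS5 <- c("mean", "median", "sd", "skewness", "kurtosis")

#' The canonical registry of all 2,504 feature names
#'
#' 14 shape features (intratumoral mask only) plus, for each of the 3
#' channels x 2 regions: 5 first-order, 45 GLCM, 125 Laws and 240 Gabor
#' features (415 each), for 14 + 6 x 415 = 2,504 globally unique names.
#' The column order of every feature table follows this registry.
#'
#' @return Character vector of 2,504 names, with a \code{"category"}
#'   attribute giving the per-name category
#'   (shape/firstorder/glcm/laws/gabor).
#' @export
feature_registry <- function() {
  shape_names <- paste0("shape_", names(shape_features(matrix(TRUE, 3, 3))))
  glcm_desc <- c("Energy", "Contrast", "Correlation", "Variance", "Entropy",
                 "Homogeneity", "InverseDifferenceMoment",
                 "InformationMeasureCorr1", "InformationMeasureCorr2")
  laws_desc <- names(laws_bank())
  gabor_desc <- names(gabor_bank())
  nm <- shape_names
  cat <- rep("shape", length(shape_names))
  for (ch in CHANNELS) for (rg in REGIONS) {
    base <- paste(ch, rg, sep = "_")
    add <- function(category, desc) {
      v <- as.vector(t(outer(desc, STATS5,
                             function(d, s) paste(base, category, d, s, sep = "_"))))
      nm <<- c(nm, v)
      cat <<- c(cat, rep(category, length(v)))
    }
    add("firstorder", "intensity")
    add("glcm", glcm_desc)
    add("laws", laws_desc)
    add("gabor", gabor_desc)
  }
  stopifnot(!anyDuplicated(nm))
  attr(nm, "category") <- cat
  nm
}

## window padding: Gabor kernels cap at half-width 12, plus the ring margin
FILTER_HALF <- 12L

#' Extract the full 2,504-feature vector for one case
#'
#' For each channel (b0, b800, ADC) and region (intratumoral, peritumoral):
#' normalises the ROI intensities to \eqn{\mu \pm 3\sigma}; first-order
#' statistics and Laws/Gabor filters operate on the continuous normalised
#' values, co-occurrence counting on the 8-bit quantised values. All
#' filtering happens on a lesion-centred window so that runtime scales with
#' lesion size, not grid size; only in-mask responses are pooled.
#'
#' @param stack List with matrices \code{b0}, \code{b800}, \code{adc} and
#'   scalar \code{pixel_spacing_mm}.
#' @param rois An \code{\link{roi_set}}.
#' @return Named numeric vector of length 2,504 in registry order.
#' @export
extract_features <- function(stack, rois) {
  stopifnot(inherits(rois, "roi_set"))
  intr <- rois$intratumoral
  peri <- rois$peritumoral
  spacing <- stack$pixel_spacing_mm %||% (340 / 256)
  out <- numeric(0)
  sf <- shape_features(intr, spacing)
  names(sf) <- paste0("shape_", names(sf))
  out <- c(out, sf)

  union_mask <- intr | peri
  bb <- expand_bbox(mask_bbox(union_mask), FILTER_HALF + 2L, dim(intr))
  ## reflect padding needs pad < window size
  if ((bb$r2 - bb$r1) < FILTER_HALF + 1L || (bb$c2 - bb$c1) < FILTER_HALF + 1L)
    bb <- expand_bbox(bb, FILTER_HALF + 2L, dim(intr))
  masks <- list(intra = crop_bbox(intr, bb), peri = crop_bbox(peri, bb))

  for (ch in CHANNELS) {
    img <- crop_bbox(stack[[ch]], bb)
    for (rg in REGIONS) {
      mk <- masks[[rg]]
      if (!any(mk))
        stop_dwr("empty %s mask for channel %s", rg, ch)
      base <- paste(ch, rg, sep = "_")
      nq <- normalize_and_quantize(img, mk)
      block <- tryCatch({
        fo <- pooled_statistics(nq$normalized[mk])
        names(fo) <- paste(base, "firstorder_intensity", names(fo), sep = "_")
        gl <- glcm_features(nq$quantized, mk)
        names(gl) <- paste(base, "glcm", names(gl), sep = "_")
        lw <- laws_features(nq$normalized, mk)
        names(lw) <- paste(base, names(lw), sep = "_")
        gb <- gabor_features(nq$normalized, mk)
        names(gb) <- paste(base, names(gb), sep = "_")
        c(fo, gl, lw, gb)
      }, error = function(e)
        stop_dwr("feature extraction failed for (%s, %s): %s",
                 ch, rg, conditionMessage(e)))
      out <- c(out, block)
    }
  }
  reg <- feature_registry()
  if (!identical(sort(names(out)), sort(as.vector(reg))))
    stop_dwr("extracted names do not match the registry")
  out <- out[as.vector(reg)]
  if (any(!is.finite(out)))
    stop_dwr("non-finite feature values: %s",
             paste(utils::head(names(out)[!is.finite(out)], 3), collapse = ", "))
  out
}

#' Fit z-score parameters on a training table and apply everywhere
#'
#' Per-column mean and standard deviation (population denominator) are
#' computed on the training table only and applied to every table, matching
#' the rule that normalisation parameters must never leak from validation
#' data. Zero-variance training columns pass through as 0 and are flagged.
#'
#' @param train Numeric matrix/data.frame of the training cohort
#'   (cases x features).
#' @param ... Further tables with identical columns (e.g. validation).
#' @return List with \code{tables} (list of transformed tables, training
#'   first), \code{z_params} (data.frame \code{feature}, \code{mean},
#'   \code{sd}) and \code{degenerate} (names of zero-variance columns).
#' @export
zscore_fit_apply <- function(train, ...) {
  train <- as.matrix(train)
  if (!nrow(train)) stop_dwr("empty training table")
  others <- lapply(list(...), as.matrix)
  for (o in others)
    if (!identical(colnames(o), colnames(train)))
      stop_dwr("column mismatch between tables")
  mu <- colMeans(train)
  sd_pop <- sqrt(colMeans(sweep(train, 2, mu)^2))
  degen <- colnames(train)[sd_pop == 0]
  scale_tab <- function(x) {
    z <- sweep(sweep(x, 2, mu), 2, ifelse(sd_pop == 0, 1, sd_pop), "/")
    z[, sd_pop == 0] <- 0
    z
  }
  list(tables = c(list(scale_tab(train)), lapply(others, scale_tab)),
       z_params = data.frame(feature = colnames(train), mean = mu,
                             sd = sd_pop, row.names = NULL),
       degenerate = degen)
}
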
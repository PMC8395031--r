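## First-order pooled statistics, GLCM descriptors, and Laws/Gabor pooling.

#' Pooled first-order statistics
#'
#' Population-style moments (denominator \eqn{n}): mean, median, standard
#' deviation, skewness \eqn{m_3/m_2^{3/2}} and (Pearson) kurtosis
#' \eqn{m_4/m_2^2}. For a zero-variance input, skewness and kurtosis are
#' defined as 0 and flagged via the \code{"degenerate"} attribute.
#'
#' @param values Nonempty numeric vector.
#' @return Named vector \code{(mean, median, sd, skewness, kurtosis)}.
#' @export
pooled_statistics <- function(values) {
  if (!length(values)) stop_dwr("pooled_statistics: empty input")
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  out <- c(mean = mu, median = stats::median(values), sd = sqrt(m2),
           skewness = 0, kurtosis = 0)
  if (m2 > 0) {
    out["skewness"] <- mean((values - mu)^3) / m2^1.5
    out["kurtosis"] <- mean((values - mu)^4) / m2^2
  } else attr(out, "degenerate") <- TRUE
  out
}

glcm_offsets <- function(directions = c(0, 45, 90, 135), distances = 1:5) {
  ## image-coordinate offsets (dr, dc); 0 deg = along a row (dc = +d)
  out <- list()
  for (d in distances) for (a in directions) {
    step <- switch(as.character(a),
                   "0" = c(0L, d), "45" = c(-d, d),
                   "90" = c(-d, 0L), "135" = c(-d, -d))
    out[[sprintf("d%d_a%d", d, a)]] <- as.integer(step)
  }
  out
}

## symmetric, normalised co-occurrence over in-mask pixel pairs, returned
## sparse: data.frame(i, j, p) over nonzero cells
glcm_matrix <- function(quantized, mask, offset, n_levels = 256L) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  dr <- offset[1]; dc <- offset[2]
  rlo <- max(1, 1 - dr); rhi <- min(nr, nr - dr)
  clo <- max(1, 1 - dc); chi <- min(nc, nc - dc)
  if (rlo > rhi || clo > chi) return(NULL)
  r1 <- rlo:rhi
  c1 <- clo:chi
  a_ok <- m[r1, c1, drop = FALSE] & m[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(a_ok)) return(NULL)
  gi <- quantized[r1, c1, drop = FALSE][a_ok]
  gj <- quantized[r1 + dr, c1 + dc, drop = FALSE][a_ok]
  code <- c(gi * n_levels + gj, gj * n_levels + gi)   # symmetric counting
  tab <- sort(unique(code))
  cnt <- tabulate(match(code, tab), nbins = length(tab))
  data.frame(i = tab %/% n_levels, j = tab %% n_levels,
             p = cnt / sum(cnt))
}

## 9 Haralick descriptors from a sparse symmetric GLCM
haralick_descriptors <- function(g) {
  p <- g$p; i <- g$i; j <- g$j
  mu <- sum(p * i)                       # symmetric: mu_x = mu_y
  sig2 <- sum(p * (i - mu)^2)
  sig <- sqrt(sig2)
  log2z <- function(x) {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- log2(x[pos])
    out
  }
  entropy <- -sum(p * log2z(p))
  ## marginals p_x over levels present (p_y identical by symmetry)
  lev <- sort(unique(c(i, j)))
  px <- vapply(split(c(p, p), factor(c(i, j), levels = lev)), sum, 0) / 2
  ## each cell contributes p to both the i- and j-marginal halves; the
  ## division by 2 restores sum(px) == 1
  hx <- -sum(px * log2z(px))
  pxv <- px[match(i, lev)]
  pyv <- px[match(j, lev)]
  hxy1 <- -sum(p * log2z(pxv * pyv))
  pp <- as.vector(outer(px, px))
  hxy2 <- -sum(pp * log2z(pp))
  denom <- hx   # max(HX, HY) with HX = HY by symmetry
  imc1 <- if (denom > 0) (entropy - hxy1) / denom else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  corr <- if (sig2 > 0) (sum(p * i * j) - mu^2) / sig2 else 0
  c(Energy = sum(p^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = corr,
    Variance = sig2,
    Entropy = entropy,
    Homogeneity = sum(p / (1 + abs(i - j))),
    InverseDifferenceMoment = sum(p / (1 + (i - j)^2)),
    InformationMeasureCorr1 = imc1,
    InformationMeasureCorr2 = imc2)
}

#' GLCM descriptor features pooled over a direction-distance ensemble
#'
#' Builds symmetric, normalised grey-level co-occurrence matrices restricted
#' to in-mask pixel pairs for each offset of the ensemble (by default 4
#' directions x 5 distances = 20 matrices), computes 9 Haralick descriptors
#' per matrix, and pools each descriptor over the ensemble with the five
#' first-order statistics, yielding 45 features.
#'
#' @param quantized Integer matrix of quantised levels (0--255; \code{NA}
#'   allowed outside the mask).
#' @param mask Logical ROI matrix.
#' @param offsets List of integer \code{c(dr, dc)} offsets (default the
#'   4-direction x 5-distance ensemble).
#' @return Named numeric vector of 45 values
#'   (\code{<Descriptor>_<statistic>}).
#' @export
glcm_features <- function(quantized, mask, offsets = glcm_offsets()) {
  m <- assert_mask(mask)
  per_offset <- lapply(offsets, function(off) {
    g <- glcm_matrix(quantized, m, off)
    if (is.null(g)) return(NULL)
    haralick_descriptors(g)
  })
  per_offset <- per_offset[!vapply(per_offset, is.null, TRUE)]
  if (!length(per_offset))
    stop_dwr("no valid in-mask pixel pairs for any co-occurrence offset")
  mat <- do.call(rbind, per_offset)
  out <- numeric(0)
  for (d in colnames(mat)) {
    st <- pooled_statistics(mat[, d])
    names(st) <- paste(d, names(st), sep = "_")
    out <- c(out, st)
  }
  out
}

## pool |response| values inside the mask with the five statistics
pool_responses <- function(responses, mask, prefix, magnitude = abs) {
  out <- numeric(0)
  mv <- which(mask)
  for (nm in names(responses)) {
    vals <- magnitude(responses[[nm]])[mv]
    st <- pooled_statistics(vals)
    names(st) <- paste(prefix, nm, names(st), sep = "_")
    out <- c(out, st)
  }
  out
}

#' Laws texture-energy features
#'
#' Convolves the (continuous, normalised) image window with the 25 Laws
#' filters and pools the absolute in-mask responses with the five
#' first-order statistics: 125 features.
#'
#' @param window Real-valued matrix.
#' @param mask Logical matrix, same shape as \code{window}.
#' @param bank Filter bank from \code{\link{laws_bank}}.
#' @return Named numeric vector of length 125 (\code{<Filter>_<statistic>}).
#' @export
laws_features <- function(window, mask, bank = default_laws_bank()) {
  m <- assert_mask(mask)
  assert_same_shape(window, mask, "window and mask")
  if (min(dim(window)) < 5)
    stop_dwr("window smaller than the 5x5 Laws filter support")
  resp <- convolve_bank(window, bank, cache_key = "laws")
  pool_responses(resp, m, "laws", magnitude = function(x) abs(Re(x)))
}

#' Gabor texture features
#'
#' Convolves the window with the 48 complex Gabor kernels and pools the
#' in-mask response magnitudes with the five statistics: 240 features.
#'
#' @inheritParams laws_features
#' @param bank Filter bank from \code{\link{gabor_bank}}.
#' @return Named numeric vector of length 240
#'   (\code{f<freq>_t<angle>_<statistic>}).
#' @export
gabor_features <- function(window, mask, bank = default_gabor_bank()) {
  m <- assert_mask(mask)
  assert_same_shape(window, mask, "window and mask")
  resp <- convolve_bank(window, bank, cache_key = "gabor")
  pool_responses(resp, m, "gabor", magnitude = Mod)
}
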
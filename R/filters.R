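## Laws and Gabor filter banks and the convolution engine.
##
## Convolution is computed on a lesion-centred window (bounding box of the
## pooled masks plus the kernel half-width) with reflect padding, via FFT.
## Only in-mask response pixels are ever pooled, so padding can influence at
## most a border of kernel-half-width pixels.

#' The 25-filter Laws texture bank
#'
#' Outer products of the five classic 1D kernels: level
#' \code{L5 = (1 4 6 4 1)}, edge \code{E5 = (-1 -2 0 2 1)}, spot
#' \code{S5 = (-1 0 2 0 -1)}, wave \code{W5 = (-1 2 0 -2 1)} and ripple
#' \code{R5 = (1 -4 6 -4 1)}. Filter \code{XaYb} applies kernel a along
#' rows (y) and kernel b along columns (x).
#'
#' @return Named list of 25 5x5 matrices (L5L5, L5E5, ..., R5R5).
#' @export
laws_bank <- function() {
  k1 <- list(L5 = c(1, 4, 6, 4, 1),
             E5 = c(-1, -2, 0, 2, 1),
             S5 = c(-1, 0, 2, 0, -1),
             W5 = c(-1, 2, 0, -2, 1),
             R5 = c(1, -4, 6, -4, 1))
  out <- list()
  for (a in names(k1)) for (b in names(k1))
    out[[paste0(a, b)]] <- outer(k1[[a]], k1[[b]])
  out
}

#' The 48-kernel Gabor filter bank
#'
#' Complex Gabor kernels at six spatial frequencies, expressed in cycles per
#' image width on the acquisition's 256-pixel grid
#' (\code{f = 0, 2, 4, 8, 16, 32}), and eight orientations
#' (0, 22.5, 45, 67.5, 90, 112.5, 135, 167.5 degrees). The envelope width
#' follows a one-octave bandwidth, capped at \code{sigma_max} pixels so that
#' low-frequency kernels keep a local support; at \code{f = 0} the kernel
#' degenerates to a Gaussian smoother with \code{sigma_max} envelope.
#'
#' @param frequencies Cycles per image width (default the six listed).
#' @param orientations_deg Orientations in degrees (default the eight
#'   listed; set \code{uniform = TRUE} to replace 167.5 by the uniform-grid
#'   157.5).
#' @param grid_size Reference grid width in pixels (default 256).
#' @param sigma_max Cap on the Gaussian envelope sigma, pixels (default 6).
#' @param uniform Use the uniform orientation grid instead (default FALSE).
#' @return Named list of complex matrices, names \code{f<freq>_t<angle>}.
#' @export
gabor_bank <- function(frequencies = c(0, 2, 4, 8, 16, 32),
                       orientations_deg = c(0, 22.5, 45, 67.5, 90,
                                            112.5, 135, 167.5),
                       grid_size = 256L, sigma_max = 6, uniform = FALSE) {
  if (uniform) orientations_deg[orientations_deg == 167.5] <- 157.5
  ## one-octave bandwidth: sigma = lambda/pi * sqrt(ln2/2) * (2^b+1)/(2^b-1)
  sigma_of <- function(f_pix) {
    if (f_pix <= 0) return(sigma_max)
    min(sigma_max, (1 / f_pix) / pi * sqrt(log(2) / 2) * 3)
  }
  out <- list()
  for (f in frequencies) {
    f_pix <- f / grid_size
    sigma <- sigma_of(f_pix)
    half <- max(2L, min(12L, ceiling(2.5 * sigma)))
    g <- seq(-half, half)
    for (th in orientations_deg) {
      a <- th * pi / 180
      xr <- outer(g, g, function(y, x) x * cos(a) + y * sin(a))
      env <- outer(g, g, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
      k <- env * exp(2i * pi * f_pix * xr)
      k <- k / sum(Mod(k))   # unit L1 mass: constant image -> |response| <= const
      nm <- sprintf("f%s_t%s", f, gsub("\\.", "p", format(th)))
      out[[nm]] <- k
    }
  }
  out
}

## reflect-pad a matrix by `pad` pixels on every side
reflect_pad <- function(x, pad) {
  if (pad == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (pad >= nr || pad >= nc) stop_dwr("reflect pad exceeds image size")
  ri <- c(rev(seq_len(pad) + 1L), seq_len(nr), nr - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(nc), nc - seq_len(pad))
  x[ri, ci]
}

## FFT of a kernel zero-padded/centred for a P1 x P2 circular convolution
kernel_fft <- function(kernel, P1, P2) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  big <- matrix(0, P1, P2)
  rows <- ((seq(-kh, kh) + P1) %% P1) + 1L
  cols <- ((seq(-kh, kh) + P2) %% P2) + 1L
  big[rows, cols] <- kernel
  stats::fft(big)
}

## environment-level cache of kernel FFTs keyed by (bank id, padded dims)
.fft_cache <- new.env(parent = emptyenv())

## memoised default banks (their construction is deterministic)
default_laws_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- laws_bank()
    bank
  }
})

default_gabor_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- gabor_bank()
    bank
  }
})

bank_ffts <- function(kernels, P1, P2, key) {
  tag <- paste0(key, "_", P1, "x", P2)
  if (!is.null(.fft_cache[[tag]])) return(.fft_cache[[tag]])
  out <- lapply(kernels, kernel_fft, P1 = P1, P2 = P2)
  .fft_cache[[tag]] <- out
  out
}

#' Convolve an image window with a filter bank (reflect padding)
#'
#' @param window Real-valued matrix (the lesion-centred crop).
#' @param kernels Named list of (possibly complex) kernel matrices, all of
#'   the same odd size; typically \code{laws_bank()} or \code{gabor_bank()}.
#' @param cache_key Optional string identifying the bank, enabling reuse of
#'   kernel FFTs across calls.
#' @return Named list of response matrices (complex if the kernels are),
#'   same shape as \code{window}.
#' @export
convolve_bank <- function(window, kernels, cache_key = NULL) {
  half <- max(vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, 1L))
  padded <- reflect_pad(window, half)
  P1 <- nrow(padded); P2 <- ncol(padded)
  Fimg <- stats::fft(padded)
  kf <- if (is.null(cache_key)) lapply(kernels, kernel_fft, P1 = P1, P2 = P2)
        else bank_ffts(kernels, P1, P2, cache_key)
  nr <- nrow(window); nc <- ncol(window)
  core <- half + 1L
  lapply(kf, function(K) {
    resp <- stats::fft(Fimg * K, inverse = TRUE) / (P1 * P2)
    resp[core:(core + nr - 1L), core:(core + nc - 1L)]
  })
}

#' Naive sliding-window convolution (reference implementation)
#'
#' Direct dot-product evaluation with reflect padding; used as an
#' independent check of the FFT path on small inputs.
#'
#' @inheritParams convolve_bank
#' @param kernel A single kernel matrix of odd size.
#' @return Response matrix the same shape as \code{window}.
#' @export
convolve_naive <- function(window, kernel) {
  half <- (nrow(kernel) - 1L) %/% 2L
  padded <- reflect_pad(window, half)
  nr <- nrow(window); nc <- ncol(window)
  out <- matrix(if (is.complex(kernel)) 0i else 0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    patch <- padded[r:(r + 2L * half), cc:(cc + 2L * half)]
    ## correlation with the flipped kernel == convolution
    out[r, cc] <- sum(patch * kernel[(2L * half + 1L):1, (2L * half + 1L):1])
  }
  out
}
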
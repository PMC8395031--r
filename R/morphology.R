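## Binary morphology on 2D masks.
##
## The 4x4 square structuring element used by the segmentation pipeline is
## even-sized, so its origin is ambiguous; we pin it at the top-left pixel of
## the central 2x2 block, i.e. offsets -1..+2 in both rows and columns.
## Erosion/dilation are implemented as vectorised shifts, which keeps the
## convention explicit and exact.

se_offsets <- function(size = 4L) {
  ## offsets of an even `size` x `size` square with origin at the top-left
  ## of the central 2x2 (size 4 -> -1:2); odd sizes are centred
  if (size %% 2 == 0) off <- seq.int(-(size %/% 2 - 1L), size %/% 2)
  else off <- seq.int(-(size %/% 2), size %/% 2)
  as.matrix(expand.grid(dr = off, dc = off))
}

shift_mask <- function(mask, dr, dc, fill = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- mask[rs - dr, cs - dc]
  out
}

#' Binary erosion with a square structuring element
#'
#' @param mask Logical matrix.
#' @param size Side of the square element (default 4; even sizes use the
#'   pinned top-left-of-centre origin).
#' @return Logical matrix.
#' @export
binary_erode <- function(mask, size = 4L) {
  m <- mask != 0
  off <- se_offsets(size)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(m, -off[i, 1], -off[i, 2], fill = FALSE)
  out
}

#' Binary dilation with a square structuring element
#'
#' @inheritParams binary_erode
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask, size = 4L) {
  m <- mask != 0
  off <- se_offsets(size)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(m, off[i, 1], off[i, 2], fill = FALSE)
  out
}

#' Label 8-connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background), with the
#'   number of components in attribute \code{"n"}.
#' @export
label_components <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(m)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (m[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  attr(lab, "n") <- cur
  lab
}

#' Keep the largest 8-connected component
#'
#' @param mask Logical matrix (nonempty).
#' @return Logical matrix containing only the largest component (ties broken
#'   by the component containing the smallest linear pixel index).
#' @export
largest_component <- function(mask) {
  m <- assert_mask(mask)
  lab <- label_components(m)
  n <- attr(lab, "n")
  if (n == 1L) return(m)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes == max(sizes))[1]
  lab == keep
}

#' Euclidean distance from each pixel to a mask
#'
#' Brute-force exact distance transform over a bounded neighbourhood,
#' adequate for the small lesion windows this package works with.
#'
#' @param mask Logical matrix (nonempty).
#' @param max_dist Distances are only resolved up to this value (pixels);
#'   farther pixels get \code{Inf}.
#' @return Numeric matrix of distances in pixel units (0 inside the mask).
#' @export
distance_to_mask <- function(mask, max_dist) {
  m <- assert_mask(mask)
  out <- matrix(Inf, nrow(m), ncol(m))
  out[m] <- 0
  bb <- expand_bbox(mask_bbox(m), ceiling(max_dist) + 1L, dim(m))
  ## only source pixels on the mask boundary matter
  interior <- m & shift_mask(m, 1, 0) & shift_mask(m, -1, 0) &
    shift_mask(m, 0, 1) & shift_mask(m, 0, -1)
  src <- which(m & !interior, arr.ind = TRUE)
  if (!nrow(src)) src <- which(m, arr.ind = TRUE)
  cand <- expand.grid(r = bb$r1:bb$r2, c = bb$c1:bb$c2)
  cand <- cand[!m[cbind(cand$r, cand$c)], , drop = FALSE]
  if (!nrow(cand)) return(out)
  ## squared distance from every candidate to every boundary pixel
  d2 <- outer(cand$r, src[, 1], "-")^2 + outer(cand$c, src[, 2], "-")^2
  out[cbind(cand$r, cand$c)] <- sqrt(do.call(pmin, as.data.frame(d2)))
  out
}

## distance from inside pixels to the background (lesion inradius field)
inner_distance <- function(mask, max_dist) {
  m <- assert_mask(mask)
  out <- matrix(0, nrow(m), ncol(m))
  bg <- !m
  ## background pixels adjacent to the mask bbox are the only relevant sources
  bb <- expand_bbox(mask_bbox(m), ceiling(max_dist) + 1L, dim(m))
  src <- which(bg, arr.ind = TRUE)
  src <- src[src[, 1] >= bb$r1 & src[, 1] <= bb$r2 &
             src[, 2] >= bb$c1 & src[, 2] <= bb$c2, , drop = FALSE]
  cand <- which(m, arr.ind = TRUE)
  if (!nrow(src)) { out[m] <- Inf; return(out) }
  d2 <- outer(cand[, 1], src[, 1], "-")^2 + outer(cand[, 2], src[, 2], "-")^2
  out[cand] <- sqrt(do.call(pmin, as.data.frame(d2)))
  out
}
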
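## 14 shape descriptors of the intratumoral mask, in physical units.

## Moore boundary tracing: ordered 8-connected boundary pixel coordinates.
trace_boundary <- function(mask) {
  m <- mask != 0
  idx <- which(m, arr.ind = TRUE)
  ## start: topmost of the leftmost column
  start <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE][1, ]
  ## neighbour ring in clockwise order starting from W
  ring <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE)  # (dr, dc): W, NW, N, NE, E, SE, S, SW
  inside <- function(r, c) r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && m[r, c]
  path <- matrix(start, ncol = 2)
  cur <- start
  backtrack <- 1L   # came from W
  repeat {
    found <- FALSE
    for (k in 0:7) {
      j <- ((backtrack - 1L + k) %% 8L) + 1L
      r2 <- cur[1] + ring[j, 1]; c2 <- cur[2] + ring[j, 2]
      if (inside(r2, c2)) {
        ## next backtrack: the position preceding j in the ring
        backtrack <- ((j - 2L + 7L) %% 8L) + 1L
        cur <- c(r2, c2)
        found <- TRUE
        break
      }
    }
    if (!found) break   # isolated pixel
    if (all(cur == start) && nrow(path) > 1) break
    path <- rbind(path, cur)
    if (nrow(path) > 4L * sum(m)) break   # safety
  }
  unname(path)
}

## chain-code perimeter: axial steps count 1, diagonal steps sqrt(2)
chain_perimeter <- function(boundary) {
  if (nrow(boundary) < 2) return(4)   # lone pixel: its square outline
  closed <- rbind(boundary, boundary[1, ])
  d <- abs(diff(closed))
  sum(ifelse(rowSums(d) == 2, sqrt(2), 1))
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Fourteen 2D shape features of a lesion mask
#'
#' Computes, in physical units derived from \code{pixel_spacing_mm}:
#' area, perimeter (boundary chain length), sphericity
#' \eqn{2\sqrt{\pi A}/P}, elongation (minor/major axis ratio), extent
#' (area / bounding-box area), circularity \eqn{4\pi A/P^2}, solidity
#' (area / convex-hull area over pixel corners), eccentricity of the
#' second-moment ellipse, equivalent diameter \eqn{2\sqrt{A/\pi}}, major and
#' minor axis lengths, perimeter-to-area ratio, maximum 2D diameter
#' (largest pairwise boundary distance) and spherical disproportion
#' \eqn{P/(2\sqrt{\pi A})} (the reciprocal of sphericity).
#'
#' @param mask Logical matrix: nonempty, single 8-connected component.
#' @param pixel_spacing_mm Pixel size in mm.
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(mask, pixel_spacing_mm = 340 / 256) {
  m <- assert_mask(mask)
  lab <- label_components(m)
  if (attr(lab, "n") != 1L)
    stop_dwr("shape features require a single connected component")
  s <- pixel_spacing_mm
  n_px <- sum(m)
  A <- n_px * s^2
  bnd <- trace_boundary(m)
  P <- chain_perimeter(bnd) * s

  idx <- which(m, arr.ind = TRUE)
  r <- idx[, 1]; cc <- idx[, 2]
  ## bounding box over pixel squares
  box_A <- (diff(range(r)) + 1) * (diff(range(cc)) + 1) * s^2
  ## convex hull over the 4 corners of each boundary pixel square
  corners <- rbind(cbind(bnd[, 1] - 0.5, bnd[, 2] - 0.5),
                   cbind(bnd[, 1] - 0.5, bnd[, 2] + 0.5),
                   cbind(bnd[, 1] + 0.5, bnd[, 2] - 0.5),
                   cbind(bnd[, 1] + 0.5, bnd[, 2] + 0.5))
  h <- grDevices::chull(corners)
  hull_A <- polygon_area(corners[h, , drop = FALSE]) * s^2

  ## second central moments of pixel centres
  mu_r <- mean(r); mu_c <- mean(cc)
  ## + 1/12: variance of a unit pixel square, so a lone pixel has finite axes
  m20 <- mean((r - mu_r)^2) + 1 / 12
  m02 <- mean((cc - mu_c)^2) + 1 / 12
  m11 <- mean((r - mu_r) * (cc - mu_c))
  tr2 <- (m20 + m02) / 2
  det_rt <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  l1 <- tr2 + det_rt
  l2 <- max(tr2 - det_rt, 0)
  major <- 4 * sqrt(l1) * s
  minor <- 4 * sqrt(l2) * s

  dmax <- if (nrow(bnd) > 1) max(stats::dist(bnd)) * s else s

  sph <- 2 * sqrt(pi * A) / P
  c(Area = A,
    Perimeter = P,
    Sphericity = sph,
    Elongation = minor / major,
    Extent = A / box_A,
    Circularity = 4 * pi * A / P^2,
    Solidity = A / hull_A,
    Eccentricity = sqrt(1 - l2 / l1),
    EquivalentDiameter = 2 * sqrt(A / pi),
    MajorAxisLength = major,
    MinorAxisLength = minor,
    PerimeterAreaRatio = P / A,
    Maximum2DDiameter = dmax,
    SphericalDisproportion = 1 / sph)
}
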
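# Programmatic fixtures shared across test files.

# digital disk mask on an n x n grid
disk_mask <- function(radius, n = 2L * radius + 11L,
                      center = c((n + 1) / 2, (n + 1) / 2)) {
  r <- outer(seq_len(n) - center[1], rep(1, n))
  c2 <- outer(rep(1, n), seq_len(n) - center[2])
  r^2 + c2^2 <= radius^2
}

rect_mask <- function(nr, nc, r0, c0, h, w) {
  m <- matrix(FALSE, nr, nc)
  m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
  m
}

# small image stack with a bright disk lesion, for segmentation/feature tests
toy_stack <- function(n = 64L, radius = 12L, contrast = 120, noise = 4,
                      seed = 1L, spacing = 1) {
  set.seed(seed)
  mask <- disk_mask(radius, n)
  b800 <- matrix(100, n, n) + contrast * mask +
    matrix(rnorm(n * n, 0, noise), n, n)
  adc <- matrix(1.8e-3, n, n); adc[mask] <- 1.0e-3
  b0 <- b800 * exp(800 * adc)
  list(b0 = b0, b800 = b800, adc = compute_adc(b0, b800),
       pixel_spacing_mm = spacing, mask = mask)
}

# synthetic feature table with `n_inf` informative columns (mean shift)
synth_feature_table <- function(n = 100L, p = 50L, n_inf = 5L,
                                shift = 1.5, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  if (n_inf > 0)
    x[, seq_len(n_inf)] <- x[, seq_len(n_inf)] + shift * y
  list(x = x, y = y)
}

small_config <- function(...) {
  phantom_config(n_cases = 12L, grid_size = 128L, seed = 11L, ...)
}
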
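test_that("the registry holds exactly 2504 unique names with the Table-1 partition", {
  reg <- feature_registry()
  expect_length(reg, 2504)
  expect_equal(anyDuplicated(reg), 0L)
  cat_tab <- table(attr(reg, "category"))
  expect_equal(as.integer(cat_tab[c("shape", "firstorder", "glcm",
                                    "laws", "gabor")]),
               c(14L, 30L, 270L, 750L, 1440L))
})

test_that("pooled statistics match a naive scalar-loop oracle", {
  expect_equal(pooled_statistics(c(1, 2, 3))[c("mean", "median")],
               c(mean = 2, median = 2))
  st <- pooled_statistics(rep(4, 10))
  expect_equal(unname(st[c("sd", "skewness", "kurtosis")]), c(0, 0, 0))
  set.seed(10)
  v <- rnorm(50)
  st <- pooled_statistics(v)
  n <- length(v)
  m <- 0; for (x in v) m <- m + x / n
  m2 <- 0; m3 <- 0; m4 <- 0
  for (x in v) { m2 <- m2 + (x - m)^2 / n
                 m3 <- m3 + (x - m)^3 / n
                 m4 <- m4 + (x - m)^4 / n }
  expect_equal(unname(st), c(m, median(v), sqrt(m2), m3 / m2^1.5, m4 / m2^2),
               tolerance = 1e-12)
  expect_error(pooled_statistics(numeric(0)), "empty")
})

test_that("shape features honour pixel scaling and the disk/rectangle limits", {
  sp <- 340 / 256
  m <- rect_mask(30, 30, 5, 5, 10, 10)
  sf <- shape_features(m, sp)
  expect_equal(sf[["Area"]], 100 * sp^2)
  expect_equal(sf[["Extent"]], 1)
  expect_equal(sf[["Solidity"]], 1, tolerance = 1e-9)
  d <- shape_features(disk_mask(40, 91), 1)
  expect_gt(d[["Circularity"]], 0.9)
  expect_lt(d[["Circularity"]], 1.1)
  expect_equal(d[["SphericalDisproportion"]] * d[["Sphericity"]], 1,
               tolerance = 1e-9)
  expect_equal(d[["EquivalentDiameter"]], 2 * sqrt(d[["Area"]] / pi))
  expect_lt(abs(d[["Maximum2DDiameter"]] - 80) / 80, 0.05)
  expect_error(shape_features(matrix(FALSE, 3, 3)), "empty")
})

test_that("GLCM descriptors on degenerate and hand-enumerable images", {
  # constant image: a single co-occurrence cell
  q <- matrix(5L, 8, 8)
  f <- glcm_features(q, matrix(TRUE, 8, 8),
                     offsets = list(c(0L, 1L)))
  expect_equal(f[["Energy_mean"]], 1)
  expect_equal(f[["Contrast_mean"]], 0)
  expect_equal(f[["Entropy_mean"]], 0)
  # two-level checkerboard: every horizontal pair differs by one level
  q <- outer(1:8, 1:8, function(r, c) as.integer((r + c) %% 2))
  f <- glcm_features(q, matrix(TRUE, 8, 8), offsets = list(c(0L, 1L)))
  expect_equal(f[["Contrast_mean"]], 1)
})

test_that("GLCM matches a brute-force nested-loop co-occurrence oracle", {
  set.seed(5)
  q <- matrix(sample(0:7, 256, replace = TRUE), 16, 16)
  mask <- matrix(TRUE, 16, 16)
  off <- c(1L, -1L)
  f <- glcm_features(q, mask, offsets = list(off))
  # oracle: count symmetric pairs cell by cell
  counts <- matrix(0, 8, 8)
  for (r in 1:16) for (cc in 1:16) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= 16 && c2 >= 1 && c2 <= 16) {
      counts[q[r, cc] + 1, q[r2, c2] + 1] <-
        counts[q[r, cc] + 1, q[r2, c2] + 1] + 1
      counts[q[r2, c2] + 1, q[r, cc] + 1] <-
        counts[q[r2, c2] + 1, q[r, cc] + 1] + 1
    }
  }
  p <- counts / sum(counts)
  ii <- row(p) - 1; jj <- col(p) - 1
  expect_equal(f[["Energy_mean"]], sum(p^2), tolerance = 1e-12)
  expect_equal(f[["Contrast_mean"]], sum(p * (ii - jj)^2), tolerance = 1e-12)
  expect_equal(f[["Entropy_mean"]], -sum(p[p > 0] * log2(p[p > 0])),
               tolerance = 1e-12)
  expect_equal(f[["Homogeneity_mean"]], sum(p / (1 + abs(ii - jj))),
               tolerance = 1e-12)
  px <- rowSums(p)
  mu <- sum(px * 0:7); sig2 <- sum(px * (0:7 - mu)^2)
  expect_equal(f[["Variance_mean"]], sig2, tolerance = 1e-12)
  expect_equal(f[["Correlation_mean"]],
               (sum(p * outer(0:7, 0:7)) - mu^2) / sig2, tolerance = 1e-12)
})

test_that("GLCM matrices are valid distributions restricted to the mask", {
  set.seed(6)
  q <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  mask <- disk_mask(7, 20)
  g <- dwiradiomics:::glcm_matrix(q, mask, c(0L, 2L))
  expect_true(all(g$p >= 0))
  expect_equal(sum(g$p), 1, tolerance = 1e-12)
  expect_error(glcm_features(q, mask, offsets = list(c(0L, 50L))),
               "no valid")
})

test_that("Laws bank structure: 25 filters, L5L5 mass 256, zero-sum kernels", {
  bank <- laws_bank()
  expect_length(bank, 25)
  expect_equal(sum(bank[["L5L5"]]), 256)
  zero_sum <- setdiff(names(bank), "L5L5")
  expect_true(all(abs(vapply(bank[zero_sum], sum, 0)) < 1e-12))
  # zero-sum kernels annihilate constant images
  const <- matrix(7, 20, 20)
  f <- laws_features(const, disk_mask(6, 20))
  zs_means <- f[paste0("laws_", zero_sum, "_mean")]
  expect_true(all(abs(zs_means) < 1e-9))
})

test_that("FFT Laws convolution equals the naive sliding-window oracle", {
  set.seed(11)
  img <- matrix(rnorm(32 * 32), 32, 32)
  bank <- laws_bank()
  resp <- convolve_bank(img, bank["E5S5"])
  expect_equal(Re(resp[["E5S5"]]), convolve_naive(img, bank[["E5S5"]]),
               tolerance = 1e-9)
  # and the pooled feature agrees with pooling the naive responses
  mask <- disk_mask(10, 32)
  f <- laws_features(img, mask)
  naive <- abs(convolve_naive(img, bank[["E5S5"]]))[mask]
  expect_equal(f[["laws_E5S5_mean"]], mean(naive), tolerance = 1e-9)
})

test_that("Gabor bank: 48 kernels, DC kernel orientation-invariant, matched grating", {
  bank <- gabor_bank()
  expect_length(bank, 48)
  expect_length(gabor_features(matrix(1, 30, 30), disk_mask(9, 30)), 240)
  # f = 0 degenerates to a Gaussian: constant image passes through with
  # identical response whatever the orientation
  const <- matrix(3, 30, 30)
  f <- gabor_features(const, disk_mask(9, 30))
  f0 <- f[grep("^gabor_f0_.*_mean$", names(f))]
  expect_equal(unname(f0), rep(3, 8), tolerance = 1e-9)
  # a pure grating at f = 8 cycles/width (256 grid), 45 degrees: the
  # matched kernel responds most strongly among all orientations at f = 8
  n <- 64
  xy <- outer(1:n, 1:n, function(r, c) (c * cos(pi / 4) + r * sin(pi / 4)))
  img <- sin(2 * pi * (8 / 256) * xy)
  f <- gabor_features(img, disk_mask(20, n))
  m8 <- f[grep("^gabor_f8_.*_mean$", names(f))]
  expect_equal(names(which.max(m8)), "gabor_f8_t45_mean")
})

test_that("extraction yields 2504 finite features with the documented sub-blocks", {
  st <- toy_stack(n = 72, radius = 13, seed = 3)
  ring <- peritumoral_ring(st$mask, 4, 1)
  fv <- extract_features(st, roi_set(st$mask, ring))
  expect_length(fv, 2504)
  expect_true(all(is.finite(fv)))
  expect_length(grep("^shape_", names(fv)), 14)
  expect_length(grep("^b800_intra_", names(fv)), 415)
  expect_length(grep("_peri_", names(fv)), 3 * 415)
})

test_that("non-shape features are invariant to whole-pixel translation", {
  st <- toy_stack(n = 72, radius = 11, seed = 9)
  ring <- peritumoral_ring(st$mask, 4, 1)
  fv <- extract_features(st, roi_set(st$mask, ring))
  sh <- function(m, k) rbind(m[(nrow(m) - k + 1):nrow(m), ],
                             m[1:(nrow(m) - k), ])
  st2 <- st
  for (ch in c("b0", "b800", "adc")) st2[[ch]] <- sh(st2[[ch]], 5)
  mask2 <- sh(st$mask, 5) != 0
  ring2 <- sh(ring, 5) != 0
  fv2 <- extract_features(st2, roi_set(mask2, ring2))
  nonshape <- grep("^shape_", names(fv), invert = TRUE)
  expect_equal(fv[nonshape], fv2[nonshape], tolerance = 1e-9)
})

test_that("z-scoring fits on training only and handles degenerate columns", {
  x <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  v <- matrix(c(4, 0, 5, 5), 2, 2, dimnames = list(NULL, c("a", "b")))
  z <- zscore_fit_apply(x, v)
  expect_equal(z$tables[[1]][, "a"], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_equal(mean(z$tables[[1]][, "a"]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z$tables[[1]][, "a"]^2)), 1, tolerance = 1e-9)
  expect_equal(z$degenerate, "b")
  expect_true(all(z$tables[[1]][, "b"] == 0))
  expect_true(all(z$tables[[2]][, "b"] == 0))
  # validation is transformed with the training parameters
  expect_equal(unname(z$tables[[2]][1, "a"]), (4 - 2) / sqrt(2 / 3),
               tolerance = 1e-9)
  expect_error(zscore_fit_apply(x, v[, c("b", "a")]), "mismatch")
})
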
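## Synthetic phantom cohort: mass-like lesions on a 256x256 DWI grid with a
## class-dependent band-pass texture effect, Rician-like noise, and clinical
## covariates drawn from class-conditional marginals.

#' Phantom cohort configuration
#'
#' Defaults emulate the clinical acquisition: a 256-pixel grid at
#' 340/256 mm spacing, lesion areas within 195--1512 mm^2 (log-normal
#' around the 352 mm^2 median), a 3:1 training:validation split, and a
#' positive-class prevalence of 97/223. The class signal is planted in the
#' spectral energy of a band-limited texture field inside the lesion
#' (and, at half strength, in the peritumoral ring) so that texture
#' features rather than size or mean intensity carry the discrimination.
#'
#' @param n_cases Number of phantom cases.
#' @param positive_fraction Proportion of positive labels in (0, 1).
#' @param train_fraction Proportion assigned to the training cohort.
#' @param grid_size Image side in pixels.
#' @param pixel_spacing_mm Pixel size in mm.
#' @param lesion_area_range_mm2 Closed interval for lesion areas.
#' @param texture_effect Nonnegative scalar: relative increase of the
#'   positive class's band-pass texture amplitude (0 = no class signal).
#' @param texture_amplitude Baseline texture amplitude, intensity units.
#' @param peri_effect_ratio Fraction of \code{texture_effect} planted in
#'   the peritumoral ring (default 0.5).
#' @param contrast Mean b800 lesion-over-background contrast, intensity
#'   units.
#' @param background_b800 Background b800 signal level.
#' @param adc_background,adc_lesion ADC levels (mm^2/s) outside/inside the
#'   lesion; the lesion value must be lower.
#' @param noise_sigma Gaussian noise SD per channel (clipped at zero, a
#'   Rician approximation).
#' @param rician Use exact Rician magnitude noise instead of the clipped
#'   Gaussian approximation.
#' @param clinical_rates Class-conditional probabilities for the four
#'   covariates; see \code{\link{default_clinical_rates}}.
#' @param ring_width_mm Peritumoral ring width.
#' @param b_low,b_high Diffusion b-values in s/mm^2.
#' @param seed Integer master seed.
#' @return Object of class \code{phantom_config}.
#' @export
phantom_config <- function(n_cases = 223L,
                           positive_fraction = 97 / 223,
                           train_fraction = 167 / 223,
                           grid_size = 256L,
                           pixel_spacing_mm = 340 / 256,
                           lesion_area_range_mm2 = c(195, 1512),
                           texture_effect = 0.35,
                           texture_amplitude = 12,
                           peri_effect_ratio = 0.5,
                           contrast = 130,
                           background_b800 = 120,
                           adc_background = 1.8e-3,
                           adc_lesion = 1.1e-3,
                           noise_sigma = 8,
                           rician = FALSE,
                           clinical_rates = default_clinical_rates(),
                           ring_width_mm = 4,
                           b_low = 0, b_high = 800,
                           seed = 1L) {
  if (n_cases < 1) stop_dwr("n_cases must be a positive integer")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop_dwr("positive_fraction must lie strictly in (0, 1)")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_dwr("train_fraction must lie strictly in (0, 1)")
  if (lesion_area_range_mm2[1] > lesion_area_range_mm2[2] ||
      lesion_area_range_mm2[1] <= 0)
    stop_dwr("invalid lesion area range")
  if (texture_effect < 0 || noise_sigma < 0)
    stop_dwr("texture_effect and noise_sigma must be nonnegative")
  check_rates(clinical_rates)
  ## max lesion radius + ring + filter margin must fit on the grid
  r_max <- sqrt(lesion_area_range_mm2[2] / pi) / pixel_spacing_mm
  need <- 2 * (1.1 * r_max + ring_width_mm / pixel_spacing_mm + 6)
  if (grid_size < need)
    stop_dwr("grid of %d px cannot contain the largest lesion plus ring",
             grid_size)
  cfg <- mget(names(formals(phantom_config)))
  structure(cfg, class = "phantom_config")
}

#' Read a phantom configuration from a declarative JSON file
#'
#' The file holds a flat key/value object whose keys are the arguments of
#' \code{\link{phantom_config}} (e.g. \code{n_cases},
#' \code{texture_effect}, \code{seed}); \code{clinical_rates} may be given
#' as an object with \code{positive}/\code{negative} arrays of the four
#' probabilities (age >= 40, ER+, PR+, Ki-67 >= 14\%). Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a JSON file.
#' @return A validated \code{phantom_config}.
#' @export
phantom_config_from_file <- function(path) {
  if (!file.exists(path)) stop_dwr("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(phantom_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_dwr("unknown configuration keys: %s", paste(bad, collapse = ", "))
  if (!is.null(raw$clinical_rates))
    raw$clinical_rates <- lapply(raw$clinical_rates, function(v)
      stats::setNames(as.numeric(v),
                      c("age_ge40", "er_pos", "pr_pos", "ki67_ge14")))
  do.call(phantom_config, raw)
}

#' Class-conditional covariate rates
#'
#' Probabilities of the age >= 40, ER-positive, PR-positive and
#' Ki-67 >= 14\% categories given the HER-2 2+ FISH label, taken from the
#' clinical characteristics of the 223-patient cohort (97 positive,
#' 126 negative).
#'
#' @return List with numeric vectors \code{positive} and \code{negative}.
#' @export
default_clinical_rates <- function() {
  list(positive = c(age_ge40 = 80 / 97, er_pos = 58 / 97,
                    pr_pos = 59 / 97, ki67_ge14 = 80 / 97),
       negative = c(age_ge40 = 105 / 126, er_pos = 112 / 126,
                    pr_pos = 105 / 126, ki67_ge14 = 80 / 126))
}

check_rates <- function(rates) {
  for (cls in c("positive", "negative")) {
    r <- rates[[cls]]
    if (is.null(r) || length(r) != 4 || any(r < 0 | r > 1))
      stop_dwr("clinical_rates$%s must be 4 probabilities in [0, 1]", cls)
  }
  invisible(TRUE)
}

#' Sample clinical covariates given the class label
#'
#' Each factor is drawn independently from its class-conditional rate.
#'
#' @param label 0 (negative) or 1 (positive HER-2 2+).
#' @param clinical_rates See \code{\link{default_clinical_rates}}.
#' @return One-row data.frame with factors \code{age_group} (<40 / >=40),
#'   \code{er}, \code{pr} (negative/positive) and \code{ki67}
#'   (<14\% / >=14\%).
#' @export
sample_clinical_factors <- function(label,
                                    clinical_rates = default_clinical_rates()) {
  check_rates(clinical_rates)
  r <- clinical_rates[[if (label == 1) "positive" else "negative"]]
  u <- stats::runif(4)
  data.frame(
    age_group = factor(if (u[1] < r[["age_ge40"]]) ">=40" else "<40",
                       levels = c("<40", ">=40")),
    er = factor(if (u[2] < r[["er_pos"]]) "positive" else "negative",
                levels = c("negative", "positive")),
    pr = factor(if (u[3] < r[["pr_pos"]]) "positive" else "negative",
                levels = c("negative", "positive")),
    ki67 = factor(if (u[4] < r[["ki67_ge14"]]) ">=14%" else "<14%",
                  levels = c("<14%", ">=14%")))
}

## band-limited isotropic texture field on an nr x nc window, unit SD;
## radial pass band in cycles/pixel
bandpass_field <- function(nr, nc, band = c(0.10, 0.28)) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  keep <- rad >= band[1] & rad <= band[2]
  if (!any(keep)) keep[2, 2] <- TRUE
  f <- stats::fft(w) * keep
  x <- Re(stats::fft(f, inverse = TRUE)) / (nr * nc)
  sdx <- stats::sd(as.vector(x))
  if (sdx == 0) return(matrix(0, nr, nc))
  x / sdx
}

## random mass-like lesion mask: rotated ellipse with a smooth radial
## boundary perturbation, centred at (cr, cc); returns a logical grid mask
lesion_mask <- function(grid_size, cr, cc, area_px, aspect, phi, pert_coef) {
  b <- sqrt(area_px / (pi * aspect))
  a <- aspect * b
  half <- ceiling(a * 1.3) + 2L
  rs <- max(1, round(cr) - half):min(grid_size, round(cr) + half)
  cs <- max(1, round(cc) - half):min(grid_size, round(cc) + half)
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - cc)
  xr <- dc * cos(phi) + dr * sin(phi)
  yr <- -dc * sin(phi) + dr * cos(phi)
  theta <- atan2(yr, xr)
  pert <- 1
  for (k in seq_along(pert_coef$amp))
    pert <- pert + pert_coef$amp[k] * cos(pert_coef$ord[k] * theta +
                                          pert_coef$phase[k])
  inside <- (xr / a)^2 + (yr / b)^2 <= pert^2
  mask <- matrix(FALSE, grid_size, grid_size)
  mask[rs, cs] <- inside
  largest_component(mask)
}

#' Render one phantom case
#'
#' Builds a mass-like lesion (random ellipse with smooth boundary
#' perturbation) whose physical area falls in the configured range, plants
#' the class-dependent band-pass texture inside the lesion and (at reduced
#' strength) in a ring around it, sets the ADC lower inside the lesion than
#' outside, derives the b0 channel through the mono-exponential model, and
#' adds zero-clipped Gaussian (or exact Rician) noise to both channels.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param label 0/1 class label.
#' @param config A \code{\link{phantom_config}}.
#' @return List with \code{b0}, \code{b800}, \code{truth_mask},
#'   \code{seed_box} (a loose rectangle around the lesion, standing in for
#'   the hand-drawn ROI), \code{clinical}, \code{label} and
#'   \code{pixel_spacing_mm}.
#' @export
render_case <- function(label, config) {
  g <- config$grid_size
  s <- config$pixel_spacing_mm
  lo <- config$lesion_area_range_mm2[1]
  hi <- config$lesion_area_range_mm2[2]
  ## target area: log-normal about the 352 mm^2 cohort median, kept inside
  ## the range with margin for the boundary perturbation
  area_mm2 <- exp(stats::rnorm(1, log(352), 0.45))
  area_mm2 <- min(max(area_mm2, lo * 1.2), hi * 0.85)
  area_px <- area_mm2 / s^2
  r_px <- sqrt(area_px / pi)
  margin <- 1.35 * r_px + config$ring_width_mm / s + 8
  cr <- stats::runif(1, margin, g - margin)
  cc <- stats::runif(1, margin, g - margin)
  aspect <- stats::runif(1, 1, 1.7)
  phi <- stats::runif(1, 0, pi)
  pert <- list(ord = 2:4, amp = stats::runif(3, 0, 0.04),
               phase = stats::runif(3, 0, 2 * pi))
  mask <- lesion_mask(g, cr, cc, area_px, aspect, phi, pert)
  ## discretisation can shift the realised area: rescale deterministically
  ## until the physical area honours the configured range
  for (it in 1:5) {
    got <- sum(mask) * s^2
    if (got >= lo && got <= hi) break
    area_px <- area_px * (area_mm2 / got)
    mask <- lesion_mask(g, cr, cc, area_px, aspect, phi, pert)
  }
  if (sum(mask) * s^2 < lo || sum(mask) * s^2 > hi)
    stop_dwr("could not realise a lesion inside the configured area range")

  ring_px <- round(config$ring_width_mm / s)
  d <- distance_to_mask(mask, ring_px + 1)
  ring <- d > 0 & d <= ring_px

  ## texture window covering lesion + ring
  bb <- expand_bbox(mask_bbox(mask | ring), 2L, c(g, g))
  nrw <- bb$r2 - bb$r1 + 1L
  ncw <- bb$c2 - bb$c1 + 1L
  tex_in <- bandpass_field(nrw, ncw)
  tex_ring <- bandpass_field(nrw, ncw)
  amp_in <- config$texture_amplitude * (1 + config$texture_effect * label)
  amp_ring <- 0.6 * config$texture_amplitude *
    (1 + config$peri_effect_ratio * config$texture_effect * label)

  b800 <- matrix(config$background_b800, g, g)
  b800[mask] <- config$background_b800 + config$contrast
  sub <- function(full) full[bb$r1:bb$r2, bb$c1:bb$c2]
  w800 <- sub(b800)
  w800[sub(mask)] <- w800[sub(mask)] + amp_in * tex_in[sub(mask)]
  w800[sub(ring)] <- w800[sub(ring)] + amp_ring * tex_ring[sub(ring)]
  b800[bb$r1:bb$r2, bb$c1:bb$c2] <- w800

  adc <- matrix(config$adc_background, g, g)
  adc[mask] <- config$adc_lesion
  b0 <- b800 * exp((config$b_high - config$b_low) * adc)

  add_noise <- function(x) {
    if (config$noise_sigma == 0) return(x)
    if (config$rician) {
      n1 <- matrix(stats::rnorm(g * g, 0, config$noise_sigma), g, g)
      n2 <- matrix(stats::rnorm(g * g, 0, config$noise_sigma), g, g)
      sqrt((x + n1)^2 + n2^2)
    } else {
      pmax(x + matrix(stats::rnorm(g * g, 0, config$noise_sigma), g, g), 0)
    }
  }
  b800 <- add_noise(b800)
  b0 <- add_noise(b0)

  seed_box <- matrix(FALSE, g, g)
  sb <- expand_bbox(mask_bbox(mask), ring_px + 4L, c(g, g))
  seed_box[sb$r1:sb$r2, sb$c1:sb$c2] <- TRUE

  list(b0 = b0, b800 = b800, truth_mask = mask, seed_box = seed_box,
       clinical = sample_clinical_factors(label, config$clinical_rates),
       label = label, pixel_spacing_mm = s)
}

#' Generate a phantom cohort
#'
#' Label counts equal their rounded expectations (assignment without
#' replacement); cases are split into training and validation cohorts by
#' index after a deterministic shuffle. The whole cohort is reproducible
#' from \code{config$seed} alone.
#'
#' @param config A \code{\link{phantom_config}}.
#' @return List of case records (as from \code{\link{render_case}}), each
#'   with added \code{case_id} and \code{cohort} fields; the clinical table
#'   is available via \code{\link{cohort_table}}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_cases
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(config$seed, "cohort"))
  n_pos <- round(n * config$positive_fraction)
  labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  n_train <- round(n * config$train_fraction)
  cohort <- rep("validation", n)
  cohort[sample.int(n)[seq_len(n_train)]] <- "training"
  ## evaluation needs both classes in both cohorts: deterministically swap
  ## lowest-index cases until each cohort holds at least two of each class
  ## (only ever triggers at very small n)
  for (cls in c(1L, 0L)) for (co in c("training", "validation")) {
    other <- setdiff(c("training", "validation"), co)
    while (sum(labels == cls & cohort == co) < 2L &&
           sum(labels == cls & cohort == other) > 2L) {
      take <- which(labels == cls & cohort == other)[1]
      give <- which(labels != cls & cohort == co)[1]
      if (!length(take) || !length(give) || is.na(take) || is.na(give)) break
      cohort[take] <- co
      cohort[give] <- other
    }
  }
  lapply(seq_len(n), function(i) {
    rec <- render_case(labels[i], config)
    rec$case_id <- sprintf("case_%03d", i)
    rec$cohort <- cohort[i]
    rec
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Clinical covariate table of a cohort
#'
#' @param cases List of case records from \code{\link{generate_cohort}}.
#' @return data.frame with case_id, label, cohort and the four covariates.
#' @export
cohort_table <- function(cases) {
  do.call(rbind, lapply(cases, function(cs)
    cbind(data.frame(case_id = cs$case_id, label = cs$label,
                     cohort = cs$cohort), cs$clinical)))
}

#' Randomly perturb a mask boundary (simulated second reader)
#'
#' Adds a smooth random field to the signed distance of the boundary, so
#' the contour is locally dilated or eroded by up to \code{magnitude}
#' pixels. Magnitudes at or above the lesion inradius are clamped with a
#' warning rather than erroring. The result is the largest connected
#' component of the perturbed region, hence always nonempty and connected.
#'
#' @param mask Logical matrix (nonempty).
#' @param magnitude Maximum boundary displacement, pixels.
#' @return Logical matrix.
#' @export
perturb_mask <- function(mask, magnitude) {
  m <- assert_mask(mask)
  if (magnitude == 0) return(m)
  inner <- inner_distance(m, 2)   # nearest background is never beyond bbox+1
  r_in <- max(inner[m])
  if (magnitude >= r_in) {
    warn_dwr("perturbation magnitude %.1f >= lesion inradius %.1f; clamping",
             magnitude, r_in)
    magnitude <- max(r_in - 1, 0.5)
  }
  d_out <- distance_to_mask(m, ceiling(magnitude) + 3)   # 0 inside
  signed <- d_out
  signed[m] <- -inner[m]
  bb <- expand_bbox(mask_bbox(m), ceiling(magnitude) + 6L, dim(m))
  w <- crop_bbox(signed, bb)
  field <- bandpass_field(nrow(w), ncol(w), band = c(0.02, 0.10))
  field <- pmax(pmin(field * 0.6 * magnitude, magnitude), -magnitude)
  newm <- matrix(FALSE, nrow(m), ncol(m))
  newm[bb$r1:bb$r2, bb$c1:bb$c2] <- w <= field & is.finite(w)
  largest_component(newm)
}
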
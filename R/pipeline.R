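## End-to-end orchestration: phantom cohort -> segmentation -> features ->
## ICC -> selection -> rad-scores -> nomogram -> evaluation; plus file I/O.

region_pool <- function(feature_names, region) {
  switch(region,
         intra = feature_names[grepl("^shape_|_intra_", feature_names)],
         peri = feature_names[grepl("_peri_", feature_names)],
         combined = feature_names,
         stop_dwr("unknown region '%s'", region))
}

#' Segment one case and extract its feature vector
#'
#' Runs the semi-automatic segmentation from the case's seed region, builds
#' the 4-mm peritumoral ring, propagates the contours to all channels and
#' extracts the 2,504-feature vector.
#'
#' @param rec Case record (from \code{\link{render_case}} or
#'   \code{\link{read_case_inputs}}).
#' @param config A \code{\link{phantom_config}} (for spacing/ring defaults).
#' @param mask Optional lesion mask overriding the segmentation (used for
#'   the simulated second reader).
#' @return List with \code{features}, \code{rois} and the derived
#'   \code{adc} channel.
#' @export
process_case <- function(rec, config, mask = NULL) {
  adc <- compute_adc(rec$b0, rec$b800, config$b_low, config$b_high)
  if (is.null(mask))
    mask <- segment_intratumoral(rec$b800, rec$seed_box)
  ring <- peritumoral_ring(mask, config$ring_width_mm,
                           config$pixel_spacing_mm, rec$breast_mask)
  rois <- roi_set(mask, ring, rec$breast_mask, config$ring_width_mm)
  stack <- list(b0 = rec$b0, b800 = rec$b800, adc = adc,
                pixel_spacing_mm = config$pixel_spacing_mm)
  list(features = extract_features(stack, rois), rois = rois, adc = adc)
}

#' Run the whole phantom study
#'
#' Generates a phantom cohort, segments and extracts features for every
#' case, optionally emulates the two-reader ICC filter on a stratified
#' subsample, z-scores on the training cohort, performs the three-step
#' selection per region (intratumoral, peritumoral, combined), fits the
#' three rad-score models, builds the clinical nomogram, and evaluates all
#' four models on both cohorts, including the pairwise DeLong matrix, the
#' nomogram calibration curves and the validation decision curve.
#'
#' @param config A \code{\link{phantom_config}}.
#' @param run_icc Emulate the two-reader reproducibility filter (default
#'   TRUE).
#' @param icc_n Size of the two-reader subsample (stratified; default 60
#'   as in the clinical protocol, reduced if the cohort is smaller).
#' @param perturb_magnitude Boundary perturbation of the simulated second
#'   reader, pixels (default 1).
#' @param mrmr_k MRMR pool size (default 20); automatically capped at a
#'   quarter of the training-cohort size so tiny phantom runs stay
#'   identified.
#' @param n_bootstrap Bootstrap resamples for operating-point CIs
#'   (default 500 at phantom scale).
#' @param out_dir Optional directory to write artifacts into.
#' @return List (class \code{phantom_study}) with cohort tables, feature
#'   tables, ICC results, selection traces, models, scores, and
#'   evaluation reports.
#' @export
run_phantom_study <- function(config, run_icc = TRUE, icc_n = 60L,
                              perturb_magnitude = 1, mrmr_k = 20L,
                              n_bootstrap = 500L, out_dir = NULL) {
  cases <- generate_cohort(config)
  clin <- cohort_table(cases)
  processed <- lapply(cases, process_case, config = config)
  feats <- do.call(rbind, lapply(processed, `[[`, "features"))
  rownames(feats) <- clin$case_id

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(config$seed, "icc"))
  icc_res <- NULL
  retained <- colnames(feats)
  if (run_icc) {
    per_class <- min(icc_n %/% 2, min(table(clin$label)))
    pick <- c(sample(which(clin$label == 1), per_class),
              sample(which(clin$label == 0), per_class))
    reader2 <- do.call(rbind, lapply(pick, function(i) {
      m2 <- perturb_mask(processed[[i]]$rois$intratumoral, perturb_magnitude)
      process_case(cases[[i]], config, mask = m2)$features
    }))
    rownames(reader2) <- rownames(feats)[pick]
    icc_res <- icc_filter(feats[pick, , drop = FALSE], reader2)
    retained <- icc_res$retained
    if (!length(retained)) stop_dwr("no feature passed the ICC filter")
  }

  train_idx <- clin$cohort == "training"
  y_train <- clin$label[train_idx]
  y_val <- clin$label[!train_idx]
  z <- zscore_fit_apply(feats[train_idx, retained, drop = FALSE],
                        feats[!train_idx, retained, drop = FALSE])
  ztrain <- z$tables[[1]]
  zval <- z$tables[[2]]

  set.seed(child_seed(config$seed, "selection"))
  ## MRMR keeps 20 features at clinical cohort sizes; very small phantom
  ## cohorts cap the pool so the downstream logistic fit stays identified
  k_eff <- min(mrmr_k, max(2L, sum(train_idx) %/% 4L))
  if (k_eff < mrmr_k)
    warn_dwr("training cohort of %d: MRMR pool capped at %d features",
             sum(train_idx), k_eff)
  regions <- c("intra", "peri", "combined")
  traces <- lapply(regions, function(rg) {
    pool <- region_pool(retained, rg)
    select_features(ztrain[, pool, drop = FALSE], y_train, k = k_eff)
  })
  names(traces) <- regions

  models <- lapply(traces, function(tr)
    fit_logistic(ztrain[, tr$final, drop = FALSE], y_train))
  scores_train <- lapply(models, rad_score, features = ztrain)
  scores_val <- lapply(models, rad_score, features = zval)

  nomo <- tryCatch(
    build_nomogram(clin[train_idx, ], scores_train$combined, y_train),
    error = function(e) {
      warn_dwr("nomogram skipped: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(nomo)) {
    prob_train <- predict_nomogram(nomo, clin[train_idx, ],
                                   scores_train$combined)
    prob_val <- predict_nomogram(nomo, clin[!train_idx, ],
                                 scores_val$combined)
    ## probabilities are a monotone map of the linear predictor, so every
    ## rank-based evaluation is unchanged and scores stay finite even when
    ## a separated fit pins probabilities at 0/1
    all_train <- c(scores_train, list(nomogram = prob_train))
    all_val <- c(scores_val, list(nomogram = prob_val))
  } else {
    prob_train <- prob_val <- NULL
    all_train <- scores_train
    all_val <- scores_val
  }

  eval_seed <- child_seed(config$seed, "bootstrap")
  reports <- list(
    training = lapply(all_train, evaluate_scores, labels = y_train,
                      n_bootstrap = n_bootstrap, seed = eval_seed),
    validation = lapply(all_val, evaluate_scores, labels = y_val,
                        n_bootstrap = n_bootstrap, seed = eval_seed))

  delong_matrix <- function(sc, y) {
    k <- length(sc)
    m <- matrix(NA_real_, k, k, dimnames = list(names(sc), names(sc)))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      p <- delong_paired_test(sc[[i]], sc[[j]], y)$p_value
      m[i, j] <- m[j, i] <- p
    }
    m
  }
  delong <- list(training = delong_matrix(all_train, y_train),
                 validation = delong_matrix(all_val, y_val))

  calib <- if (!is.null(nomo))
    list(training = calibration_curve(prob_train, y_train),
         validation = calibration_curve(prob_val, y_val))
  dca <- if (!is.null(nomo)) decision_curve(prob_val, y_val)

  t_tests <- lapply(names(scores_train), function(nm) {
    list(region = nm,
         training = two_sample_t(scores_train[[nm]][y_train == 1],
                                 scores_train[[nm]][y_train == 0]),
         validation = two_sample_t(scores_val[[nm]][y_val == 1],
                                   scores_val[[nm]][y_val == 0]))
  })

  split_test <- chi_square_2x2(sum(y_train == 1), sum(y_train == 0),
                               sum(y_val == 1), sum(y_val == 0))

  study <- structure(list(
    config = config, clinical = clin, features = feats,
    icc = icc_res, retained = retained,
    z_params = z$z_params, traces = traces, models = models,
    scores = list(training = all_train, validation = all_val),
    nomogram = nomo,
    probabilities = list(training = prob_train, validation = prob_val),
    reports = reports, delong = delong, calibration = calib, dca = dca,
    t_tests = t_tests, split_test = split_test),
    class = "phantom_study")
  if (!is.null(out_dir)) write_study(study, cases, out_dir)
  study
}

#' @export
print.phantom_study <- function(x, ...) {
  cat("Phantom radiomics study:", nrow(x$clinical), "cases (",
      sum(x$clinical$cohort == "training"), "training /",
      sum(x$clinical$cohort == "validation"), "validation )\n")
  if (is.null(x$icc))
    cat("ICC filter not run;", length(x$retained), "features in play\n")
  else
    cat("Features retained by ICC filter:", length(x$retained), "/",
        ncol(x$features), "\n")
  for (nm in names(x$reports$training))
    cat(sprintf("  %-9s AUC train %.3f / validation %.3f\n", nm,
                x$reports$training[[nm]]$auc,
                x$reports$validation[[nm]]$auc))
  invisible(x)
}

## ---------------------------------------------------------------- file I/O

#' Write a phantom case to NIfTI + masks
#'
#' @param rec Case record.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_case_nifti <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- rec$pixel_spacing_mm
  as_nii <- function(x) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- c(sp, sp)
    img
  }
  paths <- character(0)
  for (ch in c("b0", "b800")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", rec$case_id, ch))
    RNifti::writeNifti(as_nii(rec[[ch]]), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, sprintf("%s_mask.nii.gz", rec$case_id))
  RNifti::writeNifti(as_nii(rec$truth_mask + 0L), p)
  invisible(c(paths, p))
}

#' Read one case from NIfTI channels and a clinical row (real-image mode)
#'
#' @param b0_path,b800_path Paths to single-slice NIfTI images.
#' @param clinical_row One-row data.frame with \code{age_group}, \code{er},
#'   \code{pr}, \code{ki67} (and optionally \code{label}) using the
#'   documented category vocabulary.
#' @param seed_box_path Optional NIfTI mask of the rough lesion region.
#' @param breast_mask_path Optional NIfTI breast mask.
#' @return Case record list compatible with \code{\link{process_case}}.
#' @export
read_case_inputs <- function(b0_path, b800_path, clinical_row,
                             seed_box_path = NULL, breast_mask_path = NULL) {
  for (p in c(b0_path, b800_path, seed_box_path, breast_mask_path))
    if (!file.exists(p)) stop_dwr("missing image file: %s", p)
  b0 <- RNifti::readNifti(b0_path)
  b800 <- RNifti::readNifti(b800_path)
  sp <- RNifti::pixdim(b800)[1]
  if (!isTRUE(sp > 0)) stop_dwr("pixel spacing missing from NIfTI header")
  vocab <- list(age_group = c("<40", ">=40"),
                er = c("negative", "positive"),
                pr = c("negative", "positive"),
                ki67 = c("<14%", ">=14%"))
  for (v in names(vocab)) {
    val <- as.character(clinical_row[[v]])
    if (!length(val) || !val %in% vocab[[v]])
      stop_dwr("clinical value '%s' for %s outside the vocabulary (%s)",
               val, v, paste(vocab[[v]], collapse = ", "))
  }
  rec <- list(b0 = as.matrix(b0), b800 = as.matrix(b800),
              pixel_spacing_mm = sp,
              clinical = clinical_row[names(vocab)],
              label = clinical_row$label %||% NA_integer_)
  rec$seed_box <- if (!is.null(seed_box_path))
    as.matrix(RNifti::readNifti(seed_box_path)) != 0
  rec$breast_mask <- if (!is.null(breast_mask_path))
    as.matrix(RNifti::readNifti(breast_mask_path)) != 0
  rec
}

write_study <- function(study, cases, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$clinical, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(case_id = rownames(study$features),
                              study$features, check.names = FALSE),
                   file.path(out_dir, "features_raw.csv"), row.names = FALSE)
  if (!is.null(study$icc))
    utils::write.csv(study$icc$results, file.path(out_dir, "icc.csv"),
                     row.names = FALSE)
  utils::write.csv(study$z_params, file.path(out_dir, "z_params.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(study$traces, function(tr) tr[c("screened", "mrmr", "final",
                                           "aic_path")]),
    file.path(out_dir, "selection_traces.json"), auto_unbox = FALSE)
  jsonlite::write_json(
    lapply(study$models, function(m)
      list(features = m$feature_names, intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           separation = m$separation)),
    file.path(out_dir, "rad_score_models.json"), auto_unbox = TRUE)
  if (!is.null(study$nomogram)) {
    jsonlite::write_json(
      list(predictors = study$nomogram$predictors,
           univariate = study$nomogram$univariate,
           multivariate = study$nomogram$multivariate),
      file.path(out_dir, "nomogram.json"), auto_unbox = TRUE, digits = NA)
    pts <- nomogram_points(study$nomogram)
    pts_tab <- do.call(rbind, lapply(names(pts$tables), function(nm)
      cbind(predictor = nm, pts$tables[[nm]])))
    utils::write.csv(pts_tab, file.path(out_dir, "nomogram_points.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(study$reports, function(cohort)
      lapply(cohort, function(r) unclass(r))),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(study$dca, file.path(out_dir, "dca_validation.csv"),
                   row.names = FALSE)
  img_dir <- file.path(out_dir, "images")
  for (rec in cases) write_case_nifti(rec, img_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dwiradiomics")),
    r_version = R.version.string,
    seed = study$config$seed,
    config_hash = config_hash(study$config),
    n_cases = study$config$n_cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

config_hash <- function(config) {
  s <- paste(vapply(config, function(v) paste(format(v, digits = 12),
                                              collapse = ","), ""),
             collapse = ";")
  ## small stable polynomial hash, avoiding external digest dependencies
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
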
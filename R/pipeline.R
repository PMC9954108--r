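# End-to-end orchestration: generate -> quantify -> scale -> PCA 1-3 ->
# OPLS-DA 1-3 -> OPLS purity regression -> univariate compartment
# deconvolution, with every intermediate written as CSV.

#' Pipeline configuration
#'
#' All stage parameters with their conventional defaults: sevenfold
#' cross-validation, 95%/90% confidence levels, 20% test fraction for the
#' score-plane split, purity probe points 0/60/100%, formate reference at
#' 8.44 ppm.
#'
#' @param seed master seed; every random draw in the run flows from it.
#' @param cohort a [cohort_config()].
#' @param signatures a [default_signatures()] object.
#' @param use_spectra synthesize and quantify full spectra (slow path)
#'   instead of taking the mixed levels directly as region integrals.
#' @param folds cross-validation folds.
#' @param test_fraction score-plane test fraction.
#' @param purity_points purity probe points (percent).
#' @param ci_level,trend_level confidence levels for significance and trend
#'   verdicts.
#' @param purity_cutoff cancer percentage separating "malignant" from
#'   low-purity samples in the discriminant models.
#' @param skew_threshold auto-log skewness threshold.
#' @param run_deconvolution,run_chemometrics stage toggles.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = cohort_config(),
                       signatures = default_signatures(),
                       use_spectra = FALSE, folds = 7, test_fraction = 0.2,
                       purity_points = c(0, 60, 100), ci_level = 0.95,
                       trend_level = 0.90, purity_cutoff = 25,
                       skew_threshold = 1.0, run_deconvolution = TRUE,
                       run_chemometrics = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order: cohort generation, metabolite quantitation
#' (direct mixing or full spectrum synthesis + preprocessing), weight
#' normalization, log/UV scaling, PCA of the whole set and of the normal
#' tissue (models 1-3), OPLS-DA of cancer vs distant-normal with external
#' validation (model 1), OPLS-DA of high-purity vs proximal-normal with a
#' score-plane train/test split (model 2), internally validated OPLS-DA of
#' low-purity vs normal (model 3), OPLS regression of purity on the
#' metabolite profile, and the univariate purity deconvolution with
#' compartment comparisons. All outputs are written as CSV files in
#' `out_dir` together with a `manifest.txt`; the function also returns them
#' invisibly as a list.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) list with the cohort, matrices, fitted models,
#'   evaluation summaries and deconvolution tables.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("stromanmr_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config, out_dir = out_dir)

  # stage 1: cohort + metabolite levels
  cohort <- generate_cohort(config$cohort, seed = config$seed)
  levels <- mix_samples(cohort, config$signatures, seed = config$seed + 1L)
  if (config$use_spectra) {
    peaks <- default_peak_table()
    spectra <- lapply(seq_len(nrow(cohort)), function(i) {
      lv <- levels[i, ]
      list(CPMG = synthesize_spectrum(lv[setdiff(names(lv), LIPID_VARS)],
                                      peaks, ppm_offset = 0,
                                      sample_id = cohort$sample_id[i],
                                      weight_mg = cohort$weight_mg[i]),
           DIFF = synthesize_spectrum(lv[LIPID_VARS], peaks,
                                      sample_id = cohort$sample_id[i],
                                      weight_mg = cohort$weight_mg[i]))
    })
    names(spectra) <- cohort$sample_id
    mat <- quantify_spectra(spectra)
  } else {
    mat <- metabolite_matrix(levels)
  }
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  write_matrix_csv(mat, file.path(out_dir, "levels_raw.csv"))

  # stage 2: normalization + scaling
  mat <- normalize_by_weight(mat, stats::setNames(cohort$weight_mg,
                                                  cohort$sample_id))
  scaled <- log_and_uv_scale(mat, config$skew_threshold)
  write_matrix_csv(mat, file.path(out_dir, "levels_per_mg.csv"))
  res$cohort <- cohort
  res$matrix <- mat
  res$scaled <- scaled

  has_cancer <- cohort$cancer > 0
  purity <- cohort$cancer

  if (config$run_chemometrics) {
    # PCA model 1: everything; model 2: histologically normal tissue;
    # model 3: normal tissue within 1 cm of the tumor border
    res$pca1 <- pca_fit(scaled, 2)
    normal <- !has_cancer
    near <- cohort$location != "N_gt1cm"
    sub_scaled <- function(keep) {
      m <- metabolite_matrix(mat$values[keep, , drop = FALSE])
      m$scaling_state <- "weight_normalized"
      log_and_uv_scale(m, config$skew_threshold)
    }
    res$pca2 <- pca_fit(sub_scaled(normal), 2)
    pca3_keep <- normal & near
    res$pca3 <- pca_fit(sub_scaled(pca3_keep), 2)

    # OPLS-DA model 1: cancer-containing T vs N_gt1cm, external validation on
    # the remaining samples
    tr1 <- (cohort$location == "T" & has_cancer) | cohort$location == "N_gt1cm"
    lab1 <- ifelse(has_cancer[tr1], "cancer", "normal")
    m1_scaled <- sub_scaled(tr1)
    res$oplsda1 <- oplsda_fit(m1_scaled, lab1, positive = "cancer",
                              cv_seed = config$seed)
    ext1 <- !tr1
    if (any(ext1)) {
      pred1 <- predict(res$oplsda1, mat$values[ext1, , drop = FALSE],
                       truth = ifelse(has_cancer[ext1], "cancer", "normal"))
      res$eval1 <- confusion_metrics(pred1$predicted,
                                     ifelse(has_cancer[ext1], "cancer", "normal"),
                                     positive = "cancer")
      res$pred1 <- pred1
    }

    # OPLS-DA model 2: purity >= cutoff vs proximal normals, 80/20 split on
    # the PCA-3 score plane for the normals
    high <- purity >= config$purity_cutoff & near
    norm_near <- normal & near & cohort$location != "T"
    split_idx <- which(pca3_keep)
    grp <- ifelse(cohort$location[split_idx] == "TB", "TB", "N")
    sp <- split_by_score_plane(res$pca3, grp,
                               test_fraction = config$test_fraction,
                               seed = config$seed)
    norm_train <- split_idx[sp$train]
    norm_test <- split_idx[sp$test]
    tr2 <- union(which(high), intersect(norm_train, which(norm_near)))
    lab2 <- ifelse(has_cancer[tr2] & purity[tr2] >= config$purity_cutoff,
                   "cancer", "normal")
    if (min(table(lab2)) >= 7) {
      m2_scaled <- sub_scaled(tr2)
      res$oplsda2 <- oplsda_fit(m2_scaled, lab2, positive = "cancer",
                                cv_seed = config$seed)
      lowpur <- which(has_cancer & purity < config$purity_cutoff & near)
      ext2 <- union(lowpur, intersect(norm_test, which(norm_near)))
      if (length(ext2)) {
        truth2 <- ifelse(has_cancer[ext2], "cancer", "normal")
        pred2 <- predict(res$oplsda2, mat$values[ext2, , drop = FALSE],
                         truth = truth2)
        res$eval2 <- confusion_metrics(pred2$predicted, truth2,
                                       positive = "cancer")
      }
    }

    # OPLS-DA model 3: low-purity malignant vs proximal normal, internal CV
    low3 <- (has_cancer & purity < config$purity_cutoff & near) |
      (normal & near)
    lab3 <- ifelse(has_cancer[low3], "cancer", "normal")
    if (min(table(lab3)) >= 7)
      res$oplsda3 <- oplsda_fit(sub_scaled(low3), lab3, positive = "cancer",
                                cv_seed = config$seed)

    # OPLS regression of purity on the metabolite profile
    reg_keep <- select_samples(cohort, "regression")
    if (sum(reg_keep) >= 10)
      res$opls_purity <- opls_fit(sub_scaled(reg_keep), purity[reg_keep],
                                  cv_seed = config$seed)
    res$regression_subset <- reg_keep

    models <- data.frame(
      model = c("OPLS-DA 1", "OPLS-DA 2", "OPLS-DA 3", "OPLS purity"),
      r2x = sapply(list(res$oplsda1, res$oplsda2, res$oplsda3,
                        res$opls_purity), function(m) if (is.null(m)) NA else m$r2x),
      r2y = sapply(list(res$oplsda1, res$oplsda2, res$oplsda3,
                        res$opls_purity), function(m) if (is.null(m)) NA else m$r2y),
      q2 = sapply(list(res$oplsda1, res$oplsda2, res$oplsda3,
                       res$opls_purity), function(m) if (is.null(m)) NA else m$q2),
      cv_anova_p = sapply(list(res$oplsda1, res$oplsda2, res$oplsda3,
                               res$opls_purity),
                          function(m) if (is.null(m)) NA else m$cv_anova_p))
    utils::write.csv(models, file.path(out_dir, "model_summary.csv"),
                     row.names = FALSE)
  }

  if (config$run_deconvolution) {
    res$deconvolution <- deconvolve_cohort(cohort, mat,
                                           purity_points = config$purity_points)
    utils::write.csv(res$deconvolution$regressions,
                     file.path(out_dir, "purity_regressions.csv"),
                     row.names = FALSE)
    utils::write.csv(res$deconvolution$comparisons,
                     file.path(out_dir, "compartment_comparisons.csv"),
                     row.names = FALSE)
  }

  writeLines(c(sprintf("stromanmr %s", as.character(utils::packageVersion("stromanmr"))),
               sprintf("seed: %d", config$seed),
               sprintf("samples: %d", nrow(cohort)),
               sprintf("stages: chemometrics=%s deconvolution=%s",
                       config$run_chemometrics, config$run_deconvolution),
               sprintf("R: %s", R.version.string)),
             file.path(out_dir, "manifest.txt"))
  invisible(res)
}

#' Univariate purity deconvolution of a cohort
#'
#' For every metabolite variable: linear regression on the cancer-cell
#' percentage in the regression subset (cancer + intratumoral fibrosis
#' > 80%), outlier exclusion (standardized residual and Cook's distance),
#' extrapolation to the purity probe points, fat adjustment of the
#' extratumoral connective-tissue reference (calibrated on the two distant
#' normal locations), and the confidence-interval overlap verdict; grade
#' (I vs II/III) contrasts at 60% purity where both groups are large
#' enough. Samples flagged as PEG-contaminated are excluded from the
#' succinate and glutamate regressions when a `peg` variable is present.
#'
#' @param cohort cohort `data.frame`.
#' @param matrix weight-normalized `metabolite_matrix`.
#' @param purity_points purity probe points (percent).
#' @param metabolites variables to analyse (defaults to all non-lipid
#'   variables).
#' @return list with `regressions` (one tidy row per metabolite: slope,
#'   intercept, r, p, predictions at the probe points), `comparisons`
#'   (stroma vs reference verdicts), `grade_contrasts`, and the per-
#'   metabolite fit objects.
#' @export
deconvolve_cohort <- function(cohort, matrix,
                              purity_points = c(0, 60, 100),
                              metabolites = NULL) {
  v <- if (inherits(matrix, "metabolite_matrix")) matrix$values else matrix
  if (is.null(metabolites))
    metabolites <- setdiff(colnames(v), LIPID_VARS)
  reg_keep <- select_samples(cohort, "regression")
  ref_keep <- select_samples(cohort, "EC_lt1cm") |
    select_samples(cohort, "EC_ge1cm")
  cal_keep <- cohort$location %in% c("N_eq1cm", "N_gt1cm")
  peg_bad <- rep(FALSE, nrow(cohort))
  if ("peg" %in% colnames(v))
    peg_bad <- flag_peg_contamination(v[, "peg"])

  fits <- list(); rows <- list(); comps <- list(); grades <- list()
  hi_grade <- cohort$grade %in% c("II", "III")
  lo_grade <- cohort$grade == "I"
  for (m in metabolites) {
    keep <- reg_keep
    if (m %in% c("succinate", "glutamate")) keep <- keep & !peg_bad
    idx <- which(keep)
    if (length(idx) < 5) next
    fit <- fit_purity_regression(v[idx, m], cohort$cancer[idx],
                                 at = purity_points, metabolite = m,
                                 sample_ids = cohort$sample_id[idx])
    fit <- flag_outliers(fit)
    fits[[m]] <- fit
    pr <- fit$predictions
    row <- data.frame(metabolite = m, n = fit$n, slope = fit$slope,
                      intercept = fit$intercept, pearson_r = fit$pearson_r,
                      p_value = fit$p_value,
                      purity_lo = fit$purity_range[1],
                      purity_hi = fit$purity_range[2],
                      n_excluded = nrow(fit$excluded_points))
    for (j in seq_len(nrow(pr))) {
      row[[sprintf("est_%g", pr$purity[j])]] <- pr$estimate[j]
      row[[sprintf("lo_%g", pr$purity[j])]] <- pr$ci_lo[j]
      row[[sprintf("hi_%g", pr$purity[j])]] <- pr$ci_hi[j]
    }
    rows[[m]] <- row

    if (sum(ref_keep) >= 3 && sum(cal_keep) >= 5) {
      adj <- adjust_for_fat(v[ref_keep, m], cohort$fat[ref_keep],
                            v[cal_keep, m], cohort$fat[cal_keep])
      cmp <- compare_compartments(fit, as.numeric(adj))
      comps[[m]] <- data.frame(metabolite = m,
                               stroma_estimate = cmp$stroma_estimate,
                               stroma_lo95 = cmp$stroma_ci95[1],
                               stroma_hi95 = cmp$stroma_ci95[2],
                               reference_mean = cmp$reference_mean,
                               reference_lo95 = cmp$reference_ci95[1],
                               reference_hi95 = cmp$reference_ci95[2],
                               verdict = cmp$verdict)
    }

    ia <- which(keep & lo_grade); ib <- which(keep & hi_grade)
    if (length(ia) >= 5 && length(ib) >= 5) {
      fa <- fit_purity_regression(v[ia, m], cohort$cancer[ia],
                                  at = purity_points, metabolite = m)
      fb <- fit_purity_regression(v[ib, m], cohort$cancer[ib],
                                  at = purity_points, metabolite = m)
      gc <- grade_contrast(fa, fb, at_purity = 60)
      grades[[m]] <- data.frame(metabolite = m, verdict = gc$verdict,
                                est_gradeI = gc$estimate_a,
                                est_gradeII_III = gc$estimate_b)
    }
  }
  list(regressions = do.call(rbind, rows),
       comparisons = do.call(rbind, comps),
       grade_contrasts = do.call(rbind, grades),
       fits = fits)
}
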
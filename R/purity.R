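# Two-compartment purity deconvolution: per-metabolite linear regression on
# cancer-cell fraction, extrapolation to pure compartments, fat-adjusted
# extratumoral reference, confidence-interval overlap verdicts, grade and
# subtype contrasts. Purity is carried in percent (0-100) throughout.

#' Sample-selection criteria
#'
#' Named per-tissue-class thresholds (percent). `<class>_min` /-`_max` bound
#' a single class; `combined_cancer_fibrosis_min` bounds the summed cancer +
#' intratumoral fibrosis content; `locations` restricts the excision areas.
#'
#' @param ... named thresholds, e.g. `cancer_min = 40, fat_max = 10`.
#' @param locations optional character vector of admissible locations.
#' @return object of class `selection_criteria`.
#' @export
selection_criteria <- function(..., locations = NULL) {
  th <- list(...)
  cls_of <- function(nm) sub("_(min|max)$", "", nm)
  for (nm in names(th)) {
    if (!grepl("_(min|max)$", nm))
      stop("criteria must be named <class>_min or <class>_max: ", nm)
    cls <- cls_of(nm)
    if (!cls %in% c(TISSUE_CLASSES, "combined_cancer_fibrosis"))
      stop("unknown tissue class in criteria: ", cls)
    if (th[[nm]] < 0 || th[[nm]] > 100)
      stop("thresholds must be in [0, 100]")
  }
  structure(list(thresholds = th, locations = locations),
            class = "selection_criteria")
}

#' Predefined tissue-archetype criteria
#'
#' The inclusion criteria for the specimens most representative of each
#' tissue type, plus the regression-subset rule (cancer + intratumoral
#' fibrosis above 80%) used for the purity deconvolution:
#' \describe{
#'   \item{C}{cancer: cancer cells >= 40%, fat <= 10%, glandular <= 10%}
#'   \item{IF}{intratumoral fibrotic stroma >= 80%, cancer <= 15%}
#'   \item{EC_lt1cm / EC_ge1cm}{extratumoral fibrous connective tissue
#'     >= 80%, below / at-or-beyond 1 cm from the tumor border}
#'   \item{EF_lt1cm / EF_ge1cm}{pure (100%) extratumoral fatty tissue}
#'   \item{regression}{cancer + intratumoral fibrosis > 80%, tumor-proximal
#'     locations}
#' }
#' @return named list of [selection_criteria()] objects.
#' @export
archetype_criteria <- function() {
  list(
    C = selection_criteria(cancer_min = 40, fat_max = 10, glandular_max = 10),
    IF = selection_criteria(intratumoral_fibrosis_min = 80, cancer_max = 15),
    EC_lt1cm = selection_criteria(extratumoral_connective_min = 80,
                                  locations = "N_lt1cm"),
    EC_ge1cm = selection_criteria(extratumoral_connective_min = 80,
                                  locations = c("N_eq1cm", "N_gt1cm")),
    EF_lt1cm = selection_criteria(fat_min = 100, locations = "N_lt1cm"),
    EF_ge1cm = selection_criteria(fat_min = 100,
                                  locations = c("N_eq1cm", "N_gt1cm")),
    regression = selection_criteria(combined_cancer_fibrosis_min = 80,
                                    locations = c("T", "TB", "N_lt1cm",
                                                  "N_eq1cm"))
  )
}

#' Select cohort samples by histology criteria
#'
#' @param cohort cohort `data.frame` with percent tissue columns.
#' @param criteria a [selection_criteria()] object (or a name from
#'   [archetype_criteria()]).
#' @return logical vector marking the samples that satisfy every threshold.
#' @export
select_samples <- function(cohort, criteria) {
  if (is.character(criteria)) criteria <- archetype_criteria()[[criteria]]
  stopifnot(inherits(criteria, "selection_criteria"))
  keep <- rep(TRUE, nrow(cohort))
  for (nm in names(criteria$thresholds)) {
    cls <- sub("_(min|max)$", "", nm)
    val <- if (cls == "combined_cancer_fibrosis")
      cohort$cancer + cohort$intratumoral_fibrosis else cohort[[cls]]
    if (is.null(val)) stop("unknown tissue class in criteria: ", cls)
    # strict > for combined-content minima (content "above" the threshold)
    keep <- keep & if (grepl("_min$", nm)) {
      if (cls == "combined_cancer_fibrosis") val > criteria$thresholds[[nm]]
      else val >= criteria$thresholds[[nm]]
    } else val <= criteria$thresholds[[nm]]
  }
  if (!is.null(criteria$locations))
    keep <- keep & cohort$location %in% criteria$locations
  keep
}

#' Linear regression of a metabolite level on tumor purity
#'
#' Ordinary least squares of per-sample levels against the cancer-cell
#' percentage, with the Pearson correlation (two-sided p value) and
#' mean-response confidence intervals at requested purity values computed
#' from the t distribution. Extrapolation to 0% and 100% estimates the level
#' in pure intratumoral fibrotic stroma and pure cancer tissue respectively;
#' the observed purity range is stored so extrapolations can be reported in
#' context.
#'
#' @param levels numeric per-sample metabolite levels.
#' @param purity_percent per-sample cancer-cell percentages in `[0, 100]`.
#' @param at purity values (percent) at which predictions and confidence
#'   intervals are evaluated.
#' @param level confidence level for the reported interval.
#' @param metabolite optional label.
#' @param interval `"confidence"` (mean response, default) or
#'   `"prediction"`.
#' @param sample_ids optional ids used when reporting excluded points.
#' @return object of class `purity_regression`: fields `metabolite`, `n`,
#'   `slope`, `intercept`, `pearson_r`, `p_value`, `residual_se`,
#'   `purity_range`, `predictions` (data.frame purity/estimate/ci_lo/ci_hi/
#'   level), `excluded_points`, and the underlying `lm` fit.
#' @export
fit_purity_regression <- function(levels, purity_percent, at = c(0, 60, 100),
                                  level = 0.95, metabolite = "metabolite",
                                  interval = c("confidence", "prediction"),
                                  sample_ids = NULL) {
  interval <- match.arg(interval)
  stopifnot(length(levels) == length(purity_percent))
  if (any(purity_percent < 0 | purity_percent > 100))
    stop("purity must be in [0, 100] percent")
  n <- length(levels)
  if (n < 5) stop("at least 5 samples are required")
  if (stats::sd(purity_percent) < .Machine$double.eps^0.5)
    stop("purity is constant; regression undefined")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  d <- data.frame(level_ = levels, purity_ = purity_percent)
  fit <- stats::lm(level_ ~ purity_, data = d)
  ct <- stats::cor.test(purity_percent, levels)
  pr <- stats::predict(fit, data.frame(purity_ = at), interval = interval,
                       level = level)
  out <- structure(list(
    metabolite = metabolite, n = n,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = unname(ct$estimate), p_value = ct$p.value,
    # summary.lm warns on an exactly collinear fit; the sigma is still valid
    residual_se = suppressWarnings(summary(fit)$sigma),
    purity_range = range(purity_percent),
    predictions = data.frame(purity = at, estimate = pr[, "fit"],
                             ci_lo = pr[, "lwr"], ci_hi = pr[, "upr"],
                             level = level),
    excluded_points = data.frame(sample_id = character(),
                                 std_residual = numeric(),
                                 cooks_d = numeric()),
    interval = interval, ci_level = level,
    sample_ids = sample_ids, fit = fit),
    class = "purity_regression")
  out
}

#' Flag and exclude influential outliers from a purity regression
#'
#' A point is excluded only when it is extreme on both diagnostics: absolute
#' standardized residual above `std_residual_threshold` and Cook's distance
#' above `cooks_threshold`. Excluded points are recorded with their
#' diagnostics and the regression is refitted without them.
#'
#' @param fit a [fit_purity_regression()] object.
#' @param std_residual_threshold standardized-residual threshold (default 3).
#' @param cooks_threshold Cook's distance threshold (default 1).
#' @return a refitted `purity_regression` with `excluded_points` filled in
#'   (the input fit unchanged when nothing is flagged).
#' @export
flag_outliers <- function(fit, std_residual_threshold = 3.0,
                          cooks_threshold = 1.0) {
  stopifnot(inherits(fit, "purity_regression"))
  sr <- stats::rstandard(fit$fit)
  cd <- stats::cooks.distance(fit$fit)
  bad <- abs(sr) > std_residual_threshold & cd > cooks_threshold
  if (!any(bad)) return(fit)
  if (fit$n - sum(bad) < 5)
    stop("outlier removal would leave fewer than 5 samples; nothing removed")
  d <- fit$fit$model
  keep <- !bad
  refit <- fit_purity_regression(d$level_[keep], d$purity_[keep],
                                 at = fit$predictions$purity,
                                 level = fit$ci_level,
                                 metabolite = fit$metabolite,
                                 interval = fit$interval,
                                 sample_ids = fit$sample_ids[keep])
  refit$excluded_points <- data.frame(sample_id = fit$sample_ids[bad],
                                      std_residual = unname(sr[bad]),
                                      cooks_d = unname(cd[bad]))
  message(sprintf("%s: excluded %d point(s) (|std res| > %.1f and Cook's D > %.1f)",
                  fit$metabolite, sum(bad), std_residual_threshold,
                  cooks_threshold))
  refit
}

#' Adjust extratumoral reference levels for fatty-tissue content
#'
#' The extratumoral connective-tissue reference samples contain a non-zero
#' fat fraction; their levels are projected to 0% fat using the slope of a
#' linear calibration of level against fat percentage fitted on peritumoral
#' specimens spanning a wide fat range:
#' `adjusted_i = level_i - slope * fat_percent_i`.
#'
#' @param reference_levels levels of the reference samples.
#' @param fat_percent fat percentages of the reference samples.
#' @param calibration_levels,calibration_fat calibration specimens (levels
#'   and fat percentages); a fat range narrower than 10 percentage points
#'   triggers an extrapolation warning.
#' @return numeric adjusted levels, with attributes `slope` and `fit`.
#' @export
adjust_for_fat <- function(reference_levels, fat_percent,
                           calibration_levels, calibration_fat) {
  stopifnot(length(reference_levels) == length(fat_percent),
            length(calibration_levels) == length(calibration_fat))
  if (diff(range(calibration_fat)) < 10)
    warning("extrapolation unstable: calibration fat range below 10 percentage points")
  cal <- stats::lm(calibration_levels ~ calibration_fat)
  slope <- unname(stats::coef(cal)[2])
  structure(reference_levels - slope * fat_percent, slope = slope, fit = cal)
}

ci_disjoint <- function(a_lo, a_hi, b_lo, b_hi) a_hi < b_lo || b_hi < a_lo

mean_ci <- function(x, level) {
  n <- length(x)
  m <- mean(x)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Compare intratumoral stroma against the extratumoral reference
#'
#' The stroma estimate is the purity regression extrapolated to 0% cancer
#' content with its mean-response confidence interval; the reference is the
#' mean of the fat-adjusted extratumoral connective-tissue levels with a
#' t-based confidence interval. The verdict follows the two-level overlap
#' rule: `significant` when the 95% intervals are disjoint, `trend` when
#' only the 90% intervals are disjoint, otherwise `ns`.
#'
#' @param fit a `purity_regression` with predictions at 0%.
#' @param reference_levels fat-adjusted reference levels (n >= 3).
#' @return object of class `compartment_comparison`: `metabolite`,
#'   `stroma_estimate`, `stroma_ci95/90`, `reference_mean`,
#'   `reference_ci95/90`, `verdict`.
#' @export
compare_compartments <- function(fit, reference_levels) {
  stopifnot(inherits(fit, "purity_regression"))
  if (length(reference_levels) < 3)
    stop("at least 3 reference samples are required")
  d <- fit$fit$model
  band <- function(lv) {
    pr <- stats::predict(fit$fit, data.frame(purity_ = 0),
                         interval = fit$interval, level = lv)
    c(pr[1, "lwr"], pr[1, "upr"])
  }
  s95 <- band(0.95); s90 <- band(0.90)
  r95 <- mean_ci(reference_levels, 0.95)
  r90 <- mean_ci(reference_levels, 0.90)
  verdict <- if (ci_disjoint(s95[1], s95[2], r95["lo"], r95["hi"])) "significant"
    else if (ci_disjoint(s90[1], s90[2], r90["lo"], r90["hi"])) "trend"
    else "ns"
  structure(list(metabolite = fit$metabolite,
                 stroma_estimate = unname(fit$intercept),
                 stroma_ci95 = unname(s95), stroma_ci90 = unname(s90),
                 reference_mean = unname(r95["mean"]),
                 reference_ci95 = unname(r95[c("lo", "hi")]),
                 reference_ci90 = unname(r90[c("lo", "hi")]),
                 verdict = verdict),
            class = "compartment_comparison")
}

#' Grade contrast at a chosen purity
#'
#' Compares two per-grade purity regressions (typically grade I versus grade
#' II/III) through the overlap of their mean-response confidence intervals
#' at `at_purity` percent cancer cells (60% by default): `significant` when
#' the 95% intervals are disjoint, `trend` when only the 90% ones are,
#' otherwise `ns`. A group fitted on fewer than 5 samples yields
#' `insufficient`.
#'
#' @param fit_a,fit_b `purity_regression` fits for the two grade groups.
#' @param at_purity contrast purity in percent.
#' @return list with the two interval sets and the `verdict`.
#' @export
grade_contrast <- function(fit_a, fit_b, at_purity = 60) {
  if (!inherits(fit_a, "purity_regression") ||
      !inherits(fit_b, "purity_regression") || fit_a$n < 5 || fit_b$n < 5)
    return(list(verdict = "insufficient"))
  band <- function(f, lv) {
    pr <- stats::predict(f$fit, data.frame(purity_ = at_purity),
                         interval = "confidence", level = lv)
    c(pr[1, "fit"], pr[1, "lwr"], pr[1, "upr"])
  }
  a95 <- band(fit_a, 0.95); b95 <- band(fit_b, 0.95)
  a90 <- band(fit_a, 0.90); b90 <- band(fit_b, 0.90)
  verdict <- if (ci_disjoint(a95[2], a95[3], b95[2], b95[3])) "significant"
    else if (ci_disjoint(a90[2], a90[3], b90[2], b90[3])) "trend"
    else "ns"
  list(at_purity = at_purity,
       estimate_a = a95[1], ci95_a = a95[2:3],
       estimate_b = b95[1], ci95_b = b95[2:3],
       verdict = verdict)
}

#' Homogeneity-of-slopes test
#'
#' F test of the purity-by-group interaction: the separate-slopes linear
#' model `level ~ purity * group` against the common-slope model
#' `level ~ purity + group`. A small p value indicates that the
#' purity-level relationship differs between the groups (e.g. luminal A
#' versus luminal B tumors).
#'
#' @param levels per-sample metabolite levels.
#' @param purity_percent per-sample cancer-cell percentages.
#' @param group_labels group factor (>= 2 groups, each with >= 5 samples).
#' @return list with `p_value`, `F`, `df`, and the two fitted models.
#' @export
homogeneity_of_slopes <- function(levels, purity_percent, group_labels) {
  g <- droplevels(factor(group_labels))
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (any(table(g) < 5)) stop("each group needs at least 5 samples")
  d <- data.frame(level_ = levels, purity_ = purity_percent, group_ = g)
  full <- stats::lm(level_ ~ purity_ * group_, data = d)
  if (any(!is.finite(stats::coef(full))))
    stop("singular design in homogeneity-of-slopes test")
  reduced <- stats::lm(level_ ~ purity_ + group_, data = d)
  an <- stats::anova(reduced, full)
  list(p_value = an[2, "Pr(>F)"], F = an[2, "F"],
       df = c(an[2, "Df"], an[2, "Res.Df"]), full = full, reduced = reduced)
}

#' Flag polyethylene-glycol contaminated samples
#'
#' Specimens exposed to OCT fixative show a prominent PEG singlet near
#' 3.70 ppm whose intensity corrupts the neighbouring succinate and
#' glutamate regions. Samples whose PEG-region integral exceeds `multiple`
#' times the cohort median are flagged for exclusion from those analyses.
#'
#' @param peg_integrals per-sample PEG-region integrals.
#' @param multiple threshold as a multiple of the cohort median.
#' @return logical vector: `TRUE` marks contaminated samples.
#' @export
flag_peg_contamination <- function(peg_integrals, multiple = 5) {
  med <- stats::median(peg_integrals)
  ref <- if (med > 0) med else mean(peg_integrals)  # mostly-clean cohorts
  if (ref <= 0) return(rep(FALSE, length(peg_integrals)))
  out <- peg_integrals > multiple * ref
  if (any(out))
    message("flagged ", sum(out), " PEG-contaminated sample(s)")
  out
}
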
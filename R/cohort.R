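# Tissue classes tracked for every specimen. All cohort tables carry these as
# percent columns summing to 100 per sample.
TISSUE_CLASSES <- c("cancer", "intratumoral_fibrosis", "extratumoral_connective",
                    "fat", "glandular", "immune", "necrosis")

LOCATIONS <- c("T", "TB", "N_lt1cm", "N_eq1cm", "N_gt1cm")

# Piecewise-linear quantile law through (min, q1, median, q3, max), percent.
qlaw <- function(u, q) {
  stats::approx(c(0, 0.25, 0.5, 0.75, 1), q, xout = u, ties = "ordered")$y
}

# Sparse tail law: zero with probability p0, then a power ramp up to `max`.
# Used for tissue classes whose quartiles are all zero but whose maximum is not.
tail_law <- function(u, p0, max, pow = 2) {
  ifelse(u <= p0, 0, max * ((u - p0) / (1 - p0))^pow)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study design of the emulated cohort: per-location
#' specimen counts (38 tumor, 11 tumor-border, 26/30/35 at increasing distance
#' from the tumor border, 140 in total across 39 patients), specimen weights
#' 13.8 +/- 2.8 mg truncated at 5 mg, and the clinical frequency tables for
#' histological grade and intrinsic subtype.
#'
#' @param counts named integer vector of specimens per location. Names must be
#'   `T`, `TB`, `N_lt1cm`, `N_eq1cm`, `N_gt1cm`.
#' @param n_patients number of patients the specimens are attributed to.
#' @param weight_mean,weight_sd,weight_min mean, SD (mg) and truncation bound
#'   of the Gaussian specimen-weight model.
#' @param grade_probs named probabilities for histological grade
#'   (`I`, `II`, `III`, `missing`), drawn per patient.
#' @param subtype_probs named probabilities for intrinsic subtype, drawn per
#'   patient.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(counts = c("T" = 38L, "TB" = 11L, "N_lt1cm" = 26L,
                                     "N_eq1cm" = 30L, "N_gt1cm" = 35L),
                          n_patients = 39L,
                          weight_mean = 13.8, weight_sd = 2.8, weight_min = 5,
                          grade_probs = c(I = 11, II = 21, III = 6, missing = 1) / 39,
                          subtype_probs = c(luminalA = 22, luminalB_her2neg = 11,
                                            luminalB_her2pos = 3, HER2 = 1,
                                            TNBC = 2) / 39) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("per-location counts must be non-negative integers")
  if (!all(names(counts) %in% LOCATIONS))
    stop("unknown location in counts: ",
         paste(setdiff(names(counts), LOCATIONS), collapse = ", "))
  if (weight_mean <= 0 || weight_sd <= 0 || weight_min <= 0)
    stop("weight model parameters must be positive")
  stopifnot(abs(sum(grade_probs) - 1) < 1e-8, abs(sum(subtype_probs) - 1) < 1e-8)
  structure(list(counts = counts, n_patients = n_patients,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_min = weight_min, grade_probs = grade_probs,
                 subtype_probs = subtype_probs),
            class = "cohort_config")
}

# --- per-location composition samplers ------------------------------------
#
# Each sampler returns an n x 7 matrix of percent compositions summing to 100.
# The samplers are calibrated so that, marginally per location, sample medians
# (and roughly the quartiles) approximate the histological composition
# statistics of the emulated cohort. Locations close to or inside the tumor
# are anchored on a cancer-fraction quantile law; peritumoral locations are
# mixtures of specimen archetypes (tumor tissue, fatty, connective-dominant,
# mixed), since no single unimodal law reproduces their marginal quartiles.

sample_comp_T <- function(n) {
  u <- matrix(stats::runif(n * 6), n)
  cancer <- qlaw(u[, 1], c(0, 10, 30, 40, 75))
  conn  <- tail_law(u[, 2], 0.94, 95, 3)
  fat   <- tail_law(u[, 3], 0.75, 45, 3)
  gland <- tail_law(u[, 4], 0.94, 20, 2)
  imm   <- tail_law(u[, 5], 0.93, 50, 3)
  necr  <- tail_law(u[, 6], 0.94, 30, 2)
  extra <- cbind(conn, fat, gland, imm, necr)
  room <- 100 - cancer
  s <- pmin(1, room / pmax(rowSums(extra), 1e-12))
  extra <- extra * s
  fib <- 100 - cancer - rowSums(extra)
  cbind(cancer, fib, extra)
}

sample_comp_TB <- function(n) {
  u <- matrix(stats::runif(n * 8), n)
  cancer <- qlaw(u[, 1], c(0, 0, 3, 25, 30))
  # border samples are a mixture of tumor-tissue-dominated specimens and
  # peritumoral (fat/connective) ones
  tumor_mode <- u[, 2] < 0.42
  share_fib <- ifelse(tumor_mode,
                      qlaw(u[, 3], c(0.5, 0.7, 0.85, 0.95, 1)),
                      qlaw(u[, 3], c(0, 0, 0.05, 0.2, 0.4)))
  fib <- (100 - cancer) * share_fib
  rem <- 100 - cancer - fib
  imm   <- pmin(qlaw(u[, 4], c(0, 0, 5, 5, 25)), rem * 0.3)
  gland <- pmin(tail_law(u[, 5], 0.9, 15, 2), rem * 0.1)
  necr  <- pmin(tail_law(u[, 6], 0.9, 20, 2), rem * 0.1)
  rem2 <- rem - imm - gland - necr
  # the peritumoral remainder is either fat- or connective-dominant
  conn_dom <- !tumor_mode & u[, 8] < 0.3
  fat_share <- ifelse(conn_dom, stats::qbeta(u[, 7], 1, 4),
                      stats::qbeta(u[, 7], 6, 1))
  fat_share[tumor_mode] <- u[tumor_mode, 7]^(1 / 1.2)
  fat <- rem2 * fat_share
  conn <- rem2 * (1 - fat_share)
  cbind(cancer, fib, conn, fat, gland, imm, necr)
}

sample_comp_N_lt1cm <- function(n) {
  u <- matrix(stats::runif(n * 5), n)
  type <- cut(u[, 1], c(0, 0.47, 0.75, 0.85, 1), labels = FALSE)
  cancer <- fib <- conn <- fat <- gland <- numeric(n)
  i <- type == 1  # tumor tissue present (with cancer cells in 9/26 of samples)
  cancer[i] <- ifelse(u[i, 5] < (9 / 26) / 0.47,
                      qlaw(u[i, 2], c(1, 5, 15, 35, 50)), 0)
  fib[i] <- pmin(qlaw(u[i, 3], c(20, 40, 60, 85, 95)), 100 - cancer[i])
  sp <- sqrt(u[i, 4])  # fat-leaning split of the non-tumor remainder
  fat[i] <- (100 - cancer[i] - fib[i]) * sp
  conn[i] <- (100 - cancer[i] - fib[i]) * (1 - sp)
  i <- type == 2  # fatty
  f <- ifelse(u[i, 2] < 0.40, 100, qlaw(u[i, 3], c(60, 75, 90, 98, 100)))
  fat[i] <- f; conn[i] <- (100 - f) * 0.8; gland[i] <- (100 - f) * 0.2
  i <- type == 3  # connective-dominant
  cc <- qlaw(u[i, 2], c(55, 70, 82, 90, 100))
  conn[i] <- cc; fat[i] <- (100 - cc) * 0.85; gland[i] <- (100 - cc) * 0.15
  i <- type == 4  # mixed fat/connective/glandular
  a <- cbind(-log(u[i, 2]) * 2, -log(u[i, 3]) * 1.6, -log(u[i, 4]) * 0.3)
  a <- a / rowSums(a) * 100
  fat[i] <- a[, 1]; conn[i] <- a[, 2]; gland[i] <- a[, 3]
  cbind(cancer, fib, conn, fat, gland, 0, 0)
}

sample_comp_N_eq1cm <- function(n) {
  u <- matrix(stats::runif(n * 6), n)
  type <- cut(u[, 1], c(0, 0.52, 0.74, 1), labels = FALSE)
  conn <- fat <- gland <- cancer <- numeric(n)
  i <- type == 1  # fat-dominant
  f <- ifelse(u[i, 2] < 0.35, 100, qlaw(u[i, 3], c(55, 75, 88, 97, 100)))
  fat[i] <- f; conn[i] <- (100 - f) * 0.85; gland[i] <- (100 - f) * 0.15
  i <- type == 2  # connective-dominant
  cc <- qlaw(u[i, 2], c(55, 70, 85, 95, 100))
  conn[i] <- cc; fat[i] <- (100 - cc) * 0.9; gland[i] <- (100 - cc) * 0.1
  i <- type == 3  # mixed
  a <- cbind(-log(u[i, 2]) * 2.0, -log(u[i, 3]) * 2.0, -log(u[i, 4]) * 0.3)
  a <- a / rowSums(a) * 100
  fat[i] <- a[, 1]; conn[i] <- a[, 2]; gland[i] <- a[, 3]
  # roughly 1 in 30 samples at this distance carries a trace of cancer cells
  j <- u[, 5] < 1 / 30
  cancer[j] <- 1 + 4 * u[j, 6]
  sc <- 100 / (cancer + conn + fat + gland)
  cbind(cancer * sc, 0, conn * sc, fat * sc, gland * sc, 0, 0)
}

sample_comp_N_gt1cm <- function(n) {
  u <- matrix(stats::runif(n * 3), n)
  conn <- fat <- gland <- numeric(n)
  i <- u[, 1] < 0.52  # pure fat specimens
  fat[i] <- 100
  j <- !i
  f <- qlaw(u[j, 2], c(0, 25, 55, 80, 95))
  g <- pmin(tail_law(u[j, 3], 0.7, 10, 2), 100 - f)
  fat[j] <- f; gland[j] <- g; conn[j] <- 100 - f - g
  cbind(0, 0, conn, fat, gland, 0, 0)
}

sample_composition <- function(location, n) {
  f <- switch(location,
              "T" = sample_comp_T, "TB" = sample_comp_TB,
              "N_lt1cm" = sample_comp_N_lt1cm, "N_eq1cm" = sample_comp_N_eq1cm,
              "N_gt1cm" = sample_comp_N_gt1cm)
  m <- f(n)
  colnames(m) <- TISSUE_CLASSES
  m
}

#' Generate a synthetic histology cohort
#'
#' Draws a cohort of tissue specimens whose per-location counts, histological
#' compositions, specimen weights and clinical covariates mimic a
#' breast-conserving-surgery HR-MAS NMR study: multiple specimens per patient
#' from the tumor (`T`), tumor border (`TB`) and normal-appearing tissue at
#' three distances from the tumor border. Compositions are drawn from
#' per-location samplers calibrated to the composition quartiles of such a
#' cohort (tumor-location samples: median 30% cancer cells and 70%
#' intratumoral fibrotic stroma). Specimens excised beyond 1 cm from the
#' tumor border never contain cancer cells.
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(config, seed)`.
#' @return a `data.frame` with one row per specimen: `sample_id`,
#'   `patient_id`, `location`, `weight_mg`, one percent column per tissue
#'   class (summing to 100), `grade`, `subtype`, `fibrosis_grade` and
#'   `histology_available`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  counts <- config$counts[config$counts > 0]
  n <- sum(counts)
  if (n == 0L) {
    out <- empty_cohort()
    return(out)
  }
  loc <- rep(names(counts), counts)
  comp <- do.call(rbind, lapply(names(counts), function(l)
    sample_composition(l, counts[[l]])))

  # patients and their clinical covariates
  grade_lv <- c("I", "II", "III", "missing")
  subtype_lv <- names(config$subtype_probs)
  pat_grade <- sample(grade_lv, config$n_patients, TRUE, config$grade_probs)
  pat_subtype <- sample(subtype_lv, config$n_patients, TRUE, config$subtype_probs)
  patient <- sample.int(config$n_patients, n, replace = TRUE)

  weight <- rtruncnorm(n, config$weight_mean, config$weight_sd, config$weight_min)

  # fibrosis grading: intratumoral fibrotic stroma is predominantly grade 2-3,
  # extratumoral fibrous connective tissue grade 1
  fibg <- rep("none", n)
  has_if <- comp[, "intratumoral_fibrosis"] > 0
  fibg[has_if] <- sample(c("1", "2", "3"), sum(has_if), TRUE, c(0.1, 0.5, 0.4))
  only_ec <- !has_if & comp[, "extratumoral_connective"] > 0
  fibg[only_ec] <- sample(c("1", "2"), sum(only_ec), TRUE, c(0.9, 0.1))

  out <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    patient_id = sprintf("P%02d", patient),
    location = factor(loc, levels = LOCATIONS),
    weight_mg = weight,
    comp,
    grade = factor(pat_grade[patient], levels = grade_lv),
    subtype = factor(pat_subtype[patient], levels = subtype_lv),
    fibrosis_grade = factor(fibg, levels = c("1", "2", "3", "none")),
    histology_available = TRUE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("stromanmr_cohort", "data.frame")
  out
}

empty_cohort <- function() {
  out <- data.frame(sample_id = character(), patient_id = character(),
                    location = factor(character(), levels = LOCATIONS),
                    weight_mg = numeric())
  for (cl in TISSUE_CLASSES) out[[cl]] <- numeric()
  out$grade <- factor(character(), levels = c("I", "II", "III", "missing"))
  out$subtype <- factor(character())
  out$fibrosis_grade <- factor(character(), levels = c("1", "2", "3", "none"))
  out$histology_available <- logical()
  class(out) <- c("stromanmr_cohort", "data.frame")
  out
}

# Normal(mean, sd) truncated below at `lo`, by resampling.
rtruncnorm <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo
  }
  x
}

#' Intrinsic subtype from immunohistochemistry results
#'
#' Applies the standard immunohistochemical surrogate classification:
#' luminal A is hormone-receptor positive (ER and/or PR), HER2-negative with
#' Ki-67 below 14%; luminal B (HER2-negative) the same with Ki-67 >= 14%;
#' luminal B (HER2-positive) is hormone-receptor positive and HER2-positive;
#' HER2 type is hormone-receptor negative and HER2-positive; triple-negative
#' (TNBC) is negative for all three receptors.
#'
#' @param er,pr,her2 logical receptor status vectors.
#' @param ki67_percent Ki-67 labeling index in percent, in `[0, 100]`.
#' @return factor with levels `luminalA`, `luminalB_her2neg`,
#'   `luminalB_her2pos`, `HER2`, `TNBC`.
#' @export
classify_subtype <- function(er, pr, her2, ki67_percent) {
  if (any(ki67_percent < 0 | ki67_percent > 100))
    stop("ki67_percent must be in [0, 100]")
  hr <- er | pr
  out <- ifelse(hr & !her2 & ki67_percent < 14, "luminalA",
         ifelse(hr & !her2, "luminalB_her2neg",
         ifelse(hr & her2, "luminalB_her2pos",
         ifelse(her2, "HER2", "TNBC"))))
  factor(out, levels = c("luminalA", "luminalB_her2neg", "luminalB_her2pos",
                         "HER2", "TNBC"))
}
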
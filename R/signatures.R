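# Compartment metabolite signatures and the linear mixing model.

METABOLITES <- c("glucose", "lactate", "phosphoethanolamine", "phosphocholine",
                 "taurine", "glycine", "ascorbate", "creatine", "succinate",
                 "glutamate", "glutamine", "glycerophosphocholine", "choline",
                 "myo_inositol", "scyllo_inositol")
LIPID_VARS <- c("lip_09", "lip_13", "lip_203", "lip_278")

#' Default compartment signature set
#'
#' Per-compartment metabolite levels (spectral-integral units per mg) used by
#' the mixing model, grade modifiers applied to the cancer compartment, and
#' the multiplicative noise level. The values are plausible for breast tissue
#' (small-molecule metabolites concentrated in cancer cells, intermediate in
#' fibrotic stroma, low in fat; glucose depleted in cancer; lipid signals
#' dominated by fatty tissue) but are editable defaults of the generator,
#' not measured reference values.
#'
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise applied to every mixed level. The default 0.2 reproduces the
#'   moderate purity-metabolite correlations (|r| roughly 0.4-0.8) typical of
#'   region integrals from intact-tissue spectra.
#' @param grade_modifiers named numeric vector of multiplicative factors
#'   applied to cancer-compartment levels in grade II/III tumors.
#' @return an object of class `signature_set`: list with `levels`
#'   (compartment x variable matrix), `grade_modifiers`, `noise_cv`.
#' @export
default_signatures <- function(noise_cv = 0.2,
                               grade_modifiers = c(lactate = 1.5, taurine = 1.4,
                                                   phosphoethanolamine = 1.5,
                                                   glycine = 1.5, glutamate = 1.4,
                                                   creatine = 1.3)) {
  vars <- c(METABOLITES, LIPID_VARS)
  m <- matrix(0, nrow = length(TISSUE_CLASSES), ncol = length(vars),
              dimnames = list(TISSUE_CLASSES, vars))
  #                         cancer   IF    EC    fat  gland  imm  necr
  m[, "glucose"]               <- c(1.0,  2.5,  3.0, 0.30, 2.0, 1.0, 0.5)
  m[, "lactate"]               <- c(6.0,  3.0,  1.5, 0.40, 2.0, 2.5, 2.0)
  m[, "phosphoethanolamine"]   <- c(4.0,  1.5,  0.8, 0.10, 1.5, 1.0, 0.8)
  m[, "phosphocholine"]        <- c(5.0,  1.5,  0.7, 0.10, 1.2, 1.0, 0.8)
  m[, "taurine"]               <- c(5.5,  2.0,  1.0, 0.20, 2.0, 1.5, 1.0)
  m[, "glycine"]               <- c(4.5,  1.8,  0.9, 0.15, 1.5, 1.2, 0.9)
  m[, "ascorbate"]             <- c(2.5,  1.2,  0.6, 0.10, 1.0, 0.8, 0.5)
  m[, "creatine"]              <- c(3.5,  1.6,  0.8, 0.15, 1.4, 1.0, 0.7)
  m[, "succinate"]             <- c(1.8,  1.0,  0.4, 0.05, 0.6, 0.8, 0.6)
  m[, "glutamate"]             <- c(3.0,  1.6,  0.7, 0.10, 1.2, 1.2, 0.8)
  m[, "glutamine"]             <- c(2.8,  1.3,  0.7, 0.10, 1.1, 1.0, 0.7)
  m[, "glycerophosphocholine"] <- c(1.5,  1.2,  0.9, 0.20, 1.3, 0.9, 0.6)
  m[, "choline"]               <- c(1.8,  1.1,  0.6, 0.15, 0.9, 0.8, 0.6)
  m[, "myo_inositol"]          <- c(3.0,  1.8,  0.9, 0.15, 1.6, 1.1, 0.8)
  m[, "scyllo_inositol"]       <- c(0.8,  0.5, 0.25, 0.05, 0.4, 0.3, 0.2)
  m[, "lip_09"]                <- c(1.0,  2.0,  3.0, 30.0, 2.0, 1.0, 2.0)
  m[, "lip_13"]                <- c(2.0,  4.0,  6.0, 60.0, 4.0, 2.0, 4.0)
  m[, "lip_203"]               <- c(0.5,  1.0,  1.5, 12.0, 1.0, 0.5, 1.0)
  m[, "lip_278"]               <- c(0.3,  0.6,  0.8,  6.0, 0.5, 0.3, 0.5)
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (any(grade_modifiers <= 0)) stop("grade modifiers must be positive")
  structure(list(levels = m, grade_modifiers = grade_modifiers,
                 noise_cv = noise_cv),
            class = "signature_set")
}

#' Mix compartment signatures into per-sample metabolite levels
#'
#' The linear compartment-mixing model: for each sample the level of variable
#' m is `sum_c fraction_c * s[c, m]` (cancer-compartment levels multiplied by
#' the grade modifier for grade II/III tumors), scaled by multiplicative
#' log-normal noise `exp(e)`, `e ~ N(0, sigma^2)` with
#' `sigma^2 = log(1 + cv^2)` so that the noise coefficient of variation is
#' `noise_cv`. With `noise_cv = 0` the output is an exact convex combination
#' of the compartment signatures.
#'
#' @param cohort cohort `data.frame` from [generate_cohort()] (percent tissue
#'   columns).
#' @param signatures a [default_signatures()] object.
#' @param seed integer seed; levels are deterministic given
#'   `(cohort, signatures, seed)`.
#' @return numeric matrix, samples x variables, rownames = `sample_id`.
#' @export
mix_samples <- function(cohort, signatures = default_signatures(), seed = 1L) {
  stopifnot(inherits(signatures, "signature_set"))
  missing_cls <- setdiff(TISSUE_CLASSES, rownames(signatures$levels))
  if (length(missing_cls))
    stop("missing compartment signature: ", paste(missing_cls, collapse = ", "))
  frac <- as.matrix(cohort[, TISSUE_CLASSES, drop = FALSE]) / 100
  if (nrow(frac) && any(abs(rowSums(frac) - 1) > 1e-9))
    stop("tissue fractions must sum to 100 percent")
  set.seed(as.integer(seed))
  sig <- signatures$levels[TISSUE_CLASSES, , drop = FALSE]
  # grade II/III modifier acts on the cancer compartment only
  high <- !is.na(cohort$grade) & cohort$grade %in% c("II", "III")
  gm <- rep(1, ncol(sig)); names(gm) <- colnames(sig)
  gm[names(signatures$grade_modifiers)] <- signatures$grade_modifiers
  base <- frac %*% sig
  if (any(high)) {
    extra <- outer(frac[, "cancer"] * high, gm - 1) *
      matrix(sig["cancer", ], nrow(frac), ncol(sig), byrow = TRUE)
    base <- base + extra
  }
  if (signatures$noise_cv > 0) {
    sigma <- sqrt(log(1 + signatures$noise_cv^2))
    base <- base * exp(matrix(stats::rnorm(length(base), 0, sigma),
                              nrow(base), ncol(base)))
  }
  rownames(base) <- cohort$sample_id
  base
}

#' Default peak table for spectrum synthesis
#'
#' Representative resonances for each quantified variable: chemical-shift
#' centers (ppm), Lorentzian halfwidths (HWHM, ppm) and relative areas.
#' Small-molecule metabolite resonances populate the CPMG channel and the
#' residual lipid signals the diffusion-edited (DIFF) channel; the formate
#' chemical-shift reference sits at 8.44 ppm and an optional polyethylene
#' glycol contaminant singlet at 3.70 ppm.
#'
#' @param halfwidth default halfwidth (HWHM) in ppm for all peaks.
#' @return `data.frame` with columns `metabolite`, `center_ppm`,
#'   `halfwidth_ppm`, `relative_area`, `channel`.
#' @export
default_peak_table <- function(halfwidth = 0.005) {
  stopifnot(halfwidth > 0)
  tab <- data.frame(
    metabolite = c("glucose", "ascorbate", "lactate", "myo_inositol",
                   "phosphoethanolamine", "creatine", "glycine", "taurine",
                   "scyllo_inositol", "glycerophosphocholine",
                   "phosphocholine", "choline", "glutamine", "succinate",
                   "glutamate", "lip_09", "lip_13", "lip_203", "lip_278"),
    center_ppm = c(5.23, 4.52, 4.11, 4.06, 3.98, 3.93, 3.55, 3.42, 3.35,
                   3.23, 3.22, 3.20, 2.45, 2.41, 2.35,
                   0.90, 1.30, 2.03, 2.78),
    halfwidth_ppm = halfwidth,
    relative_area = 1,
    channel = c(rep("CPMG", 15), rep("DIFF", 4)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(tab$center_ppm >= 0 & tab$center_ppm <= 10),
            !anyDuplicated(tab[, c("metabolite", "center_ppm")]))
  tab
}

# Unit-area Lorentzian (HWHM gamma) evaluated on x.
lorentzian <- function(x, center, gamma) {
  (gamma / pi) / ((x - center)^2 + gamma^2)
}

# Generalized (power) Lorentzian with shape exponent m in [1, 2]:
# amp * [gamma^2 / (gamma^2 + (x-c)^2)]^m. Area = amp * gamma * beta(m - 1/2, 1/2).
gen_lorentzian <- function(x, amp, center, gamma, shape) {
  amp * (gamma^2 / (gamma^2 + (x - center)^2))^shape
}

gen_lorentzian_area <- function(amp, gamma, shape) {
  amp * gamma * beta(shape - 0.5, 0.5)
}

#' Synthesize a 1D NMR spectrum from metabolite levels
#'
#' Builds a frequency-domain spectrum as a sum of unit-area Lorentzian lines:
#' each variable contributes `level * relative_area` of integrated intensity
#' at its assigned chemical shift. A formate reference singlet and an
#' optional polyethylene glycol contaminant singlet can be added, and the
#' whole pattern can be translated by a global ppm offset (emulating an
#' uncalibrated chemical-shift axis). The metabolite part of the spectrum is
#' linear in `levels`.
#'
#' @param levels named numeric vector of variable levels (integral units).
#' @param peaks peak table as from [default_peak_table()]; only peaks whose
#'   `metabolite` appears in `names(levels)` are synthesized.
#' @param axis ppm axis (strictly monotone; NMR convention is descending).
#' @param ppm_offset global chemical-shift offset added to every peak center.
#' @param formate_area area of the formate reference singlet at 8.44 ppm
#'   (0 suppresses it).
#' @param peg_area area of the polyethylene glycol contaminant singlet at
#'   3.70 ppm (default 0: absent).
#' @param sample_id,weight_mg metadata stored on the spectrum.
#' @return object of class `stromanmr_spectrum`: list with `ppm`,
#'   `intensity`, `sample_id`, `weight_mg`.
#' @export
synthesize_spectrum <- function(levels, peaks = default_peak_table(),
                                axis = seq(10, 0, by = -0.001),
                                ppm_offset = 0, formate_area = 1,
                                peg_area = 0, sample_id = "synthetic",
                                weight_mg = 13.8) {
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) stop("axis must be strictly monotone")
  if (any(peaks$halfwidth_ppm <= 0)) stop("halfwidths must be positive")
  intensity <- numeric(length(axis))
  use <- peaks[peaks$metabolite %in% names(levels), , drop = FALSE]
  centers <- c(use$center_ppm, 8.44, 3.70) + ppm_offset
  areas <- c(levels[use$metabolite] * use$relative_area, formate_area, peg_area)
  widths <- c(use$halfwidth_ppm, 0.003, 0.004)
  keep <- areas != 0
  rng <- range(axis)
  if (any(centers[keep] < rng[1] | centers[keep] > rng[2]))
    warning("axis does not cover all shifted peak centers")
  for (i in which(keep))
    intensity <- intensity + areas[i] * lorentzian(axis, centers[i], widths[i])
  new_spectrum(axis, intensity, sample_id = sample_id, weight_mg = weight_mg)
}
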
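# Spectral quantitation: calibration, baseline, region integration,
# generalized-Lorentzian deconvolution of the choline region, and assembly of
# the scaled metabolite matrix.

#' Construct a spectrum object
#'
#' @param ppm strictly monotone chemical-shift axis (ppm); stored as given
#'   (NMR convention is descending).
#' @param intensity intensities, same length as `ppm`.
#' @param sample_id sample identifier.
#' @param weight_mg specimen weight in mg (positive).
#' @return object of class `stromanmr_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, sample_id = "", weight_mg = NA_real_) {
  if (length(ppm) != length(intensity)) stop("ppm and intensity lengths differ")
  if (!all(is.finite(ppm)) || !all(is.finite(intensity)))
    stop("spectrum values must be finite")
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone")
  if (!is.na(weight_mg) && weight_mg <= 0) stop("weight_mg must be positive")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 sample_id = sample_id, weight_mg = weight_mg),
            class = "stromanmr_spectrum")
}

# ascending copy for quadrature
ascending <- function(spectrum) {
  if (is.unsorted(spectrum$ppm)) {
    o <- order(spectrum$ppm)
    list(ppm = spectrum$ppm[o], intensity = spectrum$intensity[o])
  } else list(ppm = spectrum$ppm, intensity = spectrum$intensity)
}

#' Calibrate the chemical-shift axis on the formate reference
#'
#' Translates the ppm axis so that the apex of the tallest peak found inside
#' the search window lands exactly on `reference_ppm` (8.44 ppm for the
#' formate singlet added with the shimming/locking solution). Idempotent:
#' calibrating an already-calibrated spectrum is the identity up to one grid
#' step.
#'
#' @param spectrum a `stromanmr_spectrum`.
#' @param reference_ppm target position of the reference peak.
#' @param search_window numeric length-2 ppm interval searched for the apex.
#' @param noise_mult the apex must exceed `noise_mult` times the median
#'   absolute intensity in the window, otherwise no peak is declared.
#' @return the calibrated spectrum.
#' @export
calibrate_shift <- function(spectrum, reference_ppm = 8.44,
                            search_window = c(8.24, 8.64), noise_mult = 5) {
  w <- sort(search_window)
  idx <- which(spectrum$ppm >= w[1] & spectrum$ppm <= w[2])
  if (!length(idx)) stop("reference peak not found: window outside axis")
  seg <- spectrum$intensity[idx]
  floor_level <- noise_mult * stats::median(abs(seg))
  apex <- idx[which.max(seg)]
  if (!is.finite(max(seg)) || max(seg) <= floor_level || max(seg) <= 0)
    stop("reference peak not found")
  shift <- spectrum$ppm[apex] - reference_ppm
  out <- spectrum
  out$ppm <- spectrum$ppm - shift
  out
}

#' Piecewise-linear baseline correction
#'
#' Fits a baseline through the median intensity of each signal-free anchor
#' region (linear interpolation between anchor midpoints, constant
#' extrapolation beyond the outermost anchors) and subtracts it. After
#' correction the anchor medians are zero up to numerical tolerance.
#'
#' @param spectrum a `stromanmr_spectrum`.
#' @param anchor_regions list of length-2 ppm intervals containing no signal.
#' @return the corrected spectrum.
#' @export
baseline_correct <- function(spectrum,
                             anchor_regions = list(c(9.4, 9.9), c(7.0, 7.5),
                                                   c(5.6, 6.4), c(0.2, 0.5))) {
  mids <- meds <- numeric(length(anchor_regions))
  for (i in seq_along(anchor_regions)) {
    r <- sort(anchor_regions[[i]])
    idx <- spectrum$ppm >= r[1] & spectrum$ppm <= r[2]
    if (!any(idx)) stop("empty anchor region: ", paste(r, collapse = "-"))
    mids[i] <- mean(r)
    meds[i] <- stats::median(spectrum$intensity[idx])
  }
  o <- order(mids)
  base <- stats::approx(mids[o], meds[o], xout = spectrum$ppm, rule = 2,
                        ties = "ordered")$y
  out <- spectrum
  out$intensity <- spectrum$intensity - base
  out
}

#' Default spectral-region table
#'
#' Integration regions for the quantified variables: one region per
#' representative resonance, spanning +/- `n_halfwidths` halfwidths around the
#' assigned chemical shift. Region boundaries are deliberately overridable:
#' pass any table with columns `variable_name`, `ppm_lo`, `ppm_hi`,
#' `channel`, `mode`, `major_metabolite`, `minor_metabolites`.
#'
#' @param peaks peak table ([default_peak_table()]).
#' @param n_halfwidths half-window in units of the peak halfwidth.
#' @return `data.frame` region table. The crowded 3.0-3.3 ppm choline region
#'   (choline, phosphocholine, glycerophosphocholine) is marked
#'   `mode = "lorentzian_fit"`; all other regions `mode = "integral"`.
#' @export
default_region_table <- function(peaks = default_peak_table(),
                                 n_halfwidths = 2) {
  cho <- c("choline", "phosphocholine", "glycerophosphocholine")
  tab <- data.frame(
    variable_name = peaks$metabolite,
    ppm_lo = peaks$center_ppm - n_halfwidths * peaks$halfwidth_ppm,
    ppm_hi = peaks$center_ppm + n_halfwidths * peaks$halfwidth_ppm,
    channel = peaks$channel,
    mode = ifelse(peaks$metabolite %in% cho, "lorentzian_fit", "integral"),
    major_metabolite = peaks$metabolite,
    minor_metabolites = "",
    stringsAsFactors = FALSE
  )
  stopifnot(all(tab$ppm_lo < tab$ppm_hi), !anyDuplicated(tab$variable_name))
  tab
}

#' Integrate spectral regions
#'
#' Trapezoidal integration of each region of a (calibrated, baseline
#' corrected) spectrum, reported under the region's variable name.
#' Integration is linear in the spectrum.
#'
#' @param spectrum a `stromanmr_spectrum`.
#' @param regions region table (see [default_region_table()]).
#' @return named numeric vector of integrals.
#' @export
integrate_regions <- function(spectrum, regions) {
  asc <- ascending(spectrum)
  out <- numeric(nrow(regions))
  names(out) <- regions$variable_name
  for (i in seq_len(nrow(regions))) {
    lo <- regions$ppm_lo[i]; hi <- regions$ppm_hi[i]
    if (lo < min(asc$ppm) || hi > max(asc$ppm))
      stop("region outside axis: ", regions$variable_name[i])
    out[i] <- trapz_interval(asc$ppm, asc$intensity, lo, hi)
  }
  out
}

# trapezoid rule on [lo, hi] with linear interpolation at the boundaries
trapz_interval <- function(x, y, lo, hi) {
  ylo <- stats::approx(x, y, lo, ties = "ordered")$y
  yhi <- stats::approx(x, y, hi, ties = "ordered")$y
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(ylo, y[inside], yhi)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Deconvolve the crowded choline region
#'
#' Resolves the overlapping choline, phosphocholine and
#' glycerophosphocholine resonances between 3.0 and 3.3 ppm by nonlinear
#' least squares with one generalized Lorentzian per component: amplitude,
#' center, halfwidth and shape exponent (power Lorentzian, exponent
#' constrained to `[1, 2]`) are fitted per component and the fitted areas
#' returned. Several restarts with perturbed starting values are attempted
#' before giving up.
#'
#' @param spectrum a `stromanmr_spectrum`.
#' @param region length-2 ppm interval containing the three components.
#' @param component_centers named starting centers (ppm) for the components.
#' @param halfwidth_init starting halfwidth (ppm).
#' @param max_restarts number of perturbed restarts on failure.
#' @return named numeric vector of fitted areas, with attributes
#'   `residual_norm` and `fit` (the per-component parameter table).
#' @export
fit_choline_region <- function(spectrum, region = c(3.0, 3.3),
                               component_centers = c(choline = 3.20,
                                                     phosphocholine = 3.22,
                                                     glycerophosphocholine = 3.23),
                               halfwidth_init = 0.005, max_restarts = 5) {
  if (any(component_centers < region[1] | component_centers > region[2]))
    stop("component centers must lie inside the region")
  asc <- ascending(spectrum)
  idx <- asc$ppm >= region[1] & asc$ppm <= region[2]
  x <- asc$ppm[idx]; y <- asc$intensity[idx]
  k <- length(component_centers)
  zero <- structure(rep(0, k), names = names(component_centers),
                    residual_norm = 0)
  if (max(abs(y)) < .Machine$double.eps^0.5) return(zero)

  model <- function(par, x) {
    out <- numeric(length(x))
    for (j in seq_len(k)) {
      p <- par[(4 * j - 3):(4 * j)]
      out <- out + gen_lorentzian(x, p[1], p[2], p[3], p[4])
    }
    out
  }
  lower <- rep(c(0, region[1], 1e-4, 1), k)
  upper <- rep(c(Inf, region[2], 0.05, 2), k)
  amp0 <- vapply(component_centers, function(cc)
    max(y[abs(x - cc) <= 2 * halfwidth_init], 0), 0)
  best <- NULL
  for (r in 0:max_restarts) {
    start <- as.numeric(rbind(pmax(amp0 * (1 + 0.1 * r), max(y) * 0.01),
                              component_centers +
                                (r > 0) * stats::runif(k, -1, 1) * halfwidth_init,
                              halfwidth_init * (1 + 0.2 * r), 1.2))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(start, lower), upper),
                         lower = lower, upper = upper,
                         fn = function(p) y - model(p, x),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rn <- sqrt(sum(fit$fvec^2))
      if (is.null(best) || rn < attr(best, "residual_norm")) {
        best <- fit; attr(best, "residual_norm") <- rn
      }
      if (rn <= 1e-6 * max(1, sqrt(sum(y^2)))) break
    }
  }
  if (is.null(best))
    stop("choline-region deconvolution did not converge after ",
         max_restarts + 1, " starts")
  par <- matrix(best$par, ncol = 4, byrow = TRUE,
                dimnames = list(names(component_centers),
                                c("amplitude", "center_ppm", "halfwidth_ppm",
                                  "shape")))
  areas <- gen_lorentzian_area(par[, 1], par[, 3], par[, 4])
  names(areas) <- names(component_centers)
  structure(areas, residual_norm = attr(best, "residual_norm"), fit = par)
}

# ---- metabolite matrix ----------------------------------------------------

#' Construct a metabolite matrix
#'
#' The samples x variables quantitation table consumed by the multivariate
#' stages, with its scaling state tracked explicitly (`raw` ->
#' `weight_normalized` -> `log_uv_scaled`).
#'
#' @param values numeric matrix (samples x variables), no missing values.
#' @param sample_ids,variable_names dimension names (defaulting to the
#'   dimnames of `values`).
#' @return object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, sample_ids = rownames(values),
                              variable_names = colnames(values)) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("metabolite matrix must not contain missing values")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(variable_names)) stop("variable names are required")
  dimnames(values) <- list(sample_ids, variable_names)
  structure(list(values = values, sample_ids = sample_ids,
                 variable_names = variable_names, scaling_state = "raw",
                 log_flags = NULL, centers = NULL, scales = NULL),
            class = "metabolite_matrix")
}

#' Normalize each sample by its specimen weight
#'
#' @param matrix a `metabolite_matrix` in `raw` state.
#' @param weights_mg positive weights (mg), one per sample (recycled from a
#'   named vector by `sample_ids` when named).
#' @return weight-normalized `metabolite_matrix` (integral units per mg).
#' @export
normalize_by_weight <- function(matrix, weights_mg) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (!is.null(names(weights_mg)))
    weights_mg <- weights_mg[matrix$sample_ids]
  if (length(weights_mg) != nrow(matrix$values))
    stop("one weight per sample is required")
  if (any(!is.finite(weights_mg)) || any(weights_mg <= 0))
    stop("weights must be positive")
  out <- matrix
  out$values <- matrix$values / weights_mg
  out$scaling_state <- "weight_normalized"
  out
}

# sample skewness (moment estimator)
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 < .Machine$double.eps) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Log-transform skewed variables and scale to unit variance
#'
#' Operationalizes the automatic "log if required" rule: variables whose
#' sample skewness exceeds `auto_log_skew_threshold` are log-transformed
#' (requires strictly positive values), then every column is mean-centered
#' and scaled to unit variance. The per-variable log flags, centers and
#' scales are stored so that new samples can be projected through the same
#' transformation ([apply_scaling()]).
#'
#' @param matrix a weight-normalized `metabolite_matrix`.
#' @param auto_log_skew_threshold skewness above which a variable is logged.
#' @param log_flags optional logical vector overriding the automatic rule.
#' @return scaled `metabolite_matrix` (`scaling_state = "log_uv_scaled"`).
#' @export
log_and_uv_scale <- function(matrix, auto_log_skew_threshold = 1.0,
                             log_flags = NULL) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  v <- matrix$values
  if (is.null(log_flags))
    log_flags <- apply(v, 2, sample_skewness) > auto_log_skew_threshold
  if (any(log_flags & apply(v, 2, function(x) any(x <= 0))))
    stop("log-flagged variables must be strictly positive")
  v[, log_flags] <- log(v[, log_flags, drop = FALSE])
  centers <- colMeans(v)
  scales <- apply(v, 2, stats::sd)
  zero <- scales < .Machine$double.eps^0.5
  if (any(zero))
    stop("zero-variance variable: ",
         paste(matrix$variable_names[zero], collapse = ", "))
  out <- matrix
  out$values <- scale(v, centers, scales)[, , drop = FALSE]
  attr(out$values, "scaled:center") <- NULL
  attr(out$values, "scaled:scale") <- NULL
  out$scaling_state <- "log_uv_scaled"
  out$log_flags <- log_flags
  out$centers <- centers
  out$scales <- scales
  out
}

#' Project new samples through a stored scaling
#'
#' Applies the log flags, centers and scales learned by
#' [log_and_uv_scale()] on a training matrix to new (weight-normalized)
#' data, so out-of-sample observations live in the training model space.
#' Projecting the training data reproduces the scaled training matrix
#' exactly.
#'
#' @param values samples x variables matrix (same variables as the training
#'   matrix).
#' @param ref the scaled training `metabolite_matrix`.
#' @return scaled numeric matrix.
#' @export
apply_scaling <- function(values, ref) {
  stopifnot(inherits(ref, "metabolite_matrix"),
            ref$scaling_state == "log_uv_scaled")
  values <- as.matrix(values)
  missing <- setdiff(ref$variable_names, colnames(values))
  if (length(missing))
    stop("missing variables: ", paste(missing, collapse = ", "))
  v <- values[, ref$variable_names, drop = FALSE]
  v[, ref$log_flags] <- log(v[, ref$log_flags, drop = FALSE])
  out <- scale(v, ref$centers, ref$scales)[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Quantify a set of spectra into a raw metabolite matrix
#'
#' Full per-sample quantitation: chemical-shift calibration, baseline
#' correction, region integration (and generalized-Lorentzian deconvolution
#' for regions marked `lorentzian_fit`), one row per spectrum. CPMG and DIFF
#' channels of the same sample are quantified from their own spectra and
#' concatenated into a single row.
#'
#' @param spectra named list: for each sample a list with elements `CPMG`
#'   and/or `DIFF` holding `stromanmr_spectrum` objects.
#' @param regions region table.
#' @param calibrate,baseline logical switches for the two correction steps.
#' @return a raw `metabolite_matrix`.
#' @export
quantify_spectra <- function(spectra, regions = default_region_table(),
                             calibrate = TRUE, baseline = TRUE) {
  rows <- lapply(spectra, function(chans) {
    out <- numeric(0)
    for (ch in intersect(c("CPMG", "DIFF"), names(chans))) {
      sp <- chans[[ch]]
      if (calibrate) sp <- calibrate_shift(sp)
      if (baseline) sp <- baseline_correct(sp)
      reg <- regions[regions$channel == ch, , drop = FALSE]
      ints <- reg[reg$mode == "integral", , drop = FALSE]
      vals <- integrate_regions(sp, ints)
      fits <- reg[reg$mode == "lorentzian_fit", , drop = FALSE]
      if (nrow(fits)) {
        centers <- (fits$ppm_lo + fits$ppm_hi) / 2
        names(centers) <- fits$variable_name
        cho <- fit_choline_region(sp,
                                  region = c(min(fits$ppm_lo) - 0.05,
                                             max(fits$ppm_hi) + 0.05),
                                  component_centers = sort(centers))
        vals <- c(vals, cho[fits$variable_name])
      }
      out <- c(out, vals)
    }
    out[regions$variable_name[regions$variable_name %in% names(out)]]
  })
  metabolite_matrix(do.call(rbind, rows), sample_ids = names(spectra))
}
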
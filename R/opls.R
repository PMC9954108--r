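# Orthogonal projections to latent structures (OPLS / OPLS-DA) with one
# predictive component, sevenfold cross-validation, CV-ANOVA, VIP and
# correlation-scaled loadings.
#
# Algorithm: orthogonal signal correction in the Trygg-Wold form. For each
# orthogonal component: w = X'y/|X'y|; t = Xw; p = X't/t't;
# w_orth = p - (w'p)w (normalized); t_orth = X w_orth;
# p_orth = X't_orth/t_orth't_orth; X <- X - t_orth p_orth'. The predictive
# component is then refitted on the filtered X.

opls_core <- function(X, y, n_orth) {
  Xo <- X
  w_orth <- p_orth <- NULL
  for (i in seq_len(n_orth)) {
    w <- crossprod(Xo, y)
    w <- w / sqrt(sum(w^2))
    t1 <- Xo %*% w
    p <- crossprod(Xo, t1) / sum(t1^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no y-orthogonal variation left
    wo <- wo / nwo
    to <- Xo %*% wo
    po <- crossprod(Xo, to) / sum(to^2)
    Xo <- Xo - to %*% t(po)
    w_orth <- cbind(w_orth, wo)
    p_orth <- cbind(p_orth, po)
  }
  w <- crossprod(Xo, y)
  w <- w / sqrt(sum(w^2))
  t1 <- Xo %*% w
  p <- crossprod(Xo, t1) / sum(t1^2)
  q <- as.numeric(crossprod(y, t1) / sum(t1^2))
  list(w = w, p = p, q = q, t = t1, w_orth = w_orth, p_orth = p_orth,
       X_filtered = Xo)
}

# project new (already scaled) rows through the orthogonal filter
opls_filter_new <- function(model, Xnew) {
  Xo <- Xnew
  to_new <- NULL
  if (!is.null(model$w_orth)) for (i in seq_len(ncol(model$w_orth))) {
    to <- Xo %*% model$w_orth[, i]
    Xo <- Xo - to %*% t(model$p_orth[, i])
    to_new <- cbind(to_new, to)
  }
  list(X = Xo, to = to_new)
}

#' Fit an OPLS model with one predictive component
#'
#' Orthogonal projections to latent structures: variation in `X` that is
#' uncorrelated with the response is captured in `n_orth` orthogonal
#' components and removed before the single predictive component is fitted,
#' so that the predictive score t(1) carries all response-related variation.
#' Reported diagnostics: R2X (fraction of X variation explained by the
#' predictive plus orthogonal components), R2Y, sevenfold cross-validated
#' Q2, CV-ANOVA p value, VIP and correlation-scaled predictive loadings
#' pcorr(1).
#'
#' @param X scaled `metabolite_matrix` or numeric matrix (training data).
#' @param y numeric response (internally centered); for discriminant
#'   analysis use [oplsda_fit()].
#' @param n_orth number of orthogonal components (the models of interest use
#'   1).
#' @param folds cross-validation folds (7 by default; `0` skips CV).
#' @param cv_seed seed for the fold assignment.
#' @param cv_scheme `"random"` (seeded) or `"interleaved"` (every k-th
#'   sample, the deterministic rule used by common chemometrics software).
#' @param cv_rescale re-estimate centering/scaling of X columns inside each
#'   training fold (default) or reuse the full-data scaling.
#' @return object of class `stromanmr_opls` with entries `w`, `p`, `q`,
#'   scores `t`, y-scores `u`, orthogonal `w_orth`/`p_orth`/`t_orth`,
#'   `r2x`, `r2y`, `q2`, `press`, `cv_anova_p`, `vip`, `pcorr1`,
#'   `y_meaning`, and the training metadata needed for prediction.
#' @export
opls_fit <- function(X, y, n_orth = 1, folds = 7, cv_seed = 1L,
                     cv_scheme = c("random", "interleaved"),
                     cv_rescale = TRUE) {
  cv_scheme <- match.arg(cv_scheme)
  M <- get_X(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(M))
  if (stats::sd(y) < .Machine$double.eps^0.5)
    stop("response has zero variance")
  y_center <- mean(y)
  yc <- y - y_center
  core <- opls_core(M, yc, n_orth)

  ssx <- sum(M^2)
  # X_filtered already has the orthogonal components removed, so the residual
  # after the predictive component accounts for predictive + orthogonal R2X
  resid_X <- core$X_filtered - core$t %*% t(core$p)
  r2x <- 1 - sum(resid_X^2) / ssx
  yhat <- as.numeric(core$t) * core$q
  ssy <- sum(yc^2)
  r2y <- 1 - sum((yc - yhat)^2) / ssy
  u <- if (abs(core$q) > 0) yc / core$q else yc

  K <- ncol(M)
  vip <- sqrt(K) * abs(core$w[, 1]) / sqrt(sum(core$w^2))
  names(vip) <- colnames(M)
  pc <- as.numeric(stats::cor(M, core$t))
  names(pc) <- colnames(M)

  model <- structure(list(
    w = core$w, p = core$p, q = core$q, t = core$t, u = u,
    w_orth = core$w_orth, p_orth = core$p_orth,
    t_orth = if (is.null(core$w_orth)) NULL else
      opls_filter_new(core, M)$to,
    n_orth = if (is.null(core$w_orth)) 0L else ncol(core$w_orth),
    r2x = r2x, r2y = r2y, q2 = NA_real_, press = NA_real_,
    cv_anova_p = NA_real_, vip = vip, pcorr1 = pc,
    y_center = y_center, y_meaning = "numeric",
    n = nrow(M), variable_names = colnames(M),
    scaling_ref = if (inherits(X, "metabolite_matrix")) X else NULL),
    class = "stromanmr_opls")

  if (folds >= 2) {
    cv <- cross_validate(M, y, folds = folds, n_orth = n_orth,
                         seed = cv_seed, scheme = cv_scheme,
                         rescale = cv_rescale)
    model$q2 <- cv$q2
    model$press <- cv$press
    model$cv_anova_p <- cv_anova(cv$press, ssy, n = nrow(M),
                                 model_df = 1 + model$n_orth)
  }
  model
}

#' Fit an OPLS-DA model for a binary class contrast
#'
#' OPLS on a centered class-dummy response. The predictive score is oriented
#' so that the first class listed in `positive` (by default the first level)
#' has positive mean t(1); the decision threshold is the midpoint of the two
#' class-mean predictive scores, and a score exactly at the threshold is
#' assigned to the positive class.
#'
#' @param X scaled `metabolite_matrix` or numeric matrix.
#' @param labels binary class labels (factor or character).
#' @param positive the class mapped to the positive side of t(1).
#' @param min_class_size smallest class size accepted (sevenfold CV needs 7).
#' @inheritParams opls_fit
#' @return a `stromanmr_opls` with `y_meaning = "class_dummy"`, `classes`,
#'   `threshold`.
#' @export
oplsda_fit <- function(X, labels, positive = NULL, n_orth = 1, folds = 7,
                       cv_seed = 1L, min_class_size = 7) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) != 2)
    stop("exactly two classes are required")
  labels <- droplevels(labels)
  if (min(table(labels)) < min_class_size)
    stop("both classes need at least ", min_class_size, " samples")
  if (is.null(positive)) positive <- levels(labels)[1]
  stopifnot(positive %in% levels(labels))
  y <- as.numeric(labels == positive)
  model <- opls_fit(X, y, n_orth = n_orth, folds = folds, cv_seed = cv_seed)
  model$y_meaning <- "class_dummy"
  model$classes <- c(positive, setdiff(levels(labels), positive))
  mpos <- mean(model$t[y == 1]); mneg <- mean(model$t[y == 0])
  if (mpos < mneg) {  # orient the positive class to positive scores
    model$w <- -model$w; model$t <- -model$t; model$p <- -model$p
    model$q <- -model$q; model$u <- -model$u
    model$pcorr1 <- -model$pcorr1
    mpos <- -mpos; mneg <- -mneg
  }
  model$threshold <- (mpos + mneg) / 2
  model
}

#' Cross-validated predictive ability (Q2)
#'
#' Q2 = 1 - PRESS/SSY from k-fold cross-validation of the OPLS model, with
#' deterministic seeded fold assignment (class-stratified when `labels` are
#' supplied) and, by default, centering/scaling re-estimated inside each
#' training fold. A fold whose training part would contain a single class is
#' re-drawn with a fresh seed (with a message).
#'
#' @param X numeric matrix or `metabolite_matrix` (unscaled or scaled; when
#'   `rescale = TRUE` columns are restandardized per fold either way).
#' @param y numeric response or class dummy.
#' @param folds number of folds (>= 2, <= n).
#' @param n_orth orthogonal components.
#' @param labels optional class factor for stratification.
#' @param seed fold-assignment seed.
#' @param scheme `"random"` or `"interleaved"` (every k-th sample).
#' @param rescale re-estimate scaling within folds.
#' @return list with `q2`, `press`, `ssy`, `predictions` (cross-validated
#'   predicted response per sample), `fold`.
#' @export
cross_validate <- function(X, y, folds = 7, n_orth = 1, labels = NULL,
                           seed = 1L, scheme = c("random", "interleaved"),
                           rescale = TRUE) {
  scheme <- match.arg(scheme)
  M <- get_X(X)
  y <- as.numeric(y)
  n <- nrow(M)
  if (folds < 2 || folds > n) stop("folds must be in [2, n]")
  set.seed(as.integer(seed))
  assign_folds <- function() {
    if (scheme == "interleaved") {
      rep_len(seq_len(folds), n)
    } else if (!is.null(labels)) {
      f <- integer(n)
      for (lv in levels(factor(labels))) {
        idx <- which(labels == lv)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      f
    } else sample(rep_len(seq_len(folds), n))
  }
  fold <- assign_folds()
  if (!is.null(labels)) {
    tries <- 0
    while (any(vapply(seq_len(folds), function(f)
      length(unique(labels[fold != f])) < 2, TRUE)) && tries < 20) {
      message("refolding: a training fold contained a single class")
      fold <- assign_folds()
      tries <- tries + 1
    }
  }
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- M[tr, , drop = FALSE]
    Xte <- M[!tr, , drop = FALSE]
    if (rescale) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv < 1e-12] <- 1
      Xtr <- scale(Xtr, mu, sdv)
      Xte <- scale(Xte, mu, sdv)
    }
    ym <- mean(y[tr])
    core <- opls_core(Xtr, y[tr] - ym, n_orth)
    flt <- opls_filter_new(core, Xte)
    pred[!tr] <- as.numeric(flt$X %*% core$w) * core$q + ym
  }
  ssy <- sum((y - mean(y))^2)
  press <- sum((y - pred)^2)
  list(q2 = 1 - press / ssy, press = press, ssy = ssy, predictions = pred,
       fold = fold)
}

#' CV-ANOVA significance test
#'
#' F test comparing the cross-validated prediction residuals against the
#' total response variation:
#' `F = ((SSY - PRESS)/df1) / (PRESS/df2)` with `df1` the model degrees of
#' freedom (number of fitted latent components, predictive plus orthogonal)
#' and `df2 = n - 1 - df1`, upper-tail p value from the F distribution.
#' When PRESS exceeds SSY the model predicts worse than the mean and the
#' p value is 1 by convention.
#'
#' @param press cross-validated PRESS.
#' @param ssy total (centered) sum of squares of the response.
#' @param n number of samples.
#' @param model_df model degrees of freedom (components fitted).
#' @return p value in (0, 1].
#' @export
cv_anova <- function(press, ssy, n, model_df) {
  if (press < 0 || ssy <= 0) stop("press must be >= 0 and ssy > 0")
  df1 <- model_df
  df2 <- n - 1 - model_df
  if (df2 <= 0) stop("too few samples for CV-ANOVA")
  if (press >= ssy) return(1)
  Fv <- ((ssy - press) / df1) / (press / df2)
  stats::pf(Fv, df1, df2, lower.tail = FALSE)
}

#' Variable importance in projection
#'
#' VIP over the single predictive component: `sqrt(K) * |w_j| / |w|`, so
#' that the mean squared VIP is exactly 1 and the VIP ranking equals the
#' |w| ranking.
#'
#' @param model a fitted `stromanmr_opls`.
#' @return named non-negative numeric vector.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "stromanmr_opls"))
  K <- length(model$w)
  v <- sqrt(K) * abs(model$w[, 1]) / sqrt(sum(model$w^2))
  names(v) <- model$variable_names
  v
}

#' Correlation-scaled predictive loadings
#'
#' pcorr(1): the Pearson correlation between the predictive score t(1) and
#' each column of the (scaled) training matrix, i.e. the predictive loading
#' expressed on the correlation scale in [-1, 1].
#'
#' @param model a fitted `stromanmr_opls`.
#' @param X the training matrix the model was fitted on.
#' @return named numeric vector in `[-1, 1]`.
#' @export
pcorr <- function(model, X) {
  stopifnot(inherits(model, "stromanmr_opls"))
  M <- get_X(X)
  sds <- apply(M, 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5))
    stop("zero-variance column: ",
         paste(colnames(M)[sds < .Machine$double.eps^0.5], collapse = ", "))
  out <- as.numeric(stats::cor(M, model$t))
  names(out) <- colnames(M)
  out
}

#' Predict from an OPLS / OPLS-DA model
#'
#' Projects new samples through the stored scaling (when the model was
#' fitted on a `metabolite_matrix`) and the orthogonal filter, returning
#' predicted predictive/orthogonal scores tPS(1) and toPS(1) and either the
#' predicted response (regression) or the predicted class (discriminant
#' model, sign test of tPS(1) against the decision threshold; a tie goes to
#' the positive class).
#'
#' @param object fitted `stromanmr_opls`.
#' @param newdata samples x variables matrix (raw scale when the model holds
#'   a scaling reference, otherwise already scaled), or a
#'   `metabolite_matrix`.
#' @param scaled set `TRUE` when `newdata` is already in model space.
#' @param truth optional true classes/response; adds per-sample correctness.
#' @param ... unused.
#' @return `data.frame` with `tPS1`, `toPS1`, and `predicted` (class or
#'   response); plus `correct` when `truth` is given.
#' @export
predict.stromanmr_opls <- function(object, newdata, scaled = FALSE,
                                   truth = NULL, ...) {
  M <- get_X(newdata)
  if (!scaled && !is.null(object$scaling_ref))
    M <- apply_scaling(M, object$scaling_ref)
  if (!is.null(object$variable_names) && !is.null(colnames(M))) {
    missing <- setdiff(object$variable_names, colnames(M))
    if (length(missing))
      stop("missing variables: ", paste(missing, collapse = ", "))
    M <- M[, object$variable_names, drop = FALSE]
  } else if (ncol(M) != length(object$w)) {
    stop("missing variables: newdata has ", ncol(M), " columns, model expects ",
         length(object$w))
  }
  flt <- opls_filter_new(object, M)
  tps <- as.numeric(flt$X %*% object$w)
  tops <- if (is.null(flt$to)) rep(0, nrow(M)) else as.numeric(flt$to[, 1])
  out <- data.frame(tPS1 = tps, toPS1 = tops)
  rownames(out) <- rownames(M)
  if (identical(object$y_meaning, "class_dummy")) {
    out$predicted <- ifelse(tps >= object$threshold, object$classes[1],
                            object$classes[2])
    if (!is.null(truth)) out$correct <- out$predicted == as.character(truth)
  } else {
    out$predicted <- tps * object$q + object$y_center
    if (!is.null(truth)) out$residual <- as.numeric(truth) - out$predicted
  }
  out
}

#' @export
print.stromanmr_opls <- function(x, ...) {
  cat(sprintf("OPLS%s model: 1 predictive + %d orthogonal component(s)\n",
              if (identical(x$y_meaning, "class_dummy")) "-DA" else "", x$n_orth))
  cat(sprintf("  n = %d, K = %d\n", x$n, length(x$variable_names)))
  cat(sprintf("  R2X = %.1f%%, R2Y = %.1f%%, Q2 = %.1f%%\n",
              100 * x$r2x, 100 * x$r2y, 100 * x$q2))
  if (!is.na(x$cv_anova_p))
    cat(sprintf("  CV-ANOVA p = %.3g\n", x$cv_anova_p))
  invisible(x)
}
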
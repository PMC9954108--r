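# Principal component analysis on the scaled metabolite matrix, and the
# score-plane train/test partitioning used for external validation.

get_X <- function(X) {
  if (inherits(X, "metabolite_matrix")) X$values else as.matrix(X)
}

#' Fit a PCA model
#'
#' Singular-value decomposition of the (already scaled) data matrix. Scores
#' `t(i)` and loadings `p(i)` are returned for the first `k` components
#' together with the fraction of total variance each explains.
#'
#' @param X scaled `metabolite_matrix` or numeric matrix.
#' @param k number of components, at most `min(n - 1, p)`.
#' @return object of class `stromanmr_pca`: `scores` (n x k), `loadings`
#'   (p x k, orthonormal), `r2x_per_component`.
#' @export
pca_fit <- function(X, k = 2) {
  M <- get_X(X)
  if (k > min(nrow(M) - 1, ncol(M)))
    stop("k must not exceed min(n - 1, p)")
  sv <- svd(M, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  ev <- sv$d^2
  dimnames(scores) <- list(rownames(M), paste0("t", seq_len(k)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(M), paste0("p", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 r2x_per_component = ev[seq_len(k)] / sum(ev), k = k),
            class = "stromanmr_pca")
}

#' Split samples on the PCA score plane
#'
#' Partitions samples into training and test sets so that the test set is
#' evenly spread over the plane of the first two principal components: the
#' t(1)-t(2) plane is tiled into a 4 x 4 marginal-quantile grid, the total
#' test count `ceiling(test_fraction * n)` is allocated to occupied cells
#' proportionally to their occupancy (largest-remainder rounding), and test
#' samples are drawn within each cell stratified by group. Deterministic
#' given the seed.
#'
#' @param pca a fitted 2+ component [pca_fit()] model of the samples.
#' @param group_labels group factor used for stratification.
#' @param test_fraction fraction of samples assigned to the test set.
#' @param seed integer seed.
#' @param grid number of quantile bins per axis.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_by_score_plane <- function(pca, group_labels, test_fraction = 0.2,
                                 seed = 1L, grid = 4) {
  stopifnot(inherits(pca, "stromanmr_pca"), pca$k >= 2)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n <- nrow(pca$scores)
  stopifnot(length(group_labels) == n)
  set.seed(as.integer(seed))
  bin <- function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = grid + 1)))
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  cell <- paste(bin(pca$scores[, 1]), bin(pca$scores[, 2]))
  n_test <- ceiling(test_fraction * n)
  occ <- table(cell)
  # largest-remainder allocation of the test quota over occupied cells
  quota <- n_test * as.numeric(occ) / n
  take <- floor(quota)
  rem <- n_test - sum(take)
  if (rem > 0) {
    o <- order(quota - take, decreasing = TRUE)
    take[o[seq_len(rem)]] <- take[o[seq_len(rem)]] + 1
  }
  take <- pmin(take, as.numeric(occ))
  names(take) <- names(occ)
  test <- integer(0)
  for (cl in names(occ)) {
    idx <- which(cell == cl)
    k <- take[[cl]]
    if (k == 0) next
    # stratify the within-cell draw by group
    by_grp <- split(idx, droplevels(factor(group_labels[idx])))
    grp_quota <- k * lengths(by_grp) / length(idx)
    g_take <- floor(grp_quota)
    g_rem <- k - sum(g_take)
    if (g_rem > 0) {
      o <- order(grp_quota - g_take, decreasing = TRUE)
      g_take[o[seq_len(g_rem)]] <- g_take[o[seq_len(g_rem)]] + 1
    }
    g_take <- pmin(g_take, lengths(by_grp))
    for (g in seq_along(by_grp)) {
      pool <- by_grp[[g]]
      if (g_take[g] > 0)
        test <- c(test, pool[sample.int(length(pool), g_take[g])])
    }
  }
  test <- sort(unique(test))
  list(train = setdiff(seq_len(n), test), test = test)
}
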
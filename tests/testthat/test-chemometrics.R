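# PCA, OPLS/OPLS-DA, cross-validation, CV-ANOVA, VIP, pcorr, prediction and
# the score-plane split.

test_that("PCA explains variance in non-increasing shares and reconstructs", {
  set.seed(1)
  n <- 40; p <- 8
  X <- scale(matrix(rnorm(n * p), n, p))
  m <- pca_fit(X, k = p)
  expect_true(all(diff(m$r2x_per_component) <= 1e-12))
  expect_lte(sum(m$r2x_per_component), 1 + 1e-9)
  # full-rank round trip
  Xhat <- m$scores %*% t(m$loadings)
  expect_lt(max(abs(Xhat - X)), 1e-8)
  # loadings orthonormal
  expect_lt(max(abs(crossprod(m$loadings) - diag(p))), 1e-10)
  # rank-1 data: first component takes essentially everything
  X1 <- outer(rnorm(n), rnorm(p)) + 1e-4 * matrix(rnorm(n * p), n, p)
  m1 <- pca_fit(X1, 2)
  expect_gt(m1$r2x_per_component[1], 0.99)
  expect_error(pca_fit(X, k = n + 1), "k must not exceed")
})

test_that("OPLS with no orthogonal component equals one-component NIPALS PLS", {
  set.seed(2)
  X <- scale(matrix(rnorm(60 * 12), 60, 12))
  y <- rnorm(60)
  m <- opls_fit(X, y - mean(y), n_orth = 0, folds = 0)
  o <- nipals_pls1(X, y - mean(y))
  # sign-aligned comparison
  s <- sign(sum(m$w * o$w))
  expect_lt(max(abs(m$w - s * o$w)), 1e-8)
  expect_lt(max(abs(m$t - s * o$t)), 1e-8)
  expect_lt(max(abs(m$p - s * o$p)), 1e-8)
  expect_lt(abs(m$q - s * o$q), 1e-8)
})

test_that("orthogonal and predictive components satisfy the OPLS geometry", {
  set.seed(3)
  X <- scale(matrix(rnorm(50 * 10), 50, 10))
  y <- rnorm(50)
  m <- opls_fit(X, y, n_orth = 1, folds = 0)
  expect_lt(abs(sum(m$t * m$t_orth[, 1])), 1e-8)
  expect_lt(abs(sum(m$w_orth[, 1] * m$w)), 1e-8)
})

test_that("a noiseless linear response is captured almost perfectly", {
  # X carries a single latent direction, y follows it exactly
  set.seed(4)
  t_true <- rnorm(40); t_true <- t_true - mean(t_true)
  p_true <- rnorm(6)
  X <- outer(t_true, p_true) + 1e-6 * matrix(rnorm(240), 40, 6)
  X <- scale(X, scale = FALSE)
  y <- t_true
  m <- opls_fit(X, y, n_orth = 1, folds = 0)
  expect_gte(m$r2y, 0.999)
  # no y-orthogonal variation: the orthogonal component degenerates to zero
  expect_true(is.null(m$t_orth) || max(abs(m$t_orth)) < 1e-4)
  # cross-validation of an exact latent relationship predicts almost
  # perfectly; a second latent direction provides genuine orthogonal
  # variation for the filter to remove
  t2 <- rnorm(40); t2 <- residuals(lm(t2 ~ t_true))
  X2 <- scale(outer(t_true, p_true) + outer(t2, rev(p_true)) +
                1e-6 * matrix(rnorm(240), 40, 6))
  m2 <- opls_fit(X2, y, n_orth = 1, folds = 7)
  expect_gte(m2$r2y, 0.999)
  expect_gte(m2$q2, 0.99)
})

test_that("orthogonal filtering strengthens the score-response correlation", {
  set.seed(5)
  n <- 60; p <- 10
  y <- rnorm(n)
  X <- outer(y, rnorm(p)) + matrix(rnorm(n * p, sd = 0.3), n, p)
  ortho <- rnorm(n); ortho <- residuals(lm(ortho ~ y))
  X <- X + outer(ortho, runif(p, 2, 3))  # strong y-orthogonal structure
  X <- scale(X)
  m_opls <- opls_fit(X, y, n_orth = 1, folds = 0)
  m_pls <- nipals_pls1(X, y - mean(y))
  expect_gte(abs(cor(m_opls$t, y)), abs(cor(m_pls$t, y)))
})

test_that("Q2 never exceeds R2Y and collapses under permutation", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 30 + 5 * rep
    X <- scale(matrix(rnorm(n * 8), n, 8))
    y <- X[, 1] + rnorm(n, sd = rep / 3)
    m <- opls_fit(X, y, n_orth = 1, folds = 7, cv_seed = rep)
    expect_lte(m$q2, m$r2y + 1e-9)
  }
  # permuted labels: mean Q2 non-positive (null behaviour)
  set.seed(7)
  X <- scale(matrix(rnorm(60 * 10), 60, 10))
  y <- X[, 1] + rnorm(60, sd = 0.5)
  q2s <- vapply(1:50, function(i) {
    cross_validate(X, sample(y), folds = 7, n_orth = 1, seed = i)$q2
  }, 0)
  expect_lte(mean(q2s), 0)
})

test_that("discriminant fits separate well-separated clouds perfectly", {
  d <- two_clouds(n_per = 30, delta = 6, seed = 8)
  m <- oplsda_fit(d$X, d$labels, positive = "pos")
  pred <- predict(m, d$X, scaled = TRUE, truth = d$labels)
  expect_true(all(pred$correct))
  # positive class sits on the positive side of t(1)
  expect_true(all(m$t[d$labels == "pos"] > m$threshold))
  # held-out cloud from the positive generator lands positive
  set.seed(9)
  Xnew <- matrix(rnorm(20 * 10), 20, 10)
  Xnew[, 1] <- Xnew[, 1] + 6
  Xnew <- scale(Xnew, attr(d$X, "scaled:center"), attr(d$X, "scaled:scale"))
  pn <- predict(m, Xnew, scaled = TRUE)
  expect_gte(mean(pn$predicted == "pos"), 0.95)
})

test_that("label swap flips the score sign but not the magnitudes", {
  d <- two_clouds(n_per = 15, delta = 3, seed = 10)
  m1 <- oplsda_fit(d$X, d$labels, positive = "pos", folds = 0)
  m2 <- oplsda_fit(d$X, d$labels, positive = "neg", folds = 0)
  expect_equal(abs(m1$t), abs(m2$t), tolerance = 1e-10)
  expect_equal(m1$t, -m2$t, tolerance = 1e-10)
})

test_that("indistinguishable classes yield a useless discriminant model", {
  set.seed(11)
  q2s <- vapply(1:40, function(i) {
    X <- scale(matrix(rnorm(60 * 8), 60, 8))
    labels <- rep(c("a", "b"), each = 30)
    cross_validate(X, as.numeric(labels == "a"), folds = 7, n_orth = 1,
                   labels = labels, seed = i)$q2
  }, 0)
  expect_lte(mean(q2s), 0.1)
})

test_that("training samples re-predict their own scores", {
  d <- two_clouds(n_per = 20, delta = 4, seed = 12)
  m <- oplsda_fit(d$X, d$labels, positive = "pos", folds = 0)
  pred <- predict(m, d$X, scaled = TRUE)
  expect_lt(max(abs(pred$tPS1 - m$t)), 1e-8)
  # a sample exactly at the threshold goes to the positive class
  w <- m$w / sum(m$w^2)
  x_thr <- matrix(m$threshold * w, 1)
  colnames(x_thr) <- colnames(d$X)
  expect_equal(predict(m, x_thr, scaled = TRUE)$predicted, "pos")
  # missing variables are reported
  expect_error(predict(m, d$X[, -1], scaled = TRUE), "missing variables")
})

test_that("cross-validation handles its contract edge cases", {
  set.seed(13)
  X <- scale(matrix(rnorm(30 * 5), 30, 5))
  y <- X %*% rnorm(5)
  expect_error(cross_validate(X, y, folds = 1), "folds")
  cv1 <- cross_validate(X, y, folds = 7, seed = 3)
  cv2 <- cross_validate(X, y, folds = 7, seed = 3)
  expect_identical(cv1$fold, cv2$fold)     # deterministic fold assignment
  cv3 <- cross_validate(X, y, folds = 7, seed = 4)
  expect_false(identical(cv1$fold, cv3$fold))
  # interleaved scheme is seed-independent
  ci <- cross_validate(X, y, folds = 7, seed = 5, scheme = "interleaved")
  expect_equal(ci$fold, rep_len(1:7, 30))
})

test_that("CV-ANOVA follows its F formulation and boundary rules", {
  expect_equal(cv_anova(press = 10, ssy = 10, n = 70, model_df = 2), 1)
  expect_lt(cv_anova(press = 1e-6, ssy = 10, n = 70, model_df = 2), 1e-10)
  # closed-form check against pf
  press <- 4; ssy <- 10; n <- 30; df1 <- 2; df2 <- n - 1 - df1
  Fv <- ((ssy - press) / df1) / (press / df2)
  expect_equal(cv_anova(press, ssy, n, df1),
               pf(Fv, df1, df2, lower.tail = FALSE))
  expect_error(cv_anova(-1, 10, 30, 2), "press")
})

test_that("VIP is normalized and ranks like |w|", {
  set.seed(14)
  X <- scale(matrix(rnorm(50 * 7), 50, 7))
  y <- X %*% rnorm(7) + rnorm(50, sd = 0.5)
  m <- opls_fit(X, y, folds = 0)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-9)
  expect_equal(order(v), order(abs(m$w)))
  # one informative variable among K orthogonal variables: VIP = sqrt(K)
  X1 <- qr.Q(qr(scale(matrix(rnorm(50 * 5), 50, 5), scale = FALSE)))
  m1 <- opls_fit(X1, X1[, 3], n_orth = 0, folds = 0)
  expect_equal(unname(vip_scores(m1)[3]), sqrt(5), tolerance = 1e-6)
  # exchangeable variables: all VIP equal 1
  Xe <- scale(matrix(rep(rnorm(50), 4), 50, 4) +
                1e-8 * matrix(rnorm(200), 50, 4))
  me <- opls_fit(Xe, rnorm(50), n_orth = 0, folds = 0)
  expect_equal(unname(vip_scores(me)), rep(1, 4), tolerance = 1e-4)
})

test_that("pcorr is the score-variable correlation", {
  set.seed(15)
  X <- scale(matrix(rnorm(100 * 6), 100, 6))
  y <- X[, 1]
  m <- opls_fit(X, y, n_orth = 0, folds = 0)
  pc <- pcorr(m, X)
  # a column equal to +/- t(1) correlates at +/- 1
  X2 <- cbind(X, t_copy = as.numeric(m$t), t_neg = -as.numeric(m$t))
  pc2 <- pcorr(m, X2)
  expect_equal(unname(pc2["t_copy"]), 1, tolerance = 1e-10)
  expect_equal(unname(pc2["t_neg"]), -1, tolerance = 1e-10)
  # a random independent column decorrelates at large n
  set.seed(16)
  null_pc <- replicate(50, {
    Xr <- cbind(X, r = rnorm(100))
    unname(pcorr(m, Xr)["r"])
  })
  expect_gte(mean(abs(null_pc) < 0.2), 0.95)
  expect_error(pcorr(m, cbind(X, z = rep(1, 100))), "zero-variance")
})

test_that("score-plane split honours fraction, determinism and spread", {
  set.seed(17)
  X <- scale(matrix(rnorm(50 * 6), 50, 6))
  pca <- pca_fit(X, 2)
  grp <- rep(c("a", "b"), 25)
  sp <- split_by_score_plane(pca, grp, test_fraction = 0.2, seed = 5)
  expect_true(length(sp$test) >= 10 && length(sp$test) <= 14)
  expect_equal(sort(c(sp$train, sp$test)), 1:50)
  expect_false(anyDuplicated(sp$test) > 0)
  sp2 <- split_by_score_plane(pca, grp, test_fraction = 0.2, seed = 5)
  expect_identical(sp, sp2)
  # per-cell share close to the target on a uniform cloud
  bin <- function(x) cut(x, unique(quantile(x, 0:4 / 4)),
                         include.lowest = TRUE, labels = FALSE)
  cell <- paste(bin(pca$scores[, 1]), bin(pca$scores[, 2]))
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    expect_lte(abs(sum(idx %in% sp$test) - 0.2 * length(idx)), 1)
  }
  expect_error(split_by_score_plane(pca, grp, test_fraction = 1.2), "(0, 1)")
})

test_that("single-class and degenerate inputs are rejected", {
  X <- scale(matrix(rnorm(40 * 5), 40, 5))
  expect_error(oplsda_fit(X, rep("a", 40)), "two classes")
  expect_error(oplsda_fit(X, c(rep("a", 37), rep("b", 3))), "at least 7")
  expect_error(opls_fit(X, rep(1, 40)), "zero variance")
})
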
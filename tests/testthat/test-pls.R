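test_that("single exact predictor gives a perfect one-component model", {
  x <- matrix(seq(-3, 3, length.out = 12), ncol = 1)
  y <- drop(3 * x)
  m <- fit_pls1(x, y, A = 1)
  expect_equal(m$r2, 1)
  expect_equal(unname(m$fitted), y, tolerance = 1e-12)
  expect_equal(unname(vip_scores(m)), 1)
})

test_that("full-component PLS reproduces ordinary least squares", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(10:30, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fit_pls1(X, y, A = p)
    ols <- lm.fit(cbind(1, X), y)
    expect_equal(unname(m$fitted), unname(ols$fitted.values), tolerance = 1e-8)
  }
})

test_that("a response orthogonal to X yields a null model", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  Xc <- scale(X, scale = FALSE)
  y0 <- rnorm(10)
  # project out all X columns (and the intercept)
  y <- y0 - cbind(1, Xc) %*% qr.coef(qr(cbind(1, Xc)), y0)
  y <- drop(y)
  m <- fit_pls1(X, y, A = 3)
  expect_lt(max(abs(m$b)), 1e-8)
  expect_lt(abs(m$r2), 1e-8)
})

test_that("scores are orthogonal and VIP obeys its normalization identity", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(15 * 6), 15, 6)
    y <- X[, 1] - 2 * X[, 4] + rnorm(15, 0, 0.3)
    m <- fit_pls1(X, y, A = 3)
    G <- crossprod(m$T)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  }
})

test_that("VIP matches a direct evaluation of its formula", {
  set.seed(7)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- X[, 2] + 0.5 * X[, 3] + rnorm(12, 0, 0.2)
  m <- fit_pls1(X, y, A = 2)
  o <- oracle_pls(X, y, 2)
  ssy <- o$q^2 * o$tt
  vip <- sqrt(4 * rowSums(sweep(o$W^2, 2, colSums(o$W^2), "/") %*% diag(ssy)) / sum(ssy))
  expect_equal(unname(m$vip), vip, tolerance = 1e-10)
  expect_equal(unname(m$b), o$b, tolerance = 1e-10)
})

test_that("cross-validated Q2/SDECV matches a hand-stepped two-fold computation", {
  set.seed(5)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- X[, 1] + rnorm(8, 0, 0.4)
  fold_id <- rep(1:2, each = 4)
  got <- q2_sdecv(X, y, A = 1, fold_id = fold_id)
  press <- 0; tss <- 0
  for (f in 1:2) {
    tr <- fold_id != f
    o <- oracle_pls(X[tr, ], y[tr], 1)
    pred <- drop(sweep(X[!tr, ], 2, o$x_mean) %*% o$b) + o$y_mean
    press <- press + sum((y[!tr] - pred)^2)
    tss <- tss + sum((y[!tr] - o$y_mean)^2)
  }
  expect_equal(got$q2, 1 - press / tss, tolerance = 1e-12)
  expect_equal(got$sdecv, sqrt(press / 8), tolerance = 1e-12)
})

test_that("Q2 approaches 1 for noiseless data and is non-positive under the null", {
  set.seed(11)
  X <- matrix(rnorm(70 * 5), 70, 5)
  y <- drop(X %*% c(1, -1, 0.5, 0, 0))
  expect_gte(q2_sdecv(X, y, A = 3, seed = 1)$q2, 0.999)
  # independent y: mean Q2 over 100 seeds below 0
  q2s <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(20 * 4), 20, 4)
    yn <- rnorm(20)
    q2_sdecv(Xn, yn, A = 2, seed = s)$q2
  }, numeric(1))
  expect_lt(mean(q2s), 0)
})

test_that("cross-validated Q2 does not exceed the fitted R2", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(30 * 6), 30, 6)
    y <- X[, 1] + rnorm(30, 0, 1)
    m <- fit_pls1(X, y, A = 2)
    cv <- q2_sdecv(X, y, A = 2, seed = s)
    expect_lte(cv$q2, m$r2 + 1e-8)
  }
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls1(X, rep(1, 10), A = 1), "zero variance")
  expect_error(fit_pls1(X, rnorm(10), A = 12), "A must be")
  expect_error(q2_sdecv(X, rnorm(10), A = 1, folds = 11), "folds")
})

test_that("post-transformation exposes one predictive component without changing predictions", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(20, 0.2)
  m <- fit_pls1(X, y, A = 3)
  pt <- post_transform(m)
  # tp is exactly X_c b / ||b||
  tp_direct <- drop(sweep(X, 2, m$x_mean) %*% m$b) / sqrt(sum(m$b^2))
  expect_equal(pt$tp, tp_direct, tolerance = 1e-10)
  expect_equal(abs(cor(pt$tp, m$fitted)), 1, tolerance = 1e-8)
  # predictions recomputed from the predictive component agree exactly
  yhat_from_tp <- pt$tp * sqrt(sum(m$b^2)) + m$y_mean
  expect_equal(yhat_from_tp, unname(predict(m, X)), tolerance = 1e-10)
  # remaining components orthogonal to tp
  if (ncol(pt$T_orthogonal) > 0)
    expect_lt(max(abs(crossprod(pt$T_orthogonal, pt$tp))), 1e-8)
  # one component: tp proportional to t1
  m1 <- fit_pls1(X, y, A = 1)
  pt1 <- post_transform(m1)
  expect_equal(abs(cor(pt1$tp, m1$T[, 1])), 1, tolerance = 1e-10)
  m$b[] <- 0; m$fitted[] <- m$y_mean
  expect_error(post_transform(m), "degenerate")
})

test_that("PCA explained fractions behave and match an eigendecomposition", {
  # rank-1 matrix: first component explains everything
  u <- outer(rnorm(6), rnorm(4))
  expect_warning(pc1 <- pca_matrix(u, 3), "truncated")
  expect_equal(pc1$explained[1], 1, tolerance = 1e-10)
  # random input: non-increasing fractions summing to <= 1
  set.seed(8)
  X <- matrix(rnorm(50), 10, 5)
  pc <- pca_matrix(X, 5)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # 5 x 4 instance against eigen() of the covariance matrix
  Y <- matrix(rnorm(20), 5, 4)
  pcy <- pca_matrix(Y, 3)
  ev <- eigen(cov(Y))
  expect_equal(pcy$sdev^2, ev$values[1:3] , tolerance = 1e-10)
  for (k in 1:3)
    expect_equal(abs(sum(pcy$loadings[, k] * ev$vectors[, k])), 1, tolerance = 1e-8)
})
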
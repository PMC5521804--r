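# NIPALS PLS1 with VIP scores, cross-validated Q2/SDECV, VIP-threshold
# variable selection, response permutation test, and predictive
# post-transformation ---------------------------------------------------------
#
# For a single response the NIPALS weight vector is closed-form per
# component (w_a proportional to X_a' y), so no inner iteration is needed;
# only X is deflated.

# Core fit on already-centered X, y. Returns components up to A (fewer if X
# runs out of covariance with y). Nested: the first a columns of W/P/q give
# the a-component model.
pls1_core <- function(Xc, yc, A) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A); tt <- numeric(A)
  Xd <- Xc
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yc^2)))) break
    w <- w / nw
    t <- Xd %*% w
    t2 <- sum(t^2)
    if (t2 < 1e-24) break
    pa <- crossprod(Xd, t) / t2
    qa <- sum(yc * t) / t2
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t; q[a] <- qa; tt[a] <- t2
    Xd <- Xd - tcrossprod(t, pa)
    a_used <- a
  }
  if (a_used == 0L)
    return(list(A = 0L, W = W[, 0, drop = FALSE], P = P[, 0, drop = FALSE],
                T = Tm[, 0, drop = FALSE], q = numeric(0), tt = numeric(0),
                b = rep(0, p)))
  idx <- seq_len(a_used)
  list(A = a_used, W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       T = Tm[, idx, drop = FALSE], q = q[idx], tt = tt[idx],
       b = NULL)
}

# Regression coefficients for an a-component truncation of a core fit.
pls1_coef <- function(core, a = core$A) {
  if (a == 0L) return(rep(0, nrow(core$W)))
  W <- core$W[, seq_len(a), drop = FALSE]
  P <- core$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), core$q[seq_len(a)]))
}

#' Fit a PLS1 regression model
#'
#' NIPALS projection-to-latent-structures regression for a single response.
#' Centering is applied internally and stored; weights are closed-form per
#' component and only X is deflated.
#'
#' @param X numeric predictor matrix (samples x variables).
#' @param y numeric response vector.
#' @param A number of latent components; must not exceed
#'   `min(rank(X), n - 1)`.
#' @return Object of class `pls_model`: weights `W`, X-loadings `P`,
#'   y-loadings `q`, scores `T`, coefficients `b`, centering offsets
#'   `x_mean`/`y_mean`, `r2`, `vip`, and `A` (may be smaller than requested
#'   if X runs out of y-covariance).
#' @export
fit_pls1 <- function(X, y, A = 2L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate: y has zero variance", call. = FALSE)
  A <- stopifnot_scalar_count(A, "A")
  if (A > n - 1L)
    stop("parameter error: A must be <= n - 1", call. = FALSE)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean); yc <- y - y_mean
  core <- pls1_core(Xc, yc, min(A, p, n - 1L))
  b <- pls1_coef(core)
  fitted <- drop(Xc %*% b) + y_mean
  r2 <- 1 - sum((y - fitted)^2) / sum(yc^2)
  m <- structure(list(A = core$A, W = core$W, P = core$P, q = core$q,
                      T = core$T, tt = core$tt, b = b,
                      x_mean = x_mean, y_mean = y_mean,
                      fitted = fitted, r2 = r2,
                      q2 = NA_real_, sdecv = NA_real_,
                      variables = colnames(X)),
                 class = "pls_model")
  m$vip <- vip_scores(m)
  m
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix of new observations (same variables).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(sweep(newdata, 2L, object$x_mean) %*% object$b) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS1 model: A = %d, p = %d, R2 = %.3f", x$A, length(x$b), x$r2))
  if (!is.na(x$q2)) cat(sprintf(", Q2 = %.3f, SDECV = %.3g", x$q2, x$sdecv))
  cat("\n")
  invisible(x)
}

#' Variable influence on projection (VIP) scores
#'
#' `vip_j = sqrt( p * sum_a SSY_a w_aj^2 / sum_a SSY_a )` with
#' `SSY_a = q_a^2 t_a't_a` and unit-norm weights, so that the mean squared
#' VIP over variables is exactly 1.
#'
#' @param model a fitted `pls_model`.
#' @return Numeric VIP vector (one entry per variable).
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "pls_model") || is.null(model$W))
    stop("state error: need a fitted pls_model", call. = FALSE)
  p <- nrow(model$W)
  if (model$A == 0L) return(stats::setNames(rep(0, p), model$variables))
  ssy <- model$q^2 * model$tt
  w2 <- sweep(model$W^2, 2L, colSums(model$W^2), "/")
  vip <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  stats::setNames(vip, model$variables)
}

# Fold assignment: near-equal sizes, randomized; stratified by a label
# factor when given (keeps each cultivar represented in training folds).
make_folds <- function(n, folds, seed, strata = NULL) {
  with_seed(seed, {
    f <- integer(n)
    if (is.null(strata)) {
      f <- sample(rep_len(seq_len(folds), n))
    } else {
      strata <- as.integer(factor(strata))
      offset <- 0L
      for (s in unique(strata)) {
        idx <- which(strata == s)
        f[idx] <- sample((seq_along(idx) + offset - 1L) %% folds + 1L)
        offset <- offset + length(idx)
      }
    }
    f
  })
}

# Cross-validated PRESS for every component count 1..A_max in one pass.
# Centering is re-estimated on each training fold. Returns a list with
# press[a], per-sample CV residuals (n x A_max), tss (about training-fold
# means), and n.
cv_press <- function(X, y, A_max, fold_id) {
  n <- nrow(X)
  folds <- sort(unique(fold_id))
  press <- numeric(A_max)
  resid <- matrix(0, n, A_max)
  tss <- 0
  for (f in folds) {
    te <- fold_id == f; tr <- !te
    x_mean <- colMeans(X[tr, , drop = FALSE]); y_mean <- mean(y[tr])
    Xc <- sweep(X[tr, , drop = FALSE], 2L, x_mean)
    yc <- y[tr] - y_mean
    a_cap <- min(A_max, sum(tr) - 1L, ncol(X))
    core <- pls1_core(Xc, yc, a_cap)
    Xte <- sweep(X[te, , drop = FALSE], 2L, x_mean)
    for (a in seq_len(A_max)) {
      b <- pls1_coef(core, min(a, core$A))
      pred <- drop(Xte %*% b) + y_mean
      resid[te, a] <- y[te] - pred
      press[a] <- press[a] + sum((y[te] - pred)^2)
    }
    tss <- tss + sum((y[te] - y_mean)^2)
  }
  list(press = press, resid = resid, tss = tss, n = n)
}

#' Cross-validated Q2 and SDECV
#'
#' Seven-fold (by default) full cross-validation: `Q2 = 1 - PRESS/TSS` with
#' the total sum of squares taken about the training-fold means, and
#' `SDECV = sqrt(PRESS/n)`. Fold centering is re-estimated inside each
#' training fold so no information leaks from held-out samples.
#'
#' @param X,y data as in [fit_pls1()].
#' @param A number of components.
#' @param folds number of CV folds (default 7).
#' @param seed seed for the fold partition.
#' @param strata optional labels for stratified folds.
#' @param fold_id optional explicit fold assignment (overrides
#'   `folds`/`seed`), for reproducing a hand-stepped computation.
#' @return List with `q2`, `sdecv`, `press`, `fold_id`.
#' @export
q2_sdecv <- function(X, y, A = 2L, folds = 7L, seed = 1L, strata = NULL,
                     fold_id = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(fold_id)) {
    if (folds > n) stop("parameter error: folds > samples", call. = FALSE)
    fold_id <- make_folds(n, folds, seed, strata)
  }
  res <- cv_press(X, y, A, fold_id)
  list(q2 = 1 - res$press[A] / res$tss, sdecv = sqrt(res$press[A] / n),
       press = res$press[A], fold_id = fold_id)
}

# Choose the component count maximizing Q2 over 1..A_max; returns the chosen
# a, its q2 and sdecv.
choose_ncomp <- function(X, y, A_max = 5L, folds = 7L, seed = 1L, strata = NULL,
                         fold_id = NULL) {
  n <- nrow(X)
  A_max <- min(A_max, n - 1L - ceiling(n / folds), ncol(X))
  A_max <- max(A_max, 1L)
  if (is.null(fold_id)) fold_id <- make_folds(n, folds, seed, strata)
  res <- cv_press(X, y, A_max, fold_id)
  q2 <- 1 - res$press / res$tss
  a <- which.max(q2)
  # standard error of Q2 from the spread of squared CV residuals
  e2 <- res$resid[, a]^2
  list(A = a, q2 = q2[a], sdecv = sqrt(res$press[a] / n), q2_all = q2,
       q2_se = sqrt(n) * stats::sd(e2) / res$tss, fold_id = fold_id)
}

#' VIP-threshold variable selection by Q2 maximization
#'
#' Fits a full PLS model (component count chosen by seven-fold
#' cross-validated Q2), then scans candidate VIP thresholds — the sorted
#' unique VIP values plus 0 — refitting on the variables with VIP above each
#' threshold and recomputing Q2. Under `rule = "max"` the threshold
#' maximizing Q2 wins, ties breaking toward the sparser model. The default
#' `rule = "1se"` applies the one-standard-error parsimony rule: the
#' sparsest threshold whose Q2 is within one standard error (estimated from
#' the spread of the squared cross-validation residuals) of the maximum.
#' Cross-validated Q2 paths are nearly flat near their optimum, so a pure
#' argmax frequently drags along variables that correlate with the response
#' by chance; the 1-SE rule removes them while never giving up a
#' statistically distinguishable amount of predictive power. The returned
#' model is refit on the selected variables with its own Q2-chosen component
#' count. Optionally a response permutation test is run on the selection
#' statistic.
#'
#' @param X,y data.
#' @param folds,seed cross-validation controls (one fold partition is
#'   shared across thresholds so Q2 values are comparable).
#' @param A_max maximum component count considered.
#' @param n_perm permutations for the over-fitting test (0 skips it).
#' @param rule `"1se"` (default, parsimonious) or `"max"` (strict argmax).
#' @param strata optional stratification labels for folds.
#' @return Object of class `vip_selection`: `threshold`, `selected`
#'   (variable names), `model` (refit `pls_model` with `q2`/`sdecv` filled),
#'   `q2_path` (threshold vs q2), `vip` (full-model VIPs), `permutation_p`.
#' @export
select_by_vip <- function(X, y, folds = 7L, seed = 1L, A_max = 5L,
                          n_perm = 199L, rule = c("1se", "max"),
                          strata = NULL) {
  rule <- match.arg(rule)
  X <- as.matrix(X); y <- as.numeric(y)
  if (ncol(X) < 2) stop("need >= 2 variables to select among", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fold_id <- make_folds(nrow(X), folds, seed, strata)
  full_cv <- choose_ncomp(X, y, A_max, fold_id = fold_id)
  full <- fit_pls1(X, y, full_cv$A)
  vip <- full$vip
  thresholds <- sort(unique(c(0, vip)))
  thresholds <- thresholds[thresholds < max(vip)]  # drop the empty-set candidate
  q2_path <- data.frame(threshold = thresholds, q2 = NA_real_,
                        q2_se = NA_real_, n_selected = NA_integer_,
                        A = NA_integer_, sdecv = NA_real_)
  for (k in seq_along(thresholds)) {
    keep <- vip > thresholds[k]
    cv <- choose_ncomp(X[, keep, drop = FALSE], y, A_max, fold_id = fold_id)
    q2_path$q2[k] <- cv$q2
    q2_path$q2_se[k] <- cv$q2_se
    q2_path$n_selected[k] <- sum(keep)
    q2_path$A[k] <- cv$A
    q2_path$sdecv[k] <- cv$sdecv
  }
  ok <- is.finite(q2_path$q2)
  if (!any(ok)) {
    warning("no viable VIP threshold; returning the full model", call. = FALSE)
    best <- list(q2 = full_cv$q2, threshold = 0, keep = rep(TRUE, ncol(X)),
                 A = full_cv$A, sdecv = full_cv$sdecv)
  } else {
    kmax <- which(ok)[which.max(q2_path$q2[ok])]
    bar <- if (rule == "1se") q2_path$q2[kmax] - q2_path$q2_se[kmax] else
      q2_path$q2[kmax] - 1e-12
    cand <- which(ok & q2_path$q2 >= bar)
    k <- cand[which.min(q2_path$n_selected[cand])]
    best <- list(q2 = q2_path$q2[k], threshold = q2_path$threshold[k],
                 keep = vip > q2_path$threshold[k], A = q2_path$A[k],
                 sdecv = q2_path$sdecv[k])
  }
  model <- fit_pls1(X[, best$keep, drop = FALSE], y, best$A)
  model$q2 <- best$q2
  model$sdecv <- best$sdecv
  perm_p <- NA_real_
  if (n_perm > 0)
    perm_p <- permutation_test(X, y, n_perm = n_perm, folds = folds,
                               seed = derive_seed(seed, 7919L), A_max = A_max,
                               q2_obs = best$q2)$p_value
  structure(list(threshold = best$threshold,
                 selected = colnames(X)[best$keep],
                 model = model, q2_path = q2_path, vip = vip,
                 full_A = full_cv$A, permutation_p = perm_p,
                 folds = folds, seed = seed),
            class = "vip_selection")
}

#' @export
print.vip_selection <- function(x, ...) {
  cat(sprintf("VIP-based PLS selection: threshold %.3f -> %d/%d variables\n",
              x$threshold, length(x$selected), length(x$vip)))
  print(x$model)
  if (!is.na(x$permutation_p))
    cat(sprintf("  permutation p = %.4g\n", x$permutation_p))
  invisible(x)
}

#' Response permutation test against over-fitting
#'
#' Permutes the response and recomputes the cross-validated Q2 (maximized
#' over component count, i.e. the same statistic as the observed model
#' selection uses for A). `p = (1 + #\{Q2_perm >= Q2_obs\}) / (n_perm + 1)`.
#'
#' @param X,y data.
#' @param n_perm number of permutations (>= 1).
#' @param folds,seed CV controls; the seed also drives the permutations.
#' @param A_max maximum component count.
#' @param q2_obs optional precomputed observed Q2 (e.g. the selected model's);
#'   when `NULL` the full-model Q2 is used.
#' @param strata optional stratification labels.
#' @return List with `p_value`, `q2_obs`, `q2_perm`.
#' @export
permutation_test <- function(X, y, n_perm = 1000L, folds = 7L, seed = 1L,
                             A_max = 5L, q2_obs = NULL, strata = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n_perm <- stopifnot_scalar_count(n_perm, "n_perm")
  fold_id <- make_folds(nrow(X), folds, seed, strata)
  if (is.null(q2_obs))
    q2_obs <- choose_ncomp(X, y, A_max, fold_id = fold_id)$q2
  q2_perm <- with_seed(derive_seed(seed, 104729L),
    vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      choose_ncomp(X, yp, A_max, fold_id = fold_id)$q2
    }, numeric(1)))
  list(p_value = (1 + sum(q2_perm >= q2_obs)) / (n_perm + 1),
       q2_obs = q2_obs, q2_perm = q2_perm)
}

#' Post-transform a PLS model to expose its predictive component
#'
#' Rotates the score space so a single component, `tp = X_c b / ||b||`,
#' carries all of the model's y-predictive variation; the remaining
#' components are re-orthogonalized against it. Predictions are unchanged
#' (the coefficient vector is untouched) and `tp` is exactly proportional to
#' the fitted values, so their correlation is 1 by construction.
#'
#' @param model a fitted `pls_model`.
#' @return The model with elements `tp` (predictive scores) and
#'   `T_orthogonal` (scores orthogonal to `tp`) added.
#' @export
post_transform <- function(model) {
  if (!inherits(model, "pls_model"))
    stop("need a fitted pls_model", call. = FALSE)
  nb <- sqrt(sum(model$b^2))
  if (nb < 1e-14) stop("degenerate: zero coefficient vector", call. = FALSE)
  # T q = Xc b exactly, so tp lives in the score space
  yhat_c <- model$fitted - model$y_mean
  tp <- yhat_c / nb
  To <- model$T
  if (ncol(To) > 0 && sum(tp^2) > 0) {
    proj <- drop(crossprod(To, tp)) / sum(tp^2)
    To <- To - tcrossprod(tp, proj)
    # drop the dimension absorbed into tp
    qr_ <- qr(To)
    To <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE] *
      rep(sqrt(colSums(To^2))[seq_len(qr_$rank)], each = nrow(To))
  }
  model$tp <- tp
  model$T_orthogonal <- To
  model
}

#' Principal component analysis of a centered matrix
#'
#' Thin wrapper over [stats::prcomp()] returning scores, loadings and the
#' explained variance fractions for the leading components.
#'
#' @param X numeric matrix (centered or not; centering is applied).
#' @param n_components number of components to keep; truncated to the matrix
#'   rank with a warning when too large.
#' @return List with `scores`, `loadings`, `explained` (fractions of total
#'   variance, non-increasing, summing to <= 1) and `sdev`.
#' @export
pca_matrix <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components truncated to rank %d", rank), call. = FALSE)
    n_components <- rank
  }
  idx <- seq_len(n_components)
  list(scores = pc$x[, idx, drop = FALSE],
       loadings = pc$rotation[, idx, drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[idx],
       sdev = pc$sdev[idx])
}
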
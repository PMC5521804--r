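# Shared fixture builders (all data generated in code, fixed seeds).

# Planted linear model: `n_inf` informative variables (coefficient `beta`)
# followed by `n_noise` pure-noise variables; returns X, y and the truth.
make_planted <- function(n = 54, n_inf = 3, n_noise = 20, beta = 1,
                         noise_sd = 1, seed = 1) {
  set.seed(seed)
  p <- n_inf + n_noise
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0(c(rep("inf", n_inf), rep("noise", n_noise)),
                                           seq_len(p))))
  y <- drop(X[, seq_len(n_inf), drop = FALSE] %*% rep(beta, n_inf)) +
    rnorm(n, 0, noise_sd)
  list(X = X, y = y, informative = colnames(X)[seq_len(n_inf)],
       noise = colnames(X)[-seq_len(n_inf)])
}

# Zero-replicate-noise simulation config on a small design. Note that with
# both noise sources off a design has only n_cultivars distinct rows.
quiet_config <- function(n_cultivars = 4, ...) {
  sim_config(n_cultivars = n_cultivars, n_vintages = 2, n_replicates = 3,
             replicate_cv = 0, vintage_shift_sd = 0, response_noise_sd = 0,
             n_noise_features = 0, ...)
}

# Independent single-component-at-a-time reference implementation used as an
# oracle: explicit loops, coefficient assembly by direct matrix algebra.
oracle_pls <- function(X, y, A) {
  xm <- colMeans(X); ym <- mean(y)
  Xa <- sweep(X, 2, xm); yc <- y - ym
  W <- P <- NULL; q <- tt <- c(); Tm <- NULL
  for (a in seq_len(A)) {
    w <- drop(t(Xa) %*% yc); w <- w / sqrt(sum(w * w))
    t_ <- drop(Xa %*% w); t2 <- sum(t_ * t_)
    p_ <- drop(t(Xa) %*% t_) / t2
    q_ <- sum(yc * t_) / t2
    W <- cbind(W, w); P <- cbind(P, p_); Tm <- cbind(Tm, t_)
    q <- c(q, q_); tt <- c(tt, t2)
    Xa <- Xa - outer(t_, p_)
  }
  b <- drop(W %*% solve(t(P) %*% W) %*% q)
  list(b = b, W = W, P = P, T = Tm, q = q, tt = tt, x_mean = xm, y_mean = ym)
}

# teac_result with exact replicate values
tr <- function(values, id = "x") teac_result(sample_id = id, replicate_values = values)

# mean silhouette width of a labelling on rows of a score matrix
mean_silhouette <- function(scores, labels) {
  d <- as.matrix(dist(scores))
  labels <- as.character(labels)
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
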
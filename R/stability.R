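# Monte-Carlo stability selection around VIP-based PLS and its simple
# linear regression analogue --------------------------------------------------

#' Monte-Carlo stability selection with VIP-based PLS
#'
#' Draws random subsamples by including each sample independently with
#' probability `inclusion_prob` (redrawn if fewer than `A_max + 2` samples
#' land in the training set), runs [select_by_vip()] on each, and records
#' the selected variable set and the standard deviation error in prediction
#' (SDEP) on the excluded samples, `sqrt(sum((yhat - y)^2) / n_excluded)`,
#' using the selected-variable refit. A subsample whose permutation test
#' exceeds `gate_alpha` contributes an empty selection (over-fitting guard).
#' Variables selected in more than `freq_threshold` of the subsample models
#' form the relevant set.
#'
#' @param X,y data.
#' @param n_subsamples number of Monte-Carlo subsamples (default 1000).
#' @param inclusion_prob per-sample inclusion probability (default 0.70).
#' @param freq_threshold relevance cutoff on the selection frequency
#'   (strict `>`, default 0.5).
#' @param folds,A_max passed to [select_by_vip()].
#' @param seed master seed; per-subsample seeds are derived from it.
#' @param gate_n_perm permutations for the per-subsample over-fitting gate
#'   (0 disables gating; 19 is the smallest count that can resolve
#'   p <= 0.05 with the +1 correction).
#' @param gate_alpha gate significance level.
#' @param rule threshold rule passed to [select_by_vip()].
#' @param fixed_quota if `TRUE`, draw exactly `round(inclusion_prob * n)`
#'   samples per subsample instead of independent Bernoulli inclusion.
#' @return Object of class `stability_result`: per-variable `frequency`,
#'   `relevant` (names with frequency > threshold), `mean_sdep`,
#'   `per_model_sdep`, `mean_vip`, settings and `seed`.
#' @export
stability_select_pls <- function(X, y, n_subsamples = 1000L,
                                 inclusion_prob = 0.70, freq_threshold = 0.5,
                                 folds = 7L, A_max = 5L, seed = 1L,
                                 gate_n_perm = 19L, gate_alpha = 0.05,
                                 rule = c("1se", "max"), fixed_quota = FALSE) {
  rule <- match.arg(rule)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 10) stop("need >= 10 samples for stability selection", call. = FALSE)
  if (inclusion_prob <= 0 || inclusion_prob > 1)
    stop("`inclusion_prob` must be in (0, 1]", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n_subsamples <- stopifnot_scalar_count(n_subsamples, "n_subsamples")
  sel_count <- stats::setNames(numeric(ncol(X)), colnames(X))
  vip_sum <- sel_count
  sdeps <- rep(NA_real_, n_subsamples)
  for (b in seq_len(n_subsamples)) {
    sub_seed <- derive_seed(seed, b)
    train <- with_seed(sub_seed, {
      tr <- NULL
      for (try in seq_len(100L)) {
        tr <- if (fixed_quota) {
          idx <- logical(n); idx[sample.int(n, round(inclusion_prob * n))] <- TRUE; idx
        } else stats::runif(n) < inclusion_prob
        if (sum(tr) >= A_max + 2L) break
        tr <- NULL
      }
      if (is.null(tr))
        stop("configuration error: inclusion_prob too low to draw a ",
             "usable training set after 100 attempts", call. = FALSE)
      tr
    })
    # a subsample containing every sample is identical data: give it a
    # fixed selection seed so such degenerate draws yield identical models
    sel_seed <- if (all(train)) derive_seed(seed, 2L) else derive_seed(sub_seed, 2L)
    sel <- select_by_vip(X[train, , drop = FALSE], y[train], folds = folds,
                         seed = sel_seed, A_max = A_max,
                         n_perm = gate_n_perm, rule = rule)
    gated <- gate_n_perm > 0 && !is.na(sel$permutation_p) &&
      sel$permutation_p > gate_alpha
    if (!gated) {
      sel_count[sel$selected] <- sel_count[sel$selected] + 1
      vip_sum <- vip_sum + sel$vip[names(vip_sum)]
    }
    if (any(!train)) {
      pred <- predict(sel$model, X[!train, sel$selected, drop = FALSE])
      sdeps[b] <- sqrt(sum((pred - y[!train])^2) / sum(!train))
    }
  }
  per_model_sdep <- sdeps[!is.na(sdeps)]
  frequency <- sel_count / n_subsamples
  structure(list(frequency = frequency,
                 relevant = names(frequency)[frequency > freq_threshold],
                 mean_sdep = if (length(per_model_sdep)) mean(per_model_sdep) else NA_real_,
                 per_model_sdep = per_model_sdep,
                 all_included = length(per_model_sdep) == 0L,
                 mean_vip = vip_sum / n_subsamples,
                 n_subsamples = n_subsamples, inclusion_prob = inclusion_prob,
                 freq_threshold = freq_threshold, seed = seed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability selection: %d subsamples, prior %.2f\n",
              x$n_subsamples, x$inclusion_prob))
  cat(sprintf("  relevant (frequency > %.2f): %s\n", x$freq_threshold,
              if (length(x$relevant)) paste(x$relevant, collapse = ", ") else "(none)"))
  cat(sprintf("  mean SDEP = %.4g\n", x$mean_sdep))
  invisible(x)
}

# Closed-form univariate OLS of y on x: slope, r2, two-sided slope-test p.
slr_stats <- function(x, y) {
  n <- length(y)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx == 0) return(c(slope = NA, intercept = NA, r2 = NA, p = NA))
  slope <- sum(xc * yc) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- yc - slope * xc
  rss <- sum(res^2); tss <- sum(yc^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) .Machine$double.xmin else
    2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  c(slope = slope, intercept = intercept, r2 = r2, p = max(p, .Machine$double.xmin))
}

#' Monte-Carlo stability summary for simple linear regression
#'
#' The univariate analogue of [stability_select_pls()]: on each Monte-Carlo
#' subsample every variable is regressed individually on the response;
#' per-variable R-squared, out-of-subsample SDEP and slope-test p-value are
#' averaged over subsamples, and a variable counts as selected in a
#' subsample when its slope test has p < `alpha`. The same frequency > 0.5
#' rule defines the relevant set.
#'
#' @param X,y data.
#' @param n_subsamples,inclusion_prob,freq_threshold,seed,fixed_quota as in
#'   [stability_select_pls()].
#' @param alpha per-subsample selection level (default 0.05).
#' @return Object of class `slr_stability_result` with per-variable
#'   `mean_r2`, `mean_sdep`, `mean_p`, `frequency`, `relevant`, and the
#'   names of constant variables excluded (`excluded`).
#' @export
stability_select_slr <- function(X, y, n_subsamples = 1000L,
                                 inclusion_prob = 0.70, freq_threshold = 0.5,
                                 alpha = 0.05, seed = 1L, fixed_quota = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need >= 10 samples for stability selection", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  constant <- apply(X, 2L, function(v) stats::var(v) == 0)
  if (any(constant))
    warning("constant variable(s) excluded: ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
  vars <- colnames(X)[!constant]
  acc <- matrix(0, length(vars), 4,
                dimnames = list(vars, c("r2", "sdep", "p", "selected")))
  n_sdep <- 0L
  n_subsamples <- stopifnot_scalar_count(n_subsamples, "n_subsamples")
  for (b in seq_len(n_subsamples)) {
    sub_seed <- derive_seed(seed, b)
    train <- with_seed(sub_seed, {
      repeat {
        tr <- if (fixed_quota) {
          idx <- logical(n); idx[sample.int(n, round(inclusion_prob * n))] <- TRUE; idx
        } else stats::runif(n) < inclusion_prob
        if (sum(tr) >= 4L) break
      }
      tr
    })
    has_test <- any(!train)
    if (has_test) n_sdep <- n_sdep + 1L
    for (v in vars) {
      st <- slr_stats(X[train, v], y[train])
      acc[v, "r2"] <- acc[v, "r2"] + st["r2"]
      acc[v, "p"] <- acc[v, "p"] + st["p"]
      acc[v, "selected"] <- acc[v, "selected"] + (st["p"] < alpha)
      if (has_test) {
        pred <- st["intercept"] + st["slope"] * X[!train, v]
        acc[v, "sdep"] <- acc[v, "sdep"] +
          sqrt(sum((pred - y[!train])^2) / sum(!train))
      }
    }
  }
  frequency <- stats::setNames(acc[, "selected"] / n_subsamples, vars)
  structure(list(mean_r2 = stats::setNames(acc[, "r2"] / n_subsamples, vars),
                 mean_sdep = stats::setNames(
                   if (n_sdep) acc[, "sdep"] / n_sdep else rep(NA_real_, length(vars)),
                   vars),
                 mean_p = stats::setNames(acc[, "p"] / n_subsamples, vars),
                 frequency = frequency,
                 relevant = vars[frequency > freq_threshold],
                 excluded = colnames(X)[constant],
                 n_subsamples = n_subsamples, inclusion_prob = inclusion_prob,
                 alpha = alpha, seed = seed),
            class = "slr_stability_result")
}

#' @export
print.slr_stability_result <- function(x, ...) {
  cat(sprintf("SLR stability: %d subsamples, prior %.2f, alpha %.2f\n",
              x$n_subsamples, x$inclusion_prob, x$alpha))
  tab <- data.frame(mean_r2 = round(x$mean_r2, 3),
                    mean_sdep = round(x$mean_sdep, 3),
                    mean_p = signif(x$mean_p, 2),
                    frequency = x$frequency)
  print(tab)
  invisible(x)
}
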
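# Matrix preprocessing: median fold change normalization, log transform,
# mean centering, and assembly of the modelling matrix ------------------------

#' Median fold change normalization
#'
#' Removes per-sample global intensity (dilution/injection) factors from a
#' peak-area matrix. The reference profile is the per-feature geometric mean
#' over samples, computed on features positive in every sample; each
#' sample's factor is the median, over features positive in the sample, of
#' its ratio to the reference, rescaled so the median factor is 1. With this
#' reference the operation is exactly idempotent: renormalizing a normalized
#' matrix returns factors of 1 to machine precision.
#'
#' @param x numeric matrix (samples x features, values >= 0) or a
#'   `feature_matrix` from [generate_feature_matrix()].
#' @return For a matrix: list with `values` (normalized matrix) and
#'   `factors` (named per-sample scalars, all > 0). For a `feature_matrix`:
#'   the same object with normalized `values` and a `normalization_factors`
#'   element.
#' @export
median_fold_change_normalize <- function(x) {
  fm <- NULL
  if (inherits(x, "feature_matrix")) { fm <- x; x <- x$values }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 samples to normalize", call. = FALSE)
  if (any(x < 0)) stop("peak areas must be non-negative", call. = FALSE)
  all_pos <- colSums(x > 0) == nrow(x)
  if (!any(all_pos)) {
    empty <- rownames(x)[rowSums(x > 0) == 0]
    stop("normalization error: no feature is positive in every sample",
         if (length(empty)) paste0(" (sample(s) with no positive feature: ",
                                   paste(empty, collapse = ", "), ")"),
         call. = FALSE)
  }
  ref <- exp(colMeans(log(x[, all_pos, drop = FALSE])))
  raw <- apply(x[, all_pos, drop = FALSE], 1L, function(r) {
    ok <- r > 0
    if (!any(ok)) return(NA_real_)
    stats::median(r[ok] / ref[ok])
  })
  bad <- which(is.na(raw))
  if (length(bad))
    stop("normalization error: sample(s) share no positive feature with the ",
         "reference: ", paste(rownames(x)[bad], collapse = ", "), call. = FALSE)
  factors <- raw / stats::median(raw)
  out <- x / factors
  if (is.null(names(factors))) names(factors) <- rownames(x)
  if (!is.null(fm)) {
    fm$values <- out
    fm$normalization_factors <- factors
    return(fm)
  }
  list(values = out, factors = factors)
}

#' Log-transform and mean-center a matrix
#'
#' `X = log(value + pseudo)`, column-centered. Natural log is used for
#' feature matrices (the base is irrelevant after centering). Column means
#' are stored so the transform can be inverted.
#'
#' @param x numeric matrix (values >= 0) or `feature_matrix`.
#' @param pseudo small positive offset added before the log (default 1 area
#'   unit); `log = FALSE` centers without transforming (the convention for
#'   targeted concentration tables).
#' @param log apply the log transform?
#' @return Object of class `model_matrix`: `X` (centered), `column_means`,
#'   `transform_log`, `centered`, `pseudo`.
#' @export
log_mean_center <- function(x, pseudo = 1, log = TRUE) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (any(x < 0)) stop("values must be non-negative", call. = FALSE)
  lx <- if (log) base::log(x + pseudo) else x
  mu <- colMeans(lx)
  structure(list(X = sweep(lx, 2L, mu), column_means = mu,
                 transform_log = log, centered = TRUE, pseudo = pseudo),
            class = "model_matrix")
}

#' Assemble aligned modelling inputs
#'
#' Matches a predictor table/matrix with a response table by sample id,
#' dropping (and counting) unmatched samples, and optionally log10-transforms
#' the response (the convention for FRAP TEACs).
#'
#' @param predictors a metabolite table (data.frame with `sample_id`), a
#'   `feature_matrix`, or a numeric matrix with sample-id rownames.
#' @param responses `data.frame` with `sample_id` and `teac` columns.
#' @param response_transform `"identity"` or `"log10"`.
#' @param log_x log-transform the predictors (default FALSE: targeted
#'   concentration tables are modelled on the raw scale)?
#' @param pseudo offset for the predictor log transform.
#' @return List of class `model_inputs`: `X` (centered matrix), `y`,
#'   `sample_id`, `labels` (cultivar/vintage when available), `n_dropped`,
#'   `response_transform`.
#' @export
build_model_inputs <- function(predictors, responses,
                               response_transform = c("identity", "log10"),
                               log_x = FALSE, pseudo = 1) {
  response_transform <- match.arg(response_transform)
  labels <- NULL
  if (inherits(predictors, "feature_matrix")) {
    labels <- predictors$samples
    mat <- predictors$values
  } else if (is.data.frame(predictors) && "sample_id" %in% names(predictors)) {
    labels <- predictors[, intersect(c("sample_id", "cultivar", "vintage", "replicate"),
                                     names(predictors)), drop = FALSE]
    mat <- metabolite_matrix(predictors)
  } else {
    mat <- as.matrix(predictors)
  }
  if (is.null(rownames(mat)))
    stop("predictors must carry sample ids", call. = FALSE)
  ids <- intersect(rownames(mat), responses$sample_id)
  if (!length(ids))
    stop("alignment error: no samples shared between predictors and responses",
         call. = FALSE)
  n_dropped <- (nrow(mat) - length(ids)) +
    (length(unique(responses$sample_id)) - length(ids))
  if (n_dropped > 0)
    message(sprintf("build_model_inputs: dropped %d unmatched sample(s)", n_dropped))
  mat <- mat[ids, , drop = FALSE]
  y <- responses$teac[match(ids, responses$sample_id)]
  if (response_transform == "log10") {
    if (any(y <= 0))
      stop("log10 response transform requires strictly positive TEACs",
           call. = FALSE)
    y <- log10(y)
  }
  mm <- log_mean_center(mat, pseudo = pseudo, log = log_x)
  if (!is.null(labels)) labels <- labels[match(ids, labels$sample_id), , drop = FALSE]
  structure(list(X = mm$X, y = stats::setNames(y, ids), sample_id = ids,
                 labels = labels, n_dropped = n_dropped,
                 response_transform = response_transform,
                 transform_log = log_x, pseudo = pseudo),
            class = "model_inputs")
}
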
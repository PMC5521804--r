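# Synthetic study generator -------------------------------------------------
#
# Emulates a multi-cultivar stone-fruit metabolomics study: a targeted
# metabolite table (mg per 100 g fresh weight), per-sample antioxidant
# responses (TEAC, mmol Trolox equivalents per kg), an untargeted LC-MS
# feature matrix with isotope/adduct structure, and plate-reader assay
# simulations. Variance is cultivar-dominant with a weak vintage effect and
# replicate-pool noise, so ordination clusters samples by cultivar.

#' Names of the targeted metabolites simulated by default
#'
#' Seven compounds typical of sweet-cherry targeted panels: two cyanidin
#' glycosides (anthocyanins), two quercetin glycosides, two caffeoylquinic
#' acids (hydroxycinnamic acids) and ascorbic acid.
#'
#' @return Character vector of metabolite names.
#' @export
default_metabolites <- function() {
  c("cyanidin_3_rutinoside", "cyanidin_3_glucoside",
    "quercetin_3_rutinoside", "quercetin_3_glucoside",
    "chlorogenic_acid", "neochlorogenic_acid",
    "ascorbic_acid")
}

#' Metabolite class lookup
#'
#' Maps metabolite names to the four antioxidant classes used in the
#' depletion analysis.
#'
#' @param metabolites character vector of metabolite names.
#' @return Character vector of classes: `"anthocyanin"`, `"quercetin"`,
#'   `"hydroxycinnamic_acid"` or `"ascorbic_acid"`.
#' @export
metabolite_class <- function(metabolites) {
  cls <- rep(NA_character_, length(metabolites))
  cls[grepl("^cyanidin|^peonidin", metabolites)] <- "anthocyanin"
  cls[grepl("^quercetin", metabolites)] <- "quercetin"
  cls[grepl("chlorogenic|coumaroyl|caffeoyl", metabolites)] <- "hydroxycinnamic_acid"
  cls[grepl("ascorbic", metabolites)] <- "ascorbic_acid"
  cls
}

#' Simulation configuration
#'
#' Bundles the design and noise parameters of the synthetic study. The
#' defaults reproduce the scale of the emulated design: 18 cultivars x 2
#' vintages x 3 replicate pools (108 samples), per-cultivar anthocyanin
#' means spanning 14-114 mg/100 g fresh weight, ascorbic acid 7-15 mg/100 g,
#' hydroxycinnamic acids up to 65 and quercetin glycosides up to 7 mg/100 g.
#'
#' @param n_cultivars,n_vintages,n_replicates design counts (replicate =
#'   biological pool within cultivar x vintage).
#' @param cultivar_means optional matrix (cultivars x metabolites) of mean
#'   concentrations in mg/100 g fresh weight; drawn from the default ranges
#'   when `NULL`.
#' @param metabolites metabolite names (columns of `cultivar_means`).
#' @param vintage_shift_sd SD of the shared log-normal vintage multiplier
#'   applied per metabolite and vintage (relative scale).
#' @param replicate_cv coefficient of variation of the multiplicative
#'   log-normal replicate-pool noise.
#' @param n_noise_features count of uninformative LC-MS features.
#' @param response_intercept baseline TEAC in mmol TE/kg.
#' @param response_coefficients named per-metabolite linear weights
#'   (mmol TE/kg per mg/100 g).
#' @param synergy_terms list of `list(i =, j =, weight =)` pairwise
#'   interaction terms between metabolites (names or indices).
#' @param response_noise_sd SD of the additive response noise, mmol TE/kg.
#' @param intensity_factor_sd log-SD of the per-sample global LC-MS
#'   intensity factor.
#' @param isotope_fraction,adduct_fraction relative intensity of the +1
#'   isotopologue and adduct features (0 disables the feature).
#' @param feature_noise_cv multiplicative measurement noise on monoisotopic
#'   feature intensities.
#' @param noise_feature_cv sample-to-sample coefficient of variation of the
#'   uninformative features (their only systematic structure is the global
#'   intensity factor).
#' @param seed RNG seed; all generators derive their streams from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cultivars = 18L, n_vintages = 2L, n_replicates = 3L,
                       cultivar_means = NULL,
                       metabolites = default_metabolites(),
                       vintage_shift_sd = 0.05,
                       replicate_cv = 0.15,
                       n_noise_features = 104L,
                       response_intercept = 2,
                       response_coefficients = NULL,
                       synergy_terms = list(),
                       response_noise_sd = 1,
                       intensity_factor_sd = 0.25,
                       isotope_fraction = 0.1,
                       adduct_fraction = 0.3,
                       feature_noise_cv = 0.05,
                       noise_feature_cv = 0.3,
                       seed = 1L) {
  for (nm in c("n_cultivars", "n_vintages", "n_replicates"))
    stopifnot_scalar_count(get(nm), nm)
  if (n_noise_features < 0) stop("`n_noise_features` must be >= 0", call. = FALSE)
  for (nm in c("vintage_shift_sd", "replicate_cv", "response_noise_sd",
               "intensity_factor_sd", "isotope_fraction", "adduct_fraction",
               "feature_noise_cv", "noise_feature_cv"))
    if (get(nm) < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)

  if (is.null(cultivar_means)) {
    cultivar_means <- with_seed(derive_seed(seed, 101L),
                                default_cultivar_means(n_cultivars, metabolites))
  } else {
    cultivar_means <- as.matrix(cultivar_means)
    if (is.null(colnames(cultivar_means))) colnames(cultivar_means) <- metabolites
    metabolites <- colnames(cultivar_means)
    if (nrow(cultivar_means) != n_cultivars)
      stop("`cultivar_means` must have one row per cultivar", call. = FALSE)
    if (any(cultivar_means < 0))
      stop("`cultivar_means` must be non-negative", call. = FALSE)
  }

  if (is.null(response_coefficients)) {
    response_coefficients <- default_response_coefficients(metabolites)
  } else {
    if (is.null(names(response_coefficients)))
      names(response_coefficients) <- metabolites
    missing <- setdiff(metabolites, names(response_coefficients))
    if (length(missing))
      stop("`response_coefficients` missing for: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  structure(list(
    n_cultivars = as.integer(n_cultivars), n_vintages = as.integer(n_vintages),
    n_replicates = as.integer(n_replicates),
    cultivar_means = cultivar_means, metabolites = metabolites,
    vintage_shift_sd = vintage_shift_sd, replicate_cv = replicate_cv,
    n_noise_features = as.integer(n_noise_features),
    response_intercept = response_intercept,
    response_coefficients = response_coefficients,
    synergy_terms = synergy_terms,
    response_noise_sd = response_noise_sd,
    intensity_factor_sd = intensity_factor_sd,
    isotope_fraction = isotope_fraction, adduct_fraction = adduct_fraction,
    feature_noise_cv = feature_noise_cv,
    noise_feature_cv = noise_feature_cv,
    seed = as.integer(seed)), class = "sim_config")
}

# Per-cultivar means drawn uniformly inside the literature concentration
# ranges; class totals are split between the two glycosides with a share
# that itself varies by cultivar (so no two metabolites are collinear):
# anthocyanin totals span 14-114 mg/100 g, quercetins up to 7,
# hydroxycinnamic acids up to 65, ascorbate 7-15.
default_cultivar_means <- function(n_cultivars, metabolites) {
  m <- matrix(0, n_cultivars, length(metabolites),
              dimnames = list(paste0("cv", sprintf("%02d", seq_len(n_cultivars))),
                              metabolites))
  cls <- metabolite_class(metabolites)
  ac_total <- runif(n_cultivars, 14, 114)
  q_total <- runif(n_cultivars, 1, 7)
  hca_total <- runif(n_cultivars, 10, 65)
  asc <- runif(n_cultivars, 7, 15)
  split2 <- function(total, lo, hi) {
    share <- runif(length(total), lo, hi)
    cbind(total * share, total * (1 - share))
  }
  idx <- function(cl) which(cls == cl)
  i <- idx("anthocyanin")
  if (length(i)) m[, i] <- split2(ac_total, 0.6, 0.8)[, seq_along(i), drop = FALSE]
  i <- idx("quercetin")
  if (length(i)) m[, i] <- split2(q_total, 0.5, 0.7)[, seq_along(i), drop = FALSE]
  i <- idx("hydroxycinnamic_acid")
  if (length(i)) m[, i] <- split2(hca_total, 0.45, 0.65)[, seq_along(i), drop = FALSE]
  i <- idx("ascorbic_acid")
  if (length(i)) m[, i] <- asc
  m
}

# Unit antioxidant activities (mmol TE/kg per mg/100 g): cyanidin
# 3-O-rutinoside strongest, then ascorbate and cyanidin 3-O-glucoside;
# quercetins and hydroxycinnamic acids weaker.
default_response_coefficients <- function(metabolites) {
  cls <- metabolite_class(metabolites)
  beta <- stats::setNames(rep(0.01, length(metabolites)), metabolites)
  beta[cls == "anthocyanin"] <- 0.06
  beta["cyanidin_3_rutinoside"] <- if ("cyanidin_3_rutinoside" %in% metabolites) 0.10 else NA
  beta <- beta[!is.na(beta)]
  beta[cls == "ascorbic_acid"] <- 0.08
  beta[cls == "quercetin"] <- 0.02
  beta[cls == "hydroxycinnamic_acid"] <- 0.01
  beta[metabolites]
}

#' Generate a targeted metabolite table
#'
#' Each concentration is cultivar mean x vintage multiplier x mean-one
#' log-normal replicate noise, truncated at zero. The vintage multiplier is a
#' log-normal shift shared across cultivars, drawn per metabolite and
#' vintage, reproducing a weak vintage effect relative to cultivar identity.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with columns `sample_id`, `cultivar`, `vintage`,
#'   `replicate` and one numeric column per metabolite (mg/100 g fresh
#'   weight). The configuration seed is stored in attribute `"seed"`.
#' @export
generate_metabolite_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    nc <- config$n_cultivars; nv <- config$n_vintages; nr <- config$n_replicates
    mets <- config$metabolites; p <- length(mets)
    cultivars <- rownames(config$cultivar_means)
    vintages <- paste0("v", seq_len(nv))
    # shared multiplicative vintage shift, per metabolite x vintage
    vshift <- matrix(exp(stats::rnorm(nv * p, 0, config$vintage_shift_sd)),
                     nv, p, dimnames = list(vintages, mets))
    grid <- expand.grid(replicate = seq_len(nr), vintage = vintages,
                        cultivar = cultivars, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)[, c("cultivar", "vintage", "replicate")]
    n <- nrow(grid)
    cv <- config$replicate_cv
    sdlog <- sqrt(log1p(cv^2))
    noise <- matrix(stats::rlnorm(n * p, meanlog = -sdlog^2 / 2, sdlog = sdlog), n, p)
    conc <- config$cultivar_means[grid$cultivar, , drop = FALSE] *
      vshift[grid$vintage, , drop = FALSE] * noise
    conc[conc < 0] <- 0
    out <- data.frame(
      sample_id = paste(grid$cultivar, grid$vintage, paste0("r", grid$replicate),
                        sep = "_"),
      grid, conc, stringsAsFactors = FALSE, check.names = FALSE)
    attr(out, "seed") <- config$seed
    attr(out, "metabolites") <- mets
    out
  })
}

# numeric concentration matrix from a metabolite table
metabolite_matrix <- function(table) {
  mets <- attr(table, "metabolites")
  if (is.null(mets))
    mets <- setdiff(colnames(table), c("sample_id", "cultivar", "vintage", "replicate"))
  m <- as.matrix(table[, mets, drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

#' Generate per-sample antioxidant responses
#'
#' The response is a linear model in the concentrations plus optional
#' pairwise product (synergy) terms:
#' TEAC_i = intercept + sum_j beta_j c_ij + sum_(j,k) gamma_jk c_ij c_ik + eps_i,
#' with Gaussian noise. Positive gamma terms make the mixture exceed its
#' additive expectation, the signature of antioxidant synergy.
#'
#' @param table a metabolite table from [generate_metabolite_table()].
#' @param config a [sim_config()]; `response_coefficients` must cover the
#'   table's metabolites.
#' @return `data.frame` with `sample_id`, `teac` (mmol TE/kg) and the
#'   noise-free `teac_true`.
#' @export
generate_responses <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  conc <- metabolite_matrix(table)
  beta <- config$response_coefficients
  missing <- setdiff(colnames(conc), names(beta))
  if (length(missing))
    stop("response coefficients missing for metabolites: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mu <- config$response_intercept + drop(conc %*% beta[colnames(conc)])
  for (term in config$synergy_terms) {
    i <- term$i; j <- term$j
    if (is.character(i) && !i %in% colnames(conc))
      stop("synergy term names unknown metabolite: ", i, call. = FALSE)
    if (is.character(j) && !j %in% colnames(conc))
      stop("synergy term names unknown metabolite: ", j, call. = FALSE)
    mu <- mu + term$weight * conc[, i] * conc[, j]
  }
  eps <- with_seed(derive_seed(config$seed, 2L),
                   stats::rnorm(nrow(conc), 0, config$response_noise_sd))
  data.frame(sample_id = table$sample_id, teac = mu + eps, teac_true = mu,
             stringsAsFactors = FALSE)
}

#' Expand a metabolite table into an untargeted LC-MS feature matrix
#'
#' Each metabolite yields a monoisotopic feature plus (when the respective
#' fraction is positive) a +1 isotopologue and an adduct feature at fixed
#' relative intensity, all scaled by a per-sample global intensity factor
#' (log-normal) — the instrument drift that median fold change normalization
#' removes. Uninformative noise features are independent of cultivar but
#' share the sample intensity factor.
#'
#' @param table a metabolite table.
#' @param config a [sim_config()].
#' @return List of class `feature_matrix`: `values` (samples x features peak
#'   areas), `features` (`data.frame` with `feature_id`, `mz`, `rt`,
#'   `annotation`), `samples` (labels), and the true `intensity_factors`
#'   (kept for parameter-recovery tests).
#' @export
generate_feature_matrix <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(table) == 0) stop("metabolite table is empty", call. = FALSE)
  conc <- metabolite_matrix(table)
  n <- nrow(conc); mets <- colnames(conc)
  with_seed(derive_seed(config$seed, 3L), {
    ion_response <- stats::rlnorm(length(mets), meanlog = log(1e5), sdlog = 0.5)
    mz <- stats::runif(length(mets), 150, 900)
    rt <- stats::runif(length(mets), 2, 28)
    sf <- stats::rlnorm(n, 0, config$intensity_factor_sd)
    cvn <- config$feature_noise_cv
    sdlog <- sqrt(log1p(cvn^2))
    feats <- list(); meta <- list()
    for (k in seq_along(mets)) {
      base <- conc[, k] * ion_response[k] *
        stats::rlnorm(n, -sdlog^2 / 2, sdlog)
      feats[[length(feats) + 1L]] <- base
      meta[[length(meta) + 1L]] <- data.frame(
        feature_id = sprintf("F%03d_M", k), mz = mz[k], rt = rt[k],
        annotation = mets[k], stringsAsFactors = FALSE)
      if (config$isotope_fraction > 0) {
        feats[[length(feats) + 1L]] <- base * config$isotope_fraction
        meta[[length(meta) + 1L]] <- data.frame(
          feature_id = sprintf("F%03d_I", k), mz = mz[k] + 1.0033, rt = rt[k],
          annotation = paste0(mets[k], "_isotope"), stringsAsFactors = FALSE)
      }
      if (config$adduct_fraction > 0) {
        feats[[length(feats) + 1L]] <- base * config$adduct_fraction
        meta[[length(meta) + 1L]] <- data.frame(
          feature_id = sprintf("F%03d_A", k), mz = mz[k] + 46.0055, rt = rt[k],
          annotation = paste0(mets[k], "_adduct"), stringsAsFactors = FALSE)
      }
    }
    if (config$n_noise_features > 0) {
      nn <- config$n_noise_features
      base_mean <- stats::rlnorm(nn, log(5e4), 1)
      nsd <- sqrt(log1p(config$noise_feature_cv^2))
      noise <- matrix(stats::rlnorm(n * nn, -nsd^2 / 2, nsd), n, nn) *
        rep(base_mean, each = n)
      for (k in seq_len(nn)) {
        feats[[length(feats) + 1L]] <- noise[, k]
        meta[[length(meta) + 1L]] <- data.frame(
          feature_id = sprintf("N%03d", k), mz = stats::runif(1, 150, 900),
          rt = stats::runif(1, 2, 28), annotation = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    values <- do.call(cbind, feats) * sf
    features <- do.call(rbind, meta)
    colnames(values) <- features$feature_id
    rownames(values) <- table$sample_id
    structure(list(values = values, features = features,
                   samples = table[, c("sample_id", "cultivar", "vintage", "replicate")],
                   intensity_factors = stats::setNames(sf, table$sample_id)),
              class = "feature_matrix")
  })
}

#' Simulate a plate-reader assay
#'
#' Produces a long-format plate table with Trolox standard wells (the
#' calibration curve's own levels, read back through the line) and replicate
#' sample wells whose absorbance follows
#' `intercept + slope * implied_extract_concentration + noise`. The implied
#' concentration inverts the TEAC unit conversion used by
#' [teac_from_absorbance()], so the two functions are exact inverses at zero
#' noise.
#'
#' @param true_teac named vector of true sample TEACs, mmol TE/kg (>= 0).
#' @param curve a [calibration_curve] with positive slope (signal per mM
#'   Trolox).
#' @param protocol an [extraction_protocol()].
#' @param n_wells replicate wells per sample.
#' @param noise_sd absorbance noise SD (AU).
#' @param seed RNG seed.
#' @return `data.frame` with columns `well_type` (`"standard"`/`"sample"`),
#'   `sample_id`, `known_conc` (mM, standards only), `replicate`,
#'   `absorbance`.
#' @export
simulate_assay_plate <- function(true_teac, curve, protocol,
                                 n_wells = 3L, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration curve slope must be > 0", call. = FALSE)
  if (any(true_teac < 0)) stop("`true_teac` must be non-negative", call. = FALSE)
  if (is.null(names(true_teac)))
    names(true_teac) <- paste0("s", seq_along(true_teac))
  with_seed(seed, {
    std <- curve$levels
    std_rows <- data.frame(well_type = "standard",
                           sample_id = paste0("trolox_", seq_len(nrow(std))),
                           known_conc = std$concentration, replicate = 1L,
                           absorbance = curve$intercept + curve$slope * std$concentration +
                             stats::rnorm(nrow(std), 0, noise_sd),
                           stringsAsFactors = FALSE)
    conc <- true_teac / (protocol$solvent_volumes * protocol$dilution_factor)
    smp <- expand.grid(replicate = seq_len(n_wells),
                       sample_id = names(true_teac),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    smp_rows <- data.frame(well_type = "sample", sample_id = smp$sample_id,
                           known_conc = NA_real_, replicate = smp$replicate,
                           absorbance = curve$intercept +
                             curve$slope * conc[smp$sample_id] +
                             stats::rnorm(nrow(smp), 0, noise_sd),
                           stringsAsFactors = FALSE)
    rbind(std_rows, smp_rows)
  })
}
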
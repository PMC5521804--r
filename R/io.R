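# CSV/JSON interchange and the end-to-end pipeline driver --------------------

#' Read a schema-checked CSV table
#'
#' UTF-8, dot-decimal CSV with a header row. Missing required columns and
#' non-numeric cells in numeric columns are reported with their location;
#' decimal commas are rejected explicitly.
#'
#' @param path file path.
#' @param required_cols character vector of columns that must be present.
#' @param numeric_cols columns that must parse as numbers.
#' @return `data.frame`.
#' @export
read_table_checked <- function(path, required_cols = character(),
                               numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  miss <- setdiff(required_cols, names(tab))
  if (length(miss))
    stop("parse error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cl in intersect(numeric_cols, names(tab))) {
    v <- tab[[cl]]
    if (is.numeric(v)) next
    if (any(grepl(",", v)))
      stop(sprintf("parse error: column `%s` uses a decimal comma; ", cl),
           "dot-decimal CSV is required", call. = FALSE)
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad))
      stop(sprintf("parse error: non-numeric cell in column `%s`, row %d",
                   cl, bad[1]), call. = FALSE)
    tab[[cl]] <- num
  }
  tab
}

#' Write a table as dot-decimal UTF-8 CSV
#'
#' @param x data.frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write a metabolite table
#'
#' The CSV round trip preserves the sample labels and metabolite columns.
#'
#' @param path file path.
#' @rdname metabolite_io
#' @return `read_metabolite_table` returns the table with its metabolite
#'   attribute restored.
#' @export
read_metabolite_table <- function(path) {
  tab <- read_table_checked(path, c("sample_id", "cultivar", "vintage", "replicate"))
  mets <- setdiff(names(tab), c("sample_id", "cultivar", "vintage", "replicate"))
  for (m in mets) tab[[m]] <- as.numeric(tab[[m]])
  attr(tab, "metabolites") <- mets
  tab
}

#' @param table metabolite table.
#' @rdname metabolite_io
#' @export
write_metabolite_table <- function(table, path) write_table_csv(table, path)

#' Serialize / deserialize a calibration curve as JSON
#'
#' @param curve [calibration_curve].
#' @param path file path.
#' @rdname curve_io
#' @export
write_curve_json <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$levels <- as.data.frame(x$levels)
  structure(x, class = "calibration_curve")
}

#' Run the full synthetic-study pipeline
#'
#' Composes the package end to end: simulate a study (metabolite table,
#' responses, feature matrix, assay plates), calibrate, normalize, build the
#' modelling matrix, run VIP-based PLS selection and Monte-Carlo stability
#' selection, score a depletion panel, and write a report bundle.
#'
#' @param config named list (or path to a YAML file) with optional entries:
#'   `seed` (master seed; fans out deterministically to every stage),
#'   `out_dir` (when given, CSV/JSON artifacts and the resolved config are
#'   written there), `sim` (arguments for [sim_config()]), `folds`,
#'   `n_subsamples`, `inclusion_prob`, `n_perm`, `alpha`,
#'   `response_transform` (`"identity"`/`"log10"`), `use_features` (model
#'   the untargeted matrix instead of the targeted table), and the stage
#'   toggles `run_stability`, `run_synergy`.
#' @return List with the generated data, the selection and stability
#'   results, the synergy panel, and a one-line-per-stage `log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "sim", "folds", "n_subsamples",
             "inclusion_prob", "n_perm", "alpha", "response_transform",
             "use_features", "run_stability", "run_synergy")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(list(
    seed = 1L, out_dir = NULL, sim = list(), folds = 7L, n_subsamples = 200L,
    inclusion_prob = 0.70, n_perm = 199L, alpha = 0.05,
    response_transform = "identity", use_features = FALSE,
    run_stability = TRUE, run_synergy = TRUE), config)
  log <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log <<- c(log, line)
  }

  sim <- do.call(sim_config, utils::modifyList(list(seed = derive_seed(cfg$seed, 1L)),
                                               cfg$sim))
  table <- generate_metabolite_table(sim)
  responses <- generate_responses(table, sim)
  note("simulate: %d samples x %d metabolites", nrow(table),
       length(sim$metabolites))

  features <- generate_feature_matrix(table, sim)
  norm <- median_fold_change_normalize(features)
  note("normalize: %d features, factor range [%.3f, %.3f]",
       ncol(norm$values), min(norm$normalization_factors),
       max(norm$normalization_factors))

  predictors <- if (isTRUE(cfg$use_features)) norm else table
  inputs <- build_model_inputs(predictors, responses,
                               response_transform = cfg$response_transform,
                               log_x = isTRUE(cfg$use_features))
  sel <- select_by_vip(inputs$X, inputs$y, folds = cfg$folds,
                       seed = derive_seed(cfg$seed, 2L),
                       n_perm = cfg$n_perm)
  note("select: %d/%d variables, A = %d, R2 = %.3f, Q2 = %.3f, SDECV = %.3g, perm p = %.3g",
       length(sel$selected), ncol(inputs$X), sel$model$A, sel$model$r2,
       sel$model$q2, sel$model$sdecv, sel$permutation_p)

  stability <- NULL
  if (isTRUE(cfg$run_stability)) {
    stability <- stability_select_pls(inputs$X, inputs$y,
                                      n_subsamples = cfg$n_subsamples,
                                      inclusion_prob = cfg$inclusion_prob,
                                      seed = derive_seed(cfg$seed, 3L))
    note("stability: %d relevant of %d variables, mean SDEP = %.3g",
         length(stability$relevant), ncol(inputs$X), stability$mean_sdep)
  }

  synergy <- NULL
  if (isTRUE(cfg$run_synergy)) {
    demo <- synthetic_depletion_panel(seed = derive_seed(cfg$seed, 4L))
    synergy <- run_depletion_panel(demo$designs, demo$plates, demo$curve,
                                   demo$protocol,
                                   seed = derive_seed(cfg$seed, 5L),
                                   alpha = cfg$alpha)
    note("synergy: %d assessments (%s)", nrow(synergy),
         paste(sprintf("%s=%s", synergy$class, synergy$classification),
               collapse = ", "))
  }

  out <- list(config = cfg, metabolites = table, responses = responses,
              features = features, normalized = norm, inputs = inputs,
              selection = sel, stability = stability, synergy = synergy,
              log = log)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metabolite_table(table, file.path(cfg$out_dir, "metabolites.csv"))
    write_table_csv(responses, file.path(cfg$out_dir, "responses.csv"))
    write_table_csv(data.frame(sample_id = names(norm$normalization_factors),
                               factor = norm$normalization_factors),
                    file.path(cfg$out_dir, "normalization_factors.csv"))
    write_table_csv(data.frame(variable = names(sel$vip), vip = sel$vip,
                               selected = names(sel$vip) %in% sel$selected),
                    file.path(cfg$out_dir, "selection.csv"))
    if (!is.null(stability))
      write_table_csv(data.frame(variable = names(stability$frequency),
                                 frequency = stability$frequency,
                                 mean_vip = stability$mean_vip,
                                 relevant = names(stability$frequency) %in%
                                   stability$relevant),
                      file.path(cfg$out_dir, "stability.csv"))
    if (!is.null(synergy))
      write_table_csv(synergy, file.path(cfg$out_dir, "synergy.csv"))
    summary <- list(seed = cfg$seed, A = sel$model$A, r2 = sel$model$r2,
                    q2 = sel$model$q2, sdecv = sel$model$sdecv,
                    permutation_p = sel$permutation_p,
                    selected = sel$selected,
                    relevant = if (!is.null(stability)) stability$relevant,
                    mean_sdep = if (!is.null(stability)) stability$mean_sdep)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")],
                     file.path(cfg$out_dir, "resolved_config.yaml"))
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  }
  invisible(out)
}

#' Build a synthetic depletion-panel demonstration
#'
#' Constructs designs, noiseless-chemistry plate absorbances and the
#' matching Trolox curve for a reconstituted phytocomplex experiment with a
#' planted pairwise interaction between anthocyanins and quercetins (and
#' anthocyanins and ascorbic acid) in the first design only, mirroring a
#' cultivar-dependent synergy; the second and third designs are purely
#' additive. A fourth, anthocyanin-free design derived from the first shows
#' the synergy vanishing when its required partner is absent.
#'
#' @param seed RNG seed for plate noise.
#' @param noise_sd absorbance noise SD (AU).
#' @param synergy_weight interaction weight; activity of a full mixture is
#'   additive TEAC + weight * conc_i * conc_j for each planted pair.
#' @return List with `designs`, `plates`, `curve`, `protocol`,
#'   `true_classes` (the planted classification per design x class).
#' @export
synthetic_depletion_panel <- function(seed = 1L, noise_sd = 0.002,
                                      synergy_weight = 0.004) {
  protocol <- extraction_protocol()
  curve <- fit_standard_curve(
    data.frame(concentration = seq(0, 1, by = 0.2),
               signal = 0.05 + 0.9 * seq(0, 1, by = 0.2)),
    analyte = "trolox", wavelength = 593)
  # compound concentrations (mg/ml) and unit activities per design
  comp <- function(design, synergy) {
    x <- data.frame(
      compound = c("cyanidin_3_rutinoside", "cyanidin_3_glucoside",
                   "quercetin_3_rutinoside", "chlorogenic_acid",
                   "ascorbic_acid"),
      class = c("anthocyanin", "anthocyanin", "quercetin",
                "hydroxycinnamic_acid", "ascorbic_acid"),
      concentration = switch(design,
                             ST = c(60, 25, 5, 30, 12),
                             SA = c(25, 10, 4, 25, 10),
                             GS = c(12, 5, 3, 20, 9),
                             ST_noAC = c(0, 0, 5, 30, 12)),
      unit_activity = c(0.10, 0.06, 0.02, 0.01, 0.08),
      stringsAsFactors = FALSE)
    x <- x[x$concentration > 0, ]
    attr(x, "synergy") <- synergy
    x
  }
  class_conc <- function(x, cl) sum(x$concentration[x$class == cl])
  # true TEAC of a mixture: additive sum plus, when synergy is on and
  # anthocyanins are present, interaction terms AC x quercetin and AC x asc
  mixture_teac <- function(x) {
    teac <- expected_additive_teac(x)
    if (isTRUE(attr(x, "synergy"))) {
      ac <- class_conc(x, "anthocyanin")
      teac <- teac + synergy_weight * ac * class_conc(x, "quercetin") +
        synergy_weight * ac * class_conc(x, "ascorbic_acid")
    }
    teac
  }
  designs <- list(); plates <- list(); truth <- list()
  for (d in c("ST", "SA", "GS", "ST_noAC")) {
    syn <- d == "ST"  # planted: synergy only in the first composition
    x <- comp(d, syn)
    conds <- list(full = x)
    for (cl in unique(x$class)) {
      conds[[paste0("depleted:", cl)]] <- structure(x[x$class != cl, ],
                                                    synergy = syn)
      conds[[paste0("isolated:", cl)]] <- structure(x[x$class == cl, ],
                                                    synergy = syn)
    }
    for (cond in names(conds)) {
      xc <- conds[[cond]]
      designs[[length(designs) + 1L]] <-
        data.frame(design = d, condition = cond, compound = xc$compound,
                   class = xc$class, concentration = xc$concentration,
                   stringsAsFactors = FALSE)
      teac <- mixture_teac(xc)
      plate <- simulate_assay_plate(c(mix = teac), curve, protocol,
                                    n_wells = 3L, noise_sd = noise_sd,
                                    seed = derive_seed(seed, length(plates) + 1L))
      plate <- plate[plate$well_type == "sample", ]
      plates[[length(plates) + 1L]] <-
        data.frame(design = d, condition = cond, replicate = plate$replicate,
                   absorbance = plate$absorbance, stringsAsFactors = FALSE)
    }
    for (cl in unique(x$class)) {
      ac_present <- class_conc(x, "anthocyanin") > 0
      synergic <- syn && ac_present && synergy_weight > 0 &&
        ((cl == "anthocyanin") || cl %in% c("quercetin", "ascorbic_acid"))
      truth[[length(truth) + 1L]] <-
        data.frame(design = d, class = cl,
                   true_class = if (synergic) "synergistic" else "additive",
                   stringsAsFactors = FALSE)
    }
  }
  list(designs = do.call(rbind, designs), plates = do.call(rbind, plates),
       curve = curve, protocol = protocol,
       true_classes = do.call(rbind, truth))
}
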
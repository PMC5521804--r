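# Standard-curve calibration and TEAC conversion -----------------------------

#' Fit a linear standard curve
#'
#' Ordinary least squares of signal on concentration over serial-dilution
#' standards, intercept free (blanks are not forced to zero signal).
#'
#' @param levels `data.frame` (or list of pairs) with columns `concentration`
#'   and `signal`; at least two distinct concentrations.
#' @param analyte analyte name (e.g. `"trolox"`).
#' @param wavelength detection wavelength in nm, stored as metadata.
#' @return Object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared` and the levels used.
#' @examples
#' fit_standard_curve(data.frame(concentration = 0:2, signal = c(0, 2, 4)),
#'                    "trolox", 593)
#' @export
fit_standard_curve <- function(levels, analyte = "trolox", wavelength = NA_real_) {
  levels <- as.data.frame(levels)
  if (!all(c("concentration", "signal") %in% names(levels)))
    stop("`levels` needs columns `concentration` and `signal`", call. = FALSE)
  if (nrow(levels) < 2 || length(unique(levels$concentration)) < 2)
    stop("degenerate design: need >= 2 distinct concentration levels",
         call. = FALSE)
  fit <- stats::lm(signal ~ concentration, data = levels)
  ss_tot <- sum((levels$signal - mean(levels$signal))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(analyte = analyte, wavelength = wavelength,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, levels = levels),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: %s (%s nm)\n", x$analyte,
              format(x$wavelength)))
  cat(sprintf("  signal = %.5g + %.5g * conc   (r^2 = %.4f, %d levels)\n",
              x$intercept, x$slope, x$r_squared, nrow(x$levels)))
  invisible(x)
}

#' Extraction protocol
#'
#' Records how a powder sample becomes the liquid read on the plate:
#' `powder_mass` grams extracted in `solvent_volumes` volumes of solvent
#' (1 ml per g), diluted `dilution_factor`-fold, `aliquot_volume` ul of
#' extract added to `assay_volume` ul of reaction mixture. The defaults
#' mirror a FRAP protocol: 150 mg powder in nine volumes of acidified
#' methanol, five-fold dilution, 20 ul extract into 200 ul aliquots.
#'
#' Because extract volume is `powder_mass * solvent_volumes` ml, the
#' mmol-TE/kg conversion is independent of the mass itself; only the
#' volumes-and-dilution product matters.
#'
#' @param powder_mass g of powder.
#' @param solvent_volumes solvent volume as a multiple of the mass.
#' @param dilution_factor fold dilution of the crude extract.
#' @param aliquot_volume,assay_volume ul, metadata (standards and samples
#'   share them, so they cancel in the Trolox comparison).
#' @return Object of class `extraction_protocol`.
#' @export
extraction_protocol <- function(powder_mass = 0.150, solvent_volumes = 9,
                                dilution_factor = 5, aliquot_volume = 20,
                                assay_volume = 200) {
  vals <- c(powder_mass = powder_mass, solvent_volumes = solvent_volumes,
            dilution_factor = dilution_factor, aliquot_volume = aliquot_volume,
            assay_volume = assay_volume)
  if (any(vals <= 0))
    stop("all extraction protocol fields must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "extraction_protocol")
}

#' Convert replicate absorbances to TEAC
#'
#' Per replicate, the Trolox-equivalent concentration of the diluted extract
#' is `(A - intercept) / slope` (mM); multiplying by `dilution_factor` and
#' `solvent_volumes` converts to mmol TE per kg of starting material.
#' Sub-blank absorbances clamp to zero TEAC and set the `clamped` flag
#' (plate noise routinely produces small negatives).
#'
#' @param absorbances numeric vector of replicate absorbances (AU).
#' @param curve a [calibration_curve] with slope > 0.
#' @param protocol an [extraction_protocol()].
#' @param sample_id,assay labels carried into the result.
#' @return Object of class `teac_result`: `teac` (mean, mmol TE/kg), `sd`,
#'   `n`, `replicate_values`, `clamped`.
#' @export
teac_from_absorbance <- function(absorbances, curve, protocol,
                                 sample_id = NA_character_, assay = "FRAP") {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(protocol, "extraction_protocol"))
  if (curve$slope <= 0)
    stop("calibration error: slope must be > 0", call. = FALSE)
  conc <- (absorbances - curve$intercept) / curve$slope
  clamped <- conc < 0
  conc[clamped] <- 0
  if (any(clamped))
    warning(sprintf("%d replicate(s) below blank clamped to 0", sum(clamped)),
            call. = FALSE)
  teac <- conc * protocol$solvent_volumes * protocol$dilution_factor
  teac_result(sample_id = sample_id, assay = assay, replicate_values = teac,
              clamped = any(clamped))
}

#' TEAC result container
#'
#' @param sample_id,assay labels.
#' @param replicate_values replicate TEACs, mmol TE/kg.
#' @param clamped whether any replicate was clamped at the blank.
#' @return Object of class `teac_result`.
#' @export
teac_result <- function(sample_id, assay = "FRAP", replicate_values,
                        clamped = FALSE) {
  structure(list(sample_id = sample_id, assay = assay,
                 teac = mean(replicate_values),
                 sd = if (length(replicate_values) > 1) stats::sd(replicate_values) else NA_real_,
                 n = length(replicate_values),
                 replicate_values = replicate_values, clamped = clamped),
            class = "teac_result")
}

#' @export
print.teac_result <- function(x, ...) {
  cat(sprintf("%s TEAC [%s]: %.3f mmol TE/kg (sd %.3f, n = %d)%s\n",
              x$assay, x$sample_id, x$teac,
              if (is.na(x$sd)) 0 else x$sd, x$n,
              if (isTRUE(x$clamped)) " [clamped]" else ""))
  invisible(x)
}

#' Quantify peak areas against per-analyte calibration curves
#'
#' Converts a sample x analyte area table to concentrations in mg per 100 g
#' fresh weight via `(area - intercept) / slope`, scaled by the dilution
#' implied by the extraction protocol. Several analytes may share one curve
#' (the "equivalents" convention, e.g. glycosides quantified as
#' cyanidin-3-O-glucoside equivalents); the curve actually used is recorded
#' per analyte.
#'
#' @param areas numeric matrix or data.frame, samples x analytes.
#' @param curves named list of [calibration_curve] objects; names are
#'   analytes. Curves are in signal per (mg/100 g) of the final readout.
#' @param curve_map optional named character vector mapping each analyte to
#'   the curve name it uses; defaults to identity.
#' @param protocol optional [extraction_protocol()]; when supplied the
#'   dilution factor multiplies the concentrations.
#' @return `data.frame` of concentrations with attribute `"curve_used"`.
#' @export
quantify_peak_areas <- function(areas, curves, curve_map = NULL, protocol = NULL) {
  areas <- as.matrix(areas)
  analytes <- colnames(areas)
  if (is.null(analytes)) stop("`areas` must have analyte column names", call. = FALSE)
  if (is.null(curve_map)) curve_map <- stats::setNames(analytes, analytes)
  missing <- analytes[!analytes %in% names(curve_map) |
                        !curve_map[analytes] %in% names(curves)]
  if (length(missing))
    stop("no calibration curve mapped for analyte(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dil <- if (is.null(protocol)) 1 else
    protocol$solvent_volumes * protocol$dilution_factor
  out <- areas
  for (a in analytes) {
    cv <- curves[[curve_map[[a]]]]
    conc <- (areas[, a] - cv$intercept) / cv$slope * dil
    conc[conc < 0] <- 0
    out[, a] <- conc
  }
  out <- as.data.frame(out)
  attr(out, "curve_used") <- curve_map[analytes]
  out
}
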
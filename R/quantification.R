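# Spectrophotometric quantification: pH-differential total monomeric
# anthocyanin content (TAC) and DPPH/Trolox antioxidant calibration.

# mg/mg dry weight -> mg/g dry weight
MG_PER_G_SCALE <- 1000

#' Absorbance quadruple for the pH-differential assay
#'
#' Bundles the four readings of one pH-differential measurement:
#' absorbance at 520 nm (pigment maximum) and 700 nm (haze correction)
#' in pH 1.0 and pH 4.5 buffers. At pH 1.0 monomeric anthocyanins are in
#' the coloured flavylium form; at pH 4.5 they convert to the colourless
#' hemiketal, so the net difference isolates the monomeric pigment.
#'
#' @param a520_ph1,a700_ph1 Absorbances at 520 and 700 nm in pH 1.0 buffer.
#' @param a520_ph45,a700_ph45 Absorbances at 520 and 700 nm in pH 4.5 buffer.
#' @param cap Magnitude cap on any single reading; values with
#'   `|A| > cap` are rejected as implausible (default 4.0, beyond the
#'   linear range of any bench spectrophotometer).
#' @return An object of class `absorbance_quadruple`.
#' @examples
#' q <- absorbance_quadruple(0.5, 0.1, 0.3, 0.1)
#' net_absorbance(q)
#' @export
absorbance_quadruple <- function(a520_ph1, a700_ph1, a520_ph45, a700_ph45,
                                 cap = 4.0) {
  vals <- c(a520_ph1 = a520_ph1, a700_ph1 = a700_ph1,
            a520_ph45 = a520_ph45, a700_ph45 = a700_ph45)
  if (!is.numeric(vals) || length(vals) != 4L || !all(is.finite(vals))) {
    stop("invalid reading: all four absorbances must be finite numbers",
         call. = FALSE)
  }
  if (any(abs(vals) > cap)) {
    stop(sprintf("invalid reading: |absorbance| exceeds cap %.2f (%s)",
                 cap, paste(names(vals)[abs(vals) > cap], collapse = ", ")),
         call. = FALSE)
  }
  structure(as.list(vals), class = "absorbance_quadruple")
}

#' Net pH-differential absorbance
#'
#' Computes `(A520 - A700)_pH1.0 - (A520 - A700)_pH4.5`. A non-positive
#' result signals no detectable monomeric anthocyanin (the reading is
#' still returned; downstream quantification flags it).
#'
#' @param q An [absorbance_quadruple()].
#' @return Net absorbance (dimensionless), with attribute
#'   `non_positive` set to `TRUE` when the value is <= 0.
#' @export
net_absorbance <- function(q) {
  if (!inherits(q, "absorbance_quadruple")) {
    q <- do.call(absorbance_quadruple, as.list(unlist(q)[1:4]))
  }
  abs_net <- (q$a520_ph1 - q$a700_ph1) - (q$a520_ph45 - q$a700_ph45)
  structure(abs_net, non_positive = abs_net <= 0)
}

#' Parameters of the pH-differential TAC equation
#'
#' Physical constants and sample bookkeeping needed to convert net
#' absorbance into mg cyanidin-3-O-glucoside (C3G) equivalents per gram
#' dry weight. Defaults are the standard C3G constants: molar
#' absorptivity 26,900 L mol^-1 cm^-1, molecular weight 449.2 Da, 1 cm
#' path length.
#'
#' @param epsilon Molar absorptivity, L mol^-1 cm^-1.
#' @param path_length Cuvette path length, cm.
#' @param mol_weight Molecular weight of the reference anthocyanin, Da.
#' @param dilution_factor Dilution factor applied to the extract (>= 1).
#' @param final_volume Final extract volume, mL.
#' @param dry_mass Dry mass of sample extracted, mg.
#' @return An object of class `ph_differential_params`.
#' @export
ph_differential_params <- function(epsilon = 26900, path_length = 1,
                                   mol_weight = 449.2, dilution_factor = 1,
                                   final_volume = 1, dry_mass = 1) {
  p <- list(epsilon = epsilon, path_length = path_length,
            mol_weight = mol_weight, dilution_factor = dilution_factor,
            final_volume = final_volume, dry_mass = dry_mass)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("parameter error: ", paste(bad, collapse = ", "),
         " must be strictly positive finite scalars", call. = FALSE)
  }
  if (dilution_factor < 1) {
    stop("parameter error: dilution_factor must be >= 1", call. = FALSE)
  }
  structure(p, class = "ph_differential_params")
}

#' Total monomeric anthocyanin content by the pH-differential method
#'
#' Converts a net pH-differential absorbance into total monomeric
#' anthocyanin content:
#' \deqn{TAC = \frac{Abs}{\epsilon L} \cdot M_W \cdot DF \cdot \frac{V}{M} \cdot 1000}
#' where `Abs/(epsilon * L)` is the molar pigment concentration in the
#' cuvette (Beer-Lambert), `M_W` converts to g/L (= mg/mL), `DF` undoes
#' the assay dilution, `V` (mL) gives total mg pigment, `M` (mg dry
#' mass) normalises, and the factor 1000 rescales mg/mg to mg/g.
#'
#' A net absorbance <= 0 is a below-detection result: the function
#' returns 0 flagged via attribute `below_detection`, not an error, so
#' time series can continue past fully degraded samples.
#'
#' @param q An [absorbance_quadruple()] or a plain net absorbance value.
#' @param p A [ph_differential_params()] object.
#' @return TAC in mg C3G equivalents per g dry weight, with logical
#'   attribute `below_detection`.
#' @examples
#' p <- ph_differential_params(dilution_factor = 10, final_volume = 10,
#'                             dry_mass = 100)
#' tac_ph_differential(absorbance_quadruple(0.269, 0, 0, 0), p)  # 4.492
#' @export
tac_ph_differential <- function(q, p = ph_differential_params()) {
  stopifnot(inherits(p, "ph_differential_params"))
  abs_net <- if (inherits(q, "absorbance_quadruple")) net_absorbance(q)
             else as.numeric(q)
  if (!is.finite(abs_net)) stop("invalid reading: non-finite absorbance",
                                call. = FALSE)
  if (abs_net <= 0) {
    return(structure(0, below_detection = TRUE))
  }
  tac <- abs_net / (p$epsilon * p$path_length) * p$mol_weight *
    p$dilution_factor * p$final_volume / p$dry_mass * MG_PER_G_SCALE
  structure(tac, below_detection = FALSE)
}

#' Fit a linear Trolox calibration curve
#'
#' Ordinary least-squares line relating assay response (DPPH
#' discoloration) to Trolox standard concentration.
#'
#' @param concentration Standard concentrations (mmol/L), at least 3
#'   distinct values.
#' @param response Measured assay responses, same length.
#' @param concentration_unit Label for the concentration axis.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `n_points`, `concentration_unit`.
#' @export
fit_trolox_calibration <- function(concentration, response,
                                   concentration_unit = "mmol Trolox/L") {
  if (length(concentration) != length(response)) {
    stop("insufficient data: concentration and response differ in length",
         call. = FALSE)
  }
  ok <- is.finite(concentration) & is.finite(response)
  concentration <- concentration[ok]; response <- response[ok]
  if (length(unique(concentration)) < 3L) {
    if (length(concentration) < 3L) {
      stop("insufficient data: need at least 3 calibration points",
           call. = FALSE)
    }
    if (length(unique(concentration)) == 1L) {
      stop("degenerate design: all standard concentrations identical",
           call. = FALSE)
    }
    stop("insufficient data: need at least 3 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(response ~ concentration)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((response - mean(response))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (sst > 0) max(0, 1 - ssr / sst) else 0,
    n_points = length(concentration),
    concentration_unit = concentration_unit
  ), class = "calibration_curve")
}

#' Trolox-equivalent antioxidant activity
#'
#' Inverts a calibration curve: `(response - intercept) / slope`, then
#' scales per gram of sample dry weight. Results below the calibration
#' range (negative equivalents) are flagged, not errored.
#'
#' @param response Assay response(s) to convert.
#' @param curve A `calibration_curve` from [fit_trolox_calibration()].
#' @param dry_mass_basis Sample dry mass in g to normalise by (default 1).
#' @return Activity in mmol Trolox equivalents per g dry weight, with
#'   logical attribute `below_range` (vectorised).
#' @export
trolox_equivalents <- function(response, curve, dry_mass_basis = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope == 0) {
    stop("degenerate curve: zero slope cannot be inverted", call. = FALSE)
  }
  if (!is.numeric(dry_mass_basis) || dry_mass_basis <= 0) {
    stop("parameter error: dry_mass_basis must be > 0", call. = FALSE)
  }
  eq <- (response - curve$intercept) / curve$slope / dry_mass_basis
  structure(eq, below_range = eq < 0)
}

#' Quantify a table of pH-differential assay records
#'
#' Tidy wrapper over [tac_ph_differential()] for a data frame in the
#' `assay.csv` schema (see [read_assay_csv()]).
#'
#' @param df Data frame with columns `sample_id`, `replicate`,
#'   `a520_ph1`, `a700_ph1`, `a520_ph45`, `a700_ph45`,
#'   `dilution_factor`, `final_volume_ml`, `dry_mass_mg`.
#' @return The input with added columns `net_abs`, `tac_mg_per_g`, and
#'   `flag` (`"ok"` or `"below_detection"`).
#' @export
quantify_assay_table <- function(df) {
  needed <- c("sample_id", "replicate", "a520_ph1", "a700_ph1",
              "a520_ph45", "a700_ph45", "dilution_factor",
              "final_volume_ml", "dry_mass_mg")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("validation error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- df
  out$net_abs <- NA_real_
  out$tac_mg_per_g <- NA_real_
  out$flag <- NA_character_
  for (i in seq_len(nrow(df))) {
    q <- absorbance_quadruple(df$a520_ph1[i], df$a700_ph1[i],
                              df$a520_ph45[i], df$a700_ph45[i])
    p <- ph_differential_params(dilution_factor = df$dilution_factor[i],
                                final_volume = df$final_volume_ml[i],
                                dry_mass = df$dry_mass_mg[i])
    tac <- tac_ph_differential(q, p)
    out$net_abs[i] <- as.numeric(net_absorbance(q))
    out$tac_mg_per_g[i] <- as.numeric(tac)
    out$flag[i] <- if (isTRUE(attr(tac, "below_detection")))
      "below_detection" else "ok"
  }
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Trolox calibration: response = %.4g x conc + %.4g  (r2 = %.4f, n = %d, %s)\n",
    x$slope, x$intercept, x$r_squared, x$n_points, x$concentration_unit))
  invisible(x)
}
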
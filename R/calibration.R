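#' Fit a linear external calibration curve
#'
#' Ordinary least-squares line `signal = intercept + slope * concentration`
#' through external standards, as used to quantify anthocyanins against
#' cyanidin 3-glucoside, lipid hydroperoxides against cumene hydroperoxide,
#' and volatile aldehydes against authentic standards. The calibrated
#' concentration range is recorded so that inverse predictions outside it
#' can be flagged as extrapolation.
#'
#' @param conc Standard concentrations in µM (at least two distinct values),
#'   or a data frame with columns `conc` and `signal`.
#' @param signal Measured signals (e.g. absorbance, peak area).
#' @param analyte Optional analyte name stored with the curve.
#' @param through_origin Force the line through zero (default keeps the
#'   intercept).
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `n_points`, `range`, and the underlying `lm` in `$fit`.
#' @examples
#' cal <- fit_calibration(c(1, 2, 4, 8), c(3, 5, 9, 17))  # y = 2x + 1
#' invert_calibration(cal, 5)
#' @export
fit_calibration <- function(conc, signal = NULL, analyte = NA_character_,
                            through_origin = FALSE) {
  if (is.data.frame(conc)) {
    signal <- conc$signal; conc <- conc$conc
  }
  conc <- as.numeric(conc); signal <- as.numeric(signal)
  if (length(conc) != length(signal) || anyNA(conc) || anyNA(signal))
    stop("conc and signal must be equal-length and complete", call. = FALSE)
  if (length(unique(conc)) < 2)
    stop("singular design: need at least two distinct concentrations",
         call. = FALSE)
  fit <- if (through_origin) stats::lm(signal ~ conc - 1)
         else stats::lm(signal ~ conc)
  cf <- stats::coef(fit)
  slope <- unname(cf[["conc"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  if (slope == 0) stop("zero slope: curve is not invertible", call. = FALSE)
  tss <- sum((signal - mean(signal))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_points = length(conc), analyte = analyte,
                 range = range(conc), through_origin = through_origin,
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, digits = 4, ...) {
  cat(sprintf("Calibration curve%s: signal = %s + %s * conc  (r^2 = %s, n = %d)\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              format(x$intercept, digits = digits),
              format(x$slope, digits = digits),
              format(x$r_squared, digits = digits), x$n_points))
  cat(sprintf("  calibrated range: %s to %s uM\n",
              format(x$range[1]), format(x$range[2])))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict signal from concentration
#'
#' @param object A `calibration_curve`.
#' @param conc Concentration(s) in µM.
#' @param ... Unused.
#' @return Predicted signal(s).
#' @export
predict.calibration_curve <- function(object, conc, ...) {
  object$intercept + object$slope * conc
}

#' Inverse prediction from a calibration curve
#'
#' Maps a measured signal back to concentration,
#' `(signal - intercept) / slope`. Values outside the calibrated
#' concentration range — including negative concentrations from signals
#' below the intercept — are returned as-is but flagged via the
#' `extrapolated` attribute.
#'
#' @param curve A [fit_calibration()] result.
#' @param signal Measured signal(s).
#' @return Concentration(s) in µM with logical attribute `extrapolated`.
#' @export
invert_calibration <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("zero slope: not invertible", call. = FALSE)
  conc <- (signal - curve$intercept) / curve$slope
  tol <- 1e-9 * max(diff(curve$range), abs(curve$range))
  structure(conc,
            extrapolated = conc < curve$range[1] - tol |
                           conc > curve$range[2] + tol)
}

#' Convert a mass fraction to molar concentration
#'
#' `fraction_pct_ww` percent (w/w) of a solute of molar mass `molar_mass`
#' in a solution of density `solution_density` corresponds to
#' `fraction/100 * density * 1000 / molar_mass` mol/L, returned in mM.
#' 0.1% (w/w) SDS (M = 288.38 g/mol) gives 3.47 mM.
#'
#' @param fraction_pct_ww Mass fraction in percent (w/w), `>= 0`.
#' @param molar_mass Molar mass in g/mol, `> 0`.
#' @param solution_density Solution density in g/mL (default 1.0).
#' @return Concentration in mM.
#' @export
mass_fraction_to_molarity <- function(fraction_pct_ww, molar_mass,
                                      solution_density = 1.0) {
  if (any(fraction_pct_ww < 0)) stop("mass fraction must be >= 0", call. = FALSE)
  if (any(molar_mass <= 0) || any(solution_density <= 0))
    stop("molar mass and density must be > 0", call. = FALSE)
  fraction_pct_ww / 100 * solution_density * 1000 / molar_mass * 1000
}

#' Concentration of a stock component after dosing into a system
#'
#' A component present at `stock_conc` mM in a stock (e.g. trace iron in a
#' plant extract) dosed at `dose_g_per_L` grams of stock per litre of final
#' system contributes `stock_conc * dose / (1000 * stock_density)` mM,
#' returned in µM. Iron at 0.79 mM in an extract dosed at 0.73 g/L gives
#' about 0.58 µM.
#'
#' @param stock_conc Component concentration in the stock, mM.
#' @param dose_g_per_L Stock dose in g per litre of final system.
#' @param stock_density Stock density in g/mL (default 1.0).
#' @return Component concentration in the final system, µM.
#' @export
dilute_component <- function(stock_conc, dose_g_per_L, stock_density = 1.0) {
  if (any(stock_conc < 0) || any(dose_g_per_L < 0))
    stop("concentrations and doses must be >= 0", call. = FALSE)
  if (any(stock_density <= 0)) stop("density must be > 0", call. = FALSE)
  stock_conc * dose_g_per_L / (1000 * stock_density) * 1000
}
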
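#' Visible absorbance spectrum
#'
#' Wavelength-indexed absorbance of a pigment solution or clarified emulsion
#' extract, with the storage metadata needed by the colorimetry operations.
#'
#' @param wavelength Wavelengths in nm, strictly ascending, within
#'   `[380, 780]`.
#' @param absorbance Dimensionless absorbance values, same length; values
#'   below -0.05 (beyond baseline-noise tolerance) are rejected.
#' @param pH,sds,day Optional metadata: pH of the medium, whether surfactant
#'   (SDS) was present, storage day.
#' @param meta Further named metadata.
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelength, absorbance, pH = NA_real_,
                                sds = FALSE, day = NA_real_, meta = list()) {
  wavelength <- as.numeric(wavelength); absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    stop("wavelength and absorbance must have the same length", call. = FALSE)
  if (anyNA(wavelength) || anyNA(absorbance))
    stop("spectrum must not contain missing values", call. = FALSE)
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly ascending", call. = FALSE)
  if (min(wavelength) < 380 || max(wavelength) > 780)
    stop("wavelengths must lie within [380, 780] nm", call. = FALSE)
  if (any(absorbance < -0.05))
    stop("absorbance below -0.05: not a plausible baseline artifact",
         call. = FALSE)
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 meta = c(list(pH = pH, sds = isTRUE(sds), day = day), meta)),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("<absorbance_spectrum> %d points, %g-%g nm, pH %s, SDS %s, day %s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              format(x$meta$pH), x$meta$sds, format(x$meta$day)))
  invisible(x)
}

#' @export
plot.absorbance_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength, x$absorbance, type = "l",
                 xlab = "wavelength (nm)", ylab = "absorbance", ...)
  invisible(x)
}

#' @export
as.data.frame.absorbance_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, absorbance = x$absorbance)
}

#' Read absorbance spectra from CSV
#'
#' Expects columns `wavelength_nm` and `absorbance`; optional columns `pH`,
#' `sds`, `day` and `sample_id` split the file into one spectrum per group.
#'
#' @param path CSV path.
#' @return A list of [absorbance_spectrum] objects (length one for a
#'   single-spectrum file).
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "absorbance") %in% names(df)))
    stop("spectra CSV needs columns wavelength_nm and absorbance",
         call. = FALSE)
  keys <- intersect(c("sample_id", "pH", "sds", "day"), names(df))
  groups <- if (length(keys)) split(df, df[keys], drop = TRUE) else list(df)
  lapply(groups, function(g) {
    absorbance_spectrum(g$wavelength_nm, g$absorbance,
                        pH = if ("pH" %in% keys) g$pH[1] else NA_real_,
                        sds = if ("sds" %in% keys) as.logical(g$sds[1]) else FALSE,
                        day = if ("day" %in% keys) g$day[1] else NA_real_)
  })
}

interp_absorbance <- function(spec, wl) {
  if (min(wl) < min(spec$wavelength) || max(wl) > max(spec$wavelength))
    stop(sprintf("spectrum covers %g-%g nm; %g-%g nm requested",
                 min(spec$wavelength), max(spec$wavelength),
                 min(wl), max(wl)), call. = FALSE)
  stats::approx(spec$wavelength, spec$absorbance, xout = wl)$y
}

#' Turbidity-corrected absorbance at the pigment maximum
#'
#' Residual turbidity in clarified emulsion extracts scatters light across
#' the whole visible range; since the anthocyanins do not absorb at 750 nm,
#' the absorbance there measures that scattering baseline. The corrected
#' quantification signal is `A(peak) - A(750)`. Linear interpolation is used
#' between grid points. A negative result (stronger signal at 750 nm than at
#' the peak) is returned with a warning: it flags a scattering artifact.
#'
#' @param spec An [absorbance_spectrum] covering both wavelengths.
#' @param peak_nm Absorption maximum used for quantification; 522 nm for
#'   black carrot anthocyanins at pH 2.
#' @param reference_nm Scattering reference wavelength (750 nm).
#' @return Corrected absorbance (dimensionless scalar).
#' @export
turbidity_correct <- function(spec, peak_nm = 522, reference_nm = 750) {
  a <- interp_absorbance(spec, c(peak_nm, reference_nm))
  out <- a[1] - a[2]
  if (out < 0)
    warning(sprintf("A(%g) < A(%g): scattering artifact, corrected absorbance negative",
                    peak_nm, reference_nm), call. = FALSE)
  out
}

#' Wavelength of maximum absorbance
#'
#' Locates the absorption maximum within a window, refined beyond the grid by
#' a 3-point parabolic interpolation around the grid maximum. Exact ties are
#' broken towards the lowest wavelength; maxima at the window edge are
#' returned unrefined.
#'
#' @param spec An [absorbance_spectrum].
#' @param window Two-element numeric window in nm (default the anthocyanin
#'   band region 450-650 nm).
#' @return Peak wavelength in nm.
#' @export
lambda_max <- function(spec, window = c(450, 650)) {
  sel <- spec$wavelength >= window[1] & spec$wavelength <= window[2]
  if (sum(sel) < 5)
    stop("need at least 5 grid points inside the window", call. = FALSE)
  wl <- spec$wavelength[sel]; a <- spec$absorbance[sel]
  i <- which(a == max(a))[1]           # tie -> lowest wavelength
  if (i == 1 || i == length(a)) return(wl[i])
  # parabola through the three points around the grid maximum
  y1 <- a[i - 1]; y2 <- a[i]; y3 <- a[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(wl[i])
  delta <- 0.5 * (y1 - y3) / denom
  h <- ((wl[i + 1] - wl[i]) + (wl[i] - wl[i - 1])) / 2
  wl[i] + delta * h
}

#' Spectral shift between a reference and a test spectrum
#'
#' Quantifies how an absorption band moves and grows between two conditions
#' (e.g. without and with surfactant): the wavelength shift
#' `delta_nm = lambda_max(test) - lambda_max(ref)` classified as bathochromic
#' (towards longer wavelengths), hypsochromic (shorter), or none; and the
#' relative intensity change at the respective maxima, in percent with the
#' larger peak absorbance as denominator. A band growing from absorbance 1.0
#' to 1.25 is thus a 20% hyperchromic shift.
#'
#' @param spec_ref,spec_test [absorbance_spectrum] objects covering `window`.
#' @param window Analysis window in nm passed to [lambda_max()].
#' @return A list of class `spectral_shift` with `delta_nm`, `kind`
#'   (`"bathochromic"`, `"hypsochromic"` or `"none"`), `rel_abs_change`
#'   (percent, positive = hyperchromic), and the two peak positions and
#'   absorbances.
#' @export
spectral_shift <- function(spec_ref, spec_test, window = c(450, 650)) {
  lr <- lambda_max(spec_ref, window)
  lt <- lambda_max(spec_test, window)
  ar <- interp_absorbance(spec_ref, lr)
  at <- interp_absorbance(spec_test, lt)
  delta <- lt - lr
  kind <- if (delta > 0) "bathochromic" else if (delta < 0) "hypsochromic" else "none"
  rel <- if (at > ar) (at - ar) / at * 100
         else if (at < ar) (at - ar) / ar * 100
         else 0
  structure(list(delta_nm = delta, kind = kind, rel_abs_change = rel,
                 lambda_ref = lr, lambda_test = lt,
                 abs_ref = ar, abs_test = at),
            class = "spectral_shift")
}

#' @export
print.spectral_shift <- function(x, ...) {
  cat(sprintf("Spectral shift: %+.2f nm (%s), %s%.1f%% intensity (%.3f -> %.3f)\n",
              x$delta_nm, x$kind,
              if (x$rel_abs_change >= 0) "+" else "", x$rel_abs_change,
              x$abs_ref, x$abs_test))
  invisible(x)
}
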
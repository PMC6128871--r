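#' Construct an FTIR spectrum
#'
#' A `Spectrum` holds one sample's mid-infrared trace on its native wavenumber
#' grid. Values are always stored as absorbance; spectra acquired in
#' \%-transmittance mode are converted with [transmittance_to_absorbance()]
#' and the original acquisition mode is kept in `mode_source`. The grid is
#' canonicalized to ascending wavenumber order on construction, whatever the
#' input order (instrument files conventionally run 4000 down to 650 cm^-1).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1. Any order on
#'   input; stored strictly ascending. At least 16 points.
#' @param absorbance Numeric vector of absorbance values (unitless), one per
#'   wavenumber. Negative values are permitted (instrument baseline
#'   artifacts); non-finite values are an error.
#' @param sample_id Character scalar identifying the sample.
#' @param mode_source Either `"absorbance"` or `"percent_transmittance"`,
#'   recording how the trace was acquired. Construction does not convert;
#'   pass \%T values through [transmittance_to_absorbance()].
#' @param resolution Nominal instrument resolution in cm^-1 (default 4).
#'
#' @return An object of class `ftir_spectrum`: a list with fields
#'   `sample_id`, `wavenumbers`, `absorbance`, `mode_source`, `resolution`.
#' @seealso [read_spectrum()], [integrate_spectrum()],
#'   [transmittance_to_absorbance()]
#' @export
#' @examples
#' s <- ftir_spectrum(seq(650, 4000, by = 2), rep(0.1, 1676), "demo")
#' integrate_spectrum(s)
ftir_spectrum <- function(wavenumbers, absorbance, sample_id = "sample",
                          mode_source = c("absorbance", "percent_transmittance"),
                          resolution = 4) {
  mode_source <- match.arg(mode_source)
  if (!is.numeric(wavenumbers) || !is.numeric(absorbance))
    stop("wavenumbers and absorbance must be numeric", call. = FALSE)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance differ in length (",
         length(wavenumbers), " vs ", length(absorbance), ")", call. = FALSE)
  if (length(wavenumbers) < 16L)
    stop("a spectrum needs at least 16 points, got ", length(wavenumbers),
         call. = FALSE)
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop("non-finite wavenumbers", call. = FALSE)
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("non-finite absorbance values (row ",
         which(!is.finite(absorbance))[1L], ")", call. = FALSE)
  ord <- order(wavenumbers)
  wavenumbers <- wavenumbers[ord]
  absorbance <- absorbance[ord]
  if (anyDuplicated(wavenumbers)) {
    dup <- wavenumbers[which(duplicated(wavenumbers))[1L]]
    stop("duplicate wavenumber ", dup, " cm^-1", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id),
         wavenumbers = as.numeric(wavenumbers),
         absorbance = as.numeric(absorbance),
         mode_source = mode_source,
         resolution = resolution),
    class = "ftir_spectrum"
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat("<ftir_spectrum> ", x$sample_id, ": ", length(x$wavenumbers),
      " points, ", min(x$wavenumbers), "-", max(x$wavenumbers),
      " cm^-1 (acquired as ", x$mode_source, ")\n", sep = "")
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "ftir_spectrum")

assert_spectrum <- function(s) {
  if (!is_spectrum(s)) stop("expected an ftir_spectrum object", call. = FALSE)
  invisible(s)
}

#' Convert a \%-transmittance spectrum to absorbance
#'
#' Applies the Beer-Lambert relation A = 2 - log10(\%T) pointwise. Spectra
#' are acquired in \%-transmittance mode on many ATR instruments and must be
#' in absorbance units before any peak quantification, because only
#' absorbance is (approximately) linear in analyte concentration.
#'
#' @param s A [ftir_spectrum()] whose values are \%T (all > 0).
#' @return A `ftir_spectrum` in absorbance units with
#'   `mode_source = "percent_transmittance"` recording the origin.
#' @export
#' @examples
#' s <- ftir_spectrum(seq(650, 4000, by = 2), rep(10, 1676), "demo")
#' a <- transmittance_to_absorbance(s)
#' all(a$absorbance == 1)
transmittance_to_absorbance <- function(s) {
  assert_spectrum(s)
  bad <- which(s$absorbance <= 0)
  if (length(bad))
    stop("%T must be positive for log conversion; offending wavenumber ",
         s$wavenumbers[bad[1L]], " cm^-1 (%T = ", s$absorbance[bad[1L]], ")",
         call. = FALSE)
  s$absorbance <- 2 - log10(s$absorbance)
  s$mode_source <- "percent_transmittance"
  s
}

#' Total integrated area of a spectrum
#'
#' Composite trapezoidal integral of absorbance over the full recorded
#' wavenumber range, computed on the native (possibly non-uniform) ascending
#' grid. This total area is the per-sample normalizer for corrected peak
#' heights: dividing by it removes matrix- and instrument-induced variation
#' in overall absorbance between samples.
#'
#' Negative absorbances integrate with sign; a warning is emitted when the
#' area is not positive, and downstream normalization refuses such areas.
#'
#' @param s A [ftir_spectrum()].
#' @return Total area in absorbance * cm^-1.
#' @export
integrate_spectrum <- function(s) {
  assert_spectrum(s)
  w <- s$wavenumbers
  a <- s$absorbance
  if (length(w) < 2L) stop("need at least 2 points to integrate", call. = FALSE)
  area <- trapz_area(w, a)
  if (!is.finite(area)) stop("non-finite integrated area", call. = FALSE)
  if (area <= 0)
    warning("total integrated area is not positive (", signif(area, 6),
            "); normalization will be refused", call. = FALSE)
  area
}

# trapezoid rule on an ascending grid; exact for piecewise-linear traces
trapz_area <- function(w, a) {
  n <- length(w)
  sum((w[-1L] - w[-n]) * (a[-1L] + a[-n])) / 2
}
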
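#' Convert detector wavelength to Raman shift
#'
#' The Stokes Raman shift of light detected at wavelength \eqn{\lambda} under
#' excitation \eqn{\lambda_{ex}} is
#' \eqn{\tilde\nu = 10^7 (1/\lambda_{ex} - 1/\lambda)} in cm\eqn{^{-1}}
#' with wavelengths in nm. A detector window of 800-940 nm under 785 nm
#' excitation covers roughly 200-2100 cm\eqn{^{-1}}.
#'
#' @param wavelength Detected wavelength(s) in nm.
#' @param excitation Excitation wavelength in nm.
#' @return Raman shift(s) in cm^-1.
#' @seealso [shift_to_wavelength()]
#' @export
wavelength_to_shift <- function(wavelength, excitation) {
  if (any(wavelength <= 0) || any(excitation <= 0)) {
    abort("wavelengths must be positive.", class = "serds_error_value")
  }
  1e7 * (1 / excitation - 1 / wavelength)
}

#' Convert Raman shift to detector wavelength
#'
#' Inverse of [wavelength_to_shift()]: \eqn{\lambda = 1/(1/\lambda_{ex} -
#' \tilde\nu \cdot 10^{-7})}.
#'
#' @param shift Raman shift(s) in cm^-1.
#' @param excitation Excitation wavelength in nm.
#' @return Detected wavelength(s) in nm.
#' @export
shift_to_wavelength <- function(shift, excitation) {
  if (any(excitation <= 0)) abort("excitation must be positive.", class = "serds_error_value")
  inv <- 1 / excitation - shift * 1e-7
  if (any(inv <= 0)) abort("shift too large for this excitation.", class = "serds_error_value")
  1 / inv
}

#' Excitation-step equivalent in Raman shift
#'
#' The constant offset, in cm^-1, by which a Raman line's apparent shift moves
#' when the excitation is changed from `ex1` to `ex2` while the detector
#' wavelength axis is fixed: \eqn{10^7 (1/\lambda_1 - 1/\lambda_2)}.
#' For the 784/785 nm pair this is about 16.25 cm^-1.
#'
#' @param ex1,ex2 The two excitation wavelengths in nm.
#' @return Shift offset in cm^-1.
#' @export
excitation_step_shift <- function(ex1, ex2) {
  1e7 * (1 / ex1 - 1 / ex2)
}

#' Z-score normalize a spectrum
#'
#' Centers to mean zero and scales to unit standard deviation using the
#' population convention (divisor N).
#'
#' @param values Numeric vector with at least 2 elements and nonzero variance.
#' @return Normalized numeric vector (mean 0, population sd 1).
#' @export
zscore <- function(values) {
  if (length(values) < 2) abort("need at least 2 values.", class = "serds_error_degenerate")
  if (!all(is.finite(values))) abort("values must be finite.", class = "serds_error_value")
  mu <- mean(values)
  s <- sqrt(mean((values - mu)^2))
  if (s == 0) {
    abort("constant spectrum: z-score undefined.", class = "serds_error_degenerate")
  }
  (values - mu) / s
}

#' Form the SERDS difference spectrum
#'
#' Both mean spectra are z-score normalized, then subtracted pixelwise on the
#' shared detector grid (first minus second). Because tissue autofluorescence
#' barely responds to the 1 nm excitation step while Raman lines track it,
#' the broad background cancels and each Raman line survives as a
#' positive/negative doublet.
#'
#' @param mean_a,mean_b `mean_spectrum` tibbles from [mean_block()], acquired
#'   at two distinct excitation wavelengths on the same detector grid.
#' @return A `difference_spectrum` tibble with columns `wavelength` and
#'   `value`, carrying both excitation wavelengths as the `excitations`
#'   attribute (in the order given).
#' @export
serds_difference <- function(mean_a, mean_b) {
  stopifnot(inherits(mean_a, "mean_spectrum"), inherits(mean_b, "mean_spectrum"))
  if (!isTRUE(all.equal(mean_a$wavelength, mean_b$wavelength))) {
    abort("mean spectra must share one detector grid.", class = "serds_error_grid")
  }
  ex <- c(attr(mean_a, "excitation_nm"), attr(mean_b, "excitation_nm"))
  if (ex[1] == ex[2]) {
    abort("the two excitation wavelengths must differ.", class = "serds_error_value")
  }
  new_spectrum(
    tibble(
      wavelength = mean_a$wavelength,
      value = zscore(mean_a$intensity) - zscore(mean_b$intensity)
    ),
    "difference_spectrum",
    excitations = ex,
    locus = attr(mean_a, "locus"), label = attr(mean_a, "label")
  )
}

#' Difference spectrum of a locus row
#'
#' Convenience wrapper: average both raw blocks of a locus and form the
#' difference spectrum (lower-excitation minus higher-excitation block).
#'
#' @param block_a,block_b The two [raw_block()]s of one locus.
#' @return A `difference_spectrum` tibble.
#' @export
locus_difference <- function(block_a, block_b) {
  serds_difference(mean_block(block_a), mean_block(block_b))
}

#' Resample a difference spectrum onto a uniform Raman shift axis
#'
#' The detector-pixel wavelengths are converted to Raman shift relative to the
#' reference excitation (by convention the second, higher excitation
#' wavelength of the pair), and the values are linearly interpolated onto a
#' uniform cm^-1 grid. Bins outside the detector coverage are zero.
#'
#' @param diff A `difference_spectrum`.
#' @param shift_axis Target uniform shift axis in cm^-1 (default 550-1800,
#'   1 cm^-1 step).
#' @param reference Which excitation defines the shift axis: `"second"`
#'   (default) or `"first"`.
#' @return Tibble with columns `shift` and `value`.
#' @export
resample_difference <- function(diff, shift_axis = default_shift_axis(),
                                reference = c("second", "first")) {
  stopifnot(inherits(diff, "difference_spectrum"))
  reference <- match.arg(reference)
  ex <- attr(diff, "excitations")
  ref <- if (reference == "second") ex[2] else ex[1]
  pixel_shift <- wavelength_to_shift(diff$wavelength, ref)
  if (any(diff(pixel_shift) <= 0)) abort("degenerate pixel axis.", class = "serds_error_grid")
  out <- approx(pixel_shift, diff$value, xout = shift_axis, rule = 1)$y
  out[is.na(out)] <- 0
  tibble(shift = shift_axis, value = out)
}

#' Default classifier shift axis
#'
#' Uniform 1 cm^-1 grid over the 550-1800 cm^-1 fingerprint region used for
#' purification and classification.
#'
#' @return Numeric vector of shifts.
#' @export
default_shift_axis <- function() seq(550, 1800, by = 1)

#' Classic (integration-based) SERDS reconstruction
#'
#' Non-neural baseline recovery of the Raman spectrum from a difference
#' spectrum by shift-and-accumulate: the difference is resampled onto a
#' uniform shift axis, cumulatively summed along the axis, and a least-squares
#' line is subtracted to remove the integration drift. On an axis referenced
#' to the higher excitation wavelength, a line at shift s appears at s under
#' the higher excitation and at s minus the excitation-step equivalent under
#' the lower one, so cumulative summation of the (low minus high) difference
#' yields a positive box-smeared copy of the line centred half a step below
#' s; the axis is compensated accordingly so the reconstruction peaks at the
#' true line centre.
#'
#' @param diff A `difference_spectrum`.
#' @param shift_axis Uniform target axis (default [default_shift_axis()]).
#' @return A `purified_spectrum` tibble (`shift`, `intensity`) with
#'   `purifier = "classic"` provenance.
#' @export
classic_reconstruct <- function(diff, shift_axis = default_shift_axis()) {
  rs <- resample_difference(diff, shift_axis)
  if (length(shift_axis) < 3 || any(diff(shift_axis) <= 0)) {
    abort("degenerate shift axis.", class = "serds_error_grid")
  }
  ex <- attr(diff, "excitations")
  step <- abs(excitation_step_shift(ex[1], ex[2]))
  acc <- cumsum(rs$value)
  fit <- stats::lm.fit(cbind(1, shift_axis), acc)
  acc <- acc - cbind(1, shift_axis) %*% fit$coefficients
  # peak sits at s - step/2 on the accumulated axis; evaluate there to re-centre
  recentred <- approx(shift_axis, acc, xout = shift_axis - step / 2, rule = 2)$y
  new_spectrum(
    tibble(shift = shift_axis, intensity = as.numeric(recentred)),
    "purified_spectrum",
    locus = attr(diff, "locus"), label = attr(diff, "label"), purifier = "classic"
  )
}
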
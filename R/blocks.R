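#' Raw acquisition blocks
#'
#' A raw block holds the repeated acquisitions of one measurement locus at a
#' single excitation wavelength: an intensity matrix (repeats x detector
#' pixels, in counts) on a strictly increasing detector wavelength grid.
#'
#' @param wavelength Detector wavelength grid in nm, strictly increasing.
#' @param counts Numeric matrix, repeats x pixels.
#' @param excitation_nm Excitation wavelength in nm.
#' @param locus Locus identifier (character scalar).
#' @param label Optional tissue-class label.
#' @return An object of class `raw_block`.
#' @export
raw_block <- function(wavelength, counts, excitation_nm, locus = "locus", label = NA_character_) {
  wavelength <- as.numeric(wavelength)
  if (is.null(dim(counts))) counts <- matrix(as.numeric(counts), nrow = 1)
  counts <- as.matrix(counts)
  if (any(diff(wavelength) <= 0)) {
    abort("`wavelength` must be strictly increasing.", class = "serds_error_grid")
  }
  if (ncol(counts) != length(wavelength)) {
    abort("`counts` must have one column per wavelength pixel.", class = "serds_error_shape")
  }
  if (nrow(counts) < 1) abort("a raw block needs at least one repeat.", class = "serds_error_shape")
  if (!all(is.finite(counts))) abort("intensities must be finite.", class = "serds_error_value")
  if (length(excitation_nm) != 1 || !is.finite(excitation_nm) || excitation_nm <= 0) {
    abort("`excitation_nm` must be a single positive number.", class = "serds_error_value")
  }
  structure(
    list(
      wavelength = wavelength, counts = counts,
      excitation_nm = as.numeric(excitation_nm),
      locus = as.character(locus), label = as.character(label)
    ),
    class = "raw_block"
  )
}

#' @export
print.raw_block <- function(x, ...) {
  cat(sprintf(
    "<raw_block> locus %s (%s): %d repeats x %d pixels, excitation %.1f nm, %.1f-%.1f nm\n",
    x$locus, x$label, nrow(x$counts), ncol(x$counts), x$excitation_nm,
    min(x$wavelength), max(x$wavelength)
  ))
  invisible(x)
}

#' @export
as_tibble.raw_block <- function(x, ...) {
  tibble(
    locus = x$locus, label = x$label, excitation_nm = x$excitation_nm,
    repeat_id = rep(seq_len(nrow(x$counts)), each = length(x$wavelength)),
    wavelength = rep(x$wavelength, nrow(x$counts)),
    intensity = as.numeric(t(x$counts))
  )
}

new_spectrum <- function(df, class, ...) {
  attrs <- list(...)
  out <- as_tibble(df)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, "serds_spectrum", class(out))
  out
}

#' Average the repeats of a raw block
#'
#' Pixelwise arithmetic mean across the repeated acquisitions, the first step
#' of the SERDS processing chain.
#'
#' @param block A [raw_block()].
#' @return A `mean_spectrum` tibble with columns `wavelength` and `intensity`,
#'   carrying the excitation wavelength and repeat count as attributes.
#' @export
mean_block <- function(block) {
  stopifnot(inherits(block, "raw_block"))
  new_spectrum(
    tibble(wavelength = block$wavelength, intensity = colMeans(block$counts)),
    "mean_spectrum",
    excitation_nm = block$excitation_nm, n_repeats = nrow(block$counts),
    locus = block$locus, label = block$label
  )
}
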
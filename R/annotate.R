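#' Molecular assignment library
#'
#' Reference table mapping Raman shifts (single lines or bands) in the
#' fingerprint region to their molecular origin in soft tissue and bone:
#' collagen backbone and phenylalanine lines, lipid C-C and C-H deformation
#' bands, nucleic-acid signatures, carotenoid lines and the amide I/II/III
#' protein bands.
#'
#' @return Tibble with columns `shift_low`, `shift_high` (equal for single
#'   lines) and `assignment`.
#' @export
assignment_library <- function() {
  tribble_entries <- list(
    list(937.5, 937.5, "Proline, Hydroxyproline, C-C stretching of collagen backbone"),
    list(1004, 1004, "Phenylalanine (of collagen)"),
    list(1038, 1038, "Phenylalanine (of collagen)"),
    list(1073, 1073, "Proline (collagen), Glucose, Triglycerides, C-C (lipid)"),
    list(1095, 1095, "DNA, C-N stretching"),
    list(1126, 1126, "C-N stretching"),
    list(1160, 1160, "C-C stretching of the carotenoid polyene chain"),
    list(1200, 1320, "Amide III region"),
    list(1339, 1339, "CH2 deformation (protein, A and G of DNA/RNA), nucleic acid"),
    list(1378, 1378, "CH3 in-phase deformation (T, A, G of DNA)"),
    list(1440, 1470, "C-H deformation (CH2 and CH3 of lipid and protein)"),
    list(1532, 1532, "Amide II, carotenoid peak"),
    list(1600, 1670, "Amide I region")
  )
  out <- tibble(
    shift_low = purrr::map_dbl(tribble_entries, 1),
    shift_high = purrr::map_dbl(tribble_entries, 2),
    assignment = purrr::map_chr(tribble_entries, 3)
  )
  stopifnot(all(out$shift_low >= 200 & out$shift_high <= 2000),
            all(out$shift_low <= out$shift_high))
  out
}

peak_prominence <- function(y, apex) {
  # topographic prominence: apex height minus the higher of the two bases,
  # each base being the lowest point between the apex and the nearest higher
  # terrain (or the record edge) on that side
  n <- length(y)
  h <- y[apex]
  left_base <- h
  i <- apex - 1L
  while (i >= 1L && y[i] <= h) {
    left_base <- min(left_base, y[i])
    i <- i - 1L
  }
  right_base <- h
  i <- apex + 1L
  while (i <= n && y[i] <= h) {
    right_base <- min(right_base, y[i])
    i <- i + 1L
  }
  h - max(left_base, right_base)
}

#' Detect peaks in a purified spectrum
#'
#' Local maxima whose apex height and topographic prominence both exceed
#' `min_prominence` times the spectrum maximum, sorted by shift. Purified
#' spectra are baseline-free, so apex height and prominence agree for
#' isolated lines; the joint criterion keeps shoulders of strong bands
#' (prominent enough) while rejecting tall-but-unprominent ripple and
#' low-lying noise maxima alike.
#'
#' @param spectrum Tibble with `shift` and `intensity` (>= 3 bins).
#' @param min_prominence Detection threshold as a fraction of the spectrum
#'   maximum (default 0.05).
#' @return Tibble of peak calls: `shift`, `intensity`, `prominence`.
#' @export
detect_peaks <- function(spectrum, min_prominence = 0.05) {
  y <- spectrum$intensity
  if (length(y) < 3) abort("need at least 3 bins.", class = "serds_error_shape")
  if (!all(is.finite(y))) abort("non-finite intensities.", class = "serds_error_value")
  apex <- which(diff(sign(diff(y))) < 0) + 1L
  # plateaus: keep strict local maxima only
  apex <- apex[y[apex] > y[apex - 1] & y[apex] >= y[apex + 1]]
  if (length(apex) == 0) {
    return(tibble(shift = numeric(0), intensity = numeric(0), prominence = numeric(0)))
  }
  prom <- vapply(apex, function(a) peak_prominence(y, a), numeric(1))
  keep <- prom >= min_prominence * max(y) & y[apex] >= min_prominence * max(y)
  tibble(
    shift = spectrum$shift[apex[keep]],
    intensity = y[apex[keep]],
    prominence = prom[keep]
  ) |> dplyr::arrange(.data$shift)
}

#' Assign detected peaks to molecular origins
#'
#' Single-line library entries match when the apex lies within `tolerance`
#' of the line position; band entries match on containment. The nearest
#' entry wins ties; calls matching nothing stay unassigned.
#'
#' @param calls Peak calls from [detect_peaks()].
#' @param library Assignment table (default [assignment_library()]).
#' @param tolerance Matching tolerance for single lines, cm^-1 (default 8).
#' @return The calls with `assignment` and `distance` (cm^-1) columns.
#' @export
assign_peaks <- function(calls, library = assignment_library(), tolerance = 8) {
  if (tolerance <= 0) abort("tolerance must be positive.", class = "serds_error_value")
  if (nrow(library) == 0) abort("empty assignment library.", class = "serds_error_empty")
  res <- purrr::map(calls$shift, function(s) {
    is_band <- library$shift_high > library$shift_low
    dist <- ifelse(
      is_band,
      ifelse(s >= library$shift_low & s <= library$shift_high, 0,
             pmin(abs(s - library$shift_low), abs(s - library$shift_high))),
      abs(s - (library$shift_low + library$shift_high) / 2)
    )
    ok <- which((is_band & dist == 0) | (!is_band & dist <= tolerance))
    if (length(ok) == 0) {
      list(assignment = NA_character_, distance = NA_real_)
    } else {
      best <- ok[which.min(dist[ok])]
      list(assignment = library$assignment[best], distance = dist[best])
    }
  })
  calls$assignment <- purrr::map_chr(res, "assignment")
  calls$distance <- purrr::map_dbl(res, "distance")
  calls
}

#' Detect and annotate in one step
#'
#' @inheritParams detect_peaks
#' @inheritParams assign_peaks
#' @return Annotated peak-call tibble.
#' @export
annotate_spectrum <- function(spectrum, min_prominence = 0.05,
                              library = assignment_library(), tolerance = 8) {
  assign_peaks(detect_peaks(spectrum, min_prominence), library, tolerance)
}

#' Write annotated peak calls to a delimited table
#'
#' @param calls Annotated calls from [assign_peaks()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
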
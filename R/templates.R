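#' Tissue classes of the default library
#' @return Character vector of the six class names.
#' @export
tissue_classes <- function() {
  c("neurofibroma", "skin", "nerve", "fat", "bone", "mucosa")
}

peak_tbl <- function(center, fwhm, mean_amplitude, inter_locus_cv = 0.2) {
  tibble(
    center = center, fwhm = fwhm,
    mean_amplitude = mean_amplitude,
    inter_locus_cv = rep_len(inter_locus_cv, length(center))
  )
}

#' Construct a class template
#'
#' A generative recipe for one tissue class: Lorentzian Raman lines
#' (position, width, mean amplitude and inter-locus coefficient of variation)
#' plus a smooth fluorescence background model.
#'
#' @param class_name Class identifier.
#' @param peaks Tibble with columns `center` (cm^-1), `fwhm` (cm^-1),
#'   `mean_amplitude` (counts), `inter_locus_cv`.
#' @param background_params List with fields `centers`, `sds`, `weights`
#'   (Gaussian mixture shape in detector wavelength, nm), `amplitude_ratio`
#'   (peak background height relative to the strongest Raman line),
#'   `amplitude_cv` (lognormal inter-locus variation of that height) and
#'   `dark_offset` (counts).
#' @param noise_scale Exposure multiplier applied before Poisson sampling.
#' @return A `class_template` object.
#' @export
class_template <- function(class_name, peaks,
                           background_params = default_background_params(),
                           noise_scale = 1) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) > 0) {
    stopifnot(all(c("center", "fwhm", "mean_amplitude", "inter_locus_cv") %in% names(peaks)))
    if (any(peaks$center < 200 | peaks$center > 2000)) {
      abort("peak centers must lie in [200, 2000] cm^-1.", class = "serds_error_value")
    }
    if (any(peaks$fwhm <= 0) || any(peaks$mean_amplitude < 0)) {
      abort("fwhm must be positive and amplitudes nonnegative.", class = "serds_error_value")
    }
  }
  structure(
    list(
      class_name = class_name, peaks = peaks,
      background_params = background_params, noise_scale = noise_scale
    ),
    class = "class_template"
  )
}

#' Default fluorescence background model
#'
#' Two broad Gaussians in detector wavelength whose summed profile peaks at
#' `amplitude_ratio` times the strongest Raman line of the class; the
#' per-locus height fluctuates lognormally with CV `amplitude_cv`. The
#' profile is a function of detector wavelength only, so it is identical at
#' both excitations (exact Kasha insensitivity); `kasha_residual` adds an
#' optional excitation-dependent perturbation (fraction of the background,
#' default 0).
#'
#' @param amplitude_ratio Background-to-Raman height ratio (default 20).
#' @param amplitude_cv Lognormal CV of the per-locus background height.
#' @param dark_offset Constant detector offset in counts.
#' @param kasha_residual Fractional excitation sensitivity of the background.
#' @return List of background parameters.
#' @export
default_background_params <- function(amplitude_ratio = 20, amplitude_cv = 0.3,
                                      dark_offset = 50, kasha_residual = 0) {
  list(
    centers = c(855, 895), sds = c(45, 25), weights = c(1, 0.45),
    amplitude_ratio = amplitude_ratio, amplitude_cv = amplitude_cv,
    dark_offset = dark_offset, kasha_residual = kasha_residual
  )
}

# Default per-class line lists. Positions follow standard tissue Raman
# assignments (phenylalanine 1004/1038, proline/hydroxyproline 937,
# DNA 1095/1338/1378, lipid C-C 1073 and CH deformation 1440-1470, amide III
# 1200-1320 and amide I 1600-1670 modelled as overlapping wide Lorentzians,
# bone phosphate nu1 at 960). Amplitudes are arbitrary counts chosen to give
# each class a distinct weighting pattern; skin and mucosa deliberately share
# the protein signature of neurofibroma with shifted weights.
default_peak_sets <- function() {
  list(
    neurofibroma = peak_tbl(
      center = c(937, 1004, 1038, 1095, 1126, 1230, 1270, 1305, 1338, 1378,
                 1450, 1620, 1658),
      fwhm   = c(14, 12, 13, 16, 15, 45, 40, 35, 18, 16, 22, 40, 35),
      mean_amplitude = c(500, 1000, 450, 420, 250, 380, 420, 300, 520, 360,
                         620, 420, 700)
    ),
    skin = peak_tbl(
      center = c(937, 1004, 1038, 1095, 1126, 1230, 1270, 1305, 1338, 1450,
                 1532, 1620, 1658),
      fwhm   = c(14, 12, 13, 16, 15, 45, 40, 35, 18, 22, 18, 40, 35),
      mean_amplitude = c(420, 720, 310, 90, 190, 240, 260, 200, 300, 820,
                         160, 280, 520)
    ),
    nerve = peak_tbl(
      center = c(1004, 1073, 1126, 1270, 1300, 1338, 1440, 1460, 1658),
      fwhm   = c(12, 16, 15, 40, 22, 18, 20, 18, 32),
      mean_amplitude = c(210, 600, 410, 220, 520, 180, 1000, 580, 620)
    ),
    fat = peak_tbl(
      center = c(1004, 1073, 1126, 1300, 1440, 1460, 1655),
      fwhm   = c(12, 16, 15, 22, 20, 18, 30),
      mean_amplitude = c(90, 700, 330, 640, 1200, 700, 720)
    ),
    bone = peak_tbl(
      center = c(937, 960, 1004, 1070, 1245, 1270, 1450, 1640, 1660),
      fwhm   = c(14, 12, 12, 18, 45, 40, 22, 40, 35),
      mean_amplitude = c(200, 1200, 260, 420, 160, 170, 360, 210, 320)
    ),
    mucosa = peak_tbl(
      center = c(937, 1004, 1038, 1073, 1095, 1126, 1230, 1270, 1305, 1338,
                 1450, 1620, 1658),
      fwhm   = c(14, 12, 13, 16, 16, 15, 45, 40, 35, 18, 22, 40, 35),
      mean_amplitude = c(310, 640, 290, 360, 110, 310, 280, 310, 230, 340,
                         720, 330, 470)
    )
  )
}

#' Build the class template library
#'
#' Returns the six default tissue templates (cutaneous neurofibroma, skin,
#' nerve, fat, bone, mucosa). Neurofibroma emphasizes protein and
#' nucleic-acid lines; fat and nerve are lipid-dominated; bone alone carries
#' the 960 cm^-1 phosphate line; skin and mucosa share the protein pattern of
#' neurofibroma with different weightings and are the hardest classes to
#' separate.
#'
#' @param overrides Optional named list; each element replaces fields of one
#'   class template. An element may contain `peaks` (tibble, possibly
#'   zero-row), `background_params`, or `noise_scale`.
#' @return Named list of [class_template()] objects.
#' @export
build_class_library <- function(overrides = NULL) {
  sets <- default_peak_sets()
  lib <- lapply(names(sets), function(cl) class_template(cl, sets[[cl]]))
  names(lib) <- names(sets)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(lib))
    if (length(unknown) > 0) {
      abort(paste0("unknown class in overrides: ", paste(unknown, collapse = ", ")),
            class = "serds_error_class")
    }
    for (cl in names(overrides)) {
      ov <- overrides[[cl]]
      tpl <- lib[[cl]]
      if ("peaks" %in% names(ov)) {
        p <- ov$peaks
        if (is.null(p)) p <- peak_tbl(numeric(0), numeric(0), numeric(0))
        tpl$peaks <- as_tibble(p)
      }
      if (!is.null(ov$background_params)) tpl$background_params <- ov$background_params
      if (!is.null(ov$noise_scale)) tpl$noise_scale <- ov$noise_scale
      lib[[cl]] <- class_template(tpl$class_name, tpl$peaks, tpl$background_params, tpl$noise_scale)
    }
  }
  lib
}
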
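#' Cohort configuration
#'
#' Describes a simulated acquisition campaign: per-class locus counts,
#' repeats per excitation, the two excitation wavelengths, the detector grid
#' and the random seed. The defaults emulate the study conditions the
#' pipeline targets: 82 loci (9 neurofibroma, 12 skin, 6 nerve, 13 fat,
#' 15 bone, 27 mucosa), 50 repeats at each of 784 nm and 785 nm, and a
#' 1024-pixel detector covering 800-940 nm.
#'
#' @param counts Named integer vector of loci per class.
#' @param repeats Repeats per excitation per locus.
#' @param excitations The two excitation wavelengths (nm); must differ.
#' @param grid Detector wavelength grid (nm), strictly increasing.
#' @param seed Integer random seed.
#' @param ripple_amplitude Etaloning ripple height as a fraction of the
#'   locus background amplitude; fixed in pixel space; default 0 (off).
#' @param ripple_period Etaloning period in pixels.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(counts = c(neurofibroma = 9, skin = 12, nerve = 6,
                                     fat = 13, bone = 15, mucosa = 27),
                          repeats = 50,
                          excitations = c(784, 785),
                          grid = seq(800, 940, length.out = 1024),
                          seed = 1,
                          ripple_amplitude = 0,
                          ripple_period = 40) {
  if (any(counts <= 0)) abort("all class counts must be positive.", class = "serds_error_config")
  if (length(excitations) != 2 || excitations[1] == excitations[2]) {
    abort("need two distinct excitation wavelengths.", class = "serds_error_config")
  }
  if (any(diff(grid) <= 0)) abort("detector grid must be strictly increasing.", class = "serds_error_config")
  if (repeats < 1) abort("repeats must be >= 1.", class = "serds_error_config")
  structure(
    list(
      counts = counts, repeats = as.integer(repeats),
      excitations = as.numeric(excitations), grid = as.numeric(grid),
      seed = as.integer(seed),
      ripple_amplitude = ripple_amplitude, ripple_period = ripple_period
    ),
    class = "cohort_config"
  )
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

lorentzian <- function(x, center, fwhm, amplitude) {
  amplitude / (1 + (2 * (x - center) / fwhm)^2)
}

#' Draw one locus' clean Raman spectrum from a class template
#'
#' Sum of Lorentzian lines, one per template peak. Each line's amplitude is
#' drawn from a log-normal distribution with mean equal to the template's
#' `mean_amplitude` and coefficient of variation `inter_locus_cv`
#' (deterministic when the CV is 0), modelling between-locus biochemical
#' variability.
#'
#' @param template A [class_template()].
#' @param shift_axis Strictly increasing Raman shift grid (cm^-1).
#' @return A `clean_spectrum` tibble (`shift`, `intensity`) whose `peaks`
#'   attribute records the drawn per-line amplitudes.
#' @export
sample_clean_spectrum <- function(template, shift_axis = seq(200, 2100, by = 0.5)) {
  stopifnot(inherits(template, "class_template"))
  if (any(diff(shift_axis) <= 0)) {
    abort("shift_axis must be strictly increasing.", class = "serds_error_grid")
  }
  pk <- template$peaks
  intensity <- numeric(length(shift_axis))
  drawn <- numeric(nrow(pk))
  if (nrow(pk) > 0) {
    for (i in seq_len(nrow(pk))) {
      cv <- pk$inter_locus_cv[i]
      if (cv > 0) {
        s2 <- log(1 + cv^2)
        drawn[i] <- rlnorm(1, meanlog = log(pk$mean_amplitude[i]) - s2 / 2, sdlog = sqrt(s2))
      } else {
        drawn[i] <- pk$mean_amplitude[i]
      }
      intensity <- intensity + lorentzian(shift_axis, pk$center[i], pk$fwhm[i], drawn[i])
    }
  }
  new_spectrum(
    tibble(shift = shift_axis, intensity = intensity),
    "clean_spectrum",
    peaks = dplyr::mutate(pk, amplitude = drawn), class_name = template$class_name
  )
}

background_profile <- function(params, wavelength) {
  mix <- numeric(length(wavelength))
  for (i in seq_along(params$centers)) {
    mix <- mix + params$weights[i] * exp(-0.5 * ((wavelength - params$centers[i]) / params$sds[i])^2)
  }
  mix / max(mix)
}

#' Draw a per-locus fluorescence background amplitude
#'
#' The background peak height is `amplitude_ratio` times the strongest
#' Raman line of the template, multiplied by a log-normal factor with CV
#' `amplitude_cv` (mean 1). Fluorescence dominance is preserved by flooring
#' the factor at 1/2.
#'
#' @param template A [class_template()].
#' @return Background peak height in counts.
#' @export
draw_background_amplitude <- function(template) {
  bp <- template$background_params
  base <- if (nrow(template$peaks) > 0) max(template$peaks$mean_amplitude) else 1
  cv <- bp$amplitude_cv
  fac <- 1
  if (cv > 0) {
    s2 <- log(1 + cv^2)
    fac <- max(0.5, rlnorm(1, meanlog = -s2 / 2, sdlog = sqrt(s2)))
  }
  bp$amplitude_ratio * base * fac
}

#' Render a raw acquisition block
#'
#' Maps a clean Raman spectrum onto the detector wavelength axis for the
#' given excitation (a line at shift s appears at
#' \eqn{\lambda = 1/(1/\lambda_{ex} - s\cdot 10^{-7})}), adds the smooth
#' fluorescence profile -- a fixed function of detector wavelength, identical
#' for both excitations -- plus an optional etaloning ripple fixed in pixel
#' space, and draws `repeats` Poisson-noised spectra.
#'
#' @param clean A `clean_spectrum` on a shift axis (cm^-1).
#' @param excitation Excitation wavelength (nm); one of the config's pair.
#' @param template The [class_template()] the locus was drawn from.
#' @param config A [cohort_config()].
#' @param background_amplitude Background peak height in counts (0 disables
#'   the background; pass the same value for both excitations of a locus).
#' @param ripple_phase Phase of the etaloning ripple (radians).
#' @param noise Apply Poisson noise? (`FALSE` renders the deterministic
#'   expectation in every repeat.)
#' @param repeats Number of repeats (default `config$repeats`). With
#'   `collapse = TRUE` a single repeat is drawn as Poisson(repeats * lambda)
#'   / repeats, the exact distribution of the mean of `repeats` independent
#'   Poisson acquisitions.
#' @param collapse Draw the block mean directly (one stored repeat)?
#' @return A [raw_block()]. Its `clipped_shift_range` attribute reports the
#'   part of the clean spectrum's axis falling outside detector coverage.
#' @export
render_raw_block <- function(clean, excitation, template, config,
                             background_amplitude = 0, ripple_phase = 0,
                             noise = TRUE, repeats = config$repeats,
                             collapse = FALSE) {
  if (!excitation %in% config$excitations) {
    abort("excitation must be one of the config's wavelengths.", class = "serds_error_value")
  }
  grid <- config$grid
  s_px <- wavelength_to_shift(grid, excitation)
  raman <- approx(clean$shift, clean$intensity, xout = s_px, rule = 1)$y
  clipped <- range(clean$shift)[c(
    min(clean$shift) < min(s_px), max(clean$shift) > max(s_px)
  )]
  raman[is.na(raman)] <- 0
  bp <- template$background_params
  lambda <- raman + bp$dark_offset
  if (background_amplitude > 0) {
    bg <- background_amplitude * background_profile(bp, grid)
    if (!is.null(bp$kasha_residual) && bp$kasha_residual != 0) {
      bg <- bg * (1 + bp$kasha_residual * (excitation - config$excitations[2]))
    }
    if (config$ripple_amplitude > 0) {
      bg <- bg + config$ripple_amplitude * background_amplitude *
        sin(2 * pi * seq_along(grid) / config$ripple_period + ripple_phase)
    }
    lambda <- lambda + bg
  }
  lambda <- pmax(lambda, 0) * template$noise_scale
  n_rep <- if (collapse) 1L else as.integer(repeats)
  if (noise) {
    if (collapse) {
      counts <- matrix(rpois(length(lambda), repeats * lambda) / (repeats * template$noise_scale),
                       nrow = 1)
    } else {
      counts <- matrix(rpois(n_rep * length(lambda), rep(lambda, each = n_rep)) / template$noise_scale,
                       nrow = n_rep)
    }
  } else {
    counts <- matrix(rep(lambda / template$noise_scale, each = n_rep), nrow = n_rep)
  }
  out <- raw_block(grid, counts, excitation,
                   locus = "synthetic", label = template$class_name)
  attr(out, "clipped_shift_range") <- if (length(clipped)) clipped else NULL
  out
}

#' Generate a labelled dual-excitation cohort
#'
#' Draws, for every locus of every class, a clean Raman spectrum from the
#' class template and renders the two raw blocks (one per excitation) with a
#' shared per-locus fluorescence background. The result is a tibble with one
#' row per locus and list-columns holding the ground truth and both blocks;
#' identical seeds give bit-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param library Template library from [build_class_library()].
#' @param noise Apply Poisson noise (default TRUE).
#' @param collapse_repeats Store each block as its exactly-distributed mean
#'   (single repeat) instead of all repeats; see [render_raw_block()].
#' @return A `serds_cohort` tibble with columns `locus`, `label`, `clean`,
#'   `block_a`, `block_b` (excitations in config order, low first by
#'   default) and an `excitations` attribute.
#' @export
generate_cohort <- function(config = cohort_config(),
                            library = build_class_library(),
                            noise = TRUE, collapse_repeats = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  missing <- setdiff(names(config$counts), names(library))
  if (length(missing) > 0) {
    abort(paste0("library lacks templates for: ", paste(missing, collapse = ", ")),
          class = "serds_error_class")
  }
  rows <- with_preserved_seed(config$seed, {
    purrr::map(names(config$counts), function(cl) {
      tpl <- library[[cl]]
      purrr::map(seq_len(config$counts[[cl]]), function(i) {
        clean <- sample_clean_spectrum(tpl)
        bg_amp <- draw_background_amplitude(tpl)
        phase <- runif(1, 0, 2 * pi)
        locus <- sprintf("%s_%02d", cl, i)
        blocks <- lapply(config$excitations, function(ex) {
          b <- render_raw_block(clean, ex, tpl, config,
                                background_amplitude = bg_amp,
                                ripple_phase = phase, noise = noise,
                                collapse = collapse_repeats)
          b$locus <- locus
          b
        })
        list(locus = locus, label = cl, clean = clean,
             block_a = blocks[[1]], block_b = blocks[[2]])
      })
    }) |> purrr::flatten()
  })
  out <- tibble(
    locus = purrr::map_chr(rows, "locus"),
    label = purrr::map_chr(rows, "label"),
    clean = purrr::map(rows, "clean"),
    block_a = purrr::map(rows, "block_a"),
    block_b = purrr::map(rows, "block_b")
  )
  attr(out, "excitations") <- config$excitations
  attr(out, "repeats") <- config$repeats
  attr(out, "collapsed") <- collapse_repeats
  class(out) <- c("serds_cohort", class(out))
  out
}

#' Count the raw spectra held in a cohort
#'
#' @param cohort A `serds_cohort` tibble.
#' @return Total number of stored raw spectra across both excitations.
#' @export
n_raw_spectra <- function(cohort) {
  sum(purrr::map_int(cohort$block_a, ~ nrow(.x$counts))) +
    sum(purrr::map_int(cohort$block_b, ~ nrow(.x$counts)))
}

#' Add difference spectra to a cohort
#'
#' Averages both blocks of every locus and forms the z-scored SERDS
#' difference (first excitation minus second).
#'
#' @param cohort A `serds_cohort` tibble.
#' @return The cohort with a `diff` list-column of `difference_spectrum`s.
#' @export
cohort_differences <- function(cohort) {
  cohort$diff <- purrr::map2(cohort$block_a, cohort$block_b, locus_difference)
  cohort
}

#' Generate purifier training pairs
#'
#' Draws `n` random loci (class sampled uniformly from the library), renders
#' both excitation blocks with Poisson noise, forms the resampled difference
#' spectrum, and pairs it with the clean ground-truth spectrum on the same
#' uniform shift axis scaled to unit maximum. A small fraction of pairs is
#' rendered background-only (zero target) so the purifier also learns to
#' stay silent when no Raman signal is present.
#'
#' @param n Number of pairs.
#' @param library Template library.
#' @param config A [cohort_config()] (repeats, grid, excitations).
#' @param seed Integer seed.
#' @param flat_fraction Fraction of background-only pairs (default 0.05).
#' @param shift_axis Uniform target axis (default [default_shift_axis()]).
#' @return Tibble with columns `class`, `input` (difference values), `target`
#'   (unit-max clean spectrum) and `peaks` (true line parameters), plus the
#'   axis as an attribute.
#' @export
make_training_pairs <- function(n, library = build_class_library(),
                                config = cohort_config(), seed = 1,
                                flat_fraction = 0.05,
                                shift_axis = default_shift_axis()) {
  classes <- names(library)
  with_preserved_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      cl <- classes[1 + (i - 1) %% length(classes)]
      tpl <- library[[cl]]
      flat <- runif(1) < flat_fraction
      if (flat) tpl$peaks <- tpl$peaks[0, ]
      clean <- sample_clean_spectrum(tpl)
      bg_amp <- draw_background_amplitude(tpl)
      phase <- runif(1, 0, 2 * pi)
      blocks <- lapply(config$excitations, function(ex) {
        render_raw_block(clean, ex, tpl, config, background_amplitude = bg_amp,
                         ripple_phase = phase, noise = TRUE, collapse = TRUE)
      })
      d <- locus_difference(blocks[[1]], blocks[[2]])
      input <- resample_difference(d, shift_axis)$value
      target <- approx(clean$shift, clean$intensity, xout = shift_axis, rule = 2)$y
      m <- max(target)
      if (m > 0) target <- target / m
      list(class = cl, input = input, target = target,
           peaks = attr(clean, "peaks"))
    })
    out <- tibble(
      class = purrr::map_chr(rows, "class"),
      input = purrr::map(rows, "input"),
      target = purrr::map(rows, "target"),
      peaks = purrr::map(rows, "peaks")
    )
    attr(out, "shift_axis") <- shift_axis
    out
  })
}
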
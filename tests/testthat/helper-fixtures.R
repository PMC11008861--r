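# Small-scale fixtures shared across test files. Everything is generated in
# code; sizes are chosen so the whole suite stays desk-scale.

tiny_cohort_config <- function(n_per_class = 2, repeats = 5, seed = 7,
                               pixels = 512) {
  cohort_config(
    counts = setNames(rep(n_per_class, 6), tissue_classes()),
    repeats = repeats,
    grid = seq(800, 940, length.out = pixels),
    seed = seed
  )
}

# a single-line template: one Lorentzian at `center`, deterministic amplitude
single_line_template <- function(center = 1200, fwhm = 15, amplitude = 1000,
                                 cv = 0, background = default_background_params()) {
  class_template(
    "probe",
    tibble::tibble(center = center, fwhm = fwhm, mean_amplitude = amplitude,
                   inter_locus_cv = cv),
    background_params = background
  )
}

peakless_template <- function(background = default_background_params()) {
  class_template("flat", tibble::tibble(
    center = numeric(0), fwhm = numeric(0), mean_amplitude = numeric(0),
    inter_locus_cv = numeric(0)
  ), background_params = background)
}

# a synthetic tabular dataset of well-controlled Gaussian classes, shaped
# like a purified-spectra dataset (used for classifier unit tests)
make_gaussian_dataset <- function(n_per_class, p = 40, sep = 12, seed = 1,
                                  classes = c("neurofibroma", "skin")) {
  withr::with_seed(seed, {
    rows <- purrr::map(seq_along(classes), function(ci) {
      mu <- numeric(p)
      mu[ci] <- sep
      t(replicate(n_per_class, mu + rnorm(p)))
    })
    X <- do.call(rbind, rows)
    out <- tibble::tibble(
      locus = sprintf("l%02d", seq_len(nrow(X))),
      label = rep(classes, each = n_per_class),
      spectrum = purrr::map(seq_len(nrow(X)), ~ X[.x, ])
    )
    attr(out, "shift_axis") <- seq_len(p)
    class(out) <- c("serds_dataset", class(out))
    out
  })
}

# render the two mean spectra of one locus without noise
render_noise_free_pair <- function(template, config = tiny_cohort_config(),
                                   background_amplitude = 0) {
  clean <- withr::with_seed(1, sample_clean_spectrum(template))
  blocks <- lapply(config$excitations, function(ex) {
    render_raw_block(clean, ex, template, config,
                     background_amplitude = background_amplitude, noise = FALSE)
  })
  list(clean = clean, block_a = blocks[[1]], block_b = blocks[[2]])
}
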
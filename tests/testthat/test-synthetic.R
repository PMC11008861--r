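test_that("the default library carries the class-discriminating signatures", {
  lib <- build_class_library()
  expect_setequal(names(lib), tissue_classes())

  # bone is the only class with the phosphate line near 960 cm^-1
  has_960 <- vapply(lib, function(t) any(t$peaks$center >= 955 & t$peaks$center <= 965),
                    logical(1))
  expect_true(has_960[["bone"]])
  expect_false(any(has_960[setdiff(names(lib), "bone")]))

  # neurofibroma: phenylalanine 1004 plus nucleic-acid lines
  expect_true(1004 %in% lib$neurofibroma$peaks$center)
  expect_true(all(c(1095, 1338, 1378) %in% lib$neurofibroma$peaks$center))
  # fat and nerve are lipid-dominated
  for (cl in c("fat", "nerve")) {
    pk <- lib[[cl]]$peaks
    expect_true(1073 %in% pk$center)
    expect_true(any(pk$center >= 1440 & pk$center <= 1470))
  }
  # fluorescence dominates by design
  for (t in lib) expect_gte(t$background_params$amplitude_ratio, 1)

  # template invariants
  for (t in lib) {
    expect_true(all(t$peaks$center >= 200 & t$peaks$center <= 2000))
    expect_true(all(t$peaks$fwhm > 0))
    expect_true(all(t$peaks$mean_amplitude >= 0))
  }
})

test_that("library overrides validate class names and allow peak removal", {
  expect_error(build_class_library(overrides = list(cartilage = list())),
               class = "serds_error_class")
  lib <- build_class_library(overrides = list(skin = list(peaks = NULL)))
  expect_equal(nrow(lib$skin$peaks), 0)
  flat <- sample_clean_spectrum(lib$skin)
  expect_equal(flat$intensity, rep(0, nrow(flat)))
})

test_that("clean spectra are Lorentzian line sums with log-normal amplitudes", {
  tpl <- single_line_template(center = 1004, fwhm = 15, amplitude = 1, cv = 0)
  axis <- seq(900, 1100, by = 0.5)
  clean <- sample_clean_spectrum(tpl, axis)
  expect_equal(clean$intensity[axis == 1004], 1)
  expect_equal(clean$intensity[axis == 1004 - 7.5], 0.5)
  expect_equal(clean$intensity[axis == 1004 + 7.5], 0.5)
  expect_true(all(clean$intensity >= 0))

  # Monte-Carlo check of the log-normal parameterization: mean 1, cv 0.2
  tpl_cv <- single_line_template(center = 1004, fwhm = 15, amplitude = 1, cv = 0.2)
  amps <- withr::with_seed(99, {
    replicate(1000, attr(sample_clean_spectrum(tpl_cv, axis), "peaks")$amplitude)
  })
  se <- 0.2 / sqrt(1000)
  expect_lt(abs(mean(amps) - 1), 3 * se)

  expect_error(sample_clean_spectrum(tpl, c(1, 1, 2)), class = "serds_error_grid")
})

test_that("rendering maps lines onto the detector axis and shifts with excitation", {
  cfg <- tiny_cohort_config(pixels = 2048)
  tpl <- single_line_template(center = 1200, fwhm = 15)
  clean <- sample_clean_spectrum(tpl)

  # noise off, background off: every repeat equals the mapped clean spectrum
  b <- render_raw_block(clean, 785, tpl, cfg, background_amplitude = 0, noise = FALSE)
  expect_equal(nrow(b$counts), cfg$repeats)
  expect_equal(unique(as.vector(b$counts[, 1])), b$counts[1, 1])
  mapped <- approx(clean$shift, clean$intensity,
                   xout = wavelength_to_shift(cfg$grid, 785))$y
  mapped[is.na(mapped)] <- 0
  mapped <- mapped + tpl$background_params$dark_offset
  expect_equal(b$counts[1, ], mapped, tolerance = 1e-12)

  # on a fixed reference axis, the lower-excitation rendering sits one
  # excitation-step equivalent below the higher-excitation one
  b784 <- render_raw_block(clean, 784, tpl, cfg, background_amplitude = 0, noise = FALSE)
  s785 <- wavelength_to_shift(cfg$grid[which.max(b$counts[1, ])], 785)
  s784_on_785axis <- wavelength_to_shift(cfg$grid[which.max(b784$counts[1, ])], 785)
  delta <- s785 - s784_on_785axis
  expect_equal(delta, excitation_step_shift(784, 785), tolerance = 1)

  expect_error(render_raw_block(clean, 790, tpl, cfg), class = "serds_error_value")
})

test_that("fluorescence dominates every rendered raw spectrum under defaults", {
  cfg <- tiny_cohort_config(seed = 21)
  lib <- build_class_library()
  cohort <- generate_cohort(cfg, lib)
  for (i in seq_len(nrow(cohort))) {
    tpl <- lib[[cohort$label[i]]]
    max_line <- max(attr(cohort$clean[[i]], "peaks")$amplitude)
    bg_floor <- max(cohort$block_a[[i]]$counts[1, ]) # includes background
    expect_gte(bg_floor, max_line)
  }
})

test_that("cohort generation is seed-deterministic with the stated composition", {
  cfg <- tiny_cohort_config(n_per_class = 1, repeats = 4, seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_equal(nrow(c1), 6)
  expect_equal(n_raw_spectra(c1), 6 * 2 * 4)
  expect_identical(c1$block_a[[3]]$counts, c2$block_a[[3]]$counts)
  expect_identical(c1$clean[[6]]$intensity, c2$clean[[6]]$intensity)

  c3 <- generate_cohort(tiny_cohort_config(n_per_class = 1, repeats = 4, seed = 6))
  expect_false(identical(c1$block_a[[1]]$counts, c3$block_a[[1]]$counts))
})

test_that("the default cohort composition matches the study scale", {
  cfg <- cohort_config()
  expect_equal(sum(cfg$counts), 82)
  expect_equal(unname(cfg$counts[c("neurofibroma", "skin", "nerve", "fat", "bone", "mucosa")]),
               c(9, 12, 6, 13, 15, 27))
  expect_equal(cfg$repeats, 50L)
  expect_equal(cfg$excitations, c(784, 785))
  expect_equal(range(cfg$grid), c(800, 940))
  expect_equal(length(cfg$grid), 1024)
})

test_that("cohort config validates its invariants", {
  expect_error(cohort_config(counts = c(neurofibroma = 0)), class = "serds_error_config")
  expect_error(cohort_config(excitations = c(785, 785)), class = "serds_error_config")
  expect_error(cohort_config(grid = c(800, 800, 900)), class = "serds_error_config")
})

test_that("collapsed rendering reproduces the distribution of the repeat mean", {
  # Poisson aggregation identity: mean of n repeats ~ Pois(n*lambda)/n
  cfg <- tiny_cohort_config(repeats = 50, pixels = 128)
  tpl <- single_line_template()
  clean <- sample_clean_spectrum(tpl)
  stats <- withr::with_seed(8, {
    full <- replicate(200, mean_block(render_raw_block(
      clean, 785, tpl, cfg, background_amplitude = 1000))$intensity[64])
    coll <- replicate(200, mean_block(render_raw_block(
      clean, 785, tpl, cfg, background_amplitude = 1000, collapse = TRUE))$intensity[64])
    list(full = full, coll = coll)
  })
  expect_equal(mean(stats$full), mean(stats$coll), tolerance = 0.02)
  expect_equal(sd(stats$full), sd(stats$coll), tolerance = 0.2)
})
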
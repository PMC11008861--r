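test_that("wavelength/shift conversion matches direct evaluation and round-trips", {
  expect_equal(wavelength_to_shift(785, 785), 0)
  expect_equal(wavelength_to_shift(800, 785), 1e7 * (1 / 785 - 1 / 800))
  expect_equal(round(wavelength_to_shift(800, 785), 2), 238.85)
  expect_equal(round(wavelength_to_shift(940, 785), 2), 2100.56)
  expect_error(wavelength_to_shift(-1, 785), class = "serds_error_value")

  lambda <- seq(800, 940, length.out = 257)
  for (ex in c(784, 785)) {
    expect_equal(shift_to_wavelength(wavelength_to_shift(lambda, ex), ex),
                 lambda, tolerance = 1e-9)
  }
})

test_that("the excitation-step equivalent is constant across the detector axis", {
  lambda <- seq(800, 940, length.out = 64)
  delta <- wavelength_to_shift(lambda, 784) - wavelength_to_shift(lambda, 785)
  expect_lt(diff(range(delta)), 1e-9)
  expect_equal(delta[which.min(abs(lambda - 850))], 1e7 * (1 / 784 - 1 / 785),
               tolerance = 0.5 / 16)
  expect_equal(excitation_step_shift(784, 785), 1e7 * (1 / 784 - 1 / 785))
})

test_that("zscore uses the population convention and rejects degenerate input", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  x <- rnorm(101, mean = 7, sd = 3)
  expect_lt(abs(mean(zscore(x))), 1e-12)
  expect_equal(sqrt(mean(zscore(x)^2)), 1, tolerance = 1e-12)
  expect_error(zscore(c(5, 5, 5)), class = "serds_error_degenerate")
  expect_error(zscore(5), class = "serds_error_degenerate")
})

test_that("mean_block averages repeats pixelwise", {
  wl <- seq(800, 810, length.out = 5)
  b <- raw_block(wl, rbind(c(0, 2, 4, 0, 1), c(2, 0, 0, 4, 1)), 784)
  expect_equal(mean_block(b)$intensity, c(1, 1, 2, 2, 1))

  one <- raw_block(wl, matrix(rep(c(1, 2, 3, 4, 5), each = 50), nrow = 50), 785)
  expect_equal(mean_block(one)$intensity, c(1, 2, 3, 4, 5))
})

test_that("block averaging concentrates around the Poisson mean", {
  # mean of 50 Poisson repeats stays within 4 standard errors of the truth
  cfg <- tiny_cohort_config(repeats = 50, pixels = 256)
  tpl <- single_line_template()
  clean <- sample_clean_spectrum(tpl)
  ok <- withr::with_seed(42, {
    replicate(20, {
      b <- render_raw_block(clean, 785, tpl, cfg, background_amplitude = 5000)
      truth <- render_raw_block(clean, 785, tpl, cfg, background_amplitude = 5000,
                                noise = FALSE, repeats = 1)$counts[1, ]
      all(abs(mean_block(b)$intensity - truth) <= 4 * sqrt(pmax(truth, 1) / 50))
    })
  })
  expect_gte(mean(ok), 0.95)
})

test_that("serds_difference cancels identical input and is antisymmetric", {
  cfg <- tiny_cohort_config()
  pair <- render_noise_free_pair(single_line_template(), cfg,
                                 background_amplitude = 20000)
  m_a <- mean_block(pair$block_a)
  m_b <- mean_block(pair$block_b)

  same <- m_a
  attr(same, "excitation_nm") <- 785
  expect_equal(serds_difference(m_a, same)$value, rep(0, nrow(m_a)))

  d_ab <- serds_difference(m_a, m_b)
  d_ba <- serds_difference(m_b, m_a)
  expect_identical(d_ab$value, -d_ba$value)
  expect_error(serds_difference(m_a, m_a), class = "serds_error_value")
})

test_that("pure-fluorescence pairs cancel to machine precision", {
  cfg <- tiny_cohort_config()
  pair <- render_noise_free_pair(peakless_template(), cfg,
                                 background_amplitude = 20000)
  d <- locus_difference(pair$block_a, pair$block_b)
  expect_lt(max(abs(d$value)), 1e-10)
})

test_that("a single line yields a doublet with zero-crossing at the midpoint", {
  cfg <- tiny_cohort_config(pixels = 1024)
  tpl <- single_line_template(center = 1200, fwhm = 15)
  pair <- render_noise_free_pair(tpl, cfg, background_amplitude = 20000)
  d <- locus_difference(pair$block_a, pair$block_b)
  # positions of the line under both excitations, on the detector axis
  wl_a <- shift_to_wavelength(1200, cfg$excitations[1])
  wl_b <- shift_to_wavelength(1200, cfg$excitations[2])
  midpoint <- (wl_a + wl_b) / 2
  near <- abs(d$wavelength - midpoint) < 2
  sign_change <- which(diff(sign(d$value[near])) != 0)
  crossing <- d$wavelength[near][sign_change[1]]
  pixel <- diff(cfg$grid)[1]
  expect_lt(abs(crossing - midpoint), pixel)
})

test_that("mean_block and zscore commute with pixel reordering", {
  wl <- seq(800, 820, length.out = 16)
  counts <- matrix(rpois(5 * 16, 100), nrow = 5)
  perm <- withr::with_seed(3, sample(16))
  m <- mean_block(raw_block(wl, counts, 784))$intensity
  m_perm <- mean_block(raw_block(wl, counts[, order(perm)], 784))$intensity
  expect_equal(m_perm, m[order(perm)])
  expect_equal(zscore(m[perm]), zscore(m)[perm])
})

test_that("classic reconstruction is linear and recovers the line position", {
  cfg <- tiny_cohort_config(pixels = 1024)
  tpl <- single_line_template(center = 1200, fwhm = 15)
  pair <- render_noise_free_pair(tpl, cfg, background_amplitude = 20000)
  d <- locus_difference(pair$block_a, pair$block_b)

  rec <- classic_reconstruct(d)
  expect_lte(abs(rec$shift[which.max(rec$intensity)] - 1200),
             2 * diff(rec$shift[1:2]))

  zero <- d
  zero$value <- rep(0, nrow(d))
  expect_equal(classic_reconstruct(zero)$intensity, rep(0, nrow(rec)))

  d2 <- d
  d2$value <- rev(d$value)
  combo <- d
  combo$value <- 2 * d$value - 0.5 * d2$value
  lin <- classic_reconstruct(combo)$intensity
  parts <- 2 * classic_reconstruct(d)$intensity - 0.5 * classic_reconstruct(d2)$intensity
  expect_equal(lin, parts, tolerance = 1e-8)
})

test_that("difference resampling lands on the fingerprint axis", {
  cfg <- tiny_cohort_config()
  pair <- render_noise_free_pair(single_line_template(), cfg,
                                 background_amplitude = 20000)
  rs <- resample_difference(locus_difference(pair$block_a, pair$block_b))
  expect_equal(rs$shift, default_shift_axis())
  expect_true(all(is.finite(rs$value)))
})
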
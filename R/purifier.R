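#' Purifier configuration
#'
#' Hyperparameters of the 1-D convolutional encoder-decoder (U-Net) that maps
#' a SERDS difference spectrum to a background-free Raman spectrum. The
#' network halves resolution and doubles channels at each encoder level and
#' mirrors this in the decoder with skip connections concatenating encoder
#' features at matching resolution; activations are ReLU except for the
#' linear single-channel output projection.
#'
#' The working axis is the uniform 1 cm^-1 grid over 550-1800 cm^-1
#' (1251 bins) zero-padded to `input_len` so the length is divisible by
#' `2^depth`; outputs are cropped back after inference.
#'
#' @param input_len Network input length in bins (divisible by `2^depth`).
#' @param depth Number of encoder levels.
#' @param base_channels Channels of the first encoder level (doubled per
#'   level).
#' @param kernel Convolution kernel width (odd).
#' @param epochs,batch_size,learning_rate Training schedule (Adam).
#' @param loss Loss name; `"mse"` (mean squared error) is the only option.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A `purifier_config` object.
#' @export
purifier_config <- function(input_len = 1280, depth = 4, base_channels = 8,
                            kernel = 9, epochs = 10, batch_size = 32,
                            learning_rate = 1e-3, loss = "mse", seed = 42) {
  if (input_len %% 2^depth != 0) {
    abort("input_len must be divisible by 2^depth.", class = "serds_error_config")
  }
  if (any(c(input_len, depth, base_channels, kernel, epochs, batch_size) < 1) ||
      learning_rate <= 0) {
    abort("all purifier counts must be positive.", class = "serds_error_config")
  }
  loss <- match.arg(loss, "mse")
  structure(
    list(
      input_len = as.integer(input_len), depth = as.integer(depth),
      base_channels = as.integer(base_channels), kernel = as.integer(kernel),
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, loss = loss, seed = as.integer(seed)
    ),
    class = "purifier_config"
  )
}

arch_vec <- function(config) {
  c(config$input_len, config$depth, config$base_channels, config$kernel)
}

#' Number of learnable purifier parameters
#'
#' @param config A [purifier_config()].
#' @return Integer parameter count (weights + biases of all convolutions).
#' @export
purifier_parameter_count <- function(config) {
  unet_param_count_cpp(as.integer(arch_vec(config)))
}

#' Build an untrained purifier
#'
#' Initializes all convolution weights (He-scaled normal draws, seeded) and
#' zero biases.
#'
#' @param config A [purifier_config()].
#' @return A `serds_purifier` object with `trained = FALSE`.
#' @export
build_purifier <- function(config = purifier_config()) {
  stopifnot(inherits(config, "purifier_config"))
  n <- purifier_parameter_count(config)
  params <- with_preserved_seed(config$seed, {
    specs <- layer_specs(config)
    unlist(lapply(specs, function(s) {
      fan_in <- s$cin * s$k
      c(rnorm(s$cout * s$cin * s$k, sd = sqrt(2 / fan_in)), numeric(s$cout))
    }))
  })
  stopifnot(length(params) == n)
  structure(
    list(config = config, params = params, trained = FALSE,
         history = numeric(0), fingerprint = NULL),
    class = "serds_purifier"
  )
}

layer_specs <- function(config) {
  d <- config$depth
  b <- config$base_channels
  k <- config$kernel
  specs <- list()
  for (i in seq_len(d) - 1) {
    specs <- c(specs, list(list(cin = if (i == 0) 1 else b * 2^(i - 1), cout = b * 2^i, k = k)))
  }
  specs <- c(specs, list(list(cin = b * 2^(d - 1), cout = b * 2^d, k = k)))
  for (i in rev(seq_len(d) - 1)) {
    specs <- c(specs, list(list(cin = 3 * b * 2^i, cout = b * 2^i, k = k)))
  }
  c(specs, list(list(cin = b, cout = 1, k = 1)))
}

pad_to_len <- function(x, len) {
  extra <- len - length(x)
  if (extra < 0) abort("spectrum longer than network input.", class = "serds_error_shape")
  left <- extra %/% 2
  c(numeric(left), x, numeric(extra - left))
}

unpad_idx <- function(n, len) {
  left <- (len - n) %/% 2
  seq(left + 1, left + n)
}

pairs_to_matrices <- function(pairs, config) {
  n_axis <- length(pairs$input[[1]])
  if (!all(lengths(pairs$input) == n_axis) || !all(lengths(pairs$target) == n_axis)) {
    abort("all pairs must share one axis length.", class = "serds_error_shape")
  }
  X <- t(vapply(pairs$input, pad_to_len, numeric(config$input_len), len = config$input_len))
  Y <- t(vapply(pairs$target, pad_to_len, numeric(config$input_len), len = config$input_len))
  list(X = X, Y = Y, n_axis = n_axis)
}

#' Train the purifier on difference/clean pairs
#'
#' Minimizes mean squared error between the network output and the unit-max
#' clean spectra by Adam over shuffled minibatches. Training is a pure
#' function of (pairs, config): weight initialization and batch order are
#' derived from the config seed.
#'
#' @param pairs Tibble from [make_training_pairs()] (columns `input`,
#'   `target`).
#' @param config A [purifier_config()], or an untrained [build_purifier()]
#'   model to continue from its initialization.
#' @return A trained `serds_purifier` with per-epoch loss `history` and a
#'   training-set `fingerprint`.
#' @export
train_purifier <- function(pairs, config = purifier_config()) {
  model <- if (inherits(config, "serds_purifier")) config else build_purifier(config)
  config <- model$config
  if (nrow(pairs) < 1) abort("need at least one training pair.", class = "serds_error_value")
  m <- pairs_to_matrices(pairs, config)
  perms <- with_preserved_seed(config$seed + 1L, {
    t(vapply(seq_len(config$epochs), function(e) sample.int(nrow(m$X)),
             integer(nrow(m$X))))
  })
  fit <- unet_train_cpp(
    m$X, m$Y, model$params, as.integer(arch_vec(config)),
    epochs = config$epochs, batch_size = config$batch_size,
    lr = config$learning_rate, perm_1based = perms
  )
  model$params <- as.numeric(fit$params)
  model$history <- as.numeric(fit$history)
  model$trained <- TRUE
  model$n_axis <- m$n_axis
  model$fingerprint <- sprintf(
    "n=%d len=%d sum=%.6e ss=%.6e", nrow(m$X), ncol(m$X), sum(m$X), sum(m$X^2)
  )
  model
}

#' @export
print.serds_purifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<serds_purifier> depth %d, base %d, kernel %d, input %d (%s; %d parameters)\n",
    cfg$depth, cfg$base_channels, cfg$kernel, cfg$input_len,
    if (x$trained) sprintf("trained, final loss %.3g", tail(x$history, 1)) else "untrained",
    purifier_parameter_count(cfg)
  ))
  invisible(x)
}

forward_matrix <- function(model, X_axis) {
  X <- t(apply(X_axis, 1, pad_to_len, len = model$config$input_len))
  out <- unet_forward_cpp(X, model$params, as.integer(arch_vec(model$config)))
  out[, unpad_idx(ncol(X_axis), model$config$input_len), drop = FALSE]
}

#' Purify a difference spectrum
#'
#' Resamples the difference spectrum onto the network's uniform shift axis
#' and applies a single forward pass of the trained encoder-decoder,
#' returning the background-free Raman spectrum.
#'
#' @param model A trained `serds_purifier`.
#' @param diff A `difference_spectrum`, or a tibble with `shift`/`value`
#'   columns already on the uniform axis.
#' @param shift_axis Uniform working axis (default [default_shift_axis()]).
#' @return A `purified_spectrum` tibble (`shift`, `intensity`).
#' @export
purify <- function(model, diff, shift_axis = default_shift_axis()) {
  stopifnot(inherits(model, "serds_purifier"))
  if (!model$trained) abort("purifier is not trained.", class = "serds_error_state")
  if (inherits(diff, "difference_spectrum")) {
    rs <- resample_difference(diff, shift_axis)
  } else {
    rs <- tibble(shift = diff$shift, value = diff$value)
  }
  y <- forward_matrix(model, matrix(rs$value, nrow = 1))[1, ]
  new_spectrum(
    tibble(shift = rs$shift, intensity = y),
    "purified_spectrum",
    locus = attr(diff, "locus"), label = attr(diff, "label"), purifier = "unet"
  )
}

#' Purify a whole cohort
#'
#' Adds difference spectra (if absent) and purified spectra to a cohort
#' tibble, batching all loci through one forward pass.
#'
#' @param cohort A `serds_cohort` tibble.
#' @param model A trained `serds_purifier`.
#' @param shift_axis Uniform working axis.
#' @return The cohort with `diff` and `purified` list-columns.
#' @export
purify_cohort <- function(cohort, model, shift_axis = default_shift_axis()) {
  if (!"diff" %in% names(cohort)) cohort <- cohort_differences(cohort)
  vals <- t(vapply(cohort$diff, function(d) resample_difference(d, shift_axis)$value,
                   numeric(length(shift_axis))))
  out <- forward_matrix(model, vals)
  cohort$purified <- purrr::map(seq_len(nrow(cohort)), function(i) {
    new_spectrum(
      tibble(shift = shift_axis, intensity = out[i, ]),
      "purified_spectrum",
      locus = cohort$locus[i], label = cohort$label[i], purifier = "unet"
    )
  })
  cohort
}
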
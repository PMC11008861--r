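# The full-budget purifier (2000 pairs x 10 epochs) takes a few minutes to
# train, so it is fitted once per test run and shared by every test that
# needs a converged model; the same goes for the held-out evaluation pairs
# and the end-to-end cohort sweep.

.serds_cache <- new.env(parent = emptyenv())

full_trained_purifier <- function() {
  if (is.null(.serds_cache$model)) {
    pairs <- make_training_pairs(2000, seed = 1001)
    .serds_cache$model <- train_purifier(pairs, purifier_config())
  }
  .serds_cache$model
}

held_out_pairs <- function() {
  if (is.null(.serds_cache$held_out)) {
    .serds_cache$held_out <- make_training_pairs(150, seed = 9009)
  }
  .serds_cache$held_out
}

# forward pass over a held-out pair set; returns outputs, truths and the axis
held_out_eval <- function() {
  if (is.null(.serds_cache$eval)) {
    model <- full_trained_purifier()
    pairs <- held_out_pairs()
    X <- do.call(rbind, pairs$input)
    axis <- attr(pairs, "shift_axis")
    .serds_cache$eval <- list(
      pairs = pairs, axis = axis,
      truth = do.call(rbind, pairs$target),
      output = t(vapply(seq_len(nrow(pairs)), function(i) {
        purify(model, tibble::tibble(shift = axis, value = pairs$input[[i]]),
               shift_axis = axis)$intensity
      }, numeric(length(axis))))
    )
  }
  .serds_cache$eval
}

# default 82-locus cohorts through the full chain, one per seed
end_to_end_cv <- function(seeds = 1:10) {
  model <- full_trained_purifier()
  for (s in seeds) {
    key <- paste0("e2e_", s)
    if (is.null(.serds_cache[[key]])) {
      cohort <- generate_cohort(cohort_config(seed = s))
      cohort <- purify_cohort(cohort, model)
      data <- spectra_dataset(cohort)
      .serds_cache[[key]] <- list(
        cv = cross_validate(data, k = 5, seed = s),
        data = data
      )
    }
  }
  lapply(seeds, function(s) .serds_cache[[paste0("e2e_", s)]])
}
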
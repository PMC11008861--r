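#' Write a raw block to delimited text
#'
#' Format: comment headers (`# serds_block v1`, `# excitation_nm=...`,
#' `# locus=...`, `# label=...`) followed by a tab-separated table with a
#' wavelength column and one column per repeat.
#'
#' @param block A [raw_block()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  stopifnot(inherits(block, "raw_block"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# serds_block v1",
    sprintf("# excitation_nm=%.10g", block$excitation_nm),
    sprintf("# locus=%s", block$locus),
    sprintf("# label=%s", block$label)
  ), con)
  tab <- cbind(wavelength = block$wavelength, t(block$counts))
  colnames(tab) <- c("wavelength", sprintf("rep_%d", seq_len(nrow(block$counts))))
  utils::write.table(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_headers <- function(lines) {
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- hdr[grepl("=", hdr, fixed = TRUE)]
  keys <- sub("^# ([^=]+)=.*$", "\\1", kv)
  vals <- sub("^# [^=]+=", "", kv)
  setNames(as.list(vals), keys)
}

#' Read a raw block written by [write_block()]
#'
#' @param path File path.
#' @return A [raw_block()]. Errors on a missing excitation header or ragged
#'   rows (naming the offending line).
#' @export
read_block <- function(path) {
  lines <- readLines(path)
  meta <- parse_headers(lines)
  if (is.null(meta$excitation_nm)) {
    abort(sprintf("%s: missing mandatory '# excitation_nm=' header.", path),
          class = "serds_error_format")
  }
  body <- which(!startsWith(lines, "#"))
  if (length(body) < 2) abort(sprintf("%s: no data rows.", path), class = "serds_error_format")
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  n_col <- length(fields[[1]])
  bad <- which(lengths(fields) != n_col)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has %d fields, expected %d.",
                  path, body[bad[1]], lengths(fields)[bad[1]], n_col),
          class = "serds_error_format")
  }
  dat <- matrix(suppressWarnings(as.numeric(unlist(fields[-1]))),
                ncol = n_col, byrow = TRUE)
  if (anyNA(dat)) abort(sprintf("%s: non-numeric data value.", path), class = "serds_error_format")
  raw_block(
    wavelength = dat[, 1], counts = t(dat[, -1, drop = FALSE]),
    excitation_nm = as.numeric(meta$excitation_nm),
    locus = meta$locus %||% "locus", label = meta$label %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

round1 <- function(x) round(x, 1)

#' Write a classification report (JSON lines)
#'
#' One machine-readable record per binary comparison (confusion counts as
#' integers with the positive class named; percentages to one decimal) plus
#' a closing multiclass record with the overall accuracy and the full
#' confusion matrix.
#'
#' @param cv A `serds_cv` object from [cross_validate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(cv, path) {
  stopifnot(inherits(cv, "serds_cv"))
  recs <- purrr::map(seq_len(nrow(cv$reports)), function(i) {
    r <- cv$reports[i, ]
    jsonlite::toJSON(list(
      type = "binary", comparison = r$comparison, positive = r$positive,
      tp = as.integer(r$tp), fp = as.integer(r$fp),
      fn = as.integer(r$fn), tn = as.integer(r$tn), n = as.integer(r$n),
      sensitivity = round1(r$sensitivity), specificity = round1(r$specificity),
      accuracy = round1(r$accuracy), error = round1(r$error),
      auc = round1(r$auc)
    ), auto_unbox = TRUE, digits = NA)
  })
  multi <- jsonlite::toJSON(list(
    type = "multiclass", n = cv$n, k = cv$k, seed = cv$seed,
    overall_accuracy = round1(cv$overall_accuracy),
    classes = rownames(cv$confusion),
    confusion = unclass(unname(apply(cv$confusion, 1, as.integer, simplify = FALSE)))
  ), auto_unbox = TRUE, digits = NA)
  writeLines(c(unlist(recs), multi), path)
  invisible(path)
}

#' Read a classification report written by [write_report()]
#'
#' @param path Report path.
#' @return List with `binary` (tibble of comparisons) and `multiclass`
#'   (list).
#' @export
read_report <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  types <- vapply(recs, function(r) r$type, character(1))
  binary <- purrr::map(recs[types == "binary"], function(r) {
    as_tibble(r[setdiff(names(r), "type")])
  }) |> purrr::list_rbind()
  list(binary = binary, multiclass = recs[types == "multiclass"][[1]] %||% NULL)
}

run_config_defaults <- function() {
  list(
    seed = 1L,
    count_neurofibroma = 9L, count_skin = 12L, count_nerve = 6L,
    count_fat = 13L, count_bone = 15L, count_mucosa = 27L,
    repeats = 50L, excitation_a = 784, excitation_b = 785,
    grid_min = 800, grid_max = 940, grid_pixels = 1024L,
    pairs_n = 2000L, purifier_depth = 4L, purifier_base = 8L,
    purifier_kernel = 9L, purifier_input_len = 1280L,
    purifier_epochs = 10L, purifier_batch = 32L, purifier_lr = 1e-3,
    purifier_seed = 42L,
    cv_folds = 5L, range_low = 550, range_high = 1800, var_threshold = 0.95
  )
}

#' Read a flat key=value run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults. Pass
#' `"default"` for the all-defaults configuration.
#'
#' @param path Path to a text file of `key = value` lines (`#` comments
#'   allowed), or `"default"`.
#' @return Named list of resolved configuration values.
#' @export
read_run_config <- function(path = "default") {
  cfg <- run_config_defaults()
  if (!identical(path, "default")) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        abort(sprintf("config line without '=': %s", ln), class = "serds_error_format")
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(cfg)) {
        abort(sprintf("unknown config key: %s", key), class = "serds_error_format")
      }
      cfg[[key]] <- if (is.integer(cfg[[key]])) as.integer(val) else as.numeric(val)
    }
  }
  cfg
}

#' Write a resolved run configuration
#'
#' @param cfg Named list from [read_run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  writeLines(sprintf("%s = %.10g", names(cfg), as.numeric(unlist(cfg))), path)
  invisible(path)
}

config_to_cohort <- function(cfg, seed = NULL) {
  cohort_config(
    counts = c(
      neurofibroma = cfg$count_neurofibroma, skin = cfg$count_skin,
      nerve = cfg$count_nerve, fat = cfg$count_fat,
      bone = cfg$count_bone, mucosa = cfg$count_mucosa
    ),
    repeats = cfg$repeats,
    excitations = c(cfg$excitation_a, cfg$excitation_b),
    grid = seq(cfg$grid_min, cfg$grid_max, length.out = cfg$grid_pixels),
    seed = seed %||% cfg$seed
  )
}

config_to_purifier <- function(cfg) {
  purifier_config(
    input_len = cfg$purifier_input_len, depth = cfg$purifier_depth,
    base_channels = cfg$purifier_base, kernel = cfg$purifier_kernel,
    epochs = cfg$purifier_epochs, batch_size = cfg$purifier_batch,
    learning_rate = cfg$purifier_lr, seed = cfg$purifier_seed
  )
}

#' Save / load a trained purifier as text
#'
#' @param model A `serds_purifier`.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
write_purifier <- function(model, path) {
  stopifnot(inherits(model, "serds_purifier"))
  cfg <- model$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# serds_purifier v1",
    sprintf("# input_len=%d", cfg$input_len), sprintf("# depth=%d", cfg$depth),
    sprintf("# base_channels=%d", cfg$base_channels), sprintf("# kernel=%d", cfg$kernel),
    sprintf("# epochs=%d", cfg$epochs), sprintf("# batch_size=%d", cfg$batch_size),
    sprintf("# learning_rate=%.10g", cfg$learning_rate),
    sprintf("# seed=%d", cfg$seed),
    sprintf("# trained=%d", as.integer(model$trained)),
    sprintf("# fingerprint=%s", model$fingerprint %||% ""),
    sprintf("# history=%s", paste(sprintf("%.10g", model$history), collapse = ",")),
    sprintf("%.17g", model$params)
  ), con)
  invisible(path)
}

#' @rdname write_purifier
#' @export
read_purifier <- function(path) {
  lines <- readLines(path)
  meta <- parse_headers(lines)
  cfg <- purifier_config(
    input_len = as.integer(meta$input_len), depth = as.integer(meta$depth),
    base_channels = as.integer(meta$base_channels), kernel = as.integer(meta$kernel),
    epochs = as.integer(meta$epochs), batch_size = as.integer(meta$batch_size),
    learning_rate = as.numeric(meta$learning_rate), seed = as.integer(meta$seed)
  )
  params <- as.numeric(lines[!startsWith(lines, "#")])
  hist <- meta$history
  structure(
    list(
      config = cfg, params = params,
      trained = identical(meta$trained, "1"),
      history = if (nzchar(hist)) as.numeric(strsplit(hist, ",")[[1]]) else numeric(0),
      fingerprint = meta$fingerprint
    ),
    class = "serds_purifier"
  )
}

#' Write the classifier dataset matrix
#'
#' Tab-separated: `locus`, `label`, then one column per shift bin with the
#' shift value in the header row.
#'
#' @param data A `serds_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  axis <- attr(data, "shift_axis")
  M <- as_spectra_matrix(data)
  tab <- data.frame(locus = data$locus, label = data$label, M, check.names = FALSE)
  names(tab) <- c("locus", "label", sprintf("%.10g", axis))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset matrix written by [write_dataset()]
#'
#' @param path File path.
#' @return A `serds_dataset` tibble.
#' @export
read_dataset <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  axis <- as.numeric(names(tab)[-(1:2)])
  out <- tibble(
    locus = as.character(tab$locus), label = as.character(tab$label),
    spectrum = purrr::map(seq_len(nrow(tab)), ~ as.numeric(tab[.x, -(1:2)]))
  )
  attr(out, "shift_axis") <- axis
  class(out) <- c("serds_dataset", class(out))
  out
}
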
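#' Plain-text readers and writers
#'
#' All interchange formats are delimited or key-value text so every
#' intermediate artifact is inspectable and diffable: cohorts as
#' `patient_id, label, timestamp, f1..fd`; pedigrees as PED-like
#' `individual_id father_id mother_id affected` with `0` for unknown
#' parents; traces as `t, glucose_mmol_per_L`; models and configuration
#' as `key = value` files.
#'
#' @name glycorisk-io
NULL

#' Write a cohort as delimited text
#'
#' One row per sub-record: `patient_id, label, timestamp, f1..fd`.
#'
#' @param cohort a `glycorisk_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "glycorisk_cohort"))
  rows <- do.call(rbind, lapply(seq_along(cohort$histories), function(i) {
    h <- cohort$histories[[i]]
    data.frame(patient_id = h$patient_id, label = cohort$labels[i],
               timestamp = h$timestamps, h$features,
               stringsAsFactors = FALSE)
  }))
  names(rows) <- c("patient_id", "label", "timestamp",
                   paste0("f", seq_len(cohort$n_features)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort]
#'
#' @param path input file.
#' @return a `glycorisk_cohort`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(fcols) == 0L) stop("no feature columns f1.. in cohort file",
                                call. = FALSE)
  ids <- unique(df$patient_id)
  histories <- lapply(ids, function(id) {
    sub <- df[df$patient_id == id, , drop = FALSE]
    patient_history(id, sub$timestamp,
                    as.matrix(sub[, fcols, drop = FALSE]))
  })
  labels <- vapply(ids, function(id) {
    as.integer(df$label[df$patient_id == id][1])
  }, integer(1))
  structure(list(histories = histories, labels = unname(labels),
                 n_features = length(fcols)),
            class = "glycorisk_cohort")
}

#' Write a pedigree in PED-like text
#'
#' Whitespace-delimited `individual_id father_id mother_id affected`,
#' `0` meaning unknown parent.
#'
#' @param ped a [pedigree].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  utils::write.table(ped$members[, c("id", "father", "mother", "affected")],
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a PED-like pedigree file
#'
#' Accepts whitespace- or comma-delimited columns
#' `individual_id father_id mother_id affected`.
#'
#' @param path input file.
#' @return a [pedigree].
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop(sprintf("pedigree line %d does not have 4 fields", bad[1]),
         call. = FALSE)
  }
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- c("id", "father", "mother", "affected")
  tab$affected <- as.integer(tab$affected)
  pedigree(tab)
}

#' Write a glucose trace
#'
#' Two CSV columns: `t` (sample index from 0) and `glucose_mmol_per_L`.
#'
#' @param series a [glucose_series].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  utils::write.csv(
    data.frame(t = seq_along(series$values) - 1L,
               glucose_mmol_per_L = series$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a glucose trace written by [write_trace]
#'
#' @param path input file.
#' @param interval_minutes sampling-interval metadata for the returned
#'   series.
#' @return a [glucose_series].
#' @export
read_trace <- function(path, interval_minutes = 5) {
  df <- utils::read.csv(path)
  glucose_series(df$glucose_mmol_per_L[order(df$t)],
                 interval_minutes = interval_minutes)
}

write_kv <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    v <- kv[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 17, trim = TRUE,
                                       scientific = FALSE),
                                collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed key-value line: %s", ln),
                     call. = FALSE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    kv[[key]] <- if (!anyNA(num)) num else parts
  }
  kv
}

#' Serialize a risk model (classifier + calibration) as key-value text
#'
#' Stores the weights, bias, penalty, conversion parameters `S`/`F`, the
#' feature dimension and the decay rate, so scoring is reproducible
#' bit-for-bit.
#'
#' @param model a `margin_classifier`.
#' @param cal a `calibration`.
#' @param decay_rate the decay rate the risk inputs were built with.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, cal, decay_rate, path) {
  stopifnot(inherits(model, "margin_classifier"),
            inherits(cal, "calibration"))
  write_kv(list(dim = model$dim, weights = model$weights, bias = model$bias,
                C = model$C, S = cal$S, F = cal$F,
                decay_rate = decay_rate), path)
}

#' Read a risk model written by [write_risk_model]
#'
#' @param path input file.
#' @return list with `model`, `calibration` and `decay_rate`.
#' @export
read_risk_model <- function(path) {
  kv <- read_kv(path)
  model <- structure(
    list(weights = kv$weights, bias = kv$bias, C = kv$C,
         alpha = NULL, slacks = NULL, objective = NA_real_,
         dim = as.integer(kv$dim)),
    class = "margin_classifier")
  cal <- structure(list(S = kv$S, F = kv$F), class = "calibration")
  list(model = model, calibration = cal, decay_rate = kv$decay_rate)
}

#' Serialize an RBM forecaster as plain text
#'
#' Key-value header (shapes, encoding) followed by the flattened
#' parameter vectors.
#'
#' @param params an [rbm_params].
#' @param enc the [window_encoding] used in training.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rbm <- function(params, enc, path) {
  stopifnot(inherits(params, "rbm_params"), inherits(enc, "window_encoding"))
  write_kv(list(m = params$m, n_hidden = params$n_hidden,
                enc_min = enc$min, enc_max = enc$max, lag = enc$lag,
                b = params$b, c = params$c, W = as.numeric(params$W)),
           path)
}

#' Read an RBM forecaster written by [write_rbm]
#'
#' @param path input file.
#' @return list with `params` ([rbm_params]) and `encoding`
#'   ([window_encoding]).
#' @export
read_rbm <- function(path) {
  kv <- read_kv(path)
  m <- as.integer(kv$m)
  nh <- as.integer(kv$n_hidden)
  list(params = rbm_params(kv$b, kv$c, matrix(kv$W, m, nh)),
       encoding = structure(list(min = kv$enc_min, max = kv$enc_max,
                                 lag = as.integer(kv$lag)),
                            class = "window_encoding"))
}
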
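## CSV dialect: UTF-8, mandatory header, numerics at 9 significant digits.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 9, format = "g"))
}

write_table_9sig <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write / read recording traces
#'
#' Long-format recordings CSV with columns
#' `recording_id, subject_id, t_s, diameter_mm`, one row per sample.
#'
#' @param recordings list of [pupillogram()]s (or a `"plr_study"`).
#' @param path CSV file path.
#' @export
write_recordings <- function(recordings, path) {
  if (inherits(recordings, "plr_study")) recordings <- recordings$recordings
  df <- do.call(rbind, lapply(recordings, as.data.frame))
  write_table_9sig(df, path)
  invisible(path)
}

#' @rdname write_recordings
#' @param metadata data frame of per-recording metadata (the `meta` table
#'   of a study), with at least `recording_id` and `flash_onset_s`; when
#'   `NULL`, a 1 s flash onset is assumed.
#' @param strict error (with the offending row) on malformed values
#'   instead of dropping them.
#' @return `read_recordings()`: named list of [pupillogram()]s.
#' @export
read_recordings <- function(path, metadata = NULL, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "subject_id", "t_s", "diameter_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_recordings: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$recording_id <- as.character(df$recording_id)
  df$subject_id <- as.character(df$subject_id)
  df$t_s <- suppressWarnings(as.numeric(df$t_s))
  df$diameter_mm <- suppressWarnings(as.numeric(df$diameter_mm))
  bad <- which(!is.finite(df$diameter_mm) | df$diameter_mm <= 0 |
                 !is.finite(df$t_s))
  if (length(bad)) {
    if (strict)
      stop("read_recordings: malformed value at row ", bad[1] + 1,
           " (diameter/time must be finite and positive)", call. = FALSE)
    df <- df[-bad, , drop = FALSE]
  }
  ids <- unique(df$recording_id)
  out <- lapply(ids, function(rid) {
    rows <- df[df$recording_id == rid, , drop = FALSE]
    rows <- rows[order(rows$t_s), , drop = FALSE]
    if (any(diff(rows$t_s) <= 0))
      stop("read_recordings: duplicate time points in recording ", rid,
           call. = FALSE)
    onset <- 1; dur <- 1
    if (!is.null(metadata)) {
      m <- metadata[metadata$recording_id == rid, , drop = FALSE]
      if (nrow(m)) { onset <- m$flash_onset_s[1]; dur <- m$flash_duration_s[1] }
    }
    pupillogram(rows$t_s, rows$diameter_mm, recording_id = rid,
                subject_id = rows$subject_id[1], flash_onset = onset,
                flash_duration = dur)
  })
  names(out) <- ids
  out
}

#' Write / read the parameter table
#'
#' @param params parameter data frame (as from [study_parameters()] or
#'   [correct_plr()]).
#' @param path CSV path.
#' @export
write_parameters <- function(params, path) {
  write_table_9sig(params, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("recording_id", "subject_id"))
    if (!is.null(df[[col]])) df[[col]] <- as.character(df[[col]])
  df
}

## ---- model serialization (JSON) -------------------------------------

correction_to_list <- function(m) {
  list(parameter = m$parameter,
       terms = as.list(m$terms),
       coefficients = as.list(m$coefficients),
       intercept = m$intercept,
       average = m$average,
       alpha = m$alpha,
       diagnostics = m$diagnostics)
}

correction_from_list <- function(x, strict = TRUE) {
  known <- c("parameter", "terms", "coefficients", "intercept", "average",
             "alpha", "diagnostics")
  extra <- setdiff(names(x), known)
  if (strict && length(extra))
    stop("correction model JSON: unknown field(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  need <- setdiff(known, "diagnostics")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("correction model JSON: missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(parameter = x$parameter,
                 terms = as.character(unlist(x$terms)),
                 coefficients = unlist(x$coefficients),
                 intercept = as.numeric(x$intercept),
                 average = as.numeric(x$average),
                 alpha = as.numeric(x$alpha),
                 diagnostics = x$diagnostics),
            class = "plr_correction")
}

#' Serialize correction models to JSON
#'
#' Numbers are written with 15 significant digits, so a reloaded model
#' set reproduces predictions to within ~1e-15 relative error.
#'
#' @param models a `"plr_correction_set"`.
#' @param path JSON file path.
#' @export
write_correction_models <- function(models, path) {
  stopifnot(inherits(models, "plr_correction_set"))
  payload <- list(type = "plr_correction_set",
                  alpha = attr(models, "alpha"),
                  models = lapply(unclass(models), correction_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_correction_models
#' @param strict reject unknown fields.
#' @export
read_correction_models <- function(path, strict = TRUE) {
  x <- jsonlite::read_json(path)
  if (is.null(x$models) || !identical(x$type, "plr_correction_set"))
    stop("not a correction-model file: ", path, call. = FALSE)
  models <- lapply(x$models, correction_from_list, strict = strict)
  names(models) <- vapply(models, `[[`, character(1), "parameter")
  structure(models, class = "plr_correction_set",
            alpha = as.numeric(x$alpha))
}

#' Serialize a PuRe model (with optional scaler) to JSON
#'
#' @param model a [pure_model()].
#' @param path JSON file path.
#' @export
write_pure_model <- function(model, path) {
  stopifnot(inherits(model, "pure_model"))
  payload <- list(type = "pure_model",
                  coefficients = as.list(model$coefficients),
                  intercept = model$intercept)
  if (!is.null(model$scaler))
    payload$scaler <- list(raw = model$scaler$raw,
                           scaled = model$scaler$scaled,
                           calibration = model$scaler$calibration)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pure_model
#' @param strict reject unknown fields.
#' @export
read_pure_model <- function(path, strict = TRUE) {
  x <- jsonlite::read_json(path)
  if (!identical(x$type, "pure_model"))
    stop("not a PuRe model file: ", path, call. = FALSE)
  known <- c("type", "coefficients", "intercept", "scaler")
  extra <- setdiff(names(x), known)
  if (strict && length(extra))
    stop("PuRe model JSON: unknown field(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  scaler <- NULL
  if (!is.null(x$scaler)) {
    scaler <- structure(list(raw = as.numeric(unlist(x$scaler$raw)),
                             scaled = as.numeric(unlist(x$scaler$scaled)),
                             lower = 0, upper = 5,
                             calibration = x$scaler$calibration),
                        class = "pure_scaler")
  }
  pure_model(coefficients = unlist(x$coefficients),
             intercept = as.numeric(x$intercept), scaler = scaler)
}

## ---- run manifests ---------------------------------------------------

#' Write a run manifest
#'
#' Every CLI run records its command, seed, input/output paths (with md5
#' hashes of inputs), package version and timestamp, so identical inputs
#' can be re-run reproducibly.
#'
#' @param command the subcommand executed.
#' @param seed master seed used.
#' @param inputs,outputs character vectors of file paths.
#' @param path manifest JSON path.
#' @param extra optional named list of additional settings to record.
#' @export
write_manifest <- function(command, seed, inputs, outputs, path,
                           extra = NULL) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  payload <- list(command = command, seed = seed,
                  inputs = as.list(inputs), input_md5 = hashes,
                  outputs = as.list(outputs),
                  package_version = as.character(utils::packageVersion("purescore")),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(extra)) payload$settings <- extra
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

plr_log <- function(level = c("info", "debug", "warn", "error"), ...) {
  level <- match.arg(level)
  message(sprintf("[%s] %s", level, paste0(...)))
}
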
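#' Read a labelled dataset from CSV
#'
#' Reads a comma-separated file with a header row, numeric feature columns
#' and one label column with exactly two distinct values, and maps the
#' labels onto `{-1, +1}`. Under the default `"minority"` policy the rarer
#' raw label becomes `+1` (the positive class is the minority class); a tie
#' in class frequency maps the lexicographically larger raw label to `+1`
#' with a warning. Pass an explicit raw value as `positive_policy` to pin
#' the positive class instead. The label mapping is recorded in the
#' `label_mapping` attribute.
#'
#' @param path CSV file path.
#' @param label_column Name of the label column (default `"label"`).
#' @param positive_policy `"minority"` (default) or a raw label value.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, label_column = "label",
                         positive_policy = "minority") {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop_input(sprintf("label column \"%s\" not found (columns: %s)",
                       label_column, paste(names(df), collapse = ", ")))
  }
  raw <- as.character(df[[label_column]])
  values <- sort(unique(raw))
  if (length(values) != 2) {
    stop_input(sprintf("label column must have exactly 2 distinct values, found %d",
                       length(values)))
  }
  feat <- df[setdiff(names(df), label_column)]
  if (ncol(feat) == 0) stop_input("no feature columns besides the label")
  feat <- as.matrix(feat)
  if (!is.numeric(feat) || !all(is.finite(feat))) {
    stop_input("feature columns must be numeric and finite")
  }

  if (identical(positive_policy, "minority")) {
    counts <- table(raw)[values]
    if (counts[[1]] == counts[[2]]) {
      positive <- values[2]   # lexicographically larger
      warning("label classes are equally frequent; mapping the ",
              "lexicographically larger value \"", positive, "\" to +1")
    } else {
      positive <- values[which.min(counts)]
    }
  } else {
    positive <- as.character(positive_policy)
    if (!positive %in% values) {
      stop_config(sprintf("positive label \"%s\" not among the values (%s)",
                          positive, paste(values, collapse = ", ")))
    }
  }
  labels <- ifelse(raw == positive, 1, -1)
  out <- labeled_dataset(feat, labels)
  attr(out, "label_mapping") <- stats::setNames(
    c(1, -1), c(positive, setdiff(values, positive)))
  out
}

#' Write a labelled dataset as CSV
#'
#' Canonical dialect: comma-separated, header, UTF-8, `.` decimal. Numeric
#' features are written with 17 significant digits so the file round-trips
#' doubles exactly through [read_dataset()].
#'
#' @param data A [labeled_dataset()].
#' @param path Output file path.
#' @param label_column Name of the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, label_column = "label") {
  if (!inherits(data, "labeled_dataset")) stop_input("data must be a labeled_dataset")
  X <- data$features
  cols <- colnames(X)
  if (is.null(cols)) cols <- paste0("x", seq_len(ncol(X)))
  out <- as.data.frame(apply(X, 2, function(v) sprintf("%.17g", v)),
                       stringsAsFactors = FALSE)
  names(out) <- cols
  out[[label_column]] <- as.integer(data$labels)
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop_io(sprintf("cannot write to %s", path))
  invisible(path)
}

ARCHIVE_VERSION <- 1L

#' Save a fitted model as a JSON archive
#'
#' Writes a versioned plain-text (JSON) archive holding the model metadata
#' (kernel, gamma, scaler, provenance, timing) and the numeric payloads at
#' full precision (17 significant digits), so that a loaded model
#' reproduces decision values bitwise.
#'
#' @param model An `lssvm` or `glocal` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  payload <- if (inherits(model, "lssvm")) {
    c(list(type = "lssvm"), serialize_lssvm(model))
  } else if (inherits(model, "glocal")) {
    list(type = "glocal",
         global_model = serialize_lssvm(model$global_model),
         pool = list(features = model$merged_pool$features,
                     labels = model$merged_pool$labels,
                     row_ids = model$merged_pool$row_ids,
                     provenance = model$merged_pool$provenance),
         local_summaries = model$local_summaries,
         timing = model$timing)
  } else {
    stop_input("model must be an lssvm or glocal model")
  }
  payload$archive_version <- ARCHIVE_VERSION
  ok <- try(jsonlite::write_json(payload, path, digits = I(17),
                                 auto_unbox = TRUE, matrix = "rowmajor",
                                 na = "null"),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop_io(sprintf("cannot write archive to %s", path))
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path Archive path.
#' @return The reconstructed `lssvm` or `glocal` model. (A `glocal` archive
#'   restores the global model, the merged pool with provenance, the
#'   per-partition summaries and the timing report; the local models
#'   themselves are not archived.)
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  payload <- try(jsonlite::read_json(path, simplifyVector = TRUE), silent = TRUE)
  if (inherits(payload, "try-error") || is.null(payload$type) ||
      is.null(payload$archive_version)) {
    stop_io(sprintf("not a readable model archive: %s", path))
  }
  if (payload$archive_version != ARCHIVE_VERSION) {
    stop_io(sprintf("archive version %s not supported (expected %d); re-save the model",
                    payload$archive_version, ARCHIVE_VERSION))
  }
  if (payload$type == "lssvm") {
    deserialize_lssvm(payload)
  } else if (payload$type == "glocal") {
    pool <- labeled_dataset(payload$pool$features, payload$pool$labels,
                            payload$pool$row_ids)
    pool$provenance <- payload$pool$provenance
    structure(list(global_model = deserialize_lssvm(payload$global_model),
                   merged_pool = pool,
                   local_models = NULL,
                   local_summaries = payload$local_summaries,
                   partition = NULL,
                   timing = payload$timing,
                   config = NULL),
              class = "glocal")
  } else {
    stop_io(sprintf("unknown archive type \"%s\"", payload$type))
  }
}

serialize_lssvm <- function(m) {
  list(kernel = unclass(m$kernel), gamma = m$gamma,
       alphas = m$alphas, bias = m$bias,
       support_features = m$support_features,
       support_labels = m$support_labels,
       row_ids = m$row_ids,
       scaler = m$scaler, residual = m$residual)
}

deserialize_lssvm <- function(p) {
  k <- p$kernel
  spec <- kernel_spec(k$family, bandwidth_sq = k$bandwidth_sq %||% 1,
                      degree = k$degree %||% 2L, offset = k$offset %||% 1)
  X <- as.matrix(p$support_features)
  storage.mode(X) <- "double"
  scaler <- if (is.null(p$scaler)) NULL else
    list(center = as.numeric(p$scaler$center), scale = as.numeric(p$scaler$scale))
  structure(list(kernel = spec, gamma = as.numeric(p$gamma),
                 alphas = as.numeric(p$alphas), bias = as.numeric(p$bias),
                 support_features = X,
                 support_labels = as.numeric(p$support_labels),
                 row_ids = as.integer(p$row_ids),
                 scaler = scaler,
                 residual = as.numeric(p$residual %||% NA_real_)),
            class = "lssvm")
}
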
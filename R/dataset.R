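#' Labelled dataset for binary classification
#'
#' The universal input container: a numeric feature matrix, labels coded
#' `-1`/`+1`, and stable integer row identifiers that survive subsetting so
#' that provenance (which original rows ended up in a partition or in the
#' merged support-vector pool) can always be traced back.
#'
#' @param features Numeric matrix (or coercible data frame), one row per
#'   observation. All values must be finite.
#' @param labels Numeric vector over `{-1, +1}`, one per row.
#' @param row_ids Integer identifiers, unique, one per row. Default
#'   `seq_len(nrow(features))`.
#'
#' @return An object of class `labeled_dataset` with elements `features`,
#'   `labels`, `row_ids`.
#' @export
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c(-1, 1), 5))
#' n_obs(d)
labeled_dataset <- function(features, labels, row_ids = seq_len(nrow(features))) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.numeric(labels)
  row_ids <- as.integer(row_ids)
  if (!all(is.finite(features))) {
    stop_input("features contain non-finite values")
  }
  if (!all(labels %in% c(-1, 1))) {
    stop_input("labels must only contain -1 and +1")
  }
  if (length(labels) != nrow(features) || length(row_ids) != nrow(features)) {
    stop_input("features, labels and row_ids must have consistent lengths")
  }
  if (anyDuplicated(row_ids)) {
    stop_input("row_ids must be unique")
  }
  structure(list(features = features, labels = labels, row_ids = row_ids),
            class = "labeled_dataset")
}

#' Number of observations in a labelled dataset
#' @param data A [labeled_dataset()].
#' @return Integer row count.
#' @export
n_obs <- function(data) nrow(data$features)

#' Subset a labelled dataset by position
#'
#' @param data A [labeled_dataset()].
#' @param idx Integer (or logical) row positions.
#' @return A `labeled_dataset` holding the selected rows; `row_ids` are
#'   carried over unchanged.
#' @export
subset_dataset <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE],
                  data$labels[idx],
                  data$row_ids[idx])
}

#' Subset a labelled dataset by row identifier
#' @param data A [labeled_dataset()].
#' @param ids Row identifiers (must all be present).
#' @return A `labeled_dataset` in the order of `ids`.
#' @export
subset_by_row_id <- function(data, ids) {
  pos <- match(ids, data$row_ids)
  if (anyNA(pos)) stop_input("some requested row_ids are not in the dataset")
  subset_dataset(data, pos)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  n <- n_obs(x)
  npos <- sum(x$labels == 1)
  cat(sprintf("<labeled_dataset> %d x %d, %d positive (+1) / %d negative (-1)\n",
              n, ncol(x$features), npos, n - npos))
  invisible(x)
}

both_classes_present <- function(labels) {
  any(labels == 1) && any(labels == -1)
}

# z-score scaler estimated on a training matrix; zero-variance columns get
# sd = 1 so they standardise to a constant instead of NaN.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(center = mu, scale = sd)
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}
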
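#' Pruning configuration for sparse LS-SVM
#'
#' Controls the iterative support-value pruning that restores sparseness to
#' an LS-SVM: points with the smallest \eqn{|\alpha|} are discarded in small
#' batches and the model refitted, until a validation metric degrades past
#' `stop_tolerance` from its best value or the retention floor is reached.
#'
#' @param step_fraction Fraction of the current point set removed per
#'   iteration, in (0, 1).
#' @param stop_tolerance Maximum tolerated absolute drop of the validation
#'   metric from its best value before pruning stops. The default (0.05)
#'   sits at the resolution of an F1 score estimated on the default
#'   validation share of a region-sized input: a tolerance below one metric
#'   quantum would stop pruning on quantisation noise.
#' @param min_retained_fraction Retention floor relative to the input size,
#'   in (0, 1]. A value of 1 disables pruning entirely (pass-through).
#' @param validation_fraction Fraction held out (stratified) as the
#'   stopping oracle, in (0, 1).
#' @param metric Validation metric: `"f1_positive"` (F1 of the `+1` class)
#'   or `"balanced_accuracy"`.
#' @param seed Integer seed for the validation split.
#' @param min_prunable_size Inputs smaller than this pass through unpruned.
#' @return An object of class `prune_config`.
#' @export
prune_config <- function(step_fraction = 0.05,
                         stop_tolerance = 0.05,
                         min_retained_fraction = 0.10,
                         validation_fraction = 0.2,
                         metric = c("f1_positive", "balanced_accuracy"),
                         seed = 1L,
                         min_prunable_size = 20L) {
  metric <- match.arg(metric)
  if (step_fraction <= 0 || step_fraction >= 1) {
    stop_config("step_fraction must be in (0, 1)")
  }
  if (stop_tolerance < 0) stop_config("stop_tolerance must be non-negative")
  if (min_retained_fraction <= 0 || min_retained_fraction > 1) {
    stop_config("min_retained_fraction must be in (0, 1]")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop_config("validation_fraction must be in (0, 1)")
  }
  structure(list(step_fraction = step_fraction,
                 stop_tolerance = stop_tolerance,
                 min_retained_fraction = min_retained_fraction,
                 validation_fraction = validation_fraction,
                 metric = metric,
                 seed = as.integer(seed),
                 min_prunable_size = as.integer(min_prunable_size)),
            class = "prune_config")
}

#' Support-value ranking of a fitted LS-SVM
#'
#' In an LS-SVM every training point carries a support value
#' \eqn{\alpha_k = \gamma e_k} proportional to its residual; the points with
#' the largest \eqn{|\alpha|} are the most informative. Ties are broken by
#' ascending row id.
#'
#' @param model A fitted [fit_lssvm()] model.
#' @return A data frame with columns `row_id` and `support_value`
#'   (\eqn{|\alpha|}), sorted by descending support value.
#' @export
support_values <- function(model) {
  if (!inherits(model, "lssvm")) stop_input("model must be an lssvm")
  a <- abs(model$alphas)
  ord <- order(-a, model$row_ids)
  data.frame(row_id = model$row_ids[ord], support_value = a[ord])
}

#' Sparse LS-SVM by iterative support-value pruning
#'
#' Holds out a stratified validation fraction as the stopping oracle, then
#' repeatedly fits an LS-SVM on the current point set, records the
#' validation metric, and removes the `ceiling(step_fraction * current)`
#' points with the smallest \eqn{|\alpha|}. Pruning stops when the metric
#' drops more than `stop_tolerance` below its best value, or when the
#' retention floor `min_retained_fraction * n_obs(data)` is reached. The
#' returned model is refit on the smallest retained set whose validation
#' metric stayed within `stop_tolerance` of the best seen, keeping the
#' error performance while shedding the least informative points. A removal that would eliminate the last point
#' of a class is skipped (that point is pinned), so local models stay
#' binary.
#'
#' Inputs below `min_prunable_size`, or configurations with
#' `min_retained_fraction = 1`, pass through: the returned model is a plain
#' fit on all points and the retained set is the full input. In the normal
#' path the validation hold-out serves only as the stopping oracle and its
#' rows are not part of the retained set.
#'
#' @inheritParams fit_lssvm
#' @param config A [prune_config()].
#' @return An object of class `sparse_lssvm` with elements `model` (the
#'   refit [fit_lssvm()] model), `retained_row_ids`, and `trajectory` (a
#'   data frame of per-iteration retained counts and validation metric).
#' @export
prune_lssvm <- function(data, kernel = rbf_kernel(), gamma = 1,
                        config = prune_config()) {
  if (!inherits(data, "labeled_dataset")) stop_input("data must be a labeled_dataset")
  if (!inherits(config, "prune_config")) stop_config("config must be a prune_config")
  n <- n_obs(data)
  if (!both_classes_present(data$labels)) {
    stop_unfittable("pruning requires both classes present")
  }

  if (n < config$min_prunable_size || config$min_retained_fraction >= 1) {
    model <- fit_lssvm(data, kernel, gamma)
    return(structure(list(
      model = model,
      retained_row_ids = data$row_ids,
      trajectory = data.frame(retained = n, metric = NA_real_)),
      class = "sparse_lssvm"))
  }

  n_val <- max(1L, round(config$validation_fraction * n))
  val_pos <- stratified_holdout(data$labels, n_val, config$seed)
  if (length(val_pos) >= n - 1 ||
      !both_classes_present(data$labels[-val_pos])) {
    stop_config("degenerate validation split: too few points left to fit")
  }
  val <- subset_dataset(data, val_pos)
  cur <- setdiff(seq_len(n), val_pos)
  floor_n <- ceiling(config$min_retained_fraction * n)

  records <- list()
  states <- list()
  best <- -Inf
  repeat {
    m <- fit_lssvm(subset_dataset(data, cur), kernel, gamma)
    score <- eval_metric(val$labels, predict(m, val$features), config$metric)
    records[[length(records) + 1L]] <- c(retained = length(cur), metric = score)
    states[[length(states) + 1L]] <- cur
    best <- max(best, score)
    # stop only on persistent degradation: a single sub-tolerance dip of a
    # small-sample metric is quantisation noise, not a performance loss
    recent <- vapply(utils::tail(records, 3), function(r) r[["metric"]], 0)
    if (length(records) >= 3 && all(best - recent > config$stop_tolerance)) break
    if (length(cur) <= floor_n) break

    n_rm <- ceiling(config$step_fraction * length(cur))
    n_rm <- min(n_rm, length(cur) - floor_n)
    if (n_rm < 1) break
    drop <- pick_removals(m, data$labels[cur], n_rm)
    if (length(drop) == 0) break   # everything pinned by class preservation
    cur <- cur[-drop]
  }

  traj <- as.data.frame(do.call(rbind, records))
  metrics <- traj$metric
  # deepest iteration that maintains the metric within stop_tolerance of the
  # best seen: prune as far as possible while keeping the error performance
  eligible <- which(metrics >= max(metrics) - config$stop_tolerance)
  best_iter <- max(eligible)
  retained <- states[[best_iter]]

  structure(list(
    model = fit_lssvm(subset_dataset(data, retained), kernel, gamma),
    retained_row_ids = data$row_ids[retained],
    trajectory = traj),
    class = "sparse_lssvm")
}

#' @export
print.sparse_lssvm <- function(x, ...) {
  cat(sprintf("<sparse_lssvm> retained %d points over %d pruning iterations\n",
              length(x$retained_row_ids), nrow(x$trajectory)))
  invisible(x)
}

# Positions (within the current fit) of the n_rm smallest-|alpha| points,
# skipping any point that is the last of its class.
pick_removals <- function(model, labels, n_rm) {
  a <- abs(model$alphas)
  ord <- order(a, model$row_ids)   # ascending support value, ties by row id
  keep_count <- c(`-1` = sum(labels == -1), `1` = sum(labels == 1))
  drop <- integer(0)
  for (i in ord) {
    if (length(drop) >= n_rm) break
    cls <- as.character(labels[i])
    if (keep_count[[cls]] <= 1) next    # pinned: last point of its class
    keep_count[[cls]] <- keep_count[[cls]] - 1L
    drop <- c(drop, i)
  }
  drop
}

# Stratified sample of n_val positions: proportional per class, but a class
# never loses its last training point (a singleton class stays in training).
stratified_holdout <- function(labels, n_val, seed) {
  withr::with_seed(seed, {
    pos <- which(labels == 1); neg <- which(labels == -1)
    n_pos <- min(length(pos) - 1L, round(n_val * length(pos) / length(labels)))
    if (length(pos) > 1) n_pos <- max(n_pos, 1L) else n_pos <- 0L
    n_neg <- min(length(neg) - 1L, n_val - n_pos)
    if (length(neg) > 1) n_neg <- max(n_neg, 1L) else n_neg <- 0L
    sort(c(sample(pos, n_pos), sample(neg, n_neg)))
  })
}

# Internal scoring used by pruning and tuning. Undefined F1 (no true or
# predicted positives at all) scores 0 so the search can still rank models.
eval_metric <- function(y_true, y_pred, metric) {
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  switch(metric,
    f1_positive = {
      denom <- 2 * tp + fp + fn
      if (denom == 0) 0 else 2 * tp / denom
    },
    accuracy = (tp + tn) / length(y_true),
    balanced_accuracy = {
      sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
      spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
      (sens + spec) / 2
    },
    stop_config(sprintf("unknown metric \"%s\"", metric)))
}
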
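#' Repeated shuffled train/test splits
#'
#' The evaluation protocol: the dataset is randomly shuffled for a number
#' of independent rounds and split into training and test subsets (default
#' 90% / 10%). Splits are plain random shuffles, not stratified, matching
#' the protocol's wording; use `stratified = TRUE` to stratify by class.
#'
#' @param data A [labeled_dataset()] with at least 10 rows.
#' @param rounds Number of independent rounds (default 10).
#' @param test_fraction Test share in (0, 1) (default 0.10).
#' @param seed Master integer seed.
#' @param stratified Stratify the test set by class (default `FALSE`).
#' @return An object of class `split_plan`: a list with `rounds`,
#'   `test_fraction`, `seed`, and `splits`, a list of per-round lists with
#'   `train_row_ids` and `test_row_ids`.
#' @export
shuffled_splits <- function(data, rounds = 10L, test_fraction = 0.10,
                            seed = 1L, stratified = FALSE) {
  if (!inherits(data, "labeled_dataset")) stop_input("data must be a labeled_dataset")
  n <- n_obs(data)
  if (n < 10) stop_input("need at least 10 rows to split")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_config("test_fraction must be in (0, 1)")
  }
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n) stop_config("test_fraction leaves an empty subset")

  splits <- lapply(seq_len(rounds), function(r) {
    withr::with_seed(derive_seed(seed, r), {
      test_pos <- if (stratified) {
        stratified_holdout(data$labels, n_test, derive_seed(seed, r))
      } else {
        sample.int(n, n_test)
      }
      list(train_row_ids = data$row_ids[-test_pos],
           test_row_ids = data$row_ids[test_pos])
    })
  })
  structure(list(rounds = as.integer(rounds),
                 test_fraction = test_fraction,
                 seed = as.integer(seed),
                 splits = splits),
            class = "split_plan")
}

#' Confusion-matrix metrics with a minority-positive convention
#'
#' Computes the confusion counts and the derived rates used throughout the
#' benchmark, with the positive class conventionally the minority class:
#' sensitivity (true-positive rate), selectivity (implemented as
#' specificity, TN/(TN+FP)), precision, accuracy — all as percentages — and
#' per-class F1 scores on the unit interval. Ratios with a zero denominator
#' are reported as `NA` (missing), never coerced to 0.
#'
#' @param y_true,y_pred Equal-length label vectors over `{-1, +1}`.
#' @param positive_label Which label counts as positive (default `+1`).
#' @return An object of class `metrics_report` (a list of counts and
#'   metrics; see Details).
#' @export
#' @examples
#' confusion_metrics(c(1, 1, -1, -1), c(1, -1, -1, -1))
confusion_metrics <- function(y_true, y_pred, positive_label = 1) {
  if (length(y_true) == 0) stop_input("empty input")
  if (length(y_true) != length(y_pred)) stop_input("y_true and y_pred lengths differ")
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) stop_input("labels must be -1 or +1")
  if (!positive_label %in% c(-1, 1)) stop_config("positive_label must be -1 or +1")

  pos <- positive_label
  neg <- -positive_label
  tp <- sum(y_true == pos & y_pred == pos)
  fn <- sum(y_true == pos & y_pred == neg)
  tn <- sum(y_true == neg & y_pred == neg)
  fp <- sum(y_true == neg & y_pred == pos)

  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  prec_neg <- ratio(tn, tn + fn)
  f1 <- function(p, s) {
    if (is.na(p) || is.na(s) || p + s == 0) NA_real_ else 2 * p * s / (p + s)
  }

  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 positive_label = pos,
                 sensitivity = 100 * sens,
                 selectivity = 100 * spec,
                 precision = 100 * prec,
                 accuracy = 100 * (tp + tn) / length(y_true),
                 f1_positive = f1(prec, sens),
                 f1_negative = f1(prec_neg, spec)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metrics_report> tp %d fn %d tn %d fp %d | sensitivity %.1f%% ",
    "selectivity %.1f%% precision %.1f%% accuracy %.1f%% f1+ %.3f\n"),
    x$tp, x$fn, x$tn, x$fp, x$sensitivity, x$selectivity, x$precision,
    x$accuracy, x$f1_positive))
  invisible(x)
}

#' Welch t-test comparison of two metric samples
#'
#' Two-sided, unequal-variance (Welch) two-sample t-test by default, with
#' an optional paired mode; used to compare per-round metric samples of two
#' models. Two constant samples with equal means give `t = 0`, `p = 1`.
#'
#' @param samples_a,samples_b Numeric vectors of at least 2 values each
#'   (e.g. per-round sensitivities of two models).
#' @param alpha Significance level (default 0.05).
#' @param paired Use a paired t-test (default `FALSE`).
#' @return A list with `t`, `p_value`, `significant` (`p < alpha`), `df`
#'   and `alpha`.
#' @export
compare_models_ttest <- function(samples_a, samples_b, alpha = 0.05,
                                 paired = FALSE) {
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop_input("each sample needs at least 2 values")
  }
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  constant <- stats::var(samples_a) == 0 && stats::var(samples_b) == 0
  if (paired) constant <- stats::var(samples_a - samples_b) == 0
  if (constant) {
    delta <- mean(samples_a) - mean(samples_b)
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
    return(list(t = t, p_value = p, significant = p < alpha,
                df = NA_real_, alpha = alpha))
  }
  tt <- stats::t.test(samples_a, samples_b, paired = paired,
                      var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha,
       df = unname(tt$parameter), alpha = alpha)
}

#' Run the repeated shuffled-split benchmark protocol
#'
#' For each round of a [shuffled_splits()] plan, fits the requested model
#' on the training subset and scores it on the test subset with the
#' minority class as positive. Emits per-round metrics plus a timing table
#' shaped like the usual local/global accounting ("Accumulated Local Models
#' Time", ..., "# Data points to Train General Model").
#'
#' @param data Full [labeled_dataset()].
#' @param method `"glocal"` or `"lssvm"`.
#' @param plan A [shuffled_splits()] plan (defaults to 10 rounds, 90/10).
#' @param config A [glocal_config()] (required for `method = "glocal"`).
#' @param kernel,gamma Hyperparameters for `method = "lssvm"`; either may
#'   be `"tune"` to grid-search on each round's training set.
#' @param tuning A [tuning_grid()] used when tuning is requested.
#' @param seed Seed used when `plan` is built internally.
#' @return An object of class `benchmark_result`: list with `method`,
#'   `metrics` (per-round data frame), `timing` (per-round data frame with
#'   the timing-table column names), and `summary` (mean and sd of each
#'   metric across rounds).
#' @export
run_benchmark <- function(data, method = c("glocal", "lssvm"),
                          plan = NULL, config = NULL,
                          kernel = "tune", gamma = "tune",
                          tuning = tuning_grid(), seed = 1L) {
  method <- match.arg(method)
  if (is.null(plan)) plan <- shuffled_splits(data, seed = seed)
  if (method == "glocal" && is.null(config)) {
    stop_config("method \"glocal\" requires a glocal_config")
  }

  metrics <- list(); timing <- list()
  for (r in seq_len(plan$rounds)) {
    sp <- plan$splits[[r]]
    train <- subset_by_row_id(data, sp$train_row_ids)
    test <- subset_by_row_id(data, sp$test_row_ids)
    minority <- if (sum(train$labels == 1) <= sum(train$labels == -1)) 1 else -1

    if (method == "glocal") {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, r)
      fit <- fit_glocal(train, cfg)
      pred <- predict_glocal(fit, test$features)
      tim <- fit$timing
    } else {
      t0 <- proc.time()[["elapsed"]]
      hp <- resolve_hyperparams(train, glocal_config(
        1, kernel = kernel, gamma = gamma, prune = NULL, tuning = tuning,
        seed = derive_seed(seed, r)), derive_seed(seed, r))
      fit <- fit_lssvm(train, hp$kernel, hp$gamma)
      dt <- proc.time()[["elapsed"]] - t0
      pred <- predict(fit, test$features)
      tim <- list(accumulated_local_seconds = NA_real_,
                  average_local_seconds = NA_real_,
                  global_seconds = dt, total_seconds = dt,
                  n_pool_points = n_obs(train))
    }

    m <- confusion_metrics(test$labels, pred, positive_label = minority)
    metrics[[r]] <- data.frame(
      round = r, tp = m$tp, fn = m$fn, tn = m$tn, fp = m$fp,
      sensitivity = m$sensitivity, selectivity = m$selectivity,
      precision = m$precision, accuracy = m$accuracy,
      f1_positive = m$f1_positive, f1_negative = m$f1_negative)
    timing[[r]] <- data.frame(
      round = r,
      `Accumulated Local Models Time` = tim$accumulated_local_seconds,
      `Average Local Model Time` = tim$average_local_seconds,
      `General Model Time` = tim$global_seconds,
      `Total Time` = tim$total_seconds,
      `# Data points to Train General Model` = tim$n_pool_points,
      check.names = FALSE)
  }

  metrics <- do.call(rbind, metrics)
  num <- metrics[setdiff(names(metrics), "round")]
  structure(list(method = method,
                 metrics = metrics,
                 timing = do.call(rbind, timing),
                 summary = data.frame(
                   metric = names(num),
                   mean = vapply(num, function(v) mean(v, na.rm = TRUE), 0),
                   sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), 0),
                   row.names = NULL)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> method %s, %d rounds\n",
              x$method, nrow(x$metrics)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
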
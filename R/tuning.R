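#' Hyperparameter search grid
#'
#' Grid definition for [tune_hyperparams()]. The \eqn{\sigma^2} candidates
#' default to multiples of the median squared pairwise distance of the
#' (standardised) training features, so the grid adapts to feature scale;
#' the default factors span from roughly the width of an individual local
#' pattern (0.01) up to several times the global scale (5). Pass
#' `bandwidth_sq_values` to fix candidates in absolute units instead.
#'
#' @param gamma_values Positive regularisation candidates (default six
#'   points, logarithmic from 1e-2 to 1e3).
#' @param bandwidth_factors Multipliers of the median squared pairwise
#'   distance used to build the \eqn{\sigma^2} grid when
#'   `bandwidth_sq_values` is `NULL`.
#' @param bandwidth_sq_values Optional absolute \eqn{\sigma^2} candidates.
#' @param folds Cross-validation folds (default 5; [tune_hyperparams()]
#'   drops to 3 below 100 points).
#' @param metric Scoring metric: `"accuracy"` (default — classical LS-SVM
#'   tuners minimise the misclassification rate), `"f1_positive"` or
#'   `"balanced_accuracy"` for imbalance-aware selection.
#' @param one_se Apply the one-standard-error parsimony rule: among
#'   candidates whose mean CV score is within one standard error of the
#'   best, return the smoothest (largest \eqn{\sigma^2}, then smallest
#'   \eqn{\gamma}). Default `FALSE` (return the argmax).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `tuning_grid`.
#' @export
tuning_grid <- function(gamma_values = 10^seq(-2, 3, length.out = 6),
                        bandwidth_factors = c(0.01, 0.02, 0.05, 0.1, 0.5, 1, 5),
                        bandwidth_sq_values = NULL,
                        folds = 5L,
                        metric = c("accuracy", "f1_positive",
                                   "balanced_accuracy"),
                        one_se = FALSE,
                        seed = 1L) {
  metric <- match.arg(metric)
  if (length(gamma_values) == 0 || any(gamma_values <= 0)) {
    stop_config("gamma_values must be a non-empty set of positive numbers")
  }
  if (is.null(bandwidth_sq_values) && length(bandwidth_factors) == 0) {
    stop_config("provide bandwidth_factors or bandwidth_sq_values")
  }
  if (!is.null(bandwidth_sq_values) && any(bandwidth_sq_values <= 0)) {
    stop_config("bandwidth_sq_values must be positive")
  }
  if (folds < 2) stop_config("folds must be at least 2")
  structure(list(gamma_values = as.numeric(gamma_values),
                 bandwidth_factors = as.numeric(bandwidth_factors),
                 bandwidth_sq_values = bandwidth_sq_values,
                 folds = as.integer(folds),
                 metric = metric,
                 one_se = isTRUE(one_se),
                 seed = as.integer(seed)),
            class = "tuning_grid")
}

#' Cross-validated grid search for LS-SVM hyperparameters
#'
#' Stratified k-fold grid search over \eqn{(\gamma, \sigma^2)} for the RBF
#' LS-SVM. Returns the pair with the best mean validation metric; ties are
#' broken towards smaller \eqn{\gamma}, then smaller \eqn{\sigma^2}
#' (smoother models preferred).
#'
#' @param data A [labeled_dataset()] with both classes present.
#' @param grid A [tuning_grid()].
#' @return A list with `gamma`, `kernel` (a [kernel_spec()]), `score`
#'   (mean CV metric of the selected pair) and `scores` (the full grid with
#'   mean metric per candidate).
#' @export
tune_hyperparams <- function(data, grid = tuning_grid()) {
  if (!inherits(data, "labeled_dataset")) stop_input("data must be a labeled_dataset")
  if (!inherits(grid, "tuning_grid")) stop_config("grid must be a tuning_grid")
  n <- n_obs(data)
  if (!both_classes_present(data$labels)) {
    stop_unfittable("tuning requires both classes present")
  }
  folds <- grid$folds
  if (n < 100) folds <- min(folds, 3L)
  if (n < folds) stop_input("fewer points than folds")

  fold_of <- stratified_folds(data$labels, folds, grid$seed)
  # every training fold must keep both classes
  for (f in seq_len(folds)) {
    if (!both_classes_present(data$labels[fold_of != f])) {
      stop_config(sprintf(
        "stratification failure: training fold %d lost a class; use fewer folds", f))
    }
  }

  sigma2 <- grid$bandwidth_sq_values
  if (is.null(sigma2)) {
    scaler <- fit_scaler(data$features)
    med <- median_sq_distance(apply_scaler(data$features, scaler),
                              seed = grid$seed)
    sigma2 <- grid$bandwidth_factors * med
  }

  cand <- expand.grid(gamma = grid$gamma_values, sigma2 = sigma2,
                      KEEP.OUT.ATTRS = FALSE)
  cand$score <- NA_real_
  cand$se <- NA_real_
  for (i in seq_len(nrow(cand))) {
    sc <- numeric(folds)
    for (f in seq_len(folds)) {
      train <- subset_dataset(data, which(fold_of != f))
      test <- subset_dataset(data, which(fold_of == f))
      m <- fit_lssvm(train, rbf_kernel(cand$sigma2[i]), cand$gamma[i])
      sc[f] <- eval_metric(test$labels, predict(m, test$features), grid$metric)
    }
    cand$score[i] <- mean(sc)
    cand$se[i] <- stats::sd(sc) / sqrt(folds)
  }

  ord <- order(-cand$score, cand$gamma, cand$sigma2)
  best <- cand[ord[1], ]
  if (isTRUE(grid$one_se)) {
    eligible <- cand[cand$score >= best$score - best$se, ]
    best <- eligible[order(-eligible$sigma2, eligible$gamma), ][1, ]
  }
  list(gamma = best$gamma,
       kernel = rbf_kernel(best$sigma2),
       score = best$score,
       scores = cand)
}

# Deterministic stratified fold assignment: within each class, shuffle then
# deal round-robin so every fold sees (nearly) the class proportions.
stratified_folds <- function(labels, folds, seed) {
  withr::with_seed(seed, {
    fold_of <- integer(length(labels))
    for (cls in c(-1, 1)) {
      idx <- sample(which(labels == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_of
  })
}
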
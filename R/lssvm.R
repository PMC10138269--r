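#' Fit a least-squares support vector machine
#'
#' Solves the LS-SVM dual problem as one bordered linear system
#' \deqn{\begin{bmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ 1_N \end{bmatrix},}
#' where \eqn{\Omega_{ij} = y_i y_j k(x_i, x_j)}. Every training point
#' receives a support value \eqn{\alpha_k = \gamma e_k} proportional to its
#' residual, so the model is dense (no sparseness); see [prune_lssvm()] for
#' the pruned variant. The system is solved by a direct dense factorisation:
#' Cholesky of \eqn{H = \Omega + I/\gamma} with block elimination of the
#' bias row, falling back to an LU solve of the full bordered matrix when
#' \eqn{H} is not numerically positive definite. One step of iterative
#' refinement is applied; the relative residual of the bordered system must
#' come out below `1e-8`.
#'
#' Features are z-score standardised by default (means/sds estimated from
#' `data` and stored in the model, applied again at prediction time): both
#' the RBF kernel and the k-means partitioner upstream are scale-sensitive.
#'
#' @param data A [labeled_dataset()] with both classes present.
#' @param kernel A [kernel_spec()]; default RBF with unit bandwidth.
#' @param gamma Positive regularisation weight \eqn{\gamma} trading margin
#'   against squared residuals.
#' @param standardize Standardise features before the kernel (default TRUE).
#' @return An object of class `lssvm` with elements `kernel`, `gamma`,
#'   `alphas`, `bias`, `support_features` (standardised training points),
#'   `support_labels`, `row_ids`, `scaler`, `residual` (relative KKT
#'   residual of the solve).
#' @seealso [decision_value()], [predict.lssvm()], [support_values()]
#' @export
#' @examples
#' d <- labeled_dataset(rbind(c(0, 0), c(1, 0)), c(1, -1))
#' m <- fit_lssvm(d, linear_kernel(), gamma = 1, standardize = FALSE)
#' m$alphas   # 2/3, 2/3
#' m$bias     # 1/3
fit_lssvm <- function(data, kernel = rbf_kernel(), gamma = 1,
                      standardize = TRUE) {
  if (!inherits(data, "labeled_dataset")) stop_input("data must be a labeled_dataset")
  n <- n_obs(data)
  if (n < 2) stop_unfittable("need at least 2 training points")
  if (!both_classes_present(data$labels)) {
    stop_unfittable("training data contains a single class; LS-SVM needs both")
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma <= 0) {
    stop_config("gamma must be a positive number")
  }

  scaler <- if (standardize) fit_scaler(data$features) else NULL
  X <- apply_scaler(data$features, scaler)
  y <- data$labels

  K <- kernel_matrix(X, X, kernel)
  H <- tcrossprod(y) * K
  diag(H) <- diag(H) + 1 / gamma

  sol <- solve_bordered(H, y)
  alpha <- sol$alpha
  b <- sol$bias

  # one refinement pass on the bordered system, then a hard residual check
  rhs_norm <- sqrt(n)
  res <- bordered_residual(H, y, alpha, b)
  if (res$norm / rhs_norm > 1e-10) {
    corr <- try(solve_bordered(H, y, rhs_top = res$r_top, rhs = res$r_main),
                silent = TRUE)
    if (!inherits(corr, "try-error")) {
      alpha <- alpha + corr$alpha
      b <- b + corr$bias
      res <- bordered_residual(H, y, alpha, b)
    }
  }
  rel <- res$norm / rhs_norm
  if (!is.finite(rel) || rel > 1e-8) {
    stop_numerical(sprintf(
      "LS-SVM system is ill-conditioned even after regularisation (relative residual %.3g, reciprocal condition estimate %.3g); increase gamma or the kernel bandwidth",
      rel, rcond_estimate(H)))
  }

  structure(list(kernel = kernel, gamma = gamma,
                 alphas = alpha, bias = b,
                 support_features = X, support_labels = y,
                 row_ids = data$row_ids, scaler = scaler,
                 residual = rel),
            class = "lssvm")
}

# Solve [[0, y'], [y, H]] [b; alpha] = [rhs_top; rhs] by block elimination
# through a Cholesky factor of H, with an LU fallback on the full bordered
# matrix when H is not numerically SPD.
solve_bordered <- function(H, y, rhs_top = 0, rhs = rep(1, length(y))) {
  n <- length(y)
  ch <- try(chol(H), silent = TRUE)
  if (!inherits(ch, "try-error")) {
    s <- backsolve(ch, forwardsolve(t(ch), cbind(rhs, y)))
    nu <- s[, 1]; eta <- s[, 2]
    denom <- sum(y * eta)
    if (is.finite(denom) && abs(denom) > .Machine$double.eps * n) {
      b <- (sum(y * nu) - rhs_top) / denom
      return(list(alpha = nu - eta * b, bias = b))
    }
  }
  A <- rbind(c(0, y), cbind(y, H))
  sol <- try(solve(A, c(rhs_top, rhs)), silent = TRUE)
  if (inherits(sol, "try-error")) {
    stop_numerical(sprintf(
      "singular LS-SVM system (reciprocal condition estimate %.3g)",
      rcond_estimate(H)))
  }
  list(alpha = sol[-1], bias = sol[1])
}

bordered_residual <- function(H, y, alpha, b) {
  r_top <- -sum(y * alpha)                      # 0 - y'alpha
  r_main <- 1 - as.vector(H %*% alpha) - y * b  # 1 - (H alpha + y b)
  list(r_top = r_top, r_main = r_main,
       norm = sqrt(r_top^2 + sum(r_main^2)))
}

rcond_estimate <- function(H) {
  out <- try(rcond(H), silent = TRUE)
  if (inherits(out, "try-error")) NA_real_ else out
}

#' Decision values of an LS-SVM
#'
#' Evaluates the dual-form decision function
#' \eqn{f(x) = \sum_i \alpha_i y_i k(x_i, x) + b} at each query row, after
#' applying the scaler stored at fit time.
#'
#' @param model A fitted [fit_lssvm()] model.
#' @param X Query matrix with the same number of columns as the training
#'   features (raw, unstandardised units).
#' @return Numeric vector of decision values, one per query row (length 0
#'   for an empty query).
#' @export
decision_value <- function(model, X) {
  if (!inherits(model, "lssvm")) stop_input("model must be an lssvm")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0) return(numeric(0))
  if (ncol(X) != ncol(model$support_features)) {
    stop_input(sprintf("query has %d columns but the model was trained on %d",
                       ncol(X), ncol(model$support_features)))
  }
  Xq <- apply_scaler(X, model$scaler)
  K <- kernel_matrix(Xq, model$support_features, model$kernel)
  as.vector(K %*% (model$alphas * model$support_labels)) + model$bias
}

#' Predict class labels with an LS-SVM
#'
#' Labels are the sign of the decision value; a decision value of exactly
#' zero maps to `+1` so predictions are total.
#'
#' @param object A fitted [fit_lssvm()] model.
#' @param newdata Query feature matrix (raw units).
#' @param ... Unused.
#' @return Numeric vector over `{-1, +1}`.
#' @export
predict.lssvm <- function(object, newdata, ...) {
  dv <- decision_value(object, newdata)
  ifelse(dv >= 0, 1, -1)
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf("<lssvm> %d support points, %s kernel, gamma = %g, bias = %.4g\n",
              length(x$alphas), x$kernel$family, x$gamma, x$bias))
  invisible(x)
}
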
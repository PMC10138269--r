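#' Kernel specifications
#'
#' A kernel specification names the kernel family and its parameters.
#' The radial basis function (RBF) kernel follows the LS-SVMlab convention
#' \eqn{k(a,b) = \exp(-\lVert a-b\rVert^2 / \sigma^2)}, parameterised by the
#' squared bandwidth \eqn{\sigma^2} in (standardised) feature-space units
#' squared. The linear kernel is the plain dot product; the polynomial
#' kernel is \eqn{(a \cdot b + c)^p}.
#'
#' @param family One of `"rbf"`, `"linear"`, `"polynomial"`.
#' @param bandwidth_sq Positive squared bandwidth \eqn{\sigma^2} (RBF only).
#' @param degree Positive integer degree (polynomial only).
#' @param offset Additive offset (polynomial only).
#' @return An object of class `kernel_spec`.
#' @export
#' @examples
#' rbf_kernel(2)
#' kernel_matrix(diag(2), diag(2), linear_kernel())
kernel_spec <- function(family = c("rbf", "linear", "polynomial"),
                        bandwidth_sq = 1, degree = 2L, offset = 1) {
  family <- match.arg(family)
  if (family == "rbf" &&
      (!is.numeric(bandwidth_sq) || length(bandwidth_sq) != 1 ||
       !is.finite(bandwidth_sq) || bandwidth_sq <= 0)) {
    stop_config("bandwidth_sq must be a positive number for the RBF kernel")
  }
  if (family == "polynomial" && (degree < 1 || degree != round(degree))) {
    stop_config("degree must be a positive integer for the polynomial kernel")
  }
  structure(list(family = family,
                 bandwidth_sq = as.numeric(bandwidth_sq),
                 degree = as.integer(degree),
                 offset = as.numeric(offset)),
            class = "kernel_spec")
}

#' @rdname kernel_spec
#' @param sigma2 Positive squared bandwidth for [rbf_kernel()].
#' @export
rbf_kernel <- function(sigma2 = 1) kernel_spec("rbf", bandwidth_sq = sigma2)

#' @rdname kernel_spec
#' @export
linear_kernel <- function() kernel_spec("linear")

#' @rdname kernel_spec
#' @export
polynomial_kernel <- function(degree = 2L, offset = 1) {
  kernel_spec("polynomial", degree = degree, offset = offset)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(switch(x$family,
    rbf = sprintf("<kernel_spec> rbf, sigma2 = %g\n", x$bandwidth_sq),
    linear = "<kernel_spec> linear\n",
    polynomial = sprintf("<kernel_spec> polynomial, degree = %d, offset = %g\n",
                         x$degree, x$offset)))
  invisible(x)
}

#' Gram matrix between two point sets
#'
#' Evaluates the kernel between every row of `A` and every row of `B`.
#'
#' @param A,B Numeric matrices with the same number of columns.
#' @param spec A [kernel_spec()].
#' @return The `nrow(A)` x `nrow(B)` kernel matrix.
#' @export
kernel_matrix <- function(A, B = A, spec = rbf_kernel()) {
  A <- as.matrix(A); B <- as.matrix(B)
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  if (ncol(A) != ncol(B)) {
    stop_input(sprintf("dimension mismatch: A has %d columns, B has %d",
                       ncol(A), ncol(B)))
  }
  if (!all(is.finite(A)) || !all(is.finite(B))) {
    stop_input("kernel inputs must be finite")
  }
  if (!inherits(spec, "kernel_spec")) stop_config("spec must be a kernel_spec")
  G <- tcrossprod(A, B)
  switch(spec$family,
    linear = G,
    polynomial = (G + spec$offset)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      d2[d2 < 0] <- 0  # guard tiny negative values from cancellation
      exp(-d2 / spec$bandwidth_sq)
    })
}

# Median squared pairwise distance heuristic used to seed the sigma^2 grid;
# subsamples large inputs for an O(m^2) estimate.
median_sq_distance <- function(X, max_points = 500, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) > max_points) {
    idx <- withr::with_seed(seed, sample.int(nrow(X), max_points))
    X <- X[idx, , drop = FALSE]
  }
  d2 <- as.vector(stats::dist(X))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}
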
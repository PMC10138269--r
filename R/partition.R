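#' k-means partitioning of the input space
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_init` restarts by
#' within-cluster sum of squares. An empty cluster arising during iteration
#' is re-seeded at the point farthest from its assigned centroid. Fully
#' deterministic given `seed`.
#'
#' @param X Numeric matrix of points (rows), typically standardised.
#' @param k Number of regions, `1 <= k <= nrow(X)`.
#' @param seed Integer seed.
#' @param n_init Number of independent restarts (default 5).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @return An object of class `partition_assignment` with elements
#'   `centroids` (k x d), `assignment` (length-N integers in `1..k`),
#'   `sizes`, and `inertia` (total within-cluster sum of squares).
#' @export
kmeans_partition <- function(X, k, seed = 1L, n_init = 5L, max_iter = 300L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k < 1 || k > n) stop_input(sprintf("k must be in [1, %d], got %s", n, k))
  if (!all(is.finite(X))) stop_input("points must be finite")

  best <- NULL
  for (r in seq_len(n_init)) {
    run <- withr::with_seed(derive_seed(seed, r), {
      centers <- kmeanspp_init(X, k)
      lloyd(X, centers, max_iter)
    })
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  structure(list(centroids = best$centers,
                 assignment = best$assignment,
                 sizes = tabulate(best$assignment, nbins = k),
                 inertia = best$inertia),
            class = "partition_assignment")
}

#' @export
print.partition_assignment <- function(x, ...) {
  cat(sprintf("<partition_assignment> k = %d, sizes %d..%d, inertia = %.4g\n",
              nrow(x$centroids), min(x$sizes), max(x$sizes), x$inertia))
  invisible(x)
}

# k-means++: first centre uniform, subsequent centres with probability
# proportional to squared distance from the nearest chosen centre.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
    for (j in 2:k) {
      pick <- if (sum(d2) > 0) sample.int(n, 1, prob = d2) else sample.int(n, 1)
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ], "-")^2))
    }
  }
  centers
}

lloyd <- function(X, centers, max_iter) {
  n <- nrow(X); k <- nrow(centers)
  xsq <- rowSums(X^2)
  assignment <- integer(n)
  for (it in seq_len(max_iter)) {
    # squared distances n x k (up to the constant xsq, irrelevant for argmin)
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
    new_assignment <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters at the globally farthest point
    empty <- setdiff(seq_len(k), unique(new_assignment))
    for (j in empty) {
      nearest <- d2[cbind(seq_len(n), new_assignment)]
      far <- which.max(nearest)
      centers[j, ] <- X[far, ]
      new_assignment[far] <- j
    }
    converged <- identical(new_assignment, assignment)
    assignment <- new_assignment
    centers <- centroids_of(X, assignment, k, centers)
    if (converged) break
  }
  d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
  d2[d2 < 0] <- 0
  list(centers = centers, assignment = assignment,
       inertia = sum(d2[cbind(seq_len(n), assignment)]))
}

centroids_of <- function(X, assignment, k, fallback) {
  sums <- rowsum(X, assignment, reorder = FALSE)
  counts <- tabulate(assignment, nbins = k)
  out <- fallback
  present <- sort(unique(assignment))
  out[present, ] <- sums[as.character(present), , drop = FALSE] / counts[present]
  out
}

#' Build fit-able local problems from a partition
#'
#' Turns a k-means assignment into one [labeled_dataset()] per effective
#' partition, repairing degenerate regions. A partition that is smaller
#' than `min_size`, or that holds minority (`+1`) points only, is merged
#' into the nearest-centroid partition containing the missing class, so
#' those local problems become fit-able. An adequately sized partition
#' holding only majority (`-1`) points is not merged — pulling interior
#' majority mass into a faraway mixed region would erase that region's
#' local class balance; instead it is flagged pass-through: it describes
#' no class boundary and no local model is fitted on it. Merges are
#' recorded in `merge_log`; points are never discarded, so the union of
#' the local problems is exactly the input.
#'
#' @param data A [labeled_dataset()]; rows must correspond to the rows
#'   clustered in `pa`.
#' @param pa A [kmeans_partition()] result.
#' @param min_size Minimum healthy partition size (default 20).
#' @return An object of class `local_problems` with elements `problems`
#'   (list of `labeled_dataset`), `pass_through` (logical per problem),
#'   `partition_of` (effective partition index per input row),
#'   `class_counts` (effective partitions x 2), and `merge_log` (data
#'   frame `from`, `into`, `reason`).
#' @export
make_local_problems <- function(data, pa, min_size = 20L) {
  if (!inherits(data, "labeled_dataset")) stop_input("data must be a labeled_dataset")
  if (!inherits(pa, "partition_assignment")) stop_input("pa must be a partition_assignment")
  n <- n_obs(data)
  if (length(pa$assignment) != n) {
    stop_input("assignment length does not match the dataset")
  }
  if (!both_classes_present(data$labels)) {
    stop_unfittable("the entire training set is single-class")
  }

  k <- nrow(pa$centroids)
  group <- pa$assignment          # effective group id per point, starts as cluster id
  centroid_of <- function(g) {
    idx <- which(group == g)
    colMeans(data$features[idx, , drop = FALSE])
  }
  log <- list()

  repeat {
    ids <- sort(unique(group))
    if (length(ids) == 1) break
    npos <- vapply(ids, function(g) sum(data$labels[group == g] == 1), 0)
    nneg <- vapply(ids, function(g) sum(data$labels[group == g] == -1), 0)
    size <- npos + nneg
    # majority-only partitions of adequate size stay (pass-through)
    bad <- ids[(npos < 1 & size < min_size) | (npos >= 1 & nneg < 1) |
                 (npos >= 1 & size < min_size)]
    if (length(bad) == 0) break
    g <- bad[which.min(size[match(bad, ids)])]     # repair smallest first
    gi <- match(g, ids)
    missing_class <- if (npos[gi] < 1) 1 else if (nneg[gi] < 1) -1 else 0
    candidates <- setdiff(ids, g)
    if (missing_class == 1) {
      with_class <- candidates[vapply(candidates, function(h) any(data$labels[group == h] == 1), NA)]
      if (length(with_class)) candidates <- with_class
    } else if (missing_class == -1) {
      with_class <- candidates[vapply(candidates, function(h) any(data$labels[group == h] == -1), NA)]
      if (length(with_class)) candidates <- with_class
    }
    cg <- centroid_of(g)
    d2 <- vapply(candidates, function(h) sum((centroid_of(h) - cg)^2), 0)
    target <- candidates[which.min(d2)]
    reason <- if (missing_class != 0) {
      sprintf("missing class %+d", missing_class)
    } else {
      sprintf("size %d < min_size %d", sum(group == g), min_size)
    }
    log[[length(log) + 1L]] <- data.frame(from = g, into = target, reason = reason)
    group[group == g] <- target
  }

  ids <- sort(unique(group))
  partition_of <- match(group, ids)
  problems <- lapply(seq_along(ids), function(i) {
    subset_dataset(data, which(partition_of == i))
  })
  class_counts <- t(vapply(problems, function(p) {
    c(negative = sum(p$labels == -1), positive = sum(p$labels == 1))
  }, c(negative = 0, positive = 0)))
  pass_through <- class_counts[, "positive"] == 0 |
    class_counts[, "negative"] == 0

  structure(list(problems = problems,
                 pass_through = unname(pass_through),
                 partition_of = partition_of,
                 class_counts = class_counts,
                 merge_log = if (length(log)) do.call(rbind, log)
                             else data.frame(from = integer(0), into = integer(0),
                                             reason = character(0))),
            class = "local_problems")
}
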
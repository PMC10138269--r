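test_that("k-means degenerate cases behave as closed forms dictate", {
  withr::with_seed(1, X <- matrix(rnorm(20), 10, 2))
  # k = N: every point its own cluster, zero inertia
  pa <- kmeans_partition(X, 10, seed = 1)
  expect_equal(sort(pa$assignment), 1:10)
  expect_equal(pa$inertia, 0, tolerance = 1e-12)
  # k = 1: centroid is the mean
  pa1 <- kmeans_partition(X, 1, seed = 1)
  expect_equal(as.vector(pa1$centroids), colMeans(X), tolerance = 1e-12)
  expect_error(kmeans_partition(X, 11), class = "glocalsvm_input_error")
})

test_that("two far pairs are recovered for any seed (enumeration oracle)", {
  X <- rbind(c(0, 0), c(0.5, 0), c(100, 100), c(100.5, 100))
  # enumerate both candidate pairings: correct one has far smaller inertia
  inertia_of <- function(groups) {
    sum(vapply(unique(groups), function(g) {
      P <- X[groups == g, , drop = FALSE]
      sum(sweep(P, 2, colMeans(P), "-")^2)
    }, 0))
  }
  expect_lt(inertia_of(c(1, 1, 2, 2)), inertia_of(c(1, 2, 1, 2)))
  for (seed in 1:5) {
    pa <- kmeans_partition(X, 2, seed = seed)
    expect_equal(pa$assignment[1], pa$assignment[2])
    expect_equal(pa$assignment[3], pa$assignment[4])
    expect_false(pa$assignment[1] == pa$assignment[3])
    expect_equal(pa$inertia, inertia_of(c(1, 1, 2, 2)), tolerance = 1e-12)
  }
})

test_that("partition assignment is seed deterministic", {
  withr::with_seed(2, X <- matrix(rnorm(400), 200, 2))
  a <- kmeans_partition(X, 8, seed = 7)
  b <- kmeans_partition(X, 8, seed = 7)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$centroids, b$centroids)
})

test_that("local problems conserve the training set and repair degeneracy", {
  d <- withr::with_seed(3, {
    X <- rbind(matrix(rnorm(160, 0, 1), 80, 2),
               matrix(rnorm(40, 6, 0.3), 20, 2))
    labeled_dataset(X, c(rep(-1, 80), rep(1, 20)))
  })
  pa <- kmeans_partition(scale(d$features), 5, seed = 1)
  lp <- make_local_problems(d, pa, min_size = 10)
  # conservation: disjoint union equals the input
  ids <- sort(unlist(lapply(lp$problems, function(p) p$row_ids)))
  expect_identical(ids, sort(d$row_ids))
  expect_lt(nrow(lp$merge_log), 5)          # repair terminates, merges < k
  # non-pass-through problems are fit-able (both classes)
  for (i in seq_along(lp$problems)) {
    if (!lp$pass_through[i]) {
      expect_true(any(lp$problems[[i]]$labels == 1) &&
                    any(lp$problems[[i]]$labels == -1))
    } else {
      expect_true(all(lp$problems[[i]]$labels == -1))
    }
  }
})

test_that("k = 1 gives a single local problem identical to the input", {
  d <- make_blobs(n_per = 15, sep = 5, seed = 4)
  pa <- kmeans_partition(d$features, 1, seed = 1)
  lp <- make_local_problems(d, pa, min_size = 10)
  expect_length(lp$problems, 1)
  expect_identical(sort(lp$problems[[1]]$row_ids), sort(d$row_ids))
})

test_that("a minority-only partition is merged and logged", {
  # tight minority clump far from two majority groups
  d <- withr::with_seed(5, {
    X <- rbind(matrix(rnorm(120, 0, 0.5), 60, 2),
               matrix(rnorm(120, 8, 0.5), 60, 2),
               matrix(rnorm(24, c(4, 0), 0.1), 12, 2))
    labeled_dataset(X, c(rep(-1, 120), rep(1, 12)))
  })
  pa <- kmeans_partition(scale(d$features), 3, seed = 2)
  lp <- make_local_problems(d, pa, min_size = 5)
  # all minority ends up inside a mixed problem
  mixed <- vapply(lp$problems, function(p) any(p$labels == 1) &&
                    any(p$labels == -1), NA)
  minority_in_mixed <- sum(vapply(lp$problems[mixed],
                                  function(p) sum(p$labels == 1), 0))
  expect_equal(minority_in_mixed, 12)
  expect_error(make_local_problems(d, NULL), class = "glocalsvm_input_error")
})

test_that("a fully single-class training set is unfittable", {
  d <- labeled_dataset(matrix(rnorm(60), 30, 2), rep(-1, 30))
  pa <- kmeans_partition(d$features, 2, seed = 1)
  expect_error(make_local_problems(d, pa), class = "glocalsvm_unfittable_error")
})
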
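test_that("support values rank by |alpha| with row-id tie-break", {
  d <- labeled_dataset(rbind(c(0, 0), c(1, 0)), c(1, -1))
  m <- fit_lssvm(d, linear_kernel(), gamma = 1, standardize = FALSE)
  sv <- support_values(m)
  expect_equal(nrow(sv), 2)
  expect_equal(sv$row_id, c(1, 2))          # equal |alpha|: ascending row id
  expect_equal(sv$support_value, abs(m$alphas), tolerance = 1e-10)
  expect_true(all(diff(sv$support_value) <= 0))
})

test_that("removal targets the smallest support value (dense-solve oracle)", {
  # two-point example plus a third point close to x1
  X <- rbind(c(0, 0), c(1, 0), c(0, 0.01))
  y <- c(1, -1, 1)
  m <- fit_lssvm(labeled_dataset(X, y), linear_kernel(), gamma = 1,
                 standardize = FALSE)
  or <- oracle_lssvm(X, y, "linear", gamma = 1, standardize = FALSE)
  expect_equal(m$alphas, or$alphas, tolerance = 1e-8)
  drop <- glocalsvm:::pick_removals(m, y, 1)
  expect_equal(drop, which.min(abs(or$alphas)))
})

test_that("pruning passes through small inputs and disabled configurations", {
  d <- make_blobs(n_per = 8, sep = 8, seed = 2)   # 16 points < minimum
  s <- prune_lssvm(d, rbf_kernel(1), 1, prune_config())
  expect_identical(s$retained_row_ids, d$row_ids)
  m <- fit_lssvm(d, rbf_kernel(1), 1)
  expect_identical(s$model$alphas, m$alphas)

  # min_retained_fraction = 1 disables pruning on any size
  d2 <- make_blobs(n_per = 30, sep = 8, seed = 3)
  s2 <- prune_lssvm(d2, rbf_kernel(1), 1,
                    prune_config(min_retained_fraction = 1))
  expect_identical(s2$retained_row_ids, d2$row_ids)
  expect_identical(s2$model$alphas, fit_lssvm(d2, rbf_kernel(1), 1)$alphas)
})

test_that("prune trajectory obeys the declared invariants", {
  d <- make_blobs(n_per = 50, sep = 6, seed = 5)
  cfg <- prune_config(seed = 9)
  s <- prune_lssvm(d, rbf_kernel(1), 10, cfg)
  traj <- s$trajectory
  # strictly decreasing retained counts
  expect_true(all(diff(traj$retained) < 0))
  # step size is the ceiling of step_fraction * current (until clamped)
  expect_equal(traj$retained[2],
               traj$retained[1] - ceiling(cfg$step_fraction * traj$retained[1]))
  # final retained fraction within [floor, 1]
  frac <- length(s$retained_row_ids) / n_obs(d)
  expect_gte(frac, cfg$min_retained_fraction)
  expect_lte(frac, 1)
  # returned metric within stop_tolerance of the best seen
  ret_metric <- traj$metric[traj$retained == length(s$retained_row_ids)]
  expect_gte(ret_metric, max(traj$metric) - cfg$stop_tolerance)
  # retained ids are a subset of the input
  expect_true(all(s$retained_row_ids %in% d$row_ids))
  # seed determinism
  s2 <- prune_lssvm(d, rbf_kernel(1), 10, cfg)
  expect_identical(s$retained_row_ids, s2$retained_row_ids)
})

test_that("pruning never eliminates a class", {
  withr::with_seed(11, {
    X <- rbind(matrix(rnorm(76, 0, 1), 38, 2),
               matrix(rnorm(4, 4, 0.2), 2, 2))
    d <- labeled_dataset(X, c(rep(-1, 38), rep(1, 2)))
  })
  s <- prune_lssvm(d, rbf_kernel(1), 1,
                   prune_config(min_retained_fraction = 0.05, seed = 4))
  retained <- subset_by_row_id(d, s$retained_row_ids)
  expect_true(any(retained$labels == 1) && any(retained$labels == -1))
})
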
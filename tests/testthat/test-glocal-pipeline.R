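imbalanced_toy <- function(seed, n = 300) {
  withr::with_seed(seed, {
    n_min <- round(0.15 * n)
    X <- rbind(matrix(rnorm(2 * (n - n_min), 0, 2), n - n_min, 2),
               matrix(rnorm(2 * n_min, 3, 0.4), n_min, 2))
    labeled_dataset(X, c(rep(-1, n - n_min), rep(1, n_min)))
  })
}

test_that("k = 1 with pruning disabled reproduces the plain LS-SVM", {
  for (seed in 1:3) {
    d <- imbalanced_toy(seed)
    cfg <- glocal_config(1, kernel = rbf_kernel(1), gamma = 5,
                         prune = NULL, seed = seed)
    g <- fit_glocal(d, cfg)
    plain <- fit_lssvm(d, rbf_kernel(1), 5)
    q <- d$features[1:40, ]
    expect_equal(decision_value(g$global_model, q),
                 decision_value(plain, q), tolerance = 1e-8)
    expect_equal(predict_glocal(g, q), predict(plain, q))
    # pruning disabled everywhere: pool is the full training set
    expect_setequal(g$merged_pool$row_ids, d$row_ids)
  }
})

test_that("pool conservation, provenance and size bounds hold", {
  d <- imbalanced_toy(7, n = 400)
  g <- fit_glocal(d, glocal_config(6, kernel = rbf_kernel(1), gamma = 5,
                                   seed = 1, min_partition_size = 15))
  expect_equal(sum(g$local_summaries$size), n_obs(d))   # conservation
  expect_lte(g$timing$n_pool_points, n_obs(d))
  expect_false(anyDuplicated(g$merged_pool$row_ids) > 0)
  expect_true(all(g$merged_pool$row_ids %in% d$row_ids))
  expect_length(g$merged_pool$provenance, n_obs(g$merged_pool))
  expect_true(all(g$merged_pool$provenance %in%
                    seq_along(g$local_models)))
  # timing report is internally consistent
  t <- g$timing
  expect_gte(t$total_seconds + 1e-9, t$accumulated_local_seconds)
  expect_equal(t$average_local_seconds,
               t$accumulated_local_seconds / length(g$local_models))
  expect_equal(t$n_pool_points, n_obs(g$merged_pool))
})

test_that("extract_support_vectors concatenates disjoint retained sets", {
  d <- imbalanced_toy(2, n = 100)
  fake <- function(ids) structure(list(model = NULL, retained_row_ids = ids,
                                       trajectory = NULL),
                                  class = "sparse_lssvm")
  pool <- extract_support_vectors(list(fake(c(1, 2, 96)),
                                       fake(c(11, 12, 13, 97, 98))), d)
  expect_equal(n_obs(pool), 8)
  expect_equal(pool$provenance, rep(1:2, c(3, 5)))
  expect_error(extract_support_vectors(list(fake(1:3), fake(3:5)), d),
               class = "glocalsvm_input_error")
})

test_that("glocal prediction delegates to the global model", {
  d <- imbalanced_toy(3)
  g <- fit_glocal(d, glocal_config(4, kernel = rbf_kernel(1), gamma = 5,
                                   seed = 2))
  q <- d$features[1:25, ]
  expect_equal(predict_glocal(g, q), predict(g$global_model, q))
  expect_equal(predict(g, q), predict_glocal(g, q))
  expect_length(predict_glocal(g, matrix(numeric(0), 0, 2)), 0)
})

test_that("the full pipeline is seed deterministic", {
  d <- imbalanced_toy(5)
  cfg <- glocal_config(5, kernel = rbf_kernel(1), gamma = 5, seed = 11)
  g1 <- fit_glocal(d, cfg)
  g2 <- fit_glocal(d, cfg)
  expect_identical(g1$merged_pool$row_ids, g2$merged_pool$row_ids)
  expect_identical(g1$global_model$alphas, g2$global_model$alphas)
})

test_that("stage errors name the failing input", {
  d <- labeled_dataset(matrix(rnorm(60), 30, 2), rep(-1, 30))
  expect_error(fit_glocal(d, glocal_config(2, seed = 1)),
               class = "glocalsvm_unfittable_error")
})
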
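two_point_problem <- function() {
  labeled_dataset(rbind(c(0, 0), c(1, 0)), c(1, -1))
}

test_that("two-point linear problem is solved exactly", {
  m <- fit_lssvm(two_point_problem(), linear_kernel(), gamma = 1,
                 standardize = FALSE)
  expect_equal(m$alphas, c(2 / 3, 2 / 3), tolerance = 1e-10)
  expect_equal(m$bias, 1 / 3, tolerance = 1e-10)
  dv <- decision_value(m, rbind(c(0, 0), c(1, 0)))
  expect_equal(dv, c(1 / 3, -1 / 3), tolerance = 1e-10)
  # support values are gamma * residual
  e <- 1 - m$support_labels * dv
  expect_equal(m$alphas, m$gamma * e, tolerance = 1e-10)
  # training points perfectly recovered
  expect_equal(predict(m, rbind(c(0, 0), c(1, 0))), c(1, -1))
})

test_that("solver agrees with the dense bordered-system oracle", {
  for (seed in 1:10) {
    p <- random_problem(seed)
    m <- fit_lssvm(p$data, rbf_kernel(p$sigma2), p$gamma)
    or <- oracle_lssvm(p$data$features, p$data$labels, "rbf",
                       p$sigma2, p$gamma)
    expect_equal(m$alphas, or$alphas, tolerance = 1e-8)
    expect_equal(m$bias, or$bias, tolerance = 1e-8)
    # KKT equality and proportionality conditions
    expect_lt(abs(sum(m$alphas * m$support_labels)), 1e-6 * n_obs(p$data))
    dv <- decision_value(m, p$data$features)
    e <- 1 - p$data$labels * dv
    expect_equal(m$alphas, m$gamma * e,
                 tolerance = 1e-6 * max(1, max(abs(m$alphas))))
    # decision values match the literal dual-sum oracle
    q <- matrix(rnorm(10 * ncol(p$data$features)), 10)
    expect_equal(decision_value(m, q),
                 oracle_decision(or, p$data$labels, q, "rbf", p$sigma2),
                 tolerance = 1e-8)
  }
})

test_that("duplicating every point and halving gamma leaves decisions unchanged", {
  d <- two_point_problem()
  m1 <- fit_lssvm(d, linear_kernel(), gamma = 1, standardize = FALSE)
  d2 <- labeled_dataset(rbind(d$features, d$features),
                        c(d$labels, d$labels))
  m2 <- fit_lssvm(d2, linear_kernel(), gamma = 0.5, standardize = FALSE)
  q <- d$features
  expect_equal(decision_value(m1, q), decision_value(m2, q),
               tolerance = 1e-6)
})

test_that("well-separated blobs are classified perfectly at high gamma", {
  d <- make_blobs(n_per = 25, sep = 12, seed = 3)
  m <- fit_lssvm(d, rbf_kernel(1), gamma = 1e6)
  expect_equal(predict(m, d$features), d$labels)
})

test_that("fits are bitwise deterministic", {
  p <- random_problem(42)
  m1 <- fit_lssvm(p$data, rbf_kernel(p$sigma2), p$gamma)
  m2 <- fit_lssvm(p$data, rbf_kernel(p$sigma2), p$gamma)
  expect_identical(m1$alphas, m2$alphas)
  expect_identical(m1$bias, m2$bias)
})

test_that("prediction handles signs, exact zero and empty queries", {
  m <- fit_lssvm(two_point_problem(), linear_kernel(), gamma = 1,
                 standardize = FALSE)
  # midpoint decision value is exactly 0 -> mapped to +1
  expect_equal(decision_value(m, rbind(c(0.5, 0))), 0, tolerance = 1e-12)
  expect_equal(predict(m, rbind(c(0.5, 0))), 1)
  expect_identical(decision_value(m, matrix(numeric(0), 0, 2)), numeric(0))
  expect_length(predict(m, matrix(numeric(0), 0, 2)), 0)
})

test_that("unfittable and invalid inputs raise classed errors", {
  single <- labeled_dataset(matrix(rnorm(10), 5, 2), rep(1, 5))
  expect_error(fit_lssvm(single), class = "glocalsvm_unfittable_error")
  d <- two_point_problem()
  expect_error(fit_lssvm(d, gamma = -1), class = "glocalsvm_config_error")
  m <- fit_lssvm(d, linear_kernel(), standardize = FALSE)
  expect_error(decision_value(m, matrix(1, 1, 3)),
               class = "glocalsvm_input_error")
  expect_error(labeled_dataset(matrix(1, 2, 2), c(1, 2)),
               class = "glocalsvm_input_error")
  expect_error(labeled_dataset(matrix(c(1, NA, 1, 1), 2, 2), c(1, -1)),
               class = "glocalsvm_input_error")
})
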
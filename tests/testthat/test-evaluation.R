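test_that("shuffled splits conserve rows and are reproducible", {
  d <- make_blobs(n_per = 100, sep = 4, seed = 1)   # 200 rows
  plan <- shuffled_splits(d, rounds = 10, test_fraction = 0.1, seed = 3)
  for (sp in plan$splits) {
    expect_length(sp$test_row_ids, 20)
    expect_length(sp$train_row_ids, 180)
    expect_length(intersect(sp$train_row_ids, sp$test_row_ids), 0)
    expect_setequal(c(sp$train_row_ids, sp$test_row_ids), d$row_ids)
  }
  # ten distinct plans under one master seed
  tests <- vapply(plan$splits, function(s) paste(sort(s$test_row_ids),
                                                 collapse = ","), "")
  expect_equal(length(unique(tests)), 10)
  plan2 <- shuffled_splits(d, rounds = 10, test_fraction = 0.1, seed = 3)
  expect_identical(plan, plan2)
  expect_error(shuffled_splits(d, test_fraction = 1.2),
               class = "glocalsvm_config_error")
})

test_that("confusion metrics match hand arithmetic and zero-denominator rules", {
  y <- c(rep(1, 4), rep(-1, 6))
  p <- c(1, 1, 1, -1, -1, -1, -1, -1, -1, 1)   # tp 3 fn 1 tn 5 fp 1
  m <- confusion_metrics(y, p)
  expect_equal(m$sensitivity, 75)
  expect_equal(m$selectivity, 100 * 5 / 6, tolerance = 1e-10)
  expect_equal(m$precision, 75)

  perfect <- confusion_metrics(y, y)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$selectivity, 100)

  allneg <- confusion_metrics(y, rep(-1, 10))
  expect_equal(allneg$sensitivity, 0)
  expect_true(is.na(allneg$precision))
  expect_error(confusion_metrics(numeric(0), numeric(0)),
               class = "glocalsvm_input_error")
})

test_that("minority-positive convention flips with positive_label", {
  y <- c(1, 1, -1, -1, -1)
  p <- c(1, -1, -1, -1, 1)
  m_pos <- confusion_metrics(y, p, positive_label = 1)
  m_neg <- confusion_metrics(y, p, positive_label = -1)
  expect_equal(m_pos$sensitivity, m_neg$selectivity)
  expect_equal(m_pos$selectivity, m_neg$sensitivity)
})

test_that("Welch comparison matches the closed form and handles edge cases", {
  a <- 1:5; b <- 2:6
  out <- compare_models_ttest(a, b)
  # closed form: t = (3-4)/sqrt(2.5/5 + 2.5/5) = -1, Welch df = 8
  expect_equal(out$t, -1, tolerance = 1e-10)
  expect_equal(out$df, 8, tolerance = 1e-10)
  expect_equal(out$p_value, 2 * stats::pt(-1, 8), tolerance = 1e-10)
  expect_false(out$significant)

  same <- compare_models_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # threshold behaviour around alpha
  expect_true(compare_models_ttest(rep(c(0, 1e-9), 10),
                                   rep(c(5, 5 + 1e-9), 10))$significant)
  # paired mode on vectors with non-constant differences
  pa <- c(1, 3, 2, 5, 4); pb <- c(2, 2, 4, 4, 3)
  paired <- compare_models_ttest(pa, pb, paired = TRUE)
  expect_equal(paired$t,
               unname(stats::t.test(pa, pb, paired = TRUE)$statistic),
               tolerance = 1e-10)
  # constant differences degenerate cleanly instead of erroring
  degen <- compare_models_ttest(a, b, paired = TRUE)
  expect_equal(degen$t, -Inf)
  expect_equal(degen$p_value, 0)
})

test_that("run_benchmark emits the timing-table columns and summary", {
  d <- make_blobs(n_per = 60, sep = 3, seed = 2, sd = 1.2)
  plan <- shuffled_splits(d, rounds = 2, test_fraction = 0.2, seed = 1)
  out <- run_benchmark(d, "lssvm", plan = plan, kernel = rbf_kernel(1),
                       gamma = 5)
  expect_equal(nrow(out$metrics), 2)
  expect_true(all(c("Accumulated Local Models Time",
                    "Average Local Model Time", "General Model Time",
                    "Total Time", "# Data points to Train General Model")
                  %in% names(out$timing)))
  expect_equal(out$timing$`# Data points to Train General Model`,
               rep(96, 2))
  glc <- glocal_config(3, kernel = rbf_kernel(1), gamma = 5, seed = 1,
                       min_partition_size = 10)
  out2 <- run_benchmark(d, "glocal", plan = plan, config = glc)
  expect_true(all(out2$timing$`# Data points to Train General Model` <= 96))
  expect_true(all(c("sensitivity", "selectivity") %in% out2$summary$metric))
})
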
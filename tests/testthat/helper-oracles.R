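# Independent brute-force oracles: everything here is computed with plain
# loops and base solve(), never through the package's solver path.

# literal kernel evaluation, element by element
oracle_kernel <- function(A, B, family = "rbf", sigma2 = 1) {
  K <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      K[i, j] <- switch(family,
        rbf = exp(-sum((A[i, ] - B[j, ])^2) / sigma2),
        linear = sum(A[i, ] * B[j, ]))
    }
  }
  K
}

# dense solve of the bordered KKT system [[0, y'], [y, Omega + I/gamma]]
oracle_lssvm <- function(X, y, family = "rbf", sigma2 = 1, gamma = 1,
                         standardize = TRUE) {
  if (standardize) {
    mu <- colMeans(X)
    s <- apply(X, 2, stats::sd); s[!is.finite(s) | s == 0] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  } else {
    mu <- rep(0, ncol(X)); s <- rep(1, ncol(X))
  }
  n <- length(y)
  K <- oracle_kernel(X, X, family, sigma2)
  A <- rbind(c(0, y), cbind(y, outer(y, y) * K + diag(n) / gamma))
  sol <- unname(solve(A, c(0, rep(1, n))))
  list(bias = sol[1], alphas = sol[-1], Xs = X, center = mu, scale = s)
}

# term-by-term evaluation of the dual decision sum
oracle_decision <- function(or, y, Q, family = "rbf", sigma2 = 1) {
  Qs <- sweep(sweep(Q, 2, or$center, "-"), 2, or$scale, "/")
  out <- numeric(nrow(Qs))
  for (q in seq_len(nrow(Qs))) {
    acc <- 0
    for (i in seq_along(y)) {
      k <- switch(family,
        rbf = exp(-sum((or$Xs[i, ] - Qs[q, ])^2) / sigma2),
        linear = sum(or$Xs[i, ] * Qs[q, ]))
      acc <- acc + or$alphas[i] * y[i] * k
    }
    out[q] <- acc + or$bias
  }
  out
}

# two well-separated gaussian blobs, one per class
make_blobs <- function(n_per = 20, sep = 10, d = 2, seed = 1, sd = 0.5) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per, d),
               matrix(rnorm(n_per * d, sep, sd), n_per, d))
    labeled_dataset(X, rep(c(1, -1), each = n_per))
  })
}

# random small labelled problem with both classes guaranteed
random_problem <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(5:50, 1)
    d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    list(data = labeled_dataset(X, y),
         sigma2 = 10^runif(1, -1, 1),
         gamma = 10^runif(1, -1, 2))
  })
}

# shared heavy benchmark fixtures for the acceptance suite (computed once)
.acc_cache <- new.env(parent = emptyenv())

acceptance_fixed_hp <- function() {
  if (is.null(.acc_cache$hp)) {
    big <- generate_synthetic(synth_config(seed = 0))
    sp <- shuffled_splits(big, rounds = 1, seed = 0)
    tr <- subset_by_row_id(big, sp$splits[[1]]$train_row_ids)
    sub <- subset_dataset(tr, withr::with_seed(100, sample(n_obs(tr), 1500)))
    .acc_cache$hp <- tune_hyperparams(sub, tuning_grid(one_se = TRUE,
                                                       seed = 0))
  }
  .acc_cache$hp
}

acceptance_glocal_fixed <- function(seed) {
  key <- paste0("gl", seed)
  if (is.null(.acc_cache[[key]])) {
    hp <- acceptance_fixed_hp()
    big <- generate_synthetic(synth_config(seed = seed))
    sp <- shuffled_splits(big, rounds = 1, seed = seed)
    tr <- subset_by_row_id(big, sp$splits[[1]]$train_row_ids)
    .acc_cache[[key]] <- fit_glocal(
      tr, glocal_config(90, kernel = hp$kernel, gamma = hp$gamma, seed = seed))
  }
  .acc_cache[[key]]
}
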
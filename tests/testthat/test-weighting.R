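test_that("F-test weights match direct summation and flag significance", {
  # two integer response groups with equal feature means give F = 0
  y <- rep(c(100, 120), each = 5)
  X <- cbind(f1 = rep(c(1, 2, 3, 4, 5), 2), f2 = c(1:5, 11:15))
  wv <- ftest_weights(X, y)
  expect_equal(wv$meta$F[1], 0)
  expect_equal(wv$meta$p[1], 1)

  # hand case {1,2,3} vs {7,8,9} against the brute-force oracle
  x <- c(1, 2, 3, 7, 8, 9)
  g <- rep(c(100, 130), each = 3)
  wv2 <- ftest_weights(matrix(x), g)
  expect_equal(wv2$meta$F[1], oracle_fscore(x, g), tolerance = 1e-12)
  expect_true(wv2$meta$p[1] < 0.05)
  expect_true(wv2$meta$significant[1])

  # weights are -log10(p), ranking is a permutation by descending weight
  tab <- make_table()
  wv3 <- ftest_weights(tab$X, tab$y, binning = "quantile", n_bins = 6)
  expect_equal(wv3$weights, -log10(pmax(wv3$meta$p, 1e-300)))
  expect_setequal(wv3$ranking, seq_len(ncol(tab$X)))
  expect_error(ftest_weights(matrix(rnorm(4)), rep(1, 4)),
               class = "invalid_input")
})

test_that("mutual information matches brute force and its identities", {
  # exact product table: independent
  a <- rep(1:2, each = 20)
  b <- rep(rep(1:2, each = 10), 2)
  expect_equal(mutual_information(a, b), 0, tolerance = 1e-12)

  # identical discrete column: MI equals entropy
  z <- rep(c(1, 2, 3), times = c(10, 20, 30))
  p <- c(10, 20, 30) / 60
  expect_equal(mutual_information(z, z), -sum(p * log(p)), tolerance = 1e-12)

  # 2x2 table {{30,10},{10,30}}
  a2 <- rep(c(0, 0, 1, 1), times = c(30, 10, 10, 30))
  b2 <- rep(c(0, 1, 0, 1), times = c(30, 10, 10, 30))
  expect_equal(mutual_information(a2, b2), oracle_mi(a2, b2),
               tolerance = 1e-12)
  expect_equal(mutual_information(a2, b2), mutual_information(b2, a2))
  expect_error(mutual_information(1:3, 1:4), class = "invalid_input")
  expect_error(mutual_information(1, 1), class = "invalid_input")
})

test_that("MRMR picks relevance first and follows the greedy MIQ trace", {
  wv <- mrmr_rank(matrix(rnorm(50)), rnorm(50))
  expect_equal(wv$ranking, 1L)

  # discrete toy: feature 2 copies feature 1; trace matches the oracle
  set.seed(42)
  n <- 120
  f1 <- sample(1:3, n, replace = TRUE)
  f3 <- sample(1:3, n, replace = TRUE)
  f4 <- sample(1:2, n, replace = TRUE)
  y <- f1 + f3 + sample(0:1, n, replace = TRUE)
  X <- cbind(f1, f2 = f1, f3, f4)
  # all columns and y are discrete with <= 10 levels, so binning is a no-op
  # and the implementation sees exactly the labels the oracle sees
  wv2 <- mrmr_rank(X, y, bins = 10)
  rel <- vapply(1:4, function(j) oracle_mi(X[, j], y), numeric(1))
  expect_equal(wv2$ranking[1], which.max(rel))
  oracle <- oracle_mrmr_trace(X, y)
  expect_equal(wv2$ranking[seq_along(oracle)], oracle)
  expect_setequal(wv2$ranking, 1:4)
})

test_that("MRMR appends zero-relevance leftovers reproducibly under seed", {
  set.seed(3)
  n <- 200
  y <- rep(1:4, each = n / 4)
  # constant columns have exactly zero estimated relevance, so they exercise
  # the random-order append under the run seed
  X <- cbind(y, noise = sample(rep(1:4, n / 4)),
             const1 = rep(1, n), const2 = rep(2, n), const3 = rep(3, n))
  r1 <- mrmr_rank(X, y, bins = 4, seed = 11)
  r2 <- mrmr_rank(X, y, bins = 4, seed = 11)
  expect_identical(r1$ranking, r2$ranking)
  expect_equal(r1$ranking[1], 1)
  expect_setequal(r1$ranking, 1:5)
  expect_setequal(r1$meta$step_kind[r1$ranking %in% 3:5], "zero_relevance")
})

test_that("NCA probabilities normalize and objective matches the oracle", {
  # n = 2: each point has a single candidate reference, gamma = 1
  ob2 <- nca_objective(matrix(c(0, 1)), c(0, 1), w = 1, want_gamma = TRUE)
  expect_equal(ob2$gamma[1, 2], 1)
  expect_equal(ob2$gamma[2, 1], 1)

  set.seed(8)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  w <- runif(4, 0.5, 2)
  ob <- nca_objective(X, y, w, sigma = 1, lambda = 0.02, want_gamma = TRUE)
  expect_equal(unname(rowSums(ob$gamma)), rep(1, 10), tolerance = 1e-12)
  expect_equal(ob$value, oracle_nca_objective(X, y, w, 1, 0.02),
               tolerance = 1e-10)

  # hand-sized instance: x = y = (0, 1, 2), w = 1, sigma = 1, MAD loss
  ob3 <- nca_objective(matrix(c(0, 1, 2)), c(0, 1, 2), w = 1)
  g12 <- exp(-1) / (exp(-1) + exp(-2))
  L1 <- g12 * 1 + (1 - g12) * 2
  expect_equal(ob3$value, (L1 + 1 + L1) / 3, tolerance = 1e-12)

  # robust loss variant against the oracle
  obr <- nca_objective(X, y, w, lambda = 0.01, loss = "robust")
  expect_equal(obr$value,
               oracle_nca_objective(X, y, w, 1, 0.01, loss = "robust"),
               tolerance = 1e-10)
})

test_that("NCA analytic gradient matches central finite differences", {
  set.seed(12)
  for (rep in 1:3) {
    X <- matrix(rnorm(60), 15, 4)
    y <- rnorm(15)
    w0 <- runif(4, 0.4, 1.6)
    for (loss in c("mad", "robust")) {
      g <- nca_objective(X, y, w0, lambda = 0.05, loss = loss)$gradient
      eps <- 1e-6
      fd <- vapply(1:4, function(m) {
        wp <- w0; wp[m] <- wp[m] + eps
        wm <- w0; wm[m] <- wm[m] - eps
        (nca_objective(X, y, wp, lambda = 0.05, loss = loss)$value -
         nca_objective(X, y, wm, lambda = 0.05, loss = loss)$value) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(fd - g)) / max(abs(fd)), 1e-5)
    }
  }
})

test_that("NCA fitting separates support from noise and respects lambda", {
  expect_equal(eval(formals(nca_fit)$lambda), 0.015)

  tab <- make_table(n = 300, p = 8, support = c(1, 2),
                    effects = c(2, 1.5), noise = 0.3, seed = 5)
  st <- nca_fit(tab$X, tab$y)
  expect_true(all(st$trace == cummin(st$trace)))  # non-increasing iterates
  expect_gt(min(st$w[1:2]), max(st$w[3:8]))

  # overwhelming regularization drives all weights to (near) zero
  st_big <- nca_fit(tab$X[1:80, ], tab$y[1:80], lambda = 1e4)
  expect_lt(max(st_big$w), 1e-3)

  expect_error(nca_fit(matrix(c(1, NA), 2, 1), c(1, 2)),
               class = "invalid_input")
})

test_that("RNCA protocol: robust loss, lambda tuning, threshold rule", {
  expect_equal(robust_loss(3.7, 3.7), 0)
  expect_equal(robust_loss(0, 10), 1 - exp(-10))
  expect_equal(robust_loss(0, 10), 0.9999546, tolerance = 1e-7)

  expect_equal(select_by_threshold(c(4.1, 3.0, 0.2), 3), c(1L, 2L))

  tab <- make_table(n = 80, p = 5, support = 1, effects = 3, noise = 0.3,
                    seed = 6)
  wv <- rnca_tune(tab$X, tab$y, lambda_grid = seq(0, 0.05, length.out = 4),
                  k = 4, seed = 2, max_iter = 60)
  expect_equal(wv$meta$lambda_b,
               wv$meta$lambda_grid[which.min(wv$meta$cv_loss)])
  expect_setequal(wv$ranking, 1:5)
  expect_equal(wv$ranking[1], 1)
  expect_error(rnca_tune(tab$X, tab$y, lambda_grid = numeric(0)),
               class = "invalid_input")
})
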
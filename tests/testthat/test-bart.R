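test_that("latent draws respect their truncation supports", {
  set.seed(51)
  z1 <- sample_latent(rep(1, 10000), rep(0, 10000))
  expect_true(all(z1 > 0))
  # closed-form truncated-normal mean phi(0)/Phi(0)
  expect_equal(mean(z1), dnorm(0) / pnorm(0), tolerance = 0.03)
  z0 <- sample_latent(rep(0, 10000), rep(0, 10000))
  expect_true(all(z0 <= 0))
  # far-tail cases go through the exponential rejection branch
  zt <- sample_latent(rep(0, 2000), rep(6, 2000))
  expect_true(all(zt <= 0))
})

test_that("tree traversal follows the x < split convention", {
  leaf_only <- tibble::tibble(node = 0, var = 0, split = 0, left = -1,
                              right = -1, mu = 0.3)
  expect_equal(tree_traverse(leaf_only, c(99, -99)), 0.3)

  stump <- tibble::tibble(
    node = c(0, 1, 2), var = c(1, 0, 0), split = c(5, 0, 0),
    left = c(1, -1, -1), right = c(2, -1, -1), mu = c(0, -1, 1)
  )
  expect_equal(tree_traverse(stump, 4.9), -1)
  expect_equal(tree_traverse(stump, 5), 1)

  depth2 <- tibble::tibble(
    node = 0:6, var = c(1, 2, 2, 0, 0, 0, 0),
    split = c(0, -1, 1, 0, 0, 0, 0),
    left = c(1, 3, 5, -1, -1, -1, -1),
    right = c(2, 4, 6, -1, -1, -1, -1),
    mu = c(0, 0, 0, 10, 20, 30, 40)
  )
  oracle_rules <- function(x) {
    if (x[1] < 0) if (x[2] < -1) 10 else 20 else if (x[2] < 1) 30 else 40
  }
  set.seed(52)
  for (i in 1:100) {
    x <- rnorm(2, sd = 2)
    expect_equal(tree_traverse(depth2, x), oracle_rules(x))
  }
  expect_error(tree_traverse(stump, NA_real_), "missing value")
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(53)
  n <- 200
  x <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, 0.4)
  cfg <- bart_config(num_trees = 20, burn_in = 50, num_draws = 50)
  set.seed(99)
  f1 <- fit_probit_bart(x, y, cfg, X_test = x)
  set.seed(99)
  f2 <- fit_probit_bart(x, y, cfg, X_test = x)
  expect_identical(f1$test_draws, f2$test_draws)
  expect_identical(f1$trees, f2$trees)
})

test_that("structural moves disabled reduce to the conjugate intercept-only
           probit", {
  set.seed(54)
  n <- 2000
  y <- rbinom(n, 1, 0.23)
  x <- matrix(rnorm(n), n, 1)
  cfg <- bart_config(num_trees = 50, burn_in = 200, num_draws = 300,
                     p_grow = 0, p_prune = 0.5, p_change = 0.5)
  fit <- fit_probit_bart(x, y, cfg, X_test = matrix(0, 1, 1),
                         keep_trees = TRUE)
  # all trees stay single leaves
  trees <- bart_trees(fit)
  expect_true(all(trees$var == 0))
  pred <- mean(pnorm(fit$test_draws))
  expect_equal(pred, mean(y), tolerance = 0.02)
  # independent conjugate-augmentation oracle with the same prior variance
  v0 <- 50 * (3 / (2 * sqrt(50)))^2
  oracle <- oracle_intercept_probit(y, v0)
  expect_equal(pred, oracle, tolerance = 0.02)
})

test_that("the depth prior keeps trees small on pure noise", {
  set.seed(55)
  n <- 1000
  x <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_probit_bart(x, y,
                         bart_config(num_trees = 50, burn_in = 200,
                                     num_draws = 300),
                         keep_trees = FALSE)
  expect_lt(mean(fit$avg_leaves), 4)
})

test_that("null calibration: mean predicted probability tracks prevalence", {
  cfg <- bart_config(num_trees = 50, burn_in = 150, num_draws = 150)
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 2000
    x <- matrix(rnorm(n * 4), n, 4)
    y <- rbinom(n, 1, 0.5)
    fit <- fit_probit_bart(x, y, cfg, X_test = x, keep_trees = FALSE)
    dev <- abs(mean(pnorm(fit$test_draws)) - mean(y))
    hits <- hits + (dev < 0.05)
  }
  expect_gte(hits, 18)
})

test_that("posterior-mean probabilities recover a known threshold DGP", {
  set.seed(56)
  n <- 2000
  x <- matrix(rnorm(n * 3), n, 3)
  p <- pnorm(1 * (x[, 1] > 0) - 0.5)
  y <- as.integer(runif(n) < p)
  fit <- fit_probit_bart(x, y,
                         bart_config(num_trees = 50, burn_in = 300,
                                     num_draws = 500),
                         X_test = x, keep_trees = FALSE)
  ph <- colMeans(pnorm(fit$test_draws))
  expect_lt(sqrt(mean((ph - p)^2)), 0.08)
})

test_that("row order barely perturbs posterior-mean predictions", {
  set.seed(5)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3)
  p <- pnorm(0.8 * x[, 1] - 0.3)
  y <- as.integer(runif(n) < p)
  cfg <- bart_config(num_trees = 30, burn_in = 500, num_draws = 6000)
  set.seed(7)
  f1 <- fit_probit_bart(x, y, cfg, X_test = x, keep_trees = FALSE)
  perm <- sample(n)
  set.seed(107)
  f2 <- fit_probit_bart(x[perm, ], y[perm], cfg, X_test = x,
                        keep_trees = FALSE)
  p1 <- colMeans(pnorm(f1$test_draws))
  p2 <- colMeans(pnorm(f2$test_draws))
  expect_lt(sqrt(mean((p1 - p2)^2)), 0.01)
})

test_that("retained ensembles are structurally valid binary trees and
           reproduce the stored test draws", {
  set.seed(57)
  n <- 300
  x <- matrix(rnorm(n * 3), n, 3)
  colnames(x) <- c("a", "b", "c")
  y <- rbinom(n, 1, pnorm(x[, 1]))
  cfg <- bart_config(num_trees = 10, burn_in = 50, num_draws = 20)
  set.seed(58)
  fit <- fit_probit_bart(x, y, cfg, X_test = x[1:5, , drop = FALSE])
  trees <- bart_trees(fit)
  expect_equal(length(unique(trees$draw)), 20)
  internal <- trees[trees$var > 0, ]
  leaves <- trees[trees$var == 0, ]
  expect_true(all(internal$left >= 0 & internal$right >= 0))
  expect_true(all(internal$left != internal$right))
  expect_true(all(is.finite(leaves$mu)))
  expect_true(all(internal$var <= ncol(x)))
  # node-by-node R traversal reproduces the C++ predictions
  draws <- predict_probit_draws(fit, x[1:5, , drop = FALSE])
  expect_equal(draws, fit$test_draws, tolerance = 1e-12)
  one_draw <- trees[trees$draw == 7, ]
  manual <- sum(vapply(split(one_draw, one_draw$tree),
                       function(tr) tree_traverse(tr, x[3, ]), 0))
  expect_equal(manual, fit$test_draws[7, 3], tolerance = 1e-9)
  # duplicated prediction rows give identical columns
  dup <- predict_probit_draws(fit, x[c(1, 1), , drop = FALSE])
  expect_identical(dup[, 1], dup[, 2])
})

test_that("input validation rejects malformed training data", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(fit_probit_bart(x, rep(1, 19)), "mismatch")
  expect_error(fit_probit_bart(x, sample(0:2, 20, TRUE)), "binary")
  expect_error(fit_probit_bart(x[1:5, ], rep(0:1, 3)[1:5]), "at least")
  xna <- x; xna[1, 1] <- NA
  expect_error(fit_probit_bart(xna, rep(0:1, 10)), "missing")
})

test_that("one-hot encoding is deterministic and alignment-stable", {
  df <- tibble::tibble(
    num = c(1.5, 2.5), flag = c(TRUE, FALSE), cat = c("b", "a")
  )
  enc <- encode_covariates(df)
  expect_equal(colnames(enc$X), c("num", "flag", "cat=a", "cat=b"))
  expect_equal(enc$X[, "cat=a"], c(0, 1))
  # re-encoding new data with the training map keeps the schema
  new <- tibble::tibble(num = 9, flag = TRUE, cat = "a")
  enc2 <- encode_covariates(new, enc$levels_map)
  expect_identical(colnames(enc2$X), colnames(enc$X))
})
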
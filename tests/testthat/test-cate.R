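test_that("education years map onto the six treatment levels", {
  expect_equal(bin_education(c(0, 6, 8)), c(1L, 2L, 3L))
  expect_equal(bin_education(c(9, 12, 16)), c(4L, 5L, 6L))
  # exhaustive 0..20 against a hand-written lookup
  lookup <- c(1, rep(2, 6), 3, 3, 4, rep(5, 3), rep(6, 8))
  expect_equal(bin_education(0:20), as.integer(lookup))
  expect_error(bin_education(-1), "non-negative")
})

test_that("the 70/30 split reproduces the ceil-on-test arithmetic", {
  big <- tibble::tibble(i = seq_len(25917))
  sp <- split_train_test(big, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 18141)
  expect_equal(nrow(sp$test), 7776)
  expect_equal(sort(c(sp$train$i, sp$test$i)), big$i)

  small <- tibble::tibble(i = 1:10)
  sp <- split_train_test(small, 0.7, seed = 1)
  expect_equal(c(nrow(sp$train), nrow(sp$test)), c(7L, 3L))
  expect_error(split_train_test(small[1, ]), "at least 2")
})

test_that("split membership is seed-reproducible", {
  d <- tibble::tibble(i = 1:500)
  a <- split_train_test(d, 0.7, seed = 42)
  b <- split_train_test(d, 0.7, seed = 42)
  c <- split_train_test(d, 0.7, seed = 43)
  expect_identical(a$test_idx, b$test_idx)
  expect_false(identical(a$test_idx, c$test_idx))
})

test_that("counterfactual designs change only the treatment column", {
  kids <- tibble::tibble(
    child_id = c("a", "b", "c"), education_level = c(3L, 5L, 2L),
    iwi = c(10, 50, 90), urban = c(TRUE, FALSE, TRUE)
  )
  des <- build_counterfactual_design(kids, cf_level = 1)
  expect_equal(des$factual$education_level, c(3L, 5L, 2L))
  expect_equal(des$counterfactual$education_level, rep(1L, 3))
  expect_identical(des$factual[c("child_id", "iwi", "urban")],
                   des$counterfactual[c("child_id", "iwi", "urban")])
  expect_error(build_counterfactual_design(kids, 9), "1..6")

  # untreated analysis: observed level 1 kept factual, policy level as cf
  untreated <- tibble::tibble(child_id = "u", education_level = 1L)
  des <- build_counterfactual_design(untreated, cf_level = 4)
  expect_equal(des$counterfactual$education_level, 4L)
})

test_that("CATE from draws matches closed forms and the loop oracle", {
  z <- matrix(0, nrow = 5, ncol = 3)
  est <- estimate_cate_from_draws(z, z)
  expect_equal(est$ite$theta, rep(0, 3))
  expect_equal(est$cate, 0)

  treated <- matrix(0, 4, 2)
  control <- matrix(-0.5, 4, 2)
  est <- estimate_cate_from_draws(treated, control)
  expect_equal(est$ite$theta, rep(pnorm(0) - pnorm(-0.5), 2),
               tolerance = 1e-4)
  expect_equal(est$cate, 0.19146, tolerance = 1e-4)

  set.seed(41)
  f <- matrix(rnorm(200), 20, 10)
  g <- matrix(rnorm(200), 20, 10)
  for (orient in c(TRUE, FALSE)) {
    est <- estimate_cate_from_draws(f, g, treated_is_factual = orient)
    orc <- oracle_cate(f, g, orient)
    expect_equal(est$ite$theta, orc$theta, tolerance = 1e-12)
    expect_equal(est$cate, orc$cate, tolerance = 1e-12)
    expect_equal(est$cate, mean(est$ite$theta), tolerance = 1e-12)
    expect_true(all(abs(est$ite$theta) <= 1))
  }
  expect_error(estimate_cate_from_draws(f, g[, 1:3]), "shape")
})

test_that("a null contrast cancels exactly", {
  set.seed(42)
  draws <- matrix(rnorm(60), 6, 10)
  est <- estimate_cate_from_draws(draws, draws)
  expect_identical(est$ite$theta, rep(0, 10))
  expect_identical(est$cate, 0)
})

test_that("subgroup CATEs decompose as a weighted mean", {
  set.seed(43)
  f <- matrix(rnorm(300), 15, 20)
  g <- matrix(rnorm(300), 15, 20)
  est <- estimate_cate_from_draws(f, g)
  keep <- rep(c(TRUE, FALSE), 10)
  s1 <- subgroup_cate(est, keep, "a")
  s2 <- subgroup_cate(est, !keep, "b")
  n1 <- s1$n_children; n2 <- s2$n_children
  expect_equal((n1 * s1$cate + n2 * s2$cate) / (n1 + n2), est$cate,
               tolerance = 1e-12)
  expect_equal(subgroup_cate(est, rep(TRUE, 20))$cate, est$cate)
  expect_error(subgroup_cate(est, rep(FALSE, 20)), "empty")
})

test_that("single-iteration bootstrap degenerates to the plain CATE", {
  set.seed(44)
  n <- 80
  X <- cbind(edu = sample(1:6, n, TRUE), x = rnorm(n))
  y <- rbinom(n, 1, 0.3)
  Xf <- X[1:20, , drop = FALSE]
  Xc <- Xf; Xc[, "edu"] <- 1
  cfg <- bart_config(num_trees = 10, burn_in = 20, num_draws = 20)
  est <- bootstrap_cate(X, y, Xf, Xc, config = cfg, n_boot = 1, seed = 9)
  expect_equal(est$lower, est$cate)
  expect_equal(est$upper, est$cate)
  # and bounds always bracket the point estimate
  est5 <- bootstrap_cate(X, y, Xf, Xc, config = cfg, n_boot = 5, seed = 9)
  expect_lte(est5$lower, est5$cate)
  expect_gte(est5$upper, est5$cate)
  expect_equal(est5$cate, mean(est5$boots))
})
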
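#' Education-level treatment coding
#'
#' Bins maternal education in years into the six-level categorical
#' treatment: 1 = no education (0 years), 2 = up to and including primary
#' (1-6), 3 = lower secondary (7-<9), 4 = completed lower secondary
#' (9 years, the compulsory length), 5 = up to and including higher
#' secondary (10-12), 6 = college and higher (>12).
#'
#' @param years Integer years of education, >= 0 (vectorized).
#' @return Integer level 1..6.
#' @export
bin_education <- function(years) {
  if (any(years < 0, na.rm = TRUE)) {
    abort_nutricate("education years must be non-negative")
  }
  dplyr::case_when(
    is.na(years) ~ NA_integer_,
    years == 0 ~ 1L,
    years <= 6 ~ 2L,
    years <= 8 ~ 3L,
    years == 9 ~ 4L,
    years <= 12 ~ 5L,
    TRUE ~ 6L
  )
}

#' Random train/test split
#'
#' Splits rows into a training and a held-out test set. The test share is
#' rounded up: `n_test = ceiling((1 - fraction_train) * n)`, which for
#' n = 25,917 at 70/30 gives the 18,141 / 7,776 split. Reproducible for a
#' fixed seed.
#'
#' @param data Data frame (n >= 2 rows).
#' @param fraction_train Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test` (disjoint, exhaustive) and
#'   the integer `test_idx`.
#' @export
split_train_test <- function(data, fraction_train = 0.7, seed = 1L) {
  n <- nrow(data)
  if (n < 2) abort_nutricate("need at least 2 rows to split")
  stopifnot(fraction_train > 0, fraction_train < 1)
  # tiny epsilon guards against binary-fraction noise in (1 - fraction)
  n_test <- ceiling((1 - fraction_train) * n - 1e-9)
  test_idx <- withr::with_seed(seed, sort(sample.int(n, n_test)))
  list(train = tibble::as_tibble(data[-test_idx, ]),
       test = tibble::as_tibble(data[test_idx, ]),
       test_idx = test_idx)
}

#' Build a counterfactual design
#'
#' Stacks two otherwise identical covariate tables for the test children:
#' the factual rows keep each child's observed education level, the
#' counterfactual rows carry `cf_level`; all other columns are unchanged.
#'
#' @param test_children Tibble of test-set children (must contain
#'   `child_id` and `education_level`).
#' @param cf_level Counterfactual education level (1..6).
#' @return List with tibbles `factual` and `counterfactual` (row-aligned
#'   by `child_id`) and `child_id`.
#' @export
build_counterfactual_design <- function(test_children, cf_level) {
  if (!cf_level %in% 1:6) {
    abort_nutricate("counterfactual level must be in 1..6")
  }
  factual <- tibble::as_tibble(test_children)
  counterfactual <- factual
  counterfactual$education_level <- as.integer(cf_level)
  list(factual = factual, counterfactual = counterfactual,
       child_id = factual$child_id)
}

new_cate_estimate <- function(cate, lower, upper, ite, boots = NULL,
                              boot_theta = NULL, subgroup = NA_character_) {
  structure(list(cate = cate, lower = lower, upper = upper, ite = ite,
                 boots = boots, boot_theta = boot_theta,
                 n_children = nrow(ite), subgroup = subgroup),
            class = "cate_estimate")
}

#' @export
print.cate_estimate <- function(x, ...) {
  cat(sprintf("CATE %s= %.4f (95%% region %.4f, %.4f), n = %d\n",
              if (is.na(x$subgroup)) "" else paste0("[", x$subgroup, "] "),
              x$cate, x$lower, x$upper, x$n_children))
  invisible(x)
}

#' Individual and conditional average treatment effects from probit draws
#'
#' Applies the probit-to-probability pipeline: per child and arm, average
#' `pnorm()` over the posterior draws, then difference the two arms:
#' `theta_i = pbar_i(treated) - pbar_i(control)` so a negative value means
#' the treatment is protective. The CATE is the mean of the `theta_i`.
#'
#' @param factual_draws,cf_draws Probit-scale draw matrices
#'   (S x n, matching shapes) for the factual and counterfactual arm.
#' @param treated_is_factual `TRUE` when the factual arm is the treated
#'   one (per-level analyses of treated children); `FALSE` for the
#'   untreated analysis, where the counterfactual (policy) level is the
#'   treated arm.
#' @param child_id Optional ids for the n children.
#' @return A `cate_estimate` with a degenerate credible region (use
#'   [bootstrap_cate()] for intervals).
#' @export
estimate_cate_from_draws <- function(factual_draws, cf_draws,
                                     treated_is_factual = TRUE,
                                     child_id = NULL) {
  if (!all(dim(factual_draws) == dim(cf_draws))) {
    abort_nutricate("draw matrices must have matching shapes")
  }
  p_f <- colMeans(stats::pnorm(factual_draws))
  p_c <- colMeans(stats::pnorm(cf_draws))
  theta <- if (treated_is_factual) p_f - p_c else p_c - p_f
  ite <- tibble::tibble(
    child_id = child_id %||% as.character(seq_along(theta)),
    theta = theta
  )
  cate <- mean(theta)
  new_cate_estimate(cate, cate, cate, ite)
}

#' Bootstrap CATE with a percentile credible region
#'
#' Repeats `n_boot` times: resample the training set with replacement, fit
#' probit BART, predict probit draws for the factual and counterfactual
#' rows, and compute the CATE via [estimate_cate_from_draws()]. The point
#' estimate is the mean of the bootstrap CATEs, the 95% credible region
#' their (2.5%, 97.5%) percentiles; per-child effects are the bootstrap
#' means of the `theta_i`. The test design stays fixed across iterations.
#'
#' @param X_train,y_train Training design matrix and binary outcome.
#' @param X_factual,X_cf Row-aligned factual/counterfactual test matrices
#'   (same columns as `X_train`).
#' @param treated_is_factual See [estimate_cate_from_draws()].
#' @param config A [bart_config()].
#' @param n_boot Bootstrap iterations (>= 1).
#' @param seed Integer seed.
#' @param child_id Optional test-child ids.
#' @return A `cate_estimate` with `boots` (bootstrap CATE vector) and
#'   `boot_theta` (n_boot x n matrix of per-iteration individual effects).
#' @export
bootstrap_cate <- function(X_train, y_train, X_factual, X_cf,
                           treated_is_factual = TRUE,
                           config = bart_config(), n_boot = 1000L,
                           seed = 1L, child_id = NULL) {
  stopifnot(n_boot >= 1)
  n_test <- nrow(X_factual)
  X_pred <- rbind(as.matrix(X_factual), as.matrix(X_cf))
  boot_theta <- matrix(NA_real_, n_boot, n_test)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(X_train), replace = TRUE)
      fit <- fit_probit_bart(X_train[idx, , drop = FALSE], y_train[idx],
                             config, X_test = X_pred, keep_trees = FALSE)
      fd <- fit$test_draws[, seq_len(n_test), drop = FALSE]
      cd <- fit$test_draws[, n_test + seq_len(n_test), drop = FALSE]
      est <- estimate_cate_from_draws(fd, cd, treated_is_factual)
      boot_theta[b, ] <- est$ite$theta
    }
  })
  boots <- rowMeans(boot_theta)
  theta_bar <- colMeans(boot_theta)
  ite <- tibble::tibble(
    child_id = child_id %||% as.character(seq_len(n_test)),
    theta = theta_bar
  )
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  new_cate_estimate(mean(boots), qs[1], qs[2], ite, boots = boots,
                    boot_theta = boot_theta)
}

#' Subgroup CATE
#'
#' Restricts the averaging of the individual effects to a subgroup of the
#' test children (e.g. conflict intensity 0 vs > 10). When the estimate
#' carries bootstrap draws the credible region is recomputed from the
#' subgroup means of each bootstrap iteration.
#'
#' @param estimate A `cate_estimate` from [bootstrap_cate()] or
#'   [estimate_cate_from_draws()].
#' @param keep Logical vector (length `n_children`) selecting the
#'   subgroup; must keep at least one child.
#' @param label Optional subgroup label.
#' @return A `cate_estimate` for the subgroup.
#' @export
subgroup_cate <- function(estimate, keep, label = NA_character_) {
  stopifnot(length(keep) == estimate$n_children)
  if (!any(keep)) abort_nutricate("empty subgroup")
  ite <- estimate$ite[keep, ]
  if (!is.null(estimate$boot_theta)) {
    boots <- rowMeans(estimate$boot_theta[, keep, drop = FALSE])
    qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    new_cate_estimate(mean(boots), qs[1], qs[2], ite, boots = boots,
                      boot_theta = estimate$boot_theta[, keep,
                                                       drop = FALSE],
                      subgroup = label)
  } else {
    cate <- mean(ite$theta)
    new_cate_estimate(cate, cate, cate, ite, subgroup = label)
  }
}

#' @rdname tidy.probit_bart
#' @method tidy cate_estimate
#' @export
tidy.cate_estimate <- function(x, ...) {
  tibble::tibble(subgroup = x$subgroup, cate = x$cate, lower = x$lower,
                 upper = x$upper, n_children = x$n_children)
}

#' @rdname tidy.probit_bart
#' @method glance cate_estimate
#' @export
glance.cate_estimate <- function(x, ...) {
  tibble::tibble(cate = x$cate, lower = x$lower, upper = x$upper,
                 n_children = x$n_children,
                 n_boot = length(x$boots %||% numeric()))
}
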
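#' BART sampler configuration
#'
#' Hyperparameters of the probit sum-of-trees sampler. Defaults are the
#' canonical regularizing choices for binary BART: 200 trees, depth prior
#' `alpha (1 + d)^(-beta)` with `alpha = 0.95`, `beta = 2`, leaf prior
#' `mu ~ N(0, (3 / (k sqrt(m)))^2)` with `k = 2` on the probit scale, and
#' a grow/prune/change proposal mix of 0.28/0.28/0.44. Burn-in and
#' retained draws default to 1,000 each; scale them down for desk-scale
#' experiments.
#'
#' @param num_trees Number of trees `m`.
#' @param burn_in Discarded MCMC iterations.
#' @param num_draws Retained posterior draws.
#' @param alpha,beta Depth-prior parameters (`alpha` in (0,1),
#'   `beta >= 0`).
#' @param k Leaf-prior scale divisor.
#' @param p_grow,p_prune,p_change Structural-move proposal probabilities
#'   (must sum to 1).
#' @return List of class `bart_config`.
#' @export
bart_config <- function(num_trees = 200L, burn_in = 1000L,
                        num_draws = 1000L, alpha = 0.95, beta = 2, k = 2,
                        p_grow = 0.28, p_prune = 0.28, p_change = 0.44) {
  stopifnot(num_trees >= 1, burn_in >= 0, num_draws >= 1,
            alpha > 0, alpha < 1, beta >= 0, k > 0,
            abs(p_grow + p_prune + p_change - 1) < 1e-9)
  structure(list(num_trees = as.integer(num_trees),
                 burn_in = as.integer(burn_in),
                 num_draws = as.integer(num_draws),
                 alpha = alpha, beta = beta, k = k,
                 p_grow = p_grow, p_prune = p_prune, p_change = p_change),
            class = "bart_config")
}

#' Fit probit BART
#'
#' Fits the probit sum-of-trees model
#' \deqn{P(Y = 1 \mid X = x) = \Phi\Big(\sum_{j=1}^m g(x; T_j, M_j)\Big)}
#' by MCMC with Albert--Chib truncated-normal latent augmentation:
#' Bayesian backfitting over trees with Metropolis--Hastings
#' grow/prune/change moves under the depth-regularizing tree prior and
#' conjugate normal leaf conditionals. Proposals that would create an
#' empty leaf are rejected. The treatment variable enters `X` as an
#' ordinary predictor column. Results are deterministic for a fixed
#' `set.seed()` state.
#'
#' @param X Numeric matrix (n x K) of covariates including the treatment
#'   column; categoricals must be pre-encoded (see [encode_covariates()]).
#'   No missing values.
#' @param y Binary (0/1) outcome vector of length n.
#' @param config A [bart_config()].
#' @param X_test Optional matrix with the same columns as `X`; probit-scale
#'   posterior draws for these rows are stored with the fit (cheaper than a
#'   separate [predict_probit_draws()] pass).
#' @param keep_trees Keep the serialized retained ensembles so the fit can
#'   predict on new data later (default `TRUE`; disable inside tight
#'   bootstrap loops that predict only on `X_test`).
#' @return Object of class `probit_bart`: list with `test_draws`
#'   (`num_draws` x `nrow(X_test)` probit-scale matrix),
#'   `train_probit_mean`, `avg_leaves` (mean leaves per tree per retained
#'   draw), `trees` (serialized ensembles), `schema` (training column
#'   names) and `config`.
#' @export
fit_probit_bart <- function(X, y, config = bart_config(), X_test = NULL,
                            keep_trees = TRUE) {
  X <- as.matrix(X)
  if (anyNA(X)) abort_nutricate("X must not contain missing values")
  y <- as.integer(y)
  if (length(y) != nrow(X)) abort_nutricate("X/y length mismatch")
  if (!all(y %in% c(0L, 1L))) abort_nutricate("y must be binary 0/1")
  if (nrow(X) < 10) abort_nutricate("need at least 10 observations")
  if (length(unique(y)) < 2 && nrow(X) < 10) {
    abort_nutricate("constant y with too few observations")
  }
  if (is.null(X_test)) X_test <- X[0, , drop = FALSE]
  X_test <- as.matrix(X_test)
  if (ncol(X_test) != ncol(X)) abort_nutricate("X_test schema mismatch")
  res <- bart_probit_cpp(X, y, X_test, config$num_trees, config$burn_in,
                         config$num_draws, config$alpha, config$beta,
                         config$k, config$p_grow, config$p_prune,
                         config$p_change, keep_trees)
  structure(list(test_draws = res$test_draws,
                 train_probit_mean = as.numeric(res$train_probit_mean),
                 avg_leaves = as.numeric(res$avg_leaves),
                 trees = if (keep_trees) res$trees else NULL,
                 schema = colnames(X), n_train = nrow(X),
                 config = config),
            class = "probit_bart")
}

#' @export
print.probit_bart <- function(x, ...) {
  cat("Probit BART fit:", x$config$num_trees, "trees,",
      x$config$num_draws, "retained draws, n =", x$n_train, "\n")
  invisible(x)
}

#' Posterior predictive probit draws
#'
#' Evaluates every retained sum-of-trees state at new covariate rows.
#' Entry (s, i) is `sum_j g(x_i; T_j^(s), M_j^(s))` on the probit scale;
#' apply `pnorm()` for probabilities.
#'
#' @param fit A `probit_bart` fitted with `keep_trees = TRUE`.
#' @param X_new Numeric matrix with the training columns (same order).
#' @return `num_draws` x `nrow(X_new)` matrix of probit-scale draws.
#' @export
predict_probit_draws <- function(fit, X_new) {
  if (is.null(fit$trees)) {
    abort_nutricate("fit was run with keep_trees = FALSE")
  }
  X_new <- as.matrix(X_new)
  if (!is.null(fit$schema) && !is.null(colnames(X_new))) {
    if (!identical(colnames(X_new), fit$schema)) {
      abort_nutricate("X_new schema does not match training schema")
    }
  }
  bart_predict_cpp(fit$trees, X_new, fit$config$num_draws,
                   fit$config$num_trees)
}

#' Draw Albert--Chib latent variables
#'
#' Samples `z ~ N(eta, 1)` truncated to `(0, Inf)` when `y = 1` and to
#' `(-Inf, 0]` when `y = 0` — the conjugate latent-data step of the probit
#' sampler (far-tail cases use Robert's exponential rejection sampler).
#'
#' @param y Binary 0/1 vector.
#' @param eta Probit-scale means (same length).
#' @return Numeric vector of latent draws.
#' @export
sample_latent <- function(y, eta) {
  stopifnot(length(y) == length(eta), all(y %in% c(0, 1)),
            all(is.finite(eta)))
  sample_latent_cpp(as.integer(y), as.numeric(eta))
}

#' Tidy the retained tree ensembles
#'
#' @param fit A `probit_bart` fitted with `keep_trees = TRUE`.
#' @return Tibble with one row per node: `draw`, `tree`, `node`, `var`
#'   (0 for leaves, else 1-based training column), `split`, `left`,
#'   `right` (node ids; -1 for leaves), `mu`.
#' @export
bart_trees <- function(fit) {
  if (is.null(fit$trees)) {
    abort_nutricate("fit was run with keep_trees = FALSE")
  }
  tb <- tibble::as_tibble(as.data.frame(fit$trees))
  names(tb) <- c("draw", "tree", "node", "var", "split", "left", "right",
                 "mu")
  tb
}

#' Traverse a single decision tree
#'
#' Routes a covariate row through one tree (numeric rule `x[var] < split`
#' goes left, else right) and returns the leaf value. Mainly useful for
#' auditing fitted ensembles node by node; bulk prediction goes through
#' [predict_probit_draws()].
#'
#' @param tree Tibble of nodes for one tree as returned by [bart_trees()]
#'   (columns `node`, `var`, `split`, `left`, `right`, `mu`).
#' @param x Named or positional numeric covariate vector.
#' @return The leaf value mu (scalar).
#' @export
tree_traverse <- function(tree, x) {
  rowof <- match(0:max(tree$node), tree$node)
  k <- 0
  repeat {
    r <- rowof[k + 1]
    if (is.na(r)) abort_nutricate("malformed tree: missing node")
    if (tree$var[r] == 0) return(tree$mu[r])
    v <- tree$var[r]
    if (v > length(x) || is.na(x[v])) {
      abort_nutricate("missing value at a split variable")
    }
    k <- if (x[v] < tree$split[r]) tree$left[r] else tree$right[r]
  }
}

#' One-hot encode covariates for BART
#'
#' Numeric columns pass through; logicals become 0/1; character/factor
#' columns expand to one indicator column per observed level (all levels
#' kept, sorted for determinism). Column order is deterministic, so
#' factual and counterfactual matrices built from the same schema align.
#'
#' @param df Data frame of covariates.
#' @param levels_map Optional named list of level sets per categorical
#'   column (use the training map when encoding new data).
#' @return List with `X` (numeric matrix) and `levels_map`.
#' @export
encode_covariates <- function(df, levels_map = NULL) {
  cols <- list()
  lm_out <- list()
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- as.numeric(x)
    } else if (is.logical(x)) {
      cols[[nm]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      levs <- if (!is.null(levels_map) && !is.null(levels_map[[nm]])) {
        levels_map[[nm]]
      } else {
        sort(unique(x))
      }
      lm_out[[nm]] <- levs
      for (lv in levs) {
        cols[[paste0(nm, "=", lv)]] <- as.numeric(x == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyNA(X)) abort_nutricate("covariates contain missing values")
  list(X = X, levels_map = if (is.null(levels_map)) lm_out else levels_map)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a probit BART fit
#'
#' @param x A `probit_bart`.
#' @param ... Unused.
#' @return Tibble with one row per test observation: posterior-mean
#'   probit score, posterior-mean probability and its 2.5/97.5% quantiles.
#' @method tidy probit_bart
#' @export
tidy.probit_bart <- function(x, ...) {
  if (ncol(x$test_draws) == 0) {
    return(tibble::tibble(row = integer(), probit_mean = numeric(),
                          prob_mean = numeric(), prob_lo = numeric(),
                          prob_hi = numeric()))
  }
  pr <- stats::pnorm(x$test_draws)
  tibble::tibble(
    row = seq_len(ncol(pr)),
    probit_mean = colMeans(x$test_draws),
    prob_mean = colMeans(pr),
    prob_lo = apply(pr, 2, stats::quantile, 0.025),
    prob_hi = apply(pr, 2, stats::quantile, 0.975)
  )
}

#' @rdname tidy.probit_bart
#' @return `glance()`: one-row tibble with the configuration and the mean
#'   leaves-per-tree over retained draws.
#' @method glance probit_bart
#' @export
glance.probit_bart <- function(x, ...) {
  tibble::tibble(
    num_trees = x$config$num_trees, burn_in = x$config$burn_in,
    num_draws = x$config$num_draws, n_train = x$n_train,
    mean_leaves_per_tree = mean(x$avg_leaves)
  )
}
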
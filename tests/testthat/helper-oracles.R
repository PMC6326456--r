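# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, exhaustive enumeration) so that they
# share no code path with the package implementations they check.

# Bristol rule oracle: any non-missing z strictly below -3
oracle_severe <- function(z_wa, z_ha, z_wh) {
  vapply(seq_along(z_wa), function(i) {
    z <- c(z_wa[i], z_ha[i], z_wh[i])
    z <- z[!is.na(z)]
    if (length(z) == 0) return(NA)
    any(z < -3)
  }, NA)
}

# CATE oracle: explicit double loop over draws and children
oracle_cate <- function(factual, cf, treated_is_factual = TRUE) {
  S <- nrow(factual); n <- ncol(factual)
  theta <- numeric(n)
  for (i in seq_len(n)) {
    pf <- 0; pc <- 0
    for (s in seq_len(S)) {
      pf <- pf + pnorm(factual[s, i])
      pc <- pc + pnorm(cf[s, i])
    }
    pf <- pf / S; pc <- pc / S
    theta[i] <- if (treated_is_factual) pf - pc else pc - pf
  }
  list(theta = theta, cate = mean(theta))
}

# AUC oracle: concordance by pair counting with 0.5 for ties
oracle_auc <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Youden cutoff oracle: exhaustive search over distinct scores,
# score >= cutoff predicts positive, ties to the lowest cutoff
oracle_cutoff <- function(y, scores) {
  cand <- sort(unique(scores))
  best <- -Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(scores[y == 1] >= t)
    spec <- mean(scores[y == 0] < t)
    j <- sens + spec - 1
    if (j > best + 1e-12) {
      best <- j; best_t <- t
    }
  }
  best_t
}

# exhaustive maximum feasible partition: enumerate all set partitions of
# 1..n, keep those whose blocks are all connected and feasible, return the
# maximal block count (n <= 8 or so)
oracle_partition_count <- function(neighbors, feasible_fn, n) {
  best <- -1L
  assign_next <- function(blocks, i) {
    if (i > n) {
      ok <- all(vapply(blocks, function(b) {
        feasible_fn(b) && oracle_connected(b, neighbors)
      }, logical(1)))
      if (ok) best <<- max(best, length(blocks))
      return(invisible())
    }
    for (k in seq_along(blocks)) {
      blocks[[k]] <- c(blocks[[k]], i)
      assign_next(blocks, i + 1)
      blocks[[k]] <- blocks[[k]][-length(blocks[[k]])]
    }
    assign_next(c(blocks, list(i)), i + 1)
  }
  assign_next(list(), 1L)
  best
}

oracle_connected <- function(members, neighbors) {
  if (length(members) <= 1) return(TRUE)
  seen <- members[1]
  repeat {
    nxt <- setdiff(intersect(unlist(neighbors[seen]), members), seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
  }
  length(seen) == length(members)
}

# conjugate-augmentation oracle for the intercept-only probit model:
# eta ~ N(0, v0), z_i ~ N(eta, 1) truncated by y_i
oracle_intercept_probit <- function(y, v0, iters = 2000, burn = 500) {
  n <- length(y)
  eta <- 0
  keep <- numeric(iters - burn)
  for (it in seq_len(iters)) {
    lo <- ifelse(y == 1, 0, -Inf)
    hi <- ifelse(y == 1, Inf, 0)
    u <- runif(n)
    z <- qnorm(pnorm(lo - eta) + u * (pnorm(hi - eta) - pnorm(lo - eta))) +
      eta
    v <- 1 / (n + 1 / v0)
    eta <- rnorm(1, v * sum(z), sqrt(v))
    if (it > burn) keep[it - burn] <- eta
  }
  mean(pnorm(keep))
}
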
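# Independent oracles: deliberately naive implementations (dense matrices,
# explicit normal equations, exhaustive grids) against which the package's
# optimized paths are checked.

# Restricted log-likelihood of the random-effects meta-regression, written
# directly from the multivariate-normal density with dense matrices.
oracle_reml_ll <- function(tau2, y, se, X) {
  V <- diag(se^2 + tau2, length(y))
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  b <- solve(B, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  k <- length(y); p <- ncol(X)
  as.numeric(
    -0.5 * (k - p) * log(2 * pi) +
      0.5 * determinant(t(X) %*% X, logarithm = TRUE)$modulus -
      0.5 * determinant(V, logarithm = TRUE)$modulus -
      0.5 * determinant(B, logarithm = TRUE)$modulus -
      0.5 * t(r) %*% Vi %*% r)
}

# Dense grid search over tau2 in [0, upper] (step 1e-4), refined inside the
# bracketing cell by Brent search on the oracle likelihood.
oracle_tau2 <- function(y, se, X, upper = 5, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, function(t2) oracle_reml_ll(t2, y, se, X), numeric(1))
  i <- which.max(ll)
  lo <- max(0, grid[i] - step); hi <- min(upper, grid[i] + step)
  opt <- optimize(oracle_reml_ll, c(lo, hi), maximum = TRUE,
                  y = y, se = se, X = X, tol = 1e-12)
  if (oracle_reml_ll(0, y, se, X) >= opt$objective) 0 else opt$maximum
}

# Exhaustive 2-D grid search of the discounting likelihood over (k, slope).
oracle_discount_grid <- function(data, k_max = 5, slope_max = 50,
                                 nk = 200, ns = 200) {
  domain <- attr(data, "domain")
  Cs <- cost_transform(data$cost_small, domain)
  Cl <- cost_transform(data$cost_large, domain)
  ks <- c(0, exp(seq(log(1e-4), log(k_max), length.out = nk - 1)))
  ss <- c(0, exp(seq(log(1e-3), log(slope_max), length.out = ns - 1)))
  y <- data$choice == "smaller"
  best <- list(loglik = -Inf, k = NA, slope = NA)
  for (i in seq_along(ks)) {
    dsv <- data$r_small / (1 + ks[i] * Cs) - data$r_large / (1 + ks[i] * Cl)
    q <- outer(ss, dsv)                       # ns x trials
    ll <- rowSums(plogis(q[, y, drop = FALSE], log.p = TRUE)) +
      rowSums(plogis(-q[, !y, drop = FALSE], log.p = TRUE))
    j <- which.max(ll)
    if (ll[j] > best$loglik)
      best <- list(loglik = ll[j], k = ks[i], slope = ss[j],
                   k_index = i, slope_index = j)
  }
  best$k_ratio <- (k_max / 1e-4)^(1 / (nk - 2))      # log spacing of the grid
  best$slope_ratio <- (slope_max / 1e-3)^(1 / (ns - 2))
  best
}

# Brute-force partial correlation: explicit normal equations, no qr().
oracle_partial_cor <- function(x, y, Z) {
  A <- cbind(1, Z)
  bx <- solve(t(A) %*% A) %*% t(A) %*% x
  by <- solve(t(A) %*% A) %*% t(A) %*% y
  rx <- x - A %*% bx
  ry <- y - A %*% by
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}
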
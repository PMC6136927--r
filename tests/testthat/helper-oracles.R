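# Independent oracles used to cross-check the closed-form and
# profile-likelihood estimators. These deliberately avoid the package's
# own linear-algebra path: the GLS oracle whitens and calls lm(); the ML
# oracle is a brute-force grid search with explicit solve() calls.

# Generalized least squares of by on bx through the origin with
# covariance Omega = outer(sy, sy) * rho, via Cholesky whitening + lm().
gls_oracle <- function(bx, by, sy, rho) {
  omega <- outer(sy, sy) * rho
  w <- solve(t(chol(omega))) # whitener: w %*% omega %*% t(w) = I
  fit <- lm(as.numeric(w %*% by) ~ as.numeric(w %*% bx) - 1)
  est <- coef(fit)[[1]]
  se <- 1 / sqrt(sum((w %*% bx)^2))
  list(theta = est, se = se)
}

# Profile log-likelihood computed from first principles for the oracle:
# stack the two samples and solve the GLS normal equations with solve().
oracle_profile_ll <- function(theta, bx, sx, by, sy, rho) {
  sig_x <- outer(sx, sx) * rho
  sig_y <- outer(sy, sy) * rho
  xi_inv <- solve(sig_x)
  yi_inv <- solve(sig_y)
  xi <- solve(xi_inv + theta^2 * yi_inv, xi_inv %*% bx + theta * yi_inv %*% by)
  rx <- bx - xi
  ry <- by - theta * xi
  -0.5 * (t(rx) %*% xi_inv %*% rx + t(ry) %*% yi_inv %*% ry)[1, 1]
}

# Two-stage-refined grid search over theta in [-5, 5].
grid_ml_oracle <- function(bx, sx, by, sy, rho) {
  ll <- function(th) oracle_profile_ll(th, bx, sx, by, sy, rho)
  grid <- seq(-5, 5, length.out = 4001)
  best <- grid[which.max(vapply(grid, ll, numeric(1)))]
  step <- grid[2] - grid[1]
  for (i in 1:2) {
    grid <- seq(best - 2 * step, best + 2 * step, length.out = 4001)
    best <- grid[which.max(vapply(grid, ll, numeric(1)))]
    step <- grid[2] - grid[1]
  }
  best
}

# Random small harmonized instance on a valid correlation matrix.
random_instance <- function(k = 3, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(k * k), k)
  rho <- cov2cor(crossprod(a) + diag(k))
  rsid <- paste0("rs", seq_len(k))
  dimnames(rho) <- list(rsid, rsid)
  data <- tibble::tibble(
    rsid = rsid,
    beta_exposure = runif(k, 0.05, 0.3) * sample(c(-1, 1), k, replace = TRUE),
    se_exposure = runif(k, 0.01, 0.05),
    beta_outcome = rnorm(k, 0, 0.1),
    se_outcome = runif(k, 0.01, 0.05)
  )
  list(data = data, rho = rho)
}
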
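# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the spline oracle uses the truncated-power
# representation, the cross-basis oracle a quadruple loop, the Spearman
# oracle Pearson-on-ranks, and the Poisson oracle direct likelihood
# maximization.

# Truncated-power natural cubic spline basis (including intercept and
# linear term) on the knot sequence c(boundary[1], interior, boundary[2]).
tp_natural_basis <- function(x, interior, boundary) {
  xi <- c(boundary[1L], sort(interior), boundary[2L])
  K <- length(xi)
  d <- function(k, x) {
    (pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[k])
  }
  cols <- lapply(seq_len(K - 2L), function(j) d(j, x) - d(K - 1L, x))
  cbind(1, x, do.call(cbind, cols))
}

# Brute-force cross-basis: entry (t, (j-1)*vl + k) = sum_l b_j(x[t-l]) c_k(l)
brute_crossbasis <- function(x, L, exposure_spec, lag_spec) {
  n <- length(x)
  Bfun <- function(v) templag:::eval_basis(exposure_spec, v)
  Cfun <- function(l) templag:::eval_basis(lag_spec, l)
  vx <- exposure_spec$df
  vl <- lag_spec$df
  M <- matrix(NA_real_, n, vx * vl)
  for (t in seq_len(n)) {
    if (t <= L) next
    acc <- matrix(0, vx, vl)
    for (l in 0:L) {
      acc <- acc + as.vector(Bfun(x[t - l])) %o% as.vector(Cfun(l))
    }
    M[t, ] <- as.vector(t(acc))   # j-outer, k-inner
  }
  M
}

# Spearman via Pearson on average ranks
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Direct Poisson log-likelihood maximization (BFGS with analytic gradient)
brute_poisson_fit <- function(y, X) {
  Xi <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(Xi %*% b)
    sum(exp(eta)) - sum(y * eta)
  }
  grad <- function(b) {
    mu <- exp(drop(Xi %*% b))
    drop(crossprod(Xi, mu - y))
  }
  o <- optim(rep(0, ncol(Xi)), nll, grad, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-15))
  o$par
}

# Small deterministic series for fitting tests (shared across files)
test_series <- local({
  cache <- new.env()
  function(seed = 1L, n_days = 400L) {
    key <- paste0("s", seed, "_", n_days)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_stroke_series(seed = seed, n_days = n_days)
    cache[[key]]
  }
})

multi_covariates <- c("tv", "rh", "pm25", "so2")
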
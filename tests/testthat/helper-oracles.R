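# Independent closed-form OLS: beta = (X'X)^{-1} X'y with an explicit
# intercept column. Used to cross-check every lm-based fit.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# Dense-grid SSE oracle for the modified Ross-Minton model over a bounds box.
# Evaluates the closed form on an n^3 grid of ([eta] mL/g, k, v) and returns
# the minimal feasible SSE.
rm_grid_oracle <- function(conc, eta, eta0, lower, upper, n = 50L) {
  ivs <- seq(lower[1L], upper[1L], length.out = n)
  ks <- seq(lower[2L], upper[2L], length.out = n)
  vs <- seq(lower[3L], upper[3L], length.out = n)
  best <- Inf
  for (iv in ivs) {
    iv_mgml <- iv / 1000
    for (k in ks) {
      # vectorize over v: denom is m x length(conc)
      ratio <- outer(k / vs, iv_mgml * conc)          # (k/v) * [eta] * c
      denom <- 1 - ratio
      pred <- eta0 * exp(outer(rep(iv_mgml, length(vs)), conc) / denom)
      pred[denom <= 0] <- NA
      sse <- rowSums((matrix(eta, length(vs), length(conc), byrow = TRUE) - pred)^2)
      m <- suppressWarnings(min(sse, na.rm = TRUE))
      if (is.finite(m) && m < best) best <- m
    }
  }
  best
}

# Coarse grid + Nelder-Mead polish oracle for the exponential-growth model.
expgrowth_oracle_sse <- function(conc, eta) {
  sse <- function(p) sum((eta - p[1L] * exp(p[2L] * conc))^2)
  grid <- expand.grid(y0 = seq(0.2, 5, length.out = 25),
                      k = seq(0.001, 0.06, length.out = 25))
  vals <- apply(grid, 1L, sse)
  start <- as.numeric(grid[which.min(vals), ])
  stats::optim(start, sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))$value
}

# Direct textbook Pearson correlation (covariance formula).
pearson_oracle <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
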
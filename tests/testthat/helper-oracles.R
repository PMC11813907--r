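# Independent oracles used to cross-check the package's closed-form paths.

# cubic least squares by explicit normal equations, on a rescaled abscissa
# to keep X'X well conditioned; coefficients mapped back analytically
cubic_normal_equations <- function(tau, y) {
  s <- max(abs(tau))
  u <- tau / s
  X <- cbind(1, u, u^2, u^3)
  gamma <- unname(drop(solve(t(X) %*% X, t(X) %*% y)))
  gamma / s^(0:3)
}

# polynomial evaluation by explicit power sums (vs the package's Horner path)
power_sum_poly <- function(coefs, x) {
  sapply(x, function(xi) sum(coefs * xi^(seq_along(coefs) - 1L)))
}

# ridge weights by plain gradient descent on
#   L(w) = ||yc - Z w||^2 + lambda ||w||^2
# for a standardized design Z and centred target yc
ridge_gradient_descent <- function(z, yc, lambda, iters = 50000L) {
  w <- rep(0, ncol(z))
  ztz <- crossprod(z)
  zty <- crossprod(z, yc)
  lr <- 1 / (2 * (max(eigen(ztz, only.values = TRUE)$values) + lambda))
  for (i in seq_len(iters)) {
    grad <- 2 * (ztz %*% w - zty + lambda * w)
    w_new <- w - lr * grad
    if (max(abs(w_new - w)) < 1e-14) {
      w <- w_new
      break
    }
    w <- w_new
  }
  unname(drop(w))
}

# definitional Pearson correlation
brute_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) * length(x) / (length(x) - 1)
}

# small measured-fruit fixture: one fruit on a constant-temperature series
constant_clock <- function(temp = 20, days = 120, anthesis_offset = 5) {
  start <- as.Date("2022-09-01")
  series <- temperature_series(seq(start, by = 1, length.out = days),
                               rep(temp, days))
  thermal_clock(start + anthesis_offset, series)
}
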
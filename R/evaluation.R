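#' Mean absolute percentage error
#'
#' `MAPE = 100/n * sum(|P_i - H_i| / H_i)` in percent. Scale-invariant:
#' rescaling predictions and observations together leaves it unchanged.
#'
#' @param pred predicted masses, g.
#' @param obs observed (harvested) masses, g, all strictly positive.
#' @return MAPE in percent.
#' @examples
#' mape(c(90, 120), c(100, 100))  # 15
#' @export
mape <- function(pred, obs) {
  check_pair(pred, obs, min_n = 1L)
  if (any(obs == 0)) {
    hc_abort("MAPE undefined for zero observed mass", "hc_domain_error")
  }
  100 * mean(abs(pred - obs) / obs)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((P_i - H_i)^2) / sum((H_i - Hbar)^2)`: the standard
#' definition with the observed variance in the denominator, so a constant
#' prediction at the observed mean scores exactly 0 and values can go
#' negative for predictions worse than the mean.
#'
#' @param pred predicted masses, g.
#' @param obs observed masses, g; at least 2 values with nonzero variance.
#' @return R^2, dimensionless, `<= 1`.
#' @export
r_squared <- function(pred, obs) {
  check_pair(pred, obs, min_n = 2L)
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) {
    hc_abort("zero variance in observations: R^2 undefined",
             "hc_degenerate_error")
  }
  1 - sum((pred - obs)^2) / sstot
}

#' Root mean squared error
#'
#' @param pred predicted masses, g.
#' @param obs observed masses, g.
#' @return RMSE in g; 0 iff predictions are exact.
#' @export
rmse <- function(pred, obs) {
  check_pair(pred, obs, min_n = 1L)
  sqrt(mean((pred - obs)^2))
}

check_pair <- function(pred, obs, min_n) {
  if (length(pred) != length(obs)) {
    hc_abort("pred and obs must have equal length", "hc_schema_error")
  }
  if (length(obs) < min_n) {
    hc_abort(sprintf("need at least %d observations", min_n),
             "hc_insufficient_data")
  }
  invisible(TRUE)
}

#' Evaluation report
#'
#' @param pred predicted harvest masses, g.
#' @param obs observed harvest masses, g.
#' @return tibble with `n`, `mape_pct`, `r2`, `rmse_g`.
#' @export
eval_report <- function(pred, obs) {
  tibble::tibble(n = length(obs),
                 mape_pct = mape(pred, obs),
                 r2 = r_squared(pred, obs),
                 rmse_g = rmse(pred, obs))
}

#' Correlation of mean temperature with thermal time to harvest
#'
#' Pearson correlation (with the usual t-distribution two-sided p-value)
#' between each fruit's mean temperature over its growth period and the
#' cumulative temperature it accumulated from anthesis to harvest. Warmer
#' growing periods are expected to need fewer degree-days to reach harvest
#' ripeness, i.e. a negative correlation.
#'
#' @param mean_temp_c per-fruit mean temperatures, degC.
#' @param tau_harvest per-fruit cumulative temperatures at harvest, degC d.
#' @return list with `r` (Pearson), `p` (two-sided), `n`.
#' @export
temp_thermal_correlation <- function(mean_temp_c, tau_harvest) {
  check_pair(mean_temp_c, tau_harvest, min_n = 3L)
  if (var(mean_temp_c) == 0 || var(tau_harvest) == 0) {
    hc_abort("zero variance: correlation undefined", "hc_degenerate_error")
  }
  ct <- cor.test(mean_temp_c, tau_harvest, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(mean_temp_c))
}
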
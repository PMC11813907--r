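#' @importFrom rlang abort
#' @importFrom stats coef cor.test lm predict pt quantile rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

hc_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "hc_error"), ...)
}

#' Evaluate a polynomial with ascending coefficients
#'
#' @param coefs numeric vector `c(a0, a1, ..., ak)` for
#'   `a0 + a1*x + ... + ak*x^k`.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of polynomial values.
#' @keywords internal
eval_poly <- function(coefs, x) {
  # Horner's rule
  out <- rep(coefs[length(coefs)], length(x))
  for (k in rev(seq_len(length(coefs) - 1L))) {
    out <- out * x + coefs[k]
  }
  out
}

as_date_strict <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXt")) {
    return(x)
  }
  if (inherits(x, "Date")) {
    return(x)
  }
  if (is.character(x)) {
    out <- as.Date(x)
    if (anyNA(out)) {
      hc_abort(sprintf("could not parse %s as ISO-8601 date", what),
               "hc_schema_error")
    }
    return(out)
  }
  hc_abort(sprintf("%s must be a Date, POSIXt or ISO-8601 string", what),
           "hc_schema_error")
}

# days since epoch, fractional for sub-daily timestamps
time_to_days <- function(x) {
  if (inherits(x, "POSIXt")) {
    as.numeric(x) / 86400
  } else {
    as.numeric(as_date_strict(x))
  }
}
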
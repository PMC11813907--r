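#' Thermal anchor schemes
#'
#' An anchor scheme defines the thermal-time window over which per-fruit
#' growth curves are fitted, the fixed thermal times (anchors) at which the
#' fitted curve is read off, and the per-fruit r^2 gate below which a fruit is
#' excluded. Two presets cover the early and late prediction periods:
#'
#' * `E500`: fit on observations below 625 degC d, anchors at 200, 300 and
#'   500 degC d, gate r^2 >= 0.94 — an early-season scheme usable while
#'   thinning decisions are still open.
#' * `E800`: fit below 900 degC d, anchors at 300, 500 and 800 degC d, gate
#'   r^2 >= 0.95 — roughly two weeks before harvest at typical greenhouse
#'   temperatures.
#'
#' @param name `"E500"`, `"E800"`, or a custom label (then `window_max`,
#'   `anchors`, `r2_gate` are required).
#' @param window_max exclusive thermal-time cutoff for fitting, degC d.
#' @param anchors strictly increasing anchor thermal times, all `< window_max`.
#' @param r2_gate per-fruit inclusion gate in `(0, 1]`.
#' @return an `anchor_scheme` object.
#' @examples
#' anchor_scheme("E500")
#' anchor_scheme("custom", window_max = 700, anchors = c(250, 600), r2_gate = 0.9)
#' @export
anchor_scheme <- function(name, window_max = NULL, anchors = NULL,
                          r2_gate = NULL) {
  presets <- list(
    E500 = list(window_max = 625, anchors = c(200, 300, 500), r2_gate = 0.94),
    E800 = list(window_max = 900, anchors = c(300, 500, 800), r2_gate = 0.95)
  )
  if (name %in% names(presets) && is.null(window_max)) {
    p <- presets[[name]]
    window_max <- p$window_max
    anchors <- p$anchors
    r2_gate <- p$r2_gate
  }
  if (is.null(window_max) || is.null(anchors) || is.null(r2_gate)) {
    hc_abort(sprintf("unknown scheme '%s': give window_max, anchors, r2_gate",
                     name), "hc_config_error")
  }
  if (any(diff(anchors) <= 0) || any(anchors >= window_max)) {
    hc_abort("anchors must be strictly increasing and below window_max",
             "hc_config_error")
  }
  if (r2_gate <= 0 || r2_gate > 1) {
    hc_abort("r2_gate must lie in (0, 1]", "hc_config_error")
  }
  structure(list(name = name, window_max = window_max,
                 anchors = anchors, r2_gate = r2_gate),
            class = "anchor_scheme")
}

#' @export
print.anchor_scheme <- function(x, ...) {
  cat(sprintf("<anchor_scheme> %s: window < %g degC d, anchors [%s], r2 gate %.2f\n",
              x$name, x$window_max, paste(x$anchors, collapse = ", "),
              x$r2_gate))
  invisible(x)
}

#' Fit a per-fruit cubic growth curve
#'
#' Ordinary least-squares fit of estimated fruit mass against thermal time
#' with a third-order polynomial, restricted to observations inside the
#' scheme window (`tau < window_max`). The cubic is a flexible descriptive
#' smoother for the sigmoidal mass trajectory, not a mechanistic model; the
#' per-fruit r^2 gate rejects fruits whose measurements it fails to describe.
#'
#' @param tau thermal times of the observations, degC d, non-negative.
#' @param c_fruit estimated fruit masses at those times, g.
#' @param scheme an [anchor_scheme()].
#' @return a `growth_curve` with fields `coefficients` (ascending, g per
#'   (degC d)^k), `r2`, `n_obs`, `window_max`, `qc_pass`
#'   (`r2 >= scheme$r2_gate`), `monotone_flag` (fitted derivative >= 0 on
#'   `[0, window_max]`), `min_tau` (earliest observation used).
#' @examples
#' tau <- c(100, 200, 300, 400, 500, 600)
#' fit_growth_curve(tau, 2e-7 * tau^3, anchor_scheme("E500"))
#' @export
fit_growth_curve <- function(tau, c_fruit, scheme) {
  stopifnot(inherits(scheme, "anchor_scheme"))
  if (length(tau) != length(c_fruit)) {
    hc_abort("tau and c_fruit must have equal length", "hc_schema_error")
  }
  if (any(tau < 0) || any(c_fruit < 0)) {
    hc_abort("tau and c_fruit must be non-negative", "hc_domain_error")
  }
  keep <- tau < scheme$window_max
  tau <- tau[keep]
  y <- c_fruit[keep]
  if (length(y) < 4L) {
    hc_abort(sprintf("only %d in-window observations; cubic fit needs >= 4",
                     length(y)), "hc_insufficient_data")
  }
  if (var(y) == 0) {
    hc_abort("zero variance in c_fruit: degenerate fit", "hc_degenerate_error")
  }
  X <- cbind(1, tau, tau^2, tau^3)
  fit <- stats::lm.fit(X, y)
  beta <- unname(fit$coefficients)
  if (anyNA(beta)) {
    hc_abort("rank-deficient design (duplicated thermal times?)",
             "hc_degenerate_error")
  }
  fitted <- drop(X %*% beta)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  grid <- seq(0, scheme$window_max, length.out = 512L)
  deriv <- eval_poly(c(beta[2L], 2 * beta[3L], 3 * beta[4L]), grid)
  structure(
    list(coefficients = beta,
         r2 = r2,
         n_obs = length(y),
         window_max = scheme$window_max,
         qc_pass = r2 >= scheme$r2_gate,
         monotone_flag = all(deriv >= -1e-9),
         min_tau = min(tau)),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> cubic on %d obs (tau < %g), r2 = %.4f, qc %s%s\n",
              x$n_obs, x$window_max, x$r2,
              if (x$qc_pass) "pass" else "FAIL",
              if (x$monotone_flag) "" else ", non-monotone"))
  invisible(x)
}

#' Estimated fruit sizes at thermal anchors
#'
#' Evaluates a gated growth curve at the scheme's anchor thermal times.
#' Anchors below the first observation used in the fit are extrapolations of
#' the cubic and are flagged, not rejected — the earliest anchor necessarily
#' precedes the first caliper visit for some fruits. Negative or
#' non-increasing anchor values are likewise flagged for audit.
#'
#' @param curve a [fit_growth_curve()] result with `qc_pass = TRUE`.
#' @param scheme the [anchor_scheme()] used for the fit.
#' @return named numeric vector `E_<anchor>` of estimated masses (g), with
#'   attributes `extrapolated` (logical per anchor), `negative` and
#'   `nonincreasing` (logical flags).
#' @export
anchor_sizes <- function(curve, scheme) {
  stopifnot(inherits(curve, "growth_curve"), inherits(scheme, "anchor_scheme"))
  if (!curve$qc_pass) {
    hc_abort("growth curve failed the r2 gate; fruit is excluded",
             "hc_gated_error")
  }
  vals <- eval_poly(curve$coefficients, scheme$anchors)
  names(vals) <- paste0("E_", scheme$anchors)
  attr(vals, "extrapolated") <- scheme$anchors < curve$min_tau
  attr(vals, "negative") <- any(vals < 0)
  attr(vals, "nonincreasing") <- any(diff(vals) <= 0)
  vals
}

#' Anchor table for a measured cohort
#'
#' Runs the full per-fruit curve pipeline over a measurement table: thermal
#' time from each fruit's anthesis clock, volume index from oriented
#' diameters, mass via the cultivar density calibration, windowed cubic fit,
#' r^2 gate, anchor evaluation, and the mean temperature from anthesis to the
#' last in-window measurement (the covariate used when the model includes
#' temperature).
#'
#' @param measurements tibble with columns `fruit_id`, `cultivar`,
#'   `anthesis_date`, `meas_date`, `long_cm`, `short_cm`, `harvest_date`,
#'   `harvest_mass_g` (harvest fields may be `NA` until harvest).
#' @param series a [temperature_series()] spanning all dates.
#' @param densities named numeric vector (or single number) of cultivar
#'   densities in g cm^-3, or a named list of [calibrate_density()] fits.
#' @param scheme an [anchor_scheme()].
#' @return tibble with one row per fitted fruit: `fruit_id`, `cultivar`,
#'   `scheme`, one `E_<anchor>` column per anchor, `mean_temp_c`, `r2`,
#'   `qc_pass`, `extrapolated`, `harvest_mass_g`. Fruits with fewer than 4
#'   in-window observations are dropped; gated fruits are kept with
#'   `qc_pass = FALSE` and `NA` anchors. The attribute `counts` records
#'   per-stage exclusions.
#' @export
anchor_table <- function(measurements, series, densities, scheme) {
  stopifnot(inherits(scheme, "anchor_scheme"))
  req <- c("fruit_id", "cultivar", "anthesis_date", "meas_date",
           "long_cm", "short_cm")
  if (!all(req %in% names(measurements))) {
    hc_abort(paste("measurements need columns:", paste(req, collapse = ", ")),
             "hc_schema_error")
  }
  density_of <- function(cv) {
    d <- if (is.list(densities)) densities[[cv]] else
      if (length(densities) == 1L && is.null(names(densities))) densities else
        densities[[cv]]
    if (is.null(d) || (!inherits(d, "density_fit") && is.na(d))) {
      hc_abort(sprintf("no density calibration for cultivar '%s'", cv),
               "hc_config_error")
    }
    d
  }

  dp <- orient_diameters(measurements$long_cm, measurements$short_cm)
  measurements$volume_cm3 <- fruit_volume_index(dp$long_cm, dp$short_cm)

  rows <- vector("list", 0L)
  n_insufficient <- 0L
  ids <- unique(measurements$fruit_id)
  for (id in ids) {
    m <- measurements[measurements$fruit_id == id, ]
    clock <- thermal_clock(m$anthesis_date[1L], series)
    tau <- cumulative_temperature(clock, as_date_strict(m$meas_date))
    cf <- estimate_mass(m$volume_cm3, density_of(m$cultivar[1L]))
    curve <- tryCatch(fit_growth_curve(tau, cf, scheme), hc_error = identity)
    if (inherits(curve, "condition")) {
      n_insufficient <- n_insufficient + 1L
      next
    }
    in_win <- tau < scheme$window_max
    last_date <- max(as_date_strict(m$meas_date)[in_win])
    mt <- mean_temperature(clock, last_date)
    anch <- if (curve$qc_pass) anchor_sizes(curve, scheme) else
      stats::setNames(rep(NA_real_, length(scheme$anchors)),
                      paste0("E_", scheme$anchors))
    row <- tibble::tibble(fruit_id = id, cultivar = m$cultivar[1L],
                          scheme = scheme$name)
    for (nm in names(anch)) row[[nm]] <- unname(anch[nm])
    row$mean_temp_c <- mt
    row$r2 <- curve$r2
    row$qc_pass <- curve$qc_pass
    row$extrapolated <- if (curve$qc_pass) any(attr(anch, "extrapolated")) else NA
    row$harvest_mass_g <- if ("harvest_mass_g" %in% names(m)) {
      m$harvest_mass_g[1L]
    } else {
      NA_real_
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- dplyr::bind_rows(rows)
  n_gated <- if (nrow(out)) sum(!out$qc_pass) else 0L
  attr(out, "counts") <- list(
    fruits_in = length(ids),
    excluded_insufficient = n_insufficient,
    excluded_r2_gate = n_gated,
    gate_fraction = if (length(ids) > n_insufficient) {
      n_gated / (length(ids) - n_insufficient)
    } else {
      NA_real_
    }
  )
  out
}
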
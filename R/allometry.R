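#' Ellipsoid fruit volume index
#'
#' Tomato fruits are treated as prolate spheroids: with long diameter `l` and
#' short diameter `s` (both cm), the volume index is
#' `V = (4/3) * pi * (l/2) * (s/2)^2 = (pi/6) * l * s^2` (cm^3). Note the
#' asymmetry: V is linear in the long diameter and quadratic in the short one.
#'
#' @param long_cm long diameter(s), cm.
#' @param short_cm short diameter(s), cm.
#' @return volume index in cm^3, vectorised.
#' @examples
#' fruit_volume_index(6.0, 6.0)   # sphere: pi/6 * 6^3
#' fruit_volume_index(6.7, 6.4)
#' @export
fruit_volume_index <- function(long_cm, short_cm) {
  if (any(long_cm <= 0) || any(short_cm <= 0)) {
    hc_abort("diameters must be positive", "hc_domain_error")
  }
  (pi / 6) * long_cm * short_cm^2
}

#' Validate and orient diameter pairs
#'
#' Caliper readings are sometimes recorded in the wrong order. Pairs whose
#' short diameter exceeds the long one beyond a relative tolerance are swapped
#' and flagged rather than rejected; pairs within the tolerance are kept as
#' recorded (measurement noise on a near-spherical fruit).
#'
#' @param long_cm,short_cm recorded diameters, cm.
#' @param tol relative tolerance for `short > long` before swapping
#'   (default 0.05).
#' @return tibble with columns `long_cm`, `short_cm`, `swapped`.
#' @export
orient_diameters <- function(long_cm, short_cm, tol = 0.05) {
  if (any(long_cm <= 0) || any(short_cm <= 0)) {
    hc_abort("diameters must be positive", "hc_domain_error")
  }
  swap <- short_cm > long_cm * (1 + tol)
  long_out <- ifelse(swap, short_cm, long_cm)
  short_out <- ifelse(swap, long_cm, short_cm)
  tibble::tibble(long_cm = long_out, short_cm = short_out, swapped = swap)
}

#' Calibrate cultivar fruit density
#'
#' Fits the proportional relation `mass = density * volume` by through-origin
#' least squares: `density = sum(V*m) / sum(V^2)`. Through-origin (no
#' intercept) is used because the mass model is strictly proportional; the
#' reported r^2 is the uncentered coefficient of determination
#' `1 - sum((m - d*V)^2) / sum(m^2)`, i.e. relative to the zero line.
#'
#' @param volume_cm3 fruit volume indices, cm^3, positive.
#' @param mass_g actual fruit masses, g (destructive measurements at harvest
#'   or thinning).
#' @return A `density_fit` with fields `density` (g cm^-3), `n_fruits`,
#'   `residual_rms` (g), `r2`.
#' @examples
#' v <- c(80, 120, 160)
#' calibrate_density(v, 1.072 * v)  # exact data: density 1.072, r2 = 1
#' @export
calibrate_density <- function(volume_cm3, mass_g) {
  if (length(volume_cm3) != length(mass_g)) {
    hc_abort("volume and mass vectors must have equal length",
             "hc_schema_error")
  }
  if (length(volume_cm3) < 2L) {
    hc_abort("density calibration needs at least 2 fruits",
             "hc_insufficient_data")
  }
  if (any(volume_cm3 < 0)) {
    hc_abort("volumes must be non-negative", "hc_domain_error")
  }
  if (all(volume_cm3 == 0)) {
    hc_abort("all volumes are zero: density is unidentifiable",
             "hc_degenerate_error")
  }
  d <- sum(volume_cm3 * mass_g) / sum(volume_cm3^2)
  resid <- mass_g - d * volume_cm3
  r2 <- 1 - sum(resid^2) / sum(mass_g^2)
  structure(
    list(density = d,
         n_fruits = length(volume_cm3),
         residual_rms = sqrt(mean(resid^2)),
         r2 = r2),
    class = "density_fit"
  )
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf("<density_fit> density %.4f g/cm^3 (n = %d, r2 = %.4f, RMS %.2f g)\n",
              x$density, x$n_fruits, x$r2, x$residual_rms))
  invisible(x)
}

#' Nondestructive mass estimate from volume index
#'
#' `C = V * d`: the calculated fruit size in grams from the ellipsoid volume
#' index and a cultivar density calibration.
#'
#' @param volume_cm3 volume index/indices, cm^3, non-negative.
#' @param fit a [calibrate_density()] result, or a bare positive density in
#'   g cm^-3.
#' @return estimated mass in g, vectorised over `volume_cm3`.
#' @export
estimate_mass <- function(volume_cm3, fit) {
  d <- if (inherits(fit, "density_fit")) fit$density else fit
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    hc_abort("fit must be a density_fit or a positive density",
             "hc_schema_error")
  }
  if (any(volume_cm3 < 0)) {
    hc_abort("volume must be non-negative", "hc_domain_error")
  }
  volume_cm3 * d
}

#' Read a density-calibration CSV
#'
#' Accepts either precomputed volumes (`volume_cm3`) or raw diameters
#' (`long_cm`, `short_cm`), converted on load, together with `mass_g`.
#'
#' @param path file path.
#' @return tibble with columns `cultivar` (if present), `volume_cm3`, `mass_g`.
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"mass_g" %in% names(df)) {
    hc_abort("calibration CSV needs a mass_g column", "hc_schema_error")
  }
  if (!"volume_cm3" %in% names(df)) {
    if (!all(c("long_cm", "short_cm") %in% names(df))) {
      hc_abort("calibration CSV needs volume_cm3 or long_cm/short_cm columns",
               "hc_schema_error")
    }
    dp <- orient_diameters(df$long_cm, df$short_cm)
    df$volume_cm3 <- fruit_volume_index(dp$long_cm, dp$short_cm)
  }
  keep <- intersect(c("fruit_id", "cultivar", "volume_cm3", "mass_g"), names(df))
  tibble::as_tibble(df[keep])
}
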
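#' Cultivar parameters for the greenhouse simulator
#'
#' Describes one cultivar's harvest-mass distribution, fruit density and
#' shape, latent growth-curve shape in thermal time, and its
#' temperature-dependent harvest rule. The latent trajectory is
#' `m(tau) = M * logistic(rate_i * (tau - midpoint_i))` with per-fruit jitter
#' on `midpoint` and `rate`; `M` is drawn from
#' `Normal(mass_mean * f(Tbar), mass_sd)` truncated positive, where
#' `f(Tbar) = max(0.5, 1 - temp_penalty * (Tbar - temp_optimum)^2)` penalizes
#' growth periods away from the thermal optimum. Harvest occurs at
#' `tau_H = harvest_tau_base + harvest_temp_slope * (Tbar - temp_optimum)`;
#' a negative slope makes warm growth periods need fewer degree-days, the
#' sign observed in glasshouse crops.
#'
#' @param name cultivar label.
#' @param mass_mean,mass_sd harvest-mass distribution, g.
#' @param density fruit density, g cm^-3.
#' @param aspect_mean,aspect_sd long/short diameter ratio (>= 1) and its
#'   between-fruit spread.
#' @param growth_midpoint logistic midpoint, degC d.
#' @param growth_rate logistic rate, (degC d)^-1.
#' @param midpoint_sd,rate_sd between-fruit spread of the growth-curve shape;
#'   larger values give more trajectory variability and harder prediction.
#' @param harvest_tau_base degree-days to harvest at the thermal optimum.
#' @param harvest_temp_slope degC d per degC, typically negative.
#' @param temp_optimum thermal optimum of the growth period, degC.
#' @param temp_penalty quadratic mass penalty per degC^2 away from the
#'   optimum.
#' @return a `cultivar_params` list.
#' @export
cultivar_params <- function(name, mass_mean, mass_sd, density,
                            aspect_mean = 1.04, aspect_sd = 0.03,
                            growth_midpoint = 430, growth_rate = 0.009,
                            midpoint_sd = 60, rate_sd = 0.0018,
                            harvest_tau_base = 1000,
                            harvest_temp_slope = -30,
                            temp_optimum = 20, temp_penalty = 0.008) {
  stopifnot(mass_mean > 0, mass_sd > 0, density > 0, aspect_mean >= 1,
            harvest_tau_base > growth_midpoint)
  structure(list(name = name, mass_mean = mass_mean, mass_sd = mass_sd,
                 density = density, aspect_mean = aspect_mean,
                 aspect_sd = aspect_sd, growth_midpoint = growth_midpoint,
                 growth_rate = growth_rate, midpoint_sd = midpoint_sd,
                 rate_sd = rate_sd, harvest_tau_base = harvest_tau_base,
                 harvest_temp_slope = harvest_temp_slope,
                 temp_optimum = temp_optimum, temp_penalty = temp_penalty),
            class = "cultivar_params")
}

#' Default simulated cultivars
#'
#' Three greenhouse tomato cultivars whose harvest-mass means, standard
#' deviations and fruit densities follow published cultivar statistics
#' (mass 154.3 +/- 51.5, 140.9 +/- 27.4 and 152.0 +/- 39.2 g; densities
#' 1.005, 1.072 and 0.970 g cm^-3); aspect ratios follow the corresponding
#' long/short diameter means. Growth-shape variability (`midpoint_sd`,
#' `rate_sd`) scales with each cultivar's relative mass variability, so the
#' cultivar with the most uniform fruit also has the most uniform
#' trajectories.
#'
#' @return named list of three [cultivar_params()].
#' @export
default_cultivars <- function() {
  list(
    `CF-like` = cultivar_params("CF-like", 154.3, 51.5, 1.005,
                                aspect_mean = 6.7 / 6.4,
                                midpoint_sd = 90, rate_sd = 0.0025),
    Zayda = cultivar_params("Zayda", 140.9, 27.4, 1.072,
                            aspect_mean = 6.4 / 6.2,
                            midpoint_sd = 40, rate_sd = 0.0010),
    Adventure = cultivar_params("Adventure", 152.0, 39.2, 0.970,
                                aspect_mean = 6.7 / 6.6,
                                midpoint_sd = 80, rate_sd = 0.0022)
  )
}

#' Simulator configuration
#'
#' @param cultivars named list of [cultivar_params()].
#' @param n_fruits fruits per cultivar.
#' @param season_start,season_end temperature-log span (ISO dates).
#' @param anthesis_start,anthesis_end window over which anthesis dates are
#'   drawn uniformly; must leave enough season for every fruit to reach its
#'   harvest degree-days.
#' @param temp_base,temp_amplitude,temp_peak_doy seasonal daily-mean path
#'   `temp_base + temp_amplitude * cos(2*pi*(doy - temp_peak_doy)/365.25)`
#'   (defaults: 19.5 degC mean, 22 degC in high summer, 17 degC midwinter).
#' @param temp_jitter_sd day-to-day temperature noise, degC.
#' @param measurement_interval days between caliper visits; 3.5 alternates
#'   3- and 4-day gaps (one to two visits per week).
#' @param diameter_noise_sd caliper noise per reading, cm.
#' @param harvest_mass_noise_sd sd of the harvest-mass disturbance, g:
#'   late ripening variation plus scale error, i.e. the part of harvest mass
#'   not encoded in the growth trajectory.
#' @param n_calibration destructively measured fruits per cultivar for the
#'   density calibration.
#' @param growth_shape `"logistic"` (default) or `"cubic"` — the latter makes
#'   latent trajectories exactly cubic in thermal time, useful for
#'   verifying the fitting stage without approximation error.
#' @param seed integer; fixes every random draw in the simulation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(cultivars = default_cultivars(),
                       n_fruits = 450,
                       season_start = "2022-08-16", season_end = "2023-04-27",
                       anthesis_start = "2022-09-14",
                       anthesis_end = "2023-01-10",
                       temp_base = 19.5, temp_amplitude = 2.5,
                       temp_peak_doy = 213,
                       temp_jitter_sd = 1.5,
                       measurement_interval = 3.5,
                       diameter_noise_sd = 0.05,
                       harvest_mass_noise_sd = 13,
                       n_calibration = 450,
                       growth_shape = c("logistic", "cubic"),
                       seed = 1L) {
  growth_shape <- match.arg(growth_shape)
  if (n_fruits < 1L || measurement_interval < 1) {
    hc_abort("n_fruits >= 1 and measurement_interval >= 1 day required",
             "hc_config_error")
  }
  season_start <- as_date_strict(season_start)
  season_end <- as_date_strict(season_end)
  if (season_end <= season_start) {
    hc_abort("empty season", "hc_domain_error")
  }
  structure(list(cultivars = cultivars, n_fruits = n_fruits,
                 season_start = season_start, season_end = season_end,
                 anthesis_start = as_date_strict(anthesis_start),
                 anthesis_end = as_date_strict(anthesis_end),
                 temp_base = temp_base, temp_amplitude = temp_amplitude,
                 temp_peak_doy = temp_peak_doy,
                 temp_jitter_sd = temp_jitter_sd,
                 measurement_interval = measurement_interval,
                 diameter_noise_sd = diameter_noise_sd,
                 harvest_mass_noise_sd = harvest_mass_noise_sd,
                 n_calibration = n_calibration,
                 growth_shape = growth_shape,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Noise-free simulator configuration
#'
#' All measurement and biological shape noise switched off and the harvest
#' rule made deterministic: exact cubic latent trajectories, no caliper or
#' scale noise, no aspect/shape jitter, no temperature dependence of harvest
#' or final mass. Between-fruit mass variation (`mass_sd`) remains — it is
#' the signal the regression explains. Under this configuration anchor
#' masses are exactly proportional to harvest mass and the pipeline should
#' predict near perfectly.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_noiseless <- function(...) {
  cvs <- lapply(default_cultivars(), function(p) {
    p$aspect_sd <- 0
    p$midpoint_sd <- 0
    p$rate_sd <- 0
    p$harvest_temp_slope <- 0
    p$temp_penalty <- 0
    p
  })
  sim_config(cultivars = cvs, temp_jitter_sd = 0, diameter_noise_sd = 0,
             harvest_mass_noise_sd = 0, growth_shape = "cubic", ...)
}

# latent mass trajectory; vectorised over tau
latent_mass <- function(tau, M, midpoint, rate, shape) {
  if (shape == "cubic") {
    u <- pmin(tau / 1100, 1)
    M * (3 * u^2 - 2 * u^3)
  } else {
    M * stats::plogis(rate * (tau - midpoint))
  }
}

sim_temperature_draws <- function(config) {
  dates <- seq(config$season_start, config$season_end, by = 1)
  doy <- as.integer(format(dates, "%j"))
  path <- config$temp_base + config$temp_amplitude *
    cos(2 * pi * (doy - config$temp_peak_doy) / 365.25)
  temps <- path + rnorm(length(dates), 0, config$temp_jitter_sd)
  temperature_series(dates, temps)
}

#' Simulate the greenhouse temperature log
#'
#' Seasonal cosine path plus day-to-day Gaussian jitter; deterministic for a
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [temperature_series()].
#' @export
simulate_temperature <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, sim_temperature_draws(config))
}

draw_positive <- function(mean, sd, floor = 0) {
  if (sd == 0) {
    return(max(mean, floor + 1e-12))
  }
  repeat {
    x <- rnorm(1L, mean, sd)
    if (x > floor) {
      return(x)
    }
  }
}

#' Simulate one fruit
#'
#' Draws, in this order: aspect ratio, asymptotic mass `M`, growth midpoint,
#' growth rate, then per caliper visit a long- and a short-diameter reading
#' error, and finally the harvest scale error. Uses the caller's RNG state
#' (seed before calling, or use [simulate_cohort()]).
#'
#' @param params a [cultivar_params()].
#' @param clock a [thermal_clock()] for the fruit's anthesis date.
#' @param config a [sim_config()] (noise and cadence settings).
#' @return list with `measurements` (tibble of caliper visits) and `truth`
#'   (one-row tibble: latent and harvest quantities).
#' @export
simulate_fruit <- function(params, clock, config) {
  # harvest rule: degree-days target shifted by the mean temperature over
  # the (approximate) growth period
  t_h0 <- invert_thermal_time(clock, params$harvest_tau_base)
  tbar <- mean_temperature(clock, t_h0)
  tau_h <- params$harvest_tau_base +
    params$harvest_temp_slope * (tbar - params$temp_optimum)
  tau_h <- max(tau_h, params$growth_midpoint + 100)
  f_temp <- max(0.5, 1 - params$temp_penalty * (tbar - params$temp_optimum)^2)

  aspect <- draw_positive(params$aspect_mean, params$aspect_sd, floor = 1)
  M <- draw_positive(params$mass_mean * f_temp, params$mass_sd)
  midpoint <- if (params$midpoint_sd > 0) {
    rnorm(1L, params$growth_midpoint, params$midpoint_sd)
  } else {
    params$growth_midpoint
  }
  rate <- draw_positive(params$growth_rate, params$rate_sd,
                        floor = params$growth_rate / 2)

  # caliper visits every measurement_interval days from fruit set
  # (~50 degC d) until the first visit at or past the harvest threshold
  t_set <- invert_thermal_time(clock, 50)
  gaps <- if (abs(config$measurement_interval - round(config$measurement_interval)) < 1e-9) {
    rep(round(config$measurement_interval), 200L)
  } else {
    rep(c(floor(config$measurement_interval),
          ceiling(config$measurement_interval)), 100L)
  }
  visits <- t_set + c(0, cumsum(gaps))
  last_covered <- clock$series$date[nrow(clock$series)]
  visits <- visits[visits <= last_covered]
  tau_v <- cumulative_temperature(clock, visits)
  h_idx <- which(tau_v >= tau_h)
  if (length(h_idx) == 0L) {
    hc_abort("temperature series does not cover this fruit to harvest",
             "hc_coverage_error")
  }
  h_idx <- h_idx[1L]
  visits <- visits[seq_len(h_idx)]
  tau_v <- tau_v[seq_len(h_idx)]

  m_v <- latent_mass(tau_v, M, midpoint, rate, config$growth_shape)
  vol_v <- m_v / params$density
  s_true <- (6 * vol_v / (pi * aspect))^(1 / 3)
  l_true <- aspect * s_true
  l_obs <- pmax(l_true + rnorm(length(visits), 0, config$diameter_noise_sd), 0.05)
  s_obs <- pmax(s_true + rnorm(length(visits), 0, config$diameter_noise_sd), 0.05)

  # fruit is picked at the first visit past the threshold, but ripeness --
  # and hence the recorded mass -- is set by the threshold itself
  harvest_date <- visits[h_idx]
  m_h <- latent_mass(tau_h, M, midpoint, rate, config$growth_shape)
  harvest_mass <- if (config$harvest_mass_noise_sd > 0) {
    draw_positive(m_h, config$harvest_mass_noise_sd)
  } else {
    m_h
  }

  list(
    measurements = tibble::tibble(
      cultivar = params$name,
      anthesis_date = clock$anthesis,
      meas_date = visits,
      long_cm = l_obs,
      short_cm = s_obs,
      harvest_date = harvest_date,
      harvest_mass_g = harvest_mass
    ),
    truth = tibble::tibble(
      cultivar = params$name,
      anthesis_date = clock$anthesis,
      harvest_date = harvest_date,
      tau_harvest = tau_v[h_idx],
      tau_h_threshold = tau_h,
      mean_temp_c = mean_temperature(clock, harvest_date),
      asymptotic_mass_g = M,
      growth_midpoint = midpoint,
      growth_rate = rate,
      f_temp = f_temp,
      harvest_mass_g = harvest_mass
    )
  )
}

#' Simulate a full greenhouse cohort
#'
#' Generates, deterministically for the configured seed: the season's
#' temperature log; per cultivar `n_fruits` fruits with anthesis dates drawn
#' uniformly over the anthesis window, each followed through caliper visits
#' to harvest; and a density-calibration set of destructively measured
#' fruits sampled across growth stages. The emitted tables use the same
#' column layout the field-data readers consume.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort` list: `temperature` ([temperature_series()]),
#'   `measurements`, `calibration`, `truth` tibbles, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    series <- sim_temperature_draws(config)
    meas <- vector("list", 0L)
    truth <- vector("list", 0L)
    calib <- vector("list", 0L)
    fid <- 0L
    window <- as.numeric(config$anthesis_end - config$anthesis_start)
    for (params in config$cultivars) {
      anth <- config$anthesis_start +
        floor(runif(config$n_fruits, 0, window + 1))
      for (i in seq_len(config$n_fruits)) {
        fid <- fid + 1L
        clock <- thermal_clock(anth[i], series)
        fr <- simulate_fruit(params, clock, config)
        fr$measurements <- tibble::tibble(
          fruit_id = sprintf("F%05d", fid), fr$measurements)
        fr$truth <- tibble::tibble(fruit_id = sprintf("F%05d", fid), fr$truth)
        meas[[length(meas) + 1L]] <- fr$measurements
        truth[[length(truth) + 1L]] <- fr$truth
      }
      # density calibration: destructive single measurements across stages
      if (config$n_calibration > 0L) {
        aspect <- pmax(rnorm(config$n_calibration, params$aspect_mean,
                             params$aspect_sd), 1)
        Mc <- pmax(rnorm(config$n_calibration, params$mass_mean,
                         params$mass_sd), 1)
        midc <- rnorm(config$n_calibration, params$growth_midpoint,
                      params$midpoint_sd)
        ratec <- pmax(rnorm(config$n_calibration, params$growth_rate,
                            params$rate_sd), params$growth_rate / 2)
        tau_c <- runif(config$n_calibration, 150, 900)
        m_c <- latent_mass(tau_c, Mc, midc, ratec, config$growth_shape)
        vol_c <- m_c / params$density
        s_t <- (6 * vol_c / (pi * aspect))^(1 / 3)
        l_o <- pmax(aspect * s_t +
                      rnorm(config$n_calibration, 0, config$diameter_noise_sd),
                    0.05)
        s_o <- pmax(s_t +
                      rnorm(config$n_calibration, 0, config$diameter_noise_sd),
                    0.05)
        mass_o <- pmax(m_c + rnorm(config$n_calibration, 0,
                                   config$harvest_mass_noise_sd), 0.1)
        calib[[length(calib) + 1L]] <- tibble::tibble(
          cultivar = params$name,
          long_cm = l_o, short_cm = s_o,
          volume_cm3 = fruit_volume_index(pmax(l_o, s_o), pmin(l_o, s_o)),
          mass_g = mass_o)
      }
    }
    structure(list(temperature = series,
                   measurements = dplyr::bind_rows(meas),
                   calibration = dplyr::bind_rows(calib),
                   truth = dplyr::bind_rows(truth),
                   config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d fruits (%d cultivars), %d measurements, %d calibration pairs\n",
              nrow(x$truth), length(unique(x$truth$cultivar)),
              nrow(x$measurements), nrow(x$calibration)))
  invisible(x)
}
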
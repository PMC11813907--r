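#' Read a fruit-measurement CSV
#'
#' Expects `fruit_id, cultivar, anthesis_date, meas_date, long_cm, short_cm,
#' harvest_date, harvest_mass_g`; harvest fields may be blank for fruits not
#' yet harvested.
#'
#' @param path file path.
#' @return tibble of measurements with parsed dates.
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("fruit_id", "cultivar", "anthesis_date", "meas_date",
           "long_cm", "short_cm")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    hc_abort(paste("measurement CSV missing columns:",
                   paste(miss, collapse = ", ")), "hc_schema_error")
  }
  df$anthesis_date <- as_date_strict(df$anthesis_date, "anthesis_date")
  df$meas_date <- as_date_strict(df$meas_date, "meas_date")
  if ("harvest_date" %in% names(df)) {
    df$harvest_date <- as.Date(df$harvest_date)
  }
  if (!"harvest_mass_g" %in% names(df)) {
    df$harvest_mass_g <- NA_real_
  }
  tibble::as_tibble(df)
}

#' Write simulated cohort artifacts to CSV
#'
#' Emits `temperature.csv`, `measurements.csv` and `calibration.csv` in the
#' formats the corresponding readers consume; byte-identical across runs
#' with the same simulation seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_temperature_csv(cohort$temperature, file.path(dir, "temperature.csv"))
  m <- cohort$measurements
  m$anthesis_date <- format(m$anthesis_date)
  m$meas_date <- format(m$meas_date)
  m$harvest_date <- format(m$harvest_date)
  write.csv(m, file.path(dir, "measurements.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(cohort$calibration, file.path(dir, "calibration.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Pipeline configuration
#'
#' Settings for one end-to-end analysis. Either in-memory inputs (a
#' `sim_cohort`) or CSV paths can drive [run_pipeline()].
#'
#' @param scheme `"E500"` or `"E800"`.
#' @param cultivar restrict the analysis to one cultivar (`NULL` = all
#'   fruits pooled).
#' @param include_mean_temp add the mean temperature over the prediction
#'   period as an explanatory variable?
#' @param train_fraction train share of the random split (default 0.8).
#' @param split_seed,cv_seed integer seeds for the split and the CV folds.
#' @param lambda_grid ridge penalty grid.
#' @param cv_folds,cv_repeats repeated k-fold CV settings.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scheme = "E500", cultivar = NULL,
                            include_mean_temp = FALSE,
                            train_fraction = 0.8,
                            split_seed = 1L, cv_seed = NULL,
                            lambda_grid = c(0.01, 0.1, 1, 10, 100),
                            cv_folds = 10L, cv_repeats = 3L) {
  if (!scheme %in% c("E500", "E800")) {
    hc_abort(sprintf("unknown scheme '%s' (expected E500 or E800)", scheme),
             "hc_config_error")
  }
  structure(list(scheme = scheme, cultivar = cultivar,
                 include_mean_temp = include_mean_temp,
                 train_fraction = train_fraction,
                 split_seed = as.integer(split_seed),
                 cv_seed = as.integer(if (is.null(cv_seed)) split_seed + 1000L
                                      else cv_seed),
                 lambda_grid = lambda_grid,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `scheme`, `cultivar`, `include_mean_temp`,
#' `train_fraction`, `seed`, `lambda_grid`, `cv_folds`, `cv_repeats`, and
#' the input paths `temperature`, `measurements`, `calibration`.
#'
#' @param path YAML file.
#' @return list with `config` (a [pipeline_config()]) and `paths`.
#' @export
read_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    scheme = y$scheme %||% "E500",
    cultivar = y$cultivar,
    include_mean_temp = isTRUE(y$include_mean_temp),
    train_fraction = y$train_fraction %||% 0.8,
    split_seed = y$seed %||% 1L,
    lambda_grid = unlist(y$lambda_grid) %||% c(0.01, 0.1, 1, 10, 100),
    cv_folds = y$cv_folds %||% 10L,
    cv_repeats = y$cv_repeats %||% 3L
  )
  list(config = cfg,
       paths = y[intersect(c("temperature", "measurements", "calibration",
                             "output_dir"), names(y))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the harvest-size prediction pipeline
#'
#' End to end: cultivar density calibration, thermal-time placement, windowed
#' cubic growth curves with the scheme's r^2 gate, anchor features (optionally
#' plus mean temperature), a seeded 80/20 split, cross-validated ridge
#' regression, and MAPE/R^2/RMSE on the held-out fruits.
#'
#' @param cohort a [simulate_cohort()] result, or a list with elements
#'   `temperature` (a [temperature_series()]), `measurements` and
#'   `calibration` tibbles as produced by the CSV readers.
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, writes `anchors_<scheme>.csv`,
#'   `model_<scheme>.json` and `report_<scheme>.json` there.
#' @return list with `report` (an [eval_report()] row plus metadata),
#'   `model`, `lambda`, `anchors`, `counts`, `predictions`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_fruits = 60, seed = 7))
#' res <- run_pipeline(cohort, pipeline_config("E800", cultivar = "Zayda"))
#' res$report
#' }
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  scheme <- anchor_scheme(config$scheme)
  meas <- cohort$measurements
  calib <- cohort$calibration
  if (!is.null(config$cultivar)) {
    meas <- meas[meas$cultivar %in% config$cultivar, , drop = FALSE]
    calib <- calib[calib$cultivar %in% config$cultivar, , drop = FALSE]
    if (nrow(meas) == 0L) {
      hc_abort(sprintf("no measurements for cultivar '%s'", config$cultivar),
               "hc_config_error")
    }
  }

  dens <- lapply(split(calib, calib$cultivar), function(d) {
    calibrate_density(d$volume_cm3, d$mass_g)
  })

  anchors <- anchor_table(meas, cohort$temperature, dens, scheme)
  tbl <- build_feature_table(anchors,
                             include_mean_temp = config$include_mean_temp)
  parts <- split_train_test(tbl, config$train_fraction, config$split_seed)
  cv <- cv_select_lambda(parts$train, grid = config$lambda_grid,
                         k_folds = config$cv_folds,
                         repeats = config$cv_repeats,
                         seed = config$cv_seed)
  model <- fit_ridge(parts$train, lambda = cv$lambda)
  pred <- predict(model, parts$test)
  report <- eval_report(pred, parts$test$harvest_mass_g)
  report <- tibble::tibble(
    cultivar = if (is.null(config$cultivar)) "all" else config$cultivar,
    scheme = config$scheme,
    model = "ridge",
    include_mean_temp = config$include_mean_temp,
    lambda = cv$lambda,
    n_train = nrow(parts$train),
    report
  )

  counts <- attr(anchors, "counts")
  counts$excluded_no_harvest <-
    sum(anchors$qc_pass & is.na(anchors$harvest_mass_g))
  counts$n_model <- nrow(tbl)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(anchors,
              file.path(out_dir, sprintf("anchors_%s.csv", config$scheme)),
              row.names = FALSE, quote = FALSE)
    write_model_json(model,
                     file.path(out_dir, sprintf("model_%s.json", config$scheme)))
    jsonlite::write_json(as.list(report[1, ]),
                         file.path(out_dir,
                                   sprintf("report_%s.json", config$scheme)),
                         auto_unbox = TRUE, digits = NA)
  }

  list(report = report, model = model, lambda = cv$lambda,
       anchors = anchors, counts = counts,
       predictions = tibble::tibble(fruit_id = parts$test$fruit_id,
                                    predicted_g = pred,
                                    harvest_mass_g = parts$test$harvest_mass_g))
}
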
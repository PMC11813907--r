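#' Build a feature table from an anchor table
#'
#' Keeps fruits that passed the r^2 gate and have a recorded harvest mass,
#' sorts deterministically by `fruit_id`, and returns the regression table:
#' one `E_<anchor>` column per anchor mass, optionally the mean temperature
#' over the prediction period, and the harvest mass target.
#'
#' @param anchors an [anchor_table()] result (one scheme only).
#' @param include_mean_temp add `mean_temp_c` as a feature column?
#' @return tibble `fruit_id`, feature columns, `harvest_mass_g`.
#' @export
build_feature_table <- function(anchors, include_mean_temp = FALSE) {
  if (nrow(anchors) == 0L) {
    hc_abort("empty anchor table", "hc_insufficient_data")
  }
  if (length(unique(anchors$scheme)) > 1L) {
    hc_abort("anchor table mixes schemes; build one table per scheme",
             "hc_schema_error")
  }
  keep <- anchors$qc_pass & !is.na(anchors$harvest_mass_g)
  tbl <- anchors[keep, , drop = FALSE]
  if (nrow(tbl) == 0L) {
    hc_abort("no qc-passing fruits with harvest mass", "hc_insufficient_data")
  }
  tbl <- tbl[order(tbl$fruit_id), ]
  feat_cols <- grep("^E_", names(tbl), value = TRUE)
  if (include_mean_temp) feat_cols <- c(feat_cols, "mean_temp_c")
  out <- tbl[c("fruit_id", feat_cols, "harvest_mass_g")]
  tibble::as_tibble(out)
}

feature_matrix <- function(tbl) {
  feat <- setdiff(names(tbl), c("fruit_id", "harvest_mass_g"))
  as.matrix(tbl[feat])
}

#' Z-score normalizer fitted on training rows
#'
#' Stores per-feature means and sample standard deviations (denominator
#' `n - 1`). Test rows must be transformed with the training statistics;
#' refitting on test data would leak the evaluation set into the model.
#'
#' @param x numeric matrix or feature tibble (training rows only).
#' @return a `normalizer` with fields `means`, `sds`.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    hc_abort("z-score fit needs >= 2 training rows", "hc_insufficient_data")
  }
  means <- colMeans(x)
  sds <- apply(x, 2L, sd)
  bad <- which(sds == 0)
  if (length(bad)) {
    hc_abort(sprintf("zero-variance feature(s): %s",
                     paste(colnames(x)[bad], collapse = ", ")),
             "hc_degenerate_error")
  }
  structure(list(means = means, sds = sds), class = "normalizer")
}

#' Apply a fitted z-score normalizer
#'
#' @param norm a [zscore_fit()] result.
#' @param x matrix or feature tibble with the same columns.
#' @return matrix of standardized features.
#' @export
zscore_apply <- function(norm, x) {
  stopifnot(inherits(norm, "normalizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(norm$means)) {
    hc_abort("feature count does not match normalizer", "hc_schema_error")
  }
  sweep(sweep(x, 2L, norm$means, "-"), 2L, norm$sds, "/")
}

#' Random train/test split
#'
#' Deterministic given the seed; train size is `round(train_fraction * n)`.
#'
#' @param tbl feature table (rows are fruits).
#' @param train_fraction fraction for training, default 0.8.
#' @param seed integer RNG seed.
#' @return list with `train` and `test` tibbles (disjoint, union = input).
#' @export
split_train_test <- function(tbl, train_fraction = 0.8, seed = 1L) {
  n <- nrow(tbl)
  if (n < 5L) {
    hc_abort("need at least 5 rows to split", "hc_insufficient_data")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    hc_abort("train_fraction must lie in (0, 1)", "hc_config_error")
  }
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- round(train_fraction * n)
  list(train = tbl[sort(perm[seq_len(n_train)]), , drop = FALSE],
       test  = tbl[sort(perm[-seq_len(n_train)]), , drop = FALSE])
}

#' Ridge regression in closed form
#'
#' Solves `w = (Z'Z + lambda I)^-1 Z'y_c` on z-scored features `Z` with
#' centred targets `y_c`; the intercept (the training-mean harvest mass) is
#' never penalized and targets stay in grams. With `lambda = 0` this is
#' ordinary least squares.
#'
#' @param tbl training feature table from [build_feature_table()], or a
#'   numeric feature matrix (then `target` is required).
#' @param lambda regularization strength, `>= 0`.
#' @param target harvest masses in g (taken from `harvest_mass_g` when `tbl`
#'   is a feature table).
#' @return a `ridge_model`: `weights` (normalized space), `intercept` (g),
#'   `lambda`, `normalizer`, `schema` (feature names).
#' @examples
#' x <- tibble::tibble(fruit_id = 1:6, E_500 = c(1, 2, 3, 4, 5, 6),
#'                     harvest_mass_g = 2 * c(1, 2, 3, 4, 5, 6))
#' fit_ridge(x, lambda = 0)
#' @export
fit_ridge <- function(tbl, lambda = 0, target = NULL) {
  if (lambda < 0) {
    hc_abort("lambda must be non-negative", "hc_config_error")
  }
  if (is.data.frame(tbl)) {
    x <- feature_matrix(tbl)
    y <- tbl$harvest_mass_g
  } else {
    x <- as.matrix(tbl)
    y <- target
  }
  if (is.null(y) || length(y) != nrow(x)) {
    hc_abort("target must match the number of rows", "hc_schema_error")
  }
  norm <- zscore_fit(x)
  z <- zscore_apply(norm, x)
  a <- crossprod(z) + diag(lambda, ncol(z))
  w <- tryCatch(solve(a, crossprod(z, y - mean(y))),
                error = function(e) {
                  hc_abort(paste("singular system; features may be collinear.",
                                 "Use lambda > 0."),
                           "hc_degenerate_error")
                })
  structure(
    list(weights = stats::setNames(drop(w), colnames(x)),
         intercept = mean(y),
         lambda = lambda,
         normalizer = norm,
         schema = colnames(x)),
    class = "ridge_model"
  )
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> lambda = %g, intercept = %.1f g\n",
              x$lambda, x$intercept))
  print(round(x$weights, 3))
  invisible(x)
}

#' Predict harvest mass with a ridge model
#'
#' @param object a [fit_ridge()] model.
#' @param newdata feature table or matrix with the model's feature columns.
#' @param ... unused.
#' @return predicted harvest masses in g.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  if (!identical(colnames(x), object$schema)) {
    hc_abort("feature schema does not match the fitted model",
             "hc_schema_error")
  }
  z <- zscore_apply(object$normalizer, x)
  drop(object$intercept + z %*% object$weights)
}

#' Select lambda by repeated k-fold cross-validation
#'
#' For each grid value, repeated k-fold CV on the training rows: within every
#' fold the normalizer and ridge solution are refitted on the in-fold
#' training part, and R^2 is computed on the held-out part. The grid value
#' maximizing the mean CV R^2 wins; ties go to the larger lambda (more
#' shrinkage at equal fit). Deterministic given the seed.
#'
#' @param tbl training feature table.
#' @param grid candidate lambdas (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param k_folds number of folds (default 10).
#' @param repeats CV repeats with different fold assignments (default 3).
#' @param seed integer seed for fold assignment.
#' @return list with `lambda` (selected), `cv_r2` (named mean CV R^2 per grid
#'   value).
#' @export
cv_select_lambda <- function(tbl, grid = c(0.01, 0.1, 1, 10, 100),
                             k_folds = 10L, repeats = 3L, seed = 1L) {
  if (length(grid) == 0L) {
    hc_abort("lambda grid is empty", "hc_config_error")
  }
  x <- feature_matrix(tbl)
  y <- tbl$harvest_mass_g
  n <- nrow(x)
  if (n < k_folds) {
    hc_abort(sprintf("n = %d rows < %d folds", n, k_folds), "hc_config_error")
  }
  scores <- matrix(NA_real_, nrow = length(grid), ncol = repeats * k_folds)
  col <- 0L
  for (r in seq_len(repeats)) {
    folds <- withr::with_seed(seed + r - 1L,
                              sample(rep_len(seq_len(k_folds), n)))
    for (k in seq_len(k_folds)) {
      col <- col + 1L
      hold <- folds == k
      fit_part <- lapply(grid, function(l) {
        fit_ridge(x[!hold, , drop = FALSE], lambda = l, target = y[!hold])
      })
      for (g in seq_along(grid)) {
        pred <- predict(fit_part[[g]], x[hold, , drop = FALSE])
        scores[g, col] <- r_squared(pred, y[hold])
      }
    }
  }
  mean_r2 <- rowMeans(scores)
  best <- max(mean_r2)
  # ties (to numerical precision) break toward the larger lambda
  sel <- max(grid[mean_r2 >= best - 1e-12])
  list(lambda = sel, cv_r2 = stats::setNames(mean_r2, grid))
}

#' Fit a harvest-size regressor
#'
#' Common fit interface over the reference ridge implementation and optional
#' library-backed tree ensembles. Ridge is the reference model; tree methods
#' are plug-ins for comparison and require their packages to be installed.
#'
#' @param tbl training feature table.
#' @param method `"ridge"` (default) or `"random_forest"` (via ranger).
#' @param lambda ridge penalty (ignored by tree methods).
#' @param ... passed to the backend.
#' @return a model with a `predict()` method returning grams.
#' @export
fit_regressor <- function(tbl, method = c("ridge", "random_forest"),
                          lambda = 0, ...) {
  method <- match.arg(method)
  if (method == "ridge") {
    return(fit_ridge(tbl, lambda = lambda))
  }
  if (!requireNamespace("ranger", quietly = TRUE)) {
    hc_abort("method 'random_forest' needs the ranger package",
             "hc_config_error")
  }
  df <- as.data.frame(tbl[setdiff(names(tbl), "fruit_id")])
  fit <- ranger::ranger(harvest_mass_g ~ ., data = df, ...)
  structure(list(fit = fit, schema = setdiff(names(df), "harvest_mass_g")),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata[object$schema])
  predict(object$fit, data = df)$predictions
}

#' Persist a ridge model as JSON
#'
#' @param model a [fit_ridge()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "ridge_model"))
  obj <- list(model = "ridge",
              schema = model$schema,
              weights = unname(model$weights),
              intercept = model$intercept,
              lambda = model$lambda,
              normalizer = list(means = unname(model$normalizer$means),
                                sds = unname(model$normalizer$sds)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ridge model from JSON
#'
#' @param path a file written by [write_model_json()].
#' @return a `ridge_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$model, "ridge")) {
    hc_abort("not a ridge model file", "hc_schema_error")
  }
  norm <- structure(list(means = stats::setNames(obj$normalizer$means, obj$schema),
                         sds = stats::setNames(obj$normalizer$sds, obj$schema)),
                    class = "normalizer")
  structure(list(weights = stats::setNames(obj$weights, obj$schema),
                 intercept = obj$intercept,
                 lambda = obj$lambda,
                 normalizer = norm,
                 schema = obj$schema),
            class = "ridge_model")
}
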
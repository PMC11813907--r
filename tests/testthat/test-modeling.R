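make_table <- function(n = 40, k = 3, seed = 1, noise = 0) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * k, 10, 120), n, k,
                dimnames = list(NULL, paste0("E_", c(200, 300, 500)[seq_len(k)])))
    beta <- c(0.9, 0.4, 0.7)[seq_len(k)]
    y <- 40 + drop(x %*% beta) + rnorm(n, 0, noise)
    tibble::tibble(fruit_id = sprintf("F%03d", seq_len(n)),
                   as.data.frame(x), harvest_mass_g = y)
  })
}

test_that("feature tables keep gated fruits out and columns stable", {
  anchors <- tibble::tibble(
    fruit_id = sprintf("F%02d", 10:1),
    cultivar = "Zayda", scheme = "E500",
    E_200 = runif(10, 5, 20), E_300 = runif(10, 20, 50),
    E_500 = runif(10, 60, 120),
    mean_temp_c = runif(10, 17, 21),
    r2 = 0.99, qc_pass = c(rep(TRUE, 9), FALSE), extrapolated = FALSE,
    harvest_mass_g = runif(10, 120, 180)
  )
  tbl <- build_feature_table(anchors)
  expect_equal(nrow(tbl), 9L)
  expect_equal(names(tbl), c("fruit_id", "E_200", "E_300", "E_500",
                             "harvest_mass_g"))
  expect_equal(tbl$fruit_id, sort(tbl$fruit_id))

  with_t <- build_feature_table(anchors, include_mean_temp = TRUE)
  expect_equal(ncol(with_t), 6L)

  anchors$harvest_mass_g[1] <- NA
  expect_equal(nrow(build_feature_table(anchors)), 8L)

  mixed <- anchors
  mixed$scheme[1] <- "E800"
  expect_error(build_feature_table(mixed), class = "hc_schema_error")
  expect_error(build_feature_table(anchors[0, ]),
               class = "hc_insufficient_data")
})

test_that("z-score normalization uses training statistics only", {
  x <- matrix(c(1, 3, 10, 30), 2, 2, dimnames = list(NULL, c("a", "b")))
  norm <- zscore_fit(x)
  z <- zscore_apply(norm, x)
  # two points: symmetric around 0 with sample-sd scaling
  expect_equal(z[, "a"], c(-1, 1) / sqrt(2))
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))

  # applying to new rows uses the stored stats, not the new rows' own
  x_new <- matrix(c(100, 200, 5, 7), 2, 2, dimnames = list(NULL, c("a", "b")))
  z_new <- zscore_apply(norm, x_new)
  expect_equal(unname(z_new[1, "a"]), (100 - 2) / sqrt(2))

  # idempotence on already-fitted stats
  expect_equal(zscore_apply(zscore_fit(z), z), unname(z), ignore_attr = TRUE)

  bad <- matrix(c(1, 1, 2, 3), 2, 2, dimnames = list(NULL, c("flat", "ok")))
  err <- tryCatch(zscore_fit(bad), error = identity)
  expect_s3_class(err, "hc_degenerate_error")
  expect_match(conditionMessage(err), "flat")
})

test_that("train/test split is deterministic, disjoint and 80/20", {
  tbl <- make_table(100)
  sp <- split_train_test(tbl, 0.8, seed = 4)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  expect_length(intersect(sp$train$fruit_id, sp$test$fruit_id), 0L)
  expect_setequal(c(sp$train$fruit_id, sp$test$fruit_id), tbl$fruit_id)
  sp2 <- split_train_test(tbl, 0.8, seed = 4)
  expect_identical(sp$train$fruit_id, sp2$train$fruit_id)
  sp3 <- split_train_test(make_table(10), 0.8, seed = 1)
  expect_equal(nrow(sp3$train), 8L)
  expect_error(split_train_test(make_table(4), 0.8, 1),
               class = "hc_insufficient_data")
})

test_that("ridge at lambda 0 reproduces exact linear data and OLS", {
  tbl <- make_table(30, k = 1)
  tbl$harvest_mass_g <- 2 * tbl$E_200
  fit <- fit_ridge(tbl, lambda = 0)
  expect_equal(predict(fit, tbl), tbl$harvest_mass_g, tolerance = 1e-10)
  # raw-space slope 2, intercept 0
  probe <- tbl
  probe$E_200 <- probe$E_200 + 1
  expect_equal(predict(fit, probe) - predict(fit, tbl), rep(2, 30),
               tolerance = 1e-10)
})

test_that("ridge weights match hand closed form and an iterative oracle", {
  # 1-D closed form: w = sum(z*yc) / (sum(z^2) + lambda) on the
  # standardized feature
  tbl <- tibble::tibble(fruit_id = c("a", "b"), E_200 = c(1, -1),
                        harvest_mass_g = c(2, -2))
  fit <- fit_ridge(tbl, lambda = 2)
  z <- (c(1, -1) - 0) / sd(c(1, -1))
  expect_equal(unname(fit$weights), sum(z * c(2, -2)) / (sum(z^2) + 2))

  set.seed(31)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, 50, 20), n, k,
                dimnames = list(NULL, paste0("f", seq_len(k))))
    y <- drop(x %*% runif(k, -1, 2)) + rnorm(n, 0, 5)
    lambda <- sample(c(0, 0.5, 3, 25), 1)
    fit <- fit_ridge(x, lambda = lambda, target = y)
    z <- zscore_apply(fit$normalizer, x)
    oracle <- ridge_gradient_descent(z, y - mean(y), lambda)
    expect_equal(unname(fit$weights), oracle, tolerance = 1e-6)
    if (lambda == 0) {
      ols <- unname(coef(lm(y ~ z))[-1])
      expect_equal(unname(fit$weights), ols, tolerance = 1e-8)
    }
  }
})

test_that("ridge shrinkage is monotone in lambda", {
  tbl <- make_table(60, noise = 10, seed = 8)
  lambdas <- c(0, 0.1, 1, 10, 100, 1000)
  norms <- sapply(lambdas, function(l) {
    sqrt(sum(fit_ridge(tbl, lambda = l)$weights^2))
  })
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("collinear features at lambda 0 advise regularization", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  x[, 2] <- 2 * x[, 1]
  err <- tryCatch(fit_ridge(x, lambda = 0, target = rnorm(20)),
                  error = identity)
  expect_s3_class(err, "hc_degenerate_error")
  expect_match(conditionMessage(err), "lambda")
  expect_s3_class(fit_ridge(x, lambda = 1, target = rnorm(20)), "ridge_model")
})

test_that("prediction contracts: intercept at the mean, schema checks", {
  tbl <- make_table(40, noise = 5, seed = 2)
  fit <- fit_ridge(tbl, lambda = 1)
  mean_row <- matrix(fit$normalizer$means, 1,
                     dimnames = list(NULL, fit$schema))
  expect_equal(unname(predict(fit, mean_row)), fit$intercept)

  wrong <- matrix(1, 1, 2, dimnames = list(NULL, c("x", "y")))
  expect_error(predict(fit, wrong), class = "hc_schema_error")

  # hand matrix arithmetic on 3 rows
  feats <- as.matrix(tbl[c("E_200", "E_300", "E_500")])
  new <- feats[1:3, ]
  z <- (new - matrix(fit$normalizer$means, 3, 3, byrow = TRUE)) /
    matrix(fit$normalizer$sds, 3, 3, byrow = TRUE)
  expect_equal(predict(fit, new),
               fit$intercept + drop(z %*% fit$weights))

  # single-row prediction equals the same row inside a batch
  batch <- predict(fit, feats)
  expect_equal(unname(predict(fit, feats[5, , drop = FALSE])), batch[5])
})

test_that("cross-validated lambda selection is sane and deterministic", {
  tbl <- make_table(60)
  expect_equal(cv_select_lambda(tbl, grid = 7, seed = 1)$lambda, 7)

  # noiseless linear data needs no regularization
  sel <- cv_select_lambda(tbl, grid = c(0.01, 0.1, 1, 10, 100), seed = 3)
  expect_equal(sel$lambda, 0.01)

  perm <- tbl[withr::with_seed(5, sample(nrow(tbl))), ]
  perm <- perm[order(perm$fruit_id), ]
  sel2 <- cv_select_lambda(perm, grid = c(0.01, 0.1, 1, 10, 100), seed = 3)
  expect_equal(sel2$lambda, sel$lambda)

  expect_error(cv_select_lambda(make_table(8), k_folds = 10),
               class = "hc_config_error")
})

test_that("ridge model JSON round-trips", {
  tbl <- make_table(30, noise = 4, seed = 6)
  fit <- fit_ridge(tbl, lambda = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(predict(back, tbl), predict(fit, tbl), tolerance = 1e-12)
  expect_equal(back$lambda, 0.5)
})

test_that("tree-ensemble plug-in honours the common fit/predict interface", {
  skip_if_not_installed("ranger")
  tbl <- make_table(60, noise = 6, seed = 9)
  fit <- fit_regressor(tbl, method = "random_forest", num.trees = 50, seed = 1)
  pred <- predict(fit, tbl)
  expect_length(pred, 60L)
  expect_true(all(is.finite(pred)))
  # ridge is the default backend
  expect_s3_class(fit_regressor(tbl, lambda = 1), "ridge_model")
})
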
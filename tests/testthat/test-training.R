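# Small but real trainings: a fixed reduced-scale dataset shared across
# blocks keeps the suite fast while still exercising end-to-end descent.

shared_train_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_generator(seed = 31L, n_locations = 16L, n_years = 4L,
                             grid = c(16L, 16L), b = 16L)
      cache <<- generate_histogram_dataset(cfg, train_years = 2004:2006)
    }
    cache
  }
})

test_that("training reduces the max-loss on synthetic data", {
  data <- shared_train_data()
  train <- data[data$year < 2007L, ]
  fit <- train_yieldnet(train, training_config(iterations = 120L, seed = 2L))
  h <- fit$loss_history
  expect_length(h, 120L)
  expect_true(all(h >= 0))
  q <- length(h) %/% 4L
  expect_lt(mean(h[(length(h) - q):length(h)]), mean(h[1:q]))
})

test_that("training is reproducible given a seed", {
  data <- shared_train_data()
  train <- data[data$year < 2007L, ]
  cfg <- training_config(iterations = 30L, seed = 77L)
  f1 <- train_yieldnet(train, cfg)
  f2 <- train_yieldnet(train, cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(predict(f1, data), predict(f2, data))
})

test_that("loss config defaults to training-set means and rejects bad ones", {
  data <- shared_train_data()
  train <- data[data$year < 2007L, ]
  fit <- train_yieldnet(train, training_config(iterations = 2L, seed = 1L))
  expect_equal(fit$loss_cfg$corn_mean, mean(train$corn, na.rm = TRUE))
  expect_equal(fit$loss_cfg$soy_mean, mean(train$soy, na.rm = TRUE))
  expect_error(loss_config(0, 45), "positive")
  expect_error(train_yieldnet(train[0L, ], training_config(iterations = 1L)),
               "empty")
})

test_that("single-head variants train on and predict their crop only", {
  data <- shared_train_data()
  train <- data[data$year < 2007L, ]
  test <- data[data$year == 2007L, ]
  fit <- train_yieldnet(train, training_config(iterations = 25L, seed = 3L),
                        variant = "corn_only")
  p <- predict(fit, test)
  expect_named(p, "corn")
  expect_length(p$corn, nrow(test))
  expect_true(all(is.finite(p$corn)))
})

test_that("the max-loss gradient follows the attained crop term", {
  preds <- list(corn = c(100, 100), soy = c(40, 40))
  truths <- list(corn = c(110, 90), soy = c(50, 30))
  cfg <- loss_config(100, 40)
  lg <- yieldnet:::maxloss_and_grad(preds, truths, cfg)
  # soy term (10/40)^2 = 0.0625 beats corn (10/100)^2 = 0.01
  expect_equal(lg$loss, 0.0625)
  expect_equal(lg$dpreds$corn, c(0, 0))
  expect_equal(lg$dpreds$soy, -2 * c(10, -10) / 40 / (2 * 40))
  # ties break toward corn
  lg2 <- yieldnet:::maxloss_and_grad(
    list(corn = 100, soy = 40), list(corn = 110, soy = 44),
    loss_config(100, 40))
  expect_equal(lg2$loss, 0.01)
  expect_true(lg2$dpreds$corn != 0)
  expect_equal(lg2$dpreds$soy, 0)
  # unlabeled entries receive no gradient
  lg3 <- yieldnet:::maxloss_and_grad(
    list(corn = c(100, 100), soy = c(40, 40)),
    list(corn = c(120, NA), soy = c(NA, NA)), cfg)
  expect_equal(lg3$dpreds$corn[2L], 0)
})

test_that("classical baselines fit and predict on flattened features", {
  data <- shared_train_data()
  train <- data[data$year < 2007L, ]
  test <- data[data$year == 2007L, ]
  clim <- rmse_obs(test$corn, rep(mean(train$corn, na.rm = TRUE),
                                  nrow(test)))
  for (kind in c("ridge", "lasso", "rf", "rt")) {
    fit <- fit_classical(train, kind, "corn", seed = 5L)
    p <- predict(fit, test)
    expect_length(p, nrow(test))
    expect_true(all(is.finite(p)))
  }
  # the ridge solution actually shrinks toward but tracks the signal
  rp <- predict(fit_classical(train, "ridge", "corn"), test)
  expect_lt(rmse_obs(test$corn, rp), 1.5 * clim)
})

test_that("the closed-form ridge matches the penalized normal equations", {
  set.seed(44)
  n <- 20L; p <- 50L
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  lam <- 0.05
  f <- yieldnet:::fit_ridge_closed(X, y, lam)
  # primal solution of min ||y - a - Xb||^2 + lam ||b||^2
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  beta_primal <- solve(crossprod(Xc) + diag(lam, p), crossprod(Xc, yc))
  expect_equal(f$beta, as.vector(beta_primal), tolerance = 1e-8)
})

test_that("the forecast experiment trains only on years before the test year", {
  data <- shared_train_data()
  split <- split_spec(test_years = 2007L,
                      forecast_dates = c(oct = 296L))
  rep <- run_forecast_experiment(data, split, models = c("ridge"),
                                 cfg = training_config(iterations = 5L))
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep), 2L)            # one row per crop
  expect_true(all(rep$test_year == 2007L))
  n_lab <- c(corn = sum(is.finite(data$corn[data$year == 2007L])),
             soy = sum(is.finite(data$soy[data$year == 2007L])))
  expect_equal(rep$n, unname(n_lab[rep$crop]))
  expect_true(all(is.finite(rep$rmse)))
  # cartesian structure: dates x crops rows per model
  split2 <- split_spec(test_years = 2007L,
                       forecast_dates = c(jul = 204L, oct = 296L))
  rep2 <- run_forecast_experiment(data, split2, models = c("ridge", "rt"),
                                  cfg = training_config(iterations = 5L))
  expect_equal(nrow(rep2), 2L * 2L * 2L)
  # a test year before any training data must fail loudly
  expect_error(
    run_forecast_experiment(data, split_spec(test_years = 2004L,
                                             forecast_dates = c(oct = 296L)),
                            models = "ridge"),
    "no training entries")
})

test_that("a constant predictor's rmse equals the spread around the constant", {
  data <- shared_train_data()
  test <- data[data$year == 2007L, ]
  const <- 150
  r <- rmse(test$corn, rep(const, nrow(test)))
  expect_equal(r, sqrt(mean((test$corn - const)^2)))
})
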
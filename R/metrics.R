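#' @title Losses and evaluation metrics
#'
#' @description The training objective for the dual-head network is a
#' normalized max-loss: each crop's mean squared residual is scaled by the
#' square of that crop's average yield, so corn (~147 bu/acre) and soybean
#' (~45 bu/acre) errors live on a common scale, and the maximum of the two
#' terms is minimized so neither crop is neglected. Evaluation uses RMSE,
#' MAE, MAE as a percentage of the mean yield, and Pearson correlation.
#' @name metrics
NULL

#' Yield batch container
#'
#' Paired truths and predictions for the crops present in a batch; either
#' crop may be absent (length-0 vectors) but not both.
#'
#' @param corn_truth,corn_pred Numeric vectors of equal length (bu/acre).
#' @param soy_truth,soy_pred Numeric vectors of equal length (bu/acre).
#' @return A `yield_batch` object.
#' @export
yield_batch <- function(corn_truth = numeric(), corn_pred = numeric(),
                        soy_truth = numeric(), soy_pred = numeric()) {
  if (length(corn_truth) != length(corn_pred)) {
    stop("corn truth/pred lengths differ")
  }
  if (length(soy_truth) != length(soy_pred)) {
    stop("soy truth/pred lengths differ")
  }
  if (length(corn_truth) + length(soy_truth) == 0L) {
    stop("batch contains neither corn nor soybean records")
  }
  structure(list(corn_truth = as.numeric(corn_truth),
                 corn_pred = as.numeric(corn_pred),
                 soy_truth = as.numeric(soy_truth),
                 soy_pred = as.numeric(soy_pred)),
            class = "yield_batch")
}

#' Loss configuration: global average yields used for normalization
#'
#' The averages are computed once from the training set (never per batch,
#' which would make the scaling jitter at small batch sizes) and held fixed
#' through training.
#'
#' @param corn_mean,soy_mean Strictly positive average yields (bu/acre).
#' @return A `loss_config` object.
#' @export
loss_config <- function(corn_mean, soy_mean) {
  if (!is.finite(corn_mean) || corn_mean <= 0 ||
      !is.finite(soy_mean) || soy_mean <= 0) {
    stop("loss_config means must be strictly positive")
  }
  structure(list(corn_mean = corn_mean, soy_mean = soy_mean),
            class = "loss_config")
}

#' Normalized max-loss over the two crops
#'
#' `max( mean((Yc - Yc_hat)/corn_mean)^2 , mean((Ys - Ys_hat)/soy_mean)^2 )`.
#' If the batch contains a single crop, that crop's term alone is returned.
#'
#' @param batch A [yield_batch()].
#' @param cfg A [loss_config()].
#' @return Non-negative scalar loss.
#' @export
yieldnet_loss <- function(batch, cfg) {
  stopifnot(inherits(batch, "yield_batch"), inherits(cfg, "loss_config"))
  terms <- c()
  if (length(batch$corn_truth) > 0L) {
    terms <- c(terms, mean(((batch$corn_truth - batch$corn_pred) /
                              cfg$corn_mean)^2))
  }
  if (length(batch$soy_truth) > 0L) {
    terms <- c(terms, mean(((batch$soy_truth - batch$soy_pred) /
                              cfg$soy_mean)^2))
  }
  max(terms)
}

#' Mean squared (Euclidean) loss used by single-target baselines
#'
#' @param truth,pred Numeric vectors of equal positive length.
#' @return Mean squared residual.
#' @export
euclidean_loss <- function(truth, pred) {
  check_paired(truth, pred)
  mean((truth - pred)^2)
}

#' Root-mean-square error
#'
#' @inheritParams euclidean_loss
#' @return `sqrt(mean((truth - pred)^2))`.
#' @export
rmse <- function(truth, pred) {
  sqrt(euclidean_loss(truth, pred))
}

#' Mean absolute error
#'
#' @inheritParams euclidean_loss
#' @export
mae <- function(truth, pred) {
  check_paired(truth, pred)
  mean(abs(truth - pred))
}

#' Mean absolute error as a percentage of the mean observed yield
#'
#' @inheritParams euclidean_loss
#' @return `100 * mae / mean(truth)`.
#' @export
mae_percent <- function(truth, pred) {
  check_paired(truth, pred)
  m <- mean(truth)
  if (m <= 0) stop("mean(truth) must be positive for a percentage MAE")
  100 * mae(truth, pred) / m
}

#' Pearson product-moment correlation between truth and prediction
#'
#' @inheritParams euclidean_loss
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(truth, pred) {
  check_paired(truth, pred)
  if (length(truth) < 2L) stop("correlation requires at least 2 records")
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(truth, pred)
}

#' Per-record absolute error percentage
#'
#' @inheritParams euclidean_loss
#' @return Vector of `100 * |truth - pred| / truth`.
#' @export
error_percent_per_record <- function(truth, pred) {
  check_paired(truth, pred)
  if (any(truth == 0)) stop("truth entries must be nonzero")
  100 * abs(truth - pred) / truth
}

check_paired <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (length(truth) == 0L) stop("empty input")
  invisible(TRUE)
}
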
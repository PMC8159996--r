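# Central finite differences against the analytic backward pass, on a tiny
# two-head network covering every layer kind the full models use.

num_vs_analytic <- function(model, x, analytic, get, set, n_checks = 8L) {
  loss_of <- function(m) {
    fw <- yieldnet:::forward_full(m, x, training = TRUE)
    s <- sum(fw$preds[[1L]]^2)
    if (length(fw$preds) > 1L) s <- s + 2 * sum(fw$preds[[2L]]^2)
    s
  }
  idx <- sample(length(analytic), min(n_checks, length(analytic)))
  rel <- vapply(idx, function(i) {
    v <- get(model)
    eps <- 1e-5
    vp <- v; vp[i] <- v[i] + eps
    vm <- v; vm[i] <- v[i] - eps
    g <- (loss_of(set(model, vp)) - loss_of(set(model, vm))) / (2 * eps)
    abs(g - analytic[i]) / max(1e-4, abs(g) + abs(analytic[i]))
  }, numeric(1L))
  max(rel)
}

test_that("analytic gradients match finite differences for every layer kind", {
  set.seed(42)
  spec <- tiny_dual_spec()
  m <- build_model(spec, seed = 3L)
  x <- yieldnet:::batch_to_engine(array(rnorm(4 * 9 * 10 * 3),
                                        c(4, 9, 10, 3)), spec)
  fw <- yieldnet:::forward_full(m, x, training = TRUE)
  gr <- yieldnet:::backward_full(fw$model, fw,
                                 list(corn = 2 * fw$preds$corn,
                                      soy = 4 * fw$preds$soy))
  cases <- list(
    list(gr$backbone[[1L]]$W,
         function(m) m$params$backbone[[1L]]$W,
         function(m, v) { m$params$backbone[[1L]]$W[] <- v; m }),
    list(gr$backbone[[1L]]$gamma,
         function(m) m$params$backbone[[1L]]$gamma,
         function(m, v) { m$params$backbone[[1L]]$gamma <- v; m }),
    list(gr$backbone[[2L]]$beta,
         function(m) m$params$backbone[[2L]]$beta,
         function(m, v) { m$params$backbone[[2L]]$beta <- v; m }),
    list(gr$heads$corn[[1L]]$W,
         function(m) m$params$heads$corn[[1L]]$W,
         function(m, v) { m$params$heads$corn[[1L]]$W[] <- v; m }),
    list(gr$heads$corn[[3L]]$W,
         function(m) m$params$heads$corn[[3L]]$W,
         function(m, v) { m$params$heads$corn[[3L]]$W[] <- v; m }),
    list(gr$heads$soy[[2L]]$W,
         function(m) m$params$heads$soy[[2L]]$W,
         function(m, v) { m$params$heads$soy[[2L]]$W[] <- v; m }),
    list(gr$heads$soy[[2L]]$gamma,
         function(m) m$params$heads$soy[[2L]]$gamma,
         function(m, v) { m$params$heads$soy[[2L]]$gamma <- v; m }),
    list(gr$heads$corn[[4L]]$b,
         function(m) m$params$heads$corn[[4L]]$b,
         function(m, v) { m$params$heads$corn[[4L]]$b <- v; m })
  )
  for (cs in cases) {
    expect_lt(num_vs_analytic(m, x, cs[[1L]], cs[[2L]], cs[[3L]]), 1e-5)
  }
})

test_that("3-d convolution and max pooling gradients are exact too", {
  set.seed(17)
  spec <- yieldnet:::new_architecture_spec(
    "tiny3", input_shape = c(6L, 6L, 4L), backbone = list(),
    heads = list(yield = list(
      yieldnet:::conv3d_layer(3L, c(3L, 3L, 1L)),
      yieldnet:::maxpool3d_layer(c(2L, 2L, 2L)),
      yieldnet:::flatten_layer(),
      yieldnet:::fc_layer(5L),
      yieldnet:::output_linear_layer()
    )), input_kind = "conv3d")
  m <- build_model(spec, seed = 5L)
  x <- yieldnet:::batch_to_engine(array(rnorm(3 * 6 * 6 * 4),
                                        c(3, 6, 6, 4)), spec)
  fw <- yieldnet:::forward_full(m, x, training = TRUE)
  gr <- yieldnet:::backward_full(fw$model, fw,
                                 list(yield = 2 * fw$preds$yield))
  expect_lt(num_vs_analytic(m, x, gr$heads$yield[[1L]]$W,
                            function(m) m$params$heads$yield[[1L]]$W,
                            function(m, v) {
                              m$params$heads$yield[[1L]]$W[] <- v; m
                            }), 1e-5)
  expect_lt(num_vs_analytic(m, x, gr$heads$yield[[4L]]$W,
                            function(m) m$params$heads$yield[[4L]]$W,
                            function(m, v) {
                              m$params$heads$yield[[4L]]$W[] <- v; m
                            }), 1e-5)
})

test_that("construction is seed-reproducible and inference deterministic", {
  m1 <- build_yieldnet(seed = 9L)
  m2 <- build_yieldnet(seed = 9L)
  expect_identical(m1$params, m2$params)
  m3 <- build_yieldnet(seed = 10L)
  expect_false(identical(m1$params$backbone[[1L]]$W,
                         m3$params$backbone[[1L]]$W))
  x <- array(runif(4 * 30 * 32 * 9), c(4, 30, 32, 9))
  expect_identical(forward(m1, x), forward(m1, x))
  # building a model does not disturb the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(build_yieldnet(seed = 1L)); b <- runif(1)
  expect_identical(a, b)
})

test_that("xavier initial weights have the variance their fan dictates", {
  m <- build_yieldnet(seed = 4L)
  W <- m$params$backbone[[1L]]$W
  lim <- sqrt(6 / (49 * 9 + 49 * 48))
  expect_true(all(abs(W) <= lim))
  expect_gt(max(abs(W)), 0.8 * lim)
  expect_lt(abs(mean(W)), lim / 20)
})

test_that("batch-norm inference uses running statistics consistently", {
  set.seed(6)
  spec <- tiny_dual_spec()
  m <- build_model(spec, seed = 2L)
  x <- yieldnet:::batch_to_engine(array(rnorm(8 * 9 * 10 * 3),
                                        c(8, 9, 10, 3)), spec)
  # training-mode passes update the running statistics
  before <- m$params$backbone[[1L]]$rmean
  fw <- yieldnet:::forward_full(m, x, training = TRUE)
  after <- fw$model$params$backbone[[1L]]$rmean
  expect_false(identical(before, after))
  # inference passes do not
  fw2 <- yieldnet:::forward_full(fw$model, x, training = FALSE)
  expect_identical(fw2$model$params$backbone[[1L]]$rmean, after)
})
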
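#' @title Numerical engine: forward and backward passes
#'
#' @description A compact CNN engine in vectorised base R. Convolutions are
#' computed by im2col gathers followed by BLAS matrix multiplies; the gather
#' index tables are precomputed per layer when a model is built, so each
#' training iteration reduces to a handful of large indexing and matmul
#' operations. Activations live in channel-major layout: a feature map is a
#' `(channels, positions * batch)` matrix, which makes per-channel
#' batch-norm statistics plain row reductions and avoids array transposes
#' entirely. Gradients of every layer kind are verified against central
#' finite differences in the test suite.
#' @name engine
NULL

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# ---- im2col index machinery ------------------------------------------------

# Linear gather indices into the padded spatial volume.
# sp: padded spatial dims; k: kernel dims; st: strides; o: output dims.
# Returns a K x P integer matrix (K = prod(k) kernel offsets, P = prod(o)
# output positions), kernel offsets and output positions both column-major.
build_gather_idx <- function(sp, k, st, o) {
  nd <- length(sp)
  kgrid <- as.matrix(expand.grid(lapply(k, seq_len)))
  ogrid <- as.matrix(expand.grid(lapply(o, seq_len)))
  mult <- cumprod(c(1, sp[-nd]))
  koff <- as.vector((kgrid - 1) %*% mult)
  obase <- as.vector((ogrid - 1) %*% (mult * st))
  idx <- outer(koff, obase, `+`) + 1
  matrix(as.integer(idx), nrow = length(koff))
}

# Expand spatial gather indices to row indices of a channel-major
# (cin * Psp, N) matrix: row = c + (pos - 1) * cin for c in 1..cin.
expand_channel_rows <- function(idxvec, cin) {
  as.vector(outer(seq_len(cin), (idxvec - 1L) * cin, `+`))
}

# Zero-pad the spatial block of a channel-major (cin, spatial..., N) array.
pad_spatial <- function(x, cin, s, lo, hi, N, value = 0) {
  if (all(lo == 0L) && all(hi == 0L)) {
    dim(x) <- c(cin * prod(s), N)
    return(x)
  }
  dim(x) <- c(cin, s, N)
  nd <- length(s)
  sp <- s + lo + hi
  out <- array(value, c(cin, sp, N))
  idx <- c(list(seq_len(cin)),
           lapply(seq_len(nd), function(i) seq.int(lo[i] + 1L, lo[i] + s[i])),
           list(seq_len(N)))
  out <- do.call(`[<-`, c(list(out), idx, list(value = x)))
  dim(out) <- c(cin * prod(sp), N)
  out
}

unpad_spatial <- function(x, cin, s, lo, hi, N) {
  if (all(lo == 0L) && all(hi == 0L)) return(x)
  sp <- s + lo + hi
  dim(x) <- c(cin, sp, N)
  nd <- length(s)
  idx <- c(list(seq_len(cin)),
           lapply(seq_len(nd), function(i) seq.int(lo[i] + 1L, lo[i] + s[i])),
           list(seq_len(N)))
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  dim(out) <- c(cin * prod(s), N)
  out
}

# ---- layer planning --------------------------------------------------------

# A "plan" augments a layer_spec with everything shape-dependent: padding
# amounts, gather indices, and in/out dimensions.
plan_layer <- function(layer, shape) {
  kind <- layer$kind
  if (kind %in% c("conv2d", "conv3d", "maxpool3d")) {
    s <- shape$spatial
    k <- layer$filter_shape
    st <- layer$stride
    if (layer$padding == "same") {
      p <- same_padding(s, k, st)
      lo <- p$lo; hi <- p$hi
    } else {
      lo <- hi <- rep(0L, length(s))
    }
    o <- conv_out_size(s, k, st, layer$padding)
    sp <- s + lo + hi
    idx <- build_gather_idx(sp, k, st, o)
    cin <- shape$channels
    cout <- if (kind == "maxpool3d") cin else layer$units_or_filters
    rows <- expand_channel_rows(as.vector(idx), cin)
    # map padded spatial positions to unpadded ones (0 = zero padding), so
    # the conv path can gather/scatter without materialising padded arrays
    interior <- array(0L, dim = sp)
    slice <- lapply(seq_along(s), function(i) seq.int(lo[i] + 1L, lo[i] + s[i]))
    interior <- do.call(`[<-`, c(list(interior), slice,
                                 list(value = array(seq_len(prod(s)),
                                                    dim = s))))
    spat <- as.vector(interior)[as.vector(idx)]
    base <- (spat - 1L) * cin
    gidx <- outer(seq_len(cin), base, `+`)
    gidx[, spat == 0L] <- 0L
    plan <- c(layer, list(
      in_spatial = s, pad_lo = lo, pad_hi = hi, padded_spatial = sp,
      out_spatial = o, idx = idx, rows = rows, urows = sort(unique(rows)),
      gidx = as.integer(gidx),
      K = nrow(idx), P = ncol(idx), cin = cin, cout = cout
    ))
    list(plan = plan, shape = list(spatial = o, channels = cout))
  } else if (kind == "flatten") {
    D <- prod(shape$spatial) * shape$channels
    plan <- c(layer, list(in_spatial = shape$spatial, cin = shape$channels,
                          D = D))
    list(plan = plan, shape = list(flat = D))
  } else {
    din <- if (!is.null(shape$flat)) shape$flat else {
      prod(shape$spatial) * shape$channels
    }
    plan <- c(layer, list(din = din, dout = layer$units_or_filters))
    list(plan = plan, shape = list(flat = layer$units_or_filters))
  }
}

plan_block <- function(layers, shape) {
  plans <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    pl <- plan_layer(layers[[i]], shape)
    plans[[i]] <- pl$plan
    shape <- pl$shape
  }
  list(plans = plans, out_shape = shape)
}

# ---- initialization --------------------------------------------------------

xavier_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

init_layer_params <- function(plan) {
  kind <- plan$kind
  if (kind %in% c("conv2d", "conv3d")) {
    K <- plan$K
    W <- matrix(xavier_uniform(K * plan$cin, K * plan$cout,
                               K * plan$cin * plan$cout),
                nrow = K * plan$cin, ncol = plan$cout)
    par <- list(W = W, b = numeric(plan$cout))
    if (isTRUE(plan$batch_norm)) {
      par$gamma <- rep(1, plan$cout)
      par$beta <- numeric(plan$cout)
      par$rmean <- numeric(plan$cout)
      par$rvar <- rep(1, plan$cout)
    }
    par
  } else if (kind %in% c("fully_connected", "output_linear")) {
    W <- matrix(xavier_uniform(plan$din, plan$dout, plan$din * plan$dout),
                nrow = plan$din, ncol = plan$dout)
    par <- list(W = W, b = numeric(plan$dout))
    if (isTRUE(plan$batch_norm)) {
      par$gamma <- rep(1, plan$dout)
      par$beta <- numeric(plan$dout)
      par$rmean <- numeric(plan$dout)
      par$rvar <- rep(1, plan$dout)
    }
    par
  } else {
    list()
  }
}

# ---- batch norm ------------------------------------------------------------

# z is channel-major (C, M): one row per channel; statistics pool over all
# M = positions * batch columns. Vector-matrix arithmetic recycles down
# rows, i.e. per channel, which is exactly the broadcast batch norm needs.
bn_forward <- function(z, par, training) {
  if (training) {
    mu <- rowMeans(z)
    v <- pmax(rowMeans(z * z) - mu * mu, 0)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- (z - mu) * istd
    par$rmean <- BN_MOMENTUM * par$rmean + (1 - BN_MOMENTUM) * mu
    par$rvar <- BN_MOMENTUM * par$rvar + (1 - BN_MOMENTUM) * v
    list(y = par$gamma * xhat + par$beta,
         cache = list(xhat = xhat, istd = istd), par = par)
  } else {
    istd <- 1 / sqrt(par$rvar + BN_EPS)
    scale <- par$gamma * istd
    list(y = scale * z + (par$beta - par$rmean * scale), cache = NULL,
         par = par)
  }
}

bn_backward <- function(dy, par, cache) {
  xhat <- cache$xhat
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * par$gamma
  s1 <- rowMeans(dxhat)
  s2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - s1 - xhat * s2) * cache$istd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- layer forward/backward ------------------------------------------------

# x: channel-major (cin * prod(in_spatial), N)
conv_forward <- function(x, plan, par, training) {
  N <- ncol(x)
  cols <- gather_cols(x, plan$gidx)              # (cin*K*P, N), cin fastest
  dim(cols) <- c(plan$cin * plan$K, plan$P * N)
  z <- crossprod(par$W, cols) + par$b            # (F, P*N), row-recycled bias
  cache <- list(cols = if (training) cols else NULL, N = N)
  if (isTRUE(plan$batch_norm)) {
    bn <- bn_forward(z, par, training)
    z <- bn$y
    par <- bn$par
    cache$bn <- bn$cache
  }
  if (identical(plan$activation, "relu")) {
    mask <- z > 0
    z <- z * mask
    cache$mask <- if (training) mask else NULL
  }
  dim(z) <- c(plan$cout * plan$P, N)
  list(y = z, cache = cache, par = par)
}

conv_backward <- function(dy, plan, par, cache) {
  N <- cache$N
  dim(dy) <- c(plan$cout, plan$P * N)
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  grads <- list()
  if (isTRUE(plan$batch_norm)) {
    bb <- bn_backward(dy, par, cache$bn)
    dy <- bb$dx
    grads$gamma <- bb$dgamma
    grads$beta <- bb$dbeta
  }
  grads$b <- rowSums(dy)
  grads$W <- tcrossprod(cache$cols, dy)          # (cin*K, F)
  dcols <- par$W %*% dy                          # (cin*K, P*N)
  dim(dcols) <- c(plan$cin * plan$K * plan$P, N)
  dx <- scatter_add(dcols, plan$gidx, plan$cin * prod(plan$in_spatial))
  list(dx = dx, grads = grads)
}

maxpool_forward <- function(x, plan, par, training) {
  N <- ncol(x)
  xp <- pad_spatial(x, plan$cin, plan$in_spatial, plan$pad_lo, plan$pad_hi, N,
                    value = -Inf)
  cols <- xp[plan$rows, , drop = FALSE]          # (cin*K*P, N)
  dim(cols) <- c(plan$cin, plan$K, plan$P * N)
  best <- cols[, 1L, ]
  arg <- matrix(1L, plan$cin, plan$P * N)
  for (k in seq_len(plan$K)[-1L]) {
    ck <- cols[, k, ]
    upd <- ck > best
    best[upd] <- ck[upd]
    arg[upd] <- k
  }
  dim(best) <- c(plan$cin * plan$P, N)
  list(y = best, cache = list(arg = if (training) arg else NULL, N = N),
       par = par)
}

maxpool_backward <- function(dy, plan, par, cache) {
  N <- cache$N
  cin <- plan$cin
  P <- plan$P
  c_vec <- rep.int(seq_len(cin), P * N)
  p_vec <- rep(rep(seq_len(P), each = cin), N)
  n_vec <- rep(seq_len(N), each = cin * P)
  pos <- plan$idx[cbind(as.vector(cache$arg), p_vec)]
  rows <- c_vec + (pos - 1L) * cin
  dxp <- matrix(0, cin * prod(plan$padded_spatial), N)
  # pooling windows are disjoint (stride = pool size), so plain assignment
  # cannot collide within a column
  dxp[cbind(rows, n_vec)] <- as.vector(dy)
  dx <- unpad_spatial(dxp, cin, plan$in_spatial, plan$pad_lo, plan$pad_hi, N)
  list(dx = dx, grads = list())
}

fc_forward <- function(x, plan, par, training) {
  z <- crossprod(par$W, x) + par$b               # (dout, N)
  cache <- list(x = if (training) x else NULL, N = ncol(x))
  if (isTRUE(plan$batch_norm)) {
    bn <- bn_forward(z, par, training)
    z <- bn$y
    par <- bn$par
    cache$bn <- bn$cache
  }
  if (identical(plan$activation, "relu")) {
    mask <- z > 0
    z <- z * mask
    cache$mask <- if (training) mask else NULL
  }
  list(y = z, cache = cache, par = par)
}

fc_backward <- function(dy, plan, par, cache) {
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  grads <- list()
  if (isTRUE(plan$batch_norm)) {
    bb <- bn_backward(dy, par, cache$bn)
    dy <- bb$dx
    grads$gamma <- bb$dgamma
    grads$beta <- bb$dbeta
  }
  grads$b <- rowSums(dy)
  grads$W <- tcrossprod(cache$x, dy)             # (din, dout)
  dx <- par$W %*% dy                             # (din, N)
  list(dx = dx, grads = grads)
}

# channel-major (cin, P, N) -> (cin*P, N): already contiguous, a no-op view
flatten_forward <- function(x, plan, par, training) {
  list(y = x, cache = list(N = ncol(x)), par = par)
}

flatten_backward <- function(dy, plan, par, cache) {
  list(dx = dy, grads = list())
}

layer_forward <- function(x, plan, par, training) {
  switch(plan$kind,
    conv2d = ,
    conv3d = conv_forward(x, plan, par, training),
    maxpool3d = maxpool_forward(x, plan, par, training),
    flatten = flatten_forward(x, plan, par, training),
    fully_connected = ,
    output_linear = fc_forward(x, plan, par, training),
    stop("unknown layer kind: ", plan$kind)
  )
}

layer_backward <- function(dy, plan, par, cache) {
  switch(plan$kind,
    conv2d = ,
    conv3d = conv_backward(dy, plan, par, cache),
    maxpool3d = maxpool_backward(dy, plan, par, cache),
    flatten = flatten_backward(dy, plan, par, cache),
    fully_connected = ,
    output_linear = fc_backward(dy, plan, par, cache),
    stop("unknown layer kind: ", plan$kind)
  )
}

forward_block <- function(plans, params, x, training) {
  caches <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    fw <- layer_forward(x, plans[[i]], params[[i]], training)
    x <- fw$y
    caches[[i]] <- fw$cache
    params[[i]] <- fw$par
  }
  list(out = x, caches = caches, params = params)
}

backward_block <- function(plans, params, caches, dy) {
  grads <- vector("list", length(plans))
  for (i in rev(seq_along(plans))) {
    bw <- layer_backward(dy, plans[[i]], params[[i]], caches[[i]])
    dy <- bw$dx
    grads[[i]] <- bw$grads
  }
  list(dx = dy, grads = grads)
}

# ---- model construction ----------------------------------------------------

#' Build a model from an architecture specification
#'
#' Plans every layer (shape propagation, padding, im2col index tables) and
#' draws Xavier-uniform initial weights from the given seed, so the same
#' seed always yields bit-identical initial parameters. The caller's RNG
#' state is left untouched.
#'
#' @param spec An `architecture_spec`.
#' @param seed Integer RNG seed for initialization.
#' @return A `yieldnet_model` handle.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  shape0 <- input_shape_of(spec)
  bb <- plan_block(spec$backbone, shape0)
  head_plans <- lapply(spec$heads, function(h) plan_block(h, bb$out_shape))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  params <- list(
    backbone = lapply(bb$plans, init_layer_params),
    heads = lapply(head_plans, function(hp) lapply(hp$plans, init_layer_params))
  )
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(
    spec = spec, seed = as.integer(seed),
    plans = list(backbone = bb$plans,
                 heads = lapply(head_plans, `[[`, "plans")),
    params = params
  ), class = "yieldnet_model")
}

#' @export
print.yieldnet_model <- function(x, ...) {
  cat(sprintf("<yieldnet_model '%s': %s parameters, heads: %s>\n",
              x$spec$name,
              format(n_parameters(x), big.mark = ","),
              paste(names(x$spec$heads), collapse = ", ")))
  invisible(x)
}

#' Build the dual-head yield network (or a single-head ablation variant)
#'
#' @inheritParams yieldnet_spec
#' @param seed Integer seed for Xavier initialization.
#' @return A `yieldnet_model`.
#' @export
build_yieldnet <- function(input_shape = c(30L, 32L, 9L),
                           variant = c("dual", "corn_only", "soy_only"),
                           seed = 1L) {
  build_model(yieldnet_spec(input_shape, match.arg(variant)), seed)
}

#' Build the deep feed-forward baseline
#'
#' @inheritParams dfnn_spec
#' @param seed Integer seed for Xavier initialization.
#' @return A `yieldnet_model`.
#' @export
build_dfnn <- function(input_dim = 30L * 32L * 9L, seed = 1L) {
  build_model(dfnn_spec(input_dim), seed)
}

#' Build the 3-D CNN baseline
#'
#' @inheritParams cnn3d_spec
#' @param seed Integer seed for Xavier initialization.
#' @return A `yieldnet_model`.
#' @export
build_3dcnn <- function(input_shape = c(30L, 32L, 9L), seed = 1L) {
  build_model(cnn3d_spec(input_shape), seed)
}

#' Number of trainable parameters held by a model
#'
#' Sums the elements of every weight, bias, and batch-norm scale/shift
#' array (running statistics excluded). Agrees with [count_parameters()]
#' on the model's spec.
#'
#' @param model A `yieldnet_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "yieldnet_model"))
  count_one <- function(par) {
    sum(vapply(par[names(par) %in% c("W", "b", "gamma", "beta")], length,
               integer(1L)))
  }
  sum(vapply(model$params$backbone, count_one, integer(1L))) +
    sum(vapply(model$params$heads,
               function(h) sum(vapply(h, count_one, integer(1L))),
               integer(1L)))
}

# convert an n x T x b x d batch (or list of histogram tensors) to the
# engine's channel-major layout
batch_to_engine <- function(batch, spec) {
  if (is.list(batch) && !is.array(batch)) {
    batch <- abind_tensors(batch)
  }
  stopifnot(is.array(batch), length(dim(batch)) == 4L)
  n <- dim(batch)[1L]
  if (!identical(as.integer(dim(batch)[-1L]),
                 as.integer(if (spec$input_kind == "flat") {
                   dim(batch)[-1L]
                 } else spec$input_shape))) {
    stop("batch shape (", paste(dim(batch)[-1L], collapse = "x"),
         ") does not match model input (",
         paste(spec$input_shape, collapse = "x"), ")")
  }
  if (spec$input_kind == "conv2d") {
    x <- aperm(batch, c(4L, 2L, 3L, 1L))         # (d, T, b, n)
    dim(x) <- c(dim(batch)[4L] * dim(batch)[2L] * dim(batch)[3L], n)
  } else if (spec$input_kind == "conv3d") {
    x <- aperm(batch, c(2L, 3L, 4L, 1L))         # (T, b, d, n), 1 channel
    dim(x) <- c(prod(dim(batch)[2:4]), n)
  } else {
    x <- aperm(batch, c(2L, 3L, 4L, 1L))
    dim(x) <- c(prod(dim(batch)[2:4]), n)
  }
  x
}

# stack a list of histogram_tensor (or plain arrays) into n x T x b x d
abind_tensors <- function(tensors) {
  arrs <- lapply(tensors, function(h) {
    if (inherits(h, "histogram_tensor")) h$values else h
  })
  d3 <- dim(arrs[[1L]])
  out <- array(0, dim = c(length(arrs), d3))
  for (i in seq_along(arrs)) out[i, , , ] <- arrs[[i]]
  out
}

#' Forward pass: predict yields for a batch of histogram tensors
#'
#' @param model A `yieldnet_model`.
#' @param batch Either an `n x T x b x d` array or a list of
#'   `histogram_tensor` objects.
#' @param training Use batch statistics (`TRUE`, training mode) or running
#'   statistics (`FALSE`, deterministic inference) in batch normalization.
#' @return Named list with one numeric vector of length `n` per head.
#' @export
forward <- function(model, batch, training = FALSE) {
  stopifnot(inherits(model, "yieldnet_model"))
  x <- batch_to_engine(batch, model$spec)
  fw <- forward_full(model, x, training)
  fw$preds
}

# full forward keeping caches (used by the trainer)
forward_full <- function(model, x, training) {
  bb <- forward_block(model$plans$backbone, model$params$backbone, x, training)
  preds <- list()
  head_caches <- list()
  for (hn in names(model$plans$heads)) {
    hf <- forward_block(model$plans$heads[[hn]], model$params$heads[[hn]],
                        bb$out, training)
    preds[[hn]] <- as.vector(hf$out)
    head_caches[[hn]] <- hf$caches
    model$params$heads[[hn]] <- hf$params
  }
  model$params$backbone <- bb$params
  list(preds = preds, bb_caches = bb$caches, head_caches = head_caches,
       model = model)
}

# backward through heads and backbone given per-head output gradients
# (each a vector of length N); returns grads mirroring the param structure
backward_full <- function(model, fw, dpreds) {
  dbb <- NULL
  head_grads <- list()
  for (hn in names(model$plans$heads)) {
    dy <- matrix(dpreds[[hn]], nrow = 1L)
    bw <- backward_block(model$plans$heads[[hn]], model$params$heads[[hn]],
                         fw$head_caches[[hn]], dy)
    head_grads[[hn]] <- bw$grads
    dbb <- if (is.null(dbb)) bw$dx else dbb + bw$dx
  }
  bbw <- backward_block(model$plans$backbone, model$params$backbone,
                        fw$bb_caches, dbb)
  list(backbone = bbw$grads, heads = head_grads, dx = bbw$dx)
}
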
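#' @title Declarative network architectures
#'
#' @description Architectures are declared as layer lists so that parameter
#' counts can be derived exactly from the declaration, independently of the
#' numerical engine. The dual-head network shares a five-layer convolutional
#' backbone between a corn head and a soybean head; convolution is 2-D over
#' the (time, bin) axes of the histogram tensor with the d spectral bands as
#' input channels. Ablation variants keep one head; baselines cover a deep
#' feed-forward network and a 3-D CNN that convolves over (time, bin, band).
#' @name architectures
NULL

layer_spec <- function(kind, filter_shape = NULL, stride = NULL,
                       padding = NULL, units_or_filters = NULL,
                       batch_norm = FALSE, activation = "linear") {
  structure(list(kind = kind, filter_shape = filter_shape, stride = stride,
                 padding = padding, units_or_filters = units_or_filters,
                 batch_norm = batch_norm, activation = activation),
            class = "layer_spec")
}

conv2d_layer <- function(filters, size, stride = 1L, padding = "same",
                         batch_norm = TRUE, activation = "relu") {
  layer_spec("conv2d", filter_shape = rep(as.integer(size), length.out = 2L),
             stride = rep(as.integer(stride), length.out = 2L),
             padding = match.arg(padding, c("same", "valid")),
             units_or_filters = as.integer(filters),
             batch_norm = batch_norm, activation = activation)
}

conv3d_layer <- function(filters, size, stride = 1L, padding = "same",
                         batch_norm = TRUE, activation = "relu") {
  layer_spec("conv3d", filter_shape = rep(as.integer(size), length.out = 3L),
             stride = rep(as.integer(stride), length.out = 3L),
             padding = match.arg(padding, c("same", "valid")),
             units_or_filters = as.integer(filters),
             batch_norm = batch_norm, activation = activation)
}

maxpool3d_layer <- function(size, stride = size, padding = "same") {
  layer_spec("maxpool3d", filter_shape = rep(as.integer(size), length.out = 3L),
             stride = rep(as.integer(stride), length.out = 3L),
             padding = match.arg(padding, c("same", "valid")))
}

flatten_layer <- function() layer_spec("flatten")

fc_layer <- function(units, batch_norm = FALSE, activation = "relu") {
  layer_spec("fully_connected", units_or_filters = as.integer(units),
             batch_norm = batch_norm, activation = activation)
}

output_linear_layer <- function() {
  layer_spec("output_linear", units_or_filters = 1L,
             batch_norm = FALSE, activation = "linear")
}

new_architecture_spec <- function(name, input_shape, backbone, heads,
                                  input_kind = c("conv2d", "conv3d", "flat")) {
  structure(list(name = name, input_shape = input_shape, backbone = backbone,
                 heads = heads, input_kind = match.arg(input_kind)),
            class = "architecture_spec")
}

#' Dual-head yield network architecture
#'
#' Backbone: Conv 7x7/s2 valid (48) -> Conv 5x5/s2 valid (64) ->
#' Conv 5x5/s2 same (96) -> Conv 3x3/s1 same (128) -> Conv 3x3/s1 same
#' (128), each followed by batch normalization and ReLU. Each crop head:
#' two Conv 3x3/s1 same (148) layers (+BN+ReLU), flatten, FC-100, FC-50
#' (ReLU, no batch norm), and a 1-unit linear output. The backbone is
#' shared by both heads, which is the transfer-learning mechanism between
#' the two crops and roughly halves the parameter count relative to two
#' independent networks.
#'
#' @param input_shape Integer vector `(T, b, d)`; default `c(30, 32, 9)`.
#' @param variant `"dual"` (corn + soybean heads), `"corn_only"`, or
#'   `"soy_only"`.
#' @return An `architecture_spec`.
#' @export
yieldnet_spec <- function(input_shape = c(30L, 32L, 9L),
                          variant = c("dual", "corn_only", "soy_only")) {
  variant <- match.arg(variant)
  stopifnot(length(input_shape) == 3L)
  backbone <- list(
    conv2d_layer(48L, 7L, stride = 2L, padding = "valid"),
    conv2d_layer(64L, 5L, stride = 2L, padding = "valid"),
    conv2d_layer(96L, 5L, stride = 2L, padding = "same"),
    conv2d_layer(128L, 3L, stride = 1L, padding = "same"),
    conv2d_layer(128L, 3L, stride = 1L, padding = "same")
  )
  head <- list(
    conv2d_layer(148L, 3L, stride = 1L, padding = "same"),
    conv2d_layer(148L, 3L, stride = 1L, padding = "same"),
    flatten_layer(),
    fc_layer(100L),
    fc_layer(50L),
    output_linear_layer()
  )
  heads <- switch(variant,
    dual = list(corn = head, soy = head),
    corn_only = list(corn = head),
    soy_only = list(soy = head)
  )
  name <- if (variant == "dual") "yieldnet" else paste0("yieldnet_", variant)
  new_architecture_spec(name, as.integer(input_shape), backbone, heads,
                        input_kind = "conv2d")
}

#' Deep feed-forward network baseline architecture
#'
#' Nine hidden fully connected layers of 50 units each, batch normalization
#' on every hidden layer, ReLU activations, and a 1-unit linear output.
#' Consumes the flattened histogram tensor (8,640 features at the default
#' 30 x 32 x 9 shape).
#'
#' @param input_dim Flattened input dimension (default `30 * 32 * 9`).
#' @return An `architecture_spec`.
#' @export
dfnn_spec <- function(input_dim = 30L * 32L * 9L) {
  stopifnot(input_dim >= 1L)
  hidden <- lapply(seq_len(9L), function(i) {
    fc_layer(50L, batch_norm = TRUE, activation = "relu")
  })
  new_architecture_spec("dfnn", as.integer(input_dim), list(),
                        heads = list(yield = c(hidden, list(output_linear_layer()))),
                        input_kind = "flat")
}

#' 3-D convolutional baseline architecture
#'
#' Treats the histogram tensor as a `T x b x d` volume with a single
#' channel and convolves over all three axes: Conv 3x3x1 (64) -> MaxPool
#' 4x4x2 -> four Conv 3x3x1 (64) -> Conv 3x3x1 (128) -> MaxPool 2x2x1 ->
#' flatten -> FC-256 -> FC-128 -> linear output. All convolutions stride 1
#' with same padding and are followed by batch normalization and ReLU;
#' pooling strides default to the pool size.
#'
#' @param input_shape Integer vector `(T, b, d)`; default `c(30, 32, 9)`.
#' @return An `architecture_spec`.
#' @export
cnn3d_spec <- function(input_shape = c(30L, 32L, 9L)) {
  stopifnot(length(input_shape) == 3L)
  layers <- list(
    conv3d_layer(64L, c(3L, 3L, 1L)),
    maxpool3d_layer(c(4L, 4L, 2L)),
    conv3d_layer(64L, c(3L, 3L, 1L)),
    conv3d_layer(64L, c(3L, 3L, 1L)),
    conv3d_layer(64L, c(3L, 3L, 1L)),
    conv3d_layer(64L, c(3L, 3L, 1L)),
    conv3d_layer(128L, c(3L, 3L, 1L)),
    maxpool3d_layer(c(2L, 2L, 1L)),
    flatten_layer(),
    fc_layer(256L),
    fc_layer(128L),
    output_linear_layer()
  )
  new_architecture_spec("cnn3d", as.integer(input_shape), list(),
                        heads = list(yield = layers), input_kind = "conv3d")
}

# ---- shape propagation -----------------------------------------------------

conv_out_size <- function(s, k, st, padding) {
  if (padding == "valid") {
    o <- floor((s - k) / st) + 1L
    if (any(o < 1L)) {
      stop("input spatial size (", paste(s, collapse = "x"),
           ") too small for valid-padded filter ", paste(k, collapse = "x"))
    }
  } else {
    o <- ceiling(s / st)
  }
  as.integer(o)
}

same_padding <- function(s, k, st) {
  o <- ceiling(s / st)
  total <- pmax((o - 1L) * st + k - s, 0L)
  lo <- total %/% 2L
  list(lo = as.integer(lo), hi = as.integer(total - lo))
}

# propagate one layer's input shape to its output shape; shapes are lists
# (spatial = integer vector or NULL, channels = integer) for conv stages or
# (flat = integer) after flattening
propagate_layer <- function(layer, shape) {
  kind <- layer$kind
  if (kind %in% c("conv2d", "conv3d")) {
    if (is.null(shape$spatial)) stop(kind, " applied to flattened input")
    o <- conv_out_size(shape$spatial, layer$filter_shape, layer$stride,
                       layer$padding)
    list(spatial = o, channels = layer$units_or_filters)
  } else if (kind == "maxpool3d") {
    o <- conv_out_size(shape$spatial, layer$filter_shape, layer$stride,
                       layer$padding)
    list(spatial = o, channels = shape$channels)
  } else if (kind == "flatten") {
    list(flat = prod(shape$spatial) * shape$channels)
  } else if (kind %in% c("fully_connected", "output_linear")) {
    din <- if (!is.null(shape$flat)) shape$flat else {
      prod(shape$spatial) * shape$channels
    }
    list(flat = layer$units_or_filters, .in = din)
  } else {
    stop("unknown layer kind: ", kind)
  }
}

input_shape_of <- function(spec) {
  if (spec$input_kind == "conv2d") {
    list(spatial = spec$input_shape[1:2], channels = spec$input_shape[3L])
  } else if (spec$input_kind == "conv3d") {
    list(spatial = spec$input_shape, channels = 1L)
  } else {
    list(flat = spec$input_shape[1L])
  }
}

propagate_shapes <- function(layers, shape) {
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    shape <- propagate_layer(layers[[i]], shape)
    out[[i]] <- shape
  }
  out
}

layer_parameter_count <- function(layer, in_shape) {
  kind <- layer$kind
  if (kind %in% c("conv2d", "conv3d")) {
    f <- layer$units_or_filters
    w <- prod(layer$filter_shape) * in_shape$channels * f
    # conv bias kept even under batch norm; batch norm contributes the
    # trainable scale and shift only (running statistics are not parameters)
    w + f + if (layer$batch_norm) 2L * f else 0L
  } else if (kind %in% c("fully_connected", "output_linear")) {
    din <- if (!is.null(in_shape$flat)) in_shape$flat else {
      prod(in_shape$spatial) * in_shape$channels
    }
    u <- layer$units_or_filters
    din * u + u + if (layer$batch_norm) 2L * u else 0L
  } else {
    0L
  }
}

count_block <- function(layers, shape) {
  total <- 0
  for (layer in layers) {
    total <- total + layer_parameter_count(layer, shape)
    shape <- propagate_layer(layer, shape)
  }
  total
}

#' Count trainable parameters of an architecture
#'
#' Counts weights and biases of convolutional and fully connected layers
#' plus the per-channel scale and shift of batch normalization; running
#' batch-norm statistics and pooling/flatten layers contribute nothing.
#' The count is derived from the declared layer list by exact shape
#' propagation, so it can serve as an oracle for the numerical engine.
#'
#' @param spec An `architecture_spec` from [yieldnet_spec()],
#'   [dfnn_spec()], or [cnn3d_spec()].
#' @return Integer-valued total; attributes `backbone` and `heads` carry
#'   the per-block subtotals.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  shape0 <- input_shape_of(spec)
  bb <- count_block(spec$backbone, shape0)
  bb_out <- if (length(spec$backbone) > 0L) {
    propagate_shapes(spec$backbone, shape0)[[length(spec$backbone)]]
  } else {
    shape0
  }
  hd <- vapply(spec$heads, function(h) count_block(h, bb_out), numeric(1L))
  structure(bb + sum(hd), backbone = bb, heads = hd)
}
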
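# Shared fixture builders; everything is generated in code at test time.

# A minimal composite frame from a matrix-per-band list.
make_frame <- function(band_list, location_id = "locA", year = 2010L,
                       time_index = 1L, valid_mask = NULL) {
  H <- nrow(band_list[[1L]]); W <- ncol(band_list[[1L]])
  bands <- array(0, dim = c(H, W, length(band_list)))
  for (j in seq_along(band_list)) bands[, , j] <- band_list[[j]]
  composite_frame(bands, location_id, year, time_index,
                  valid_mask = valid_mask)
}

full_mask <- function(H, W, location_id = "locA", year = 2010L) {
  cropland_mask(matrix(TRUE, H, W), location_id, year)
}

# A tiny two-head architecture that keeps finite-difference checks cheap.
tiny_dual_spec <- function() {
  yieldnet:::new_architecture_spec(
    "tiny",
    input_shape = c(9L, 10L, 3L),
    backbone = list(
      yieldnet:::conv2d_layer(4L, 3L, stride = 2L, padding = "valid"),
      yieldnet:::conv2d_layer(5L, 3L, stride = 1L, padding = "same")
    ),
    heads = list(
      corn = list(yieldnet:::conv2d_layer(3L, 3L, stride = 1L,
                                          padding = "same"),
                  yieldnet:::flatten_layer(),
                  yieldnet:::fc_layer(7L),
                  yieldnet:::output_linear_layer()),
      soy = list(yieldnet:::flatten_layer(),
                 yieldnet:::fc_layer(6L, batch_norm = TRUE),
                 yieldnet:::output_linear_layer())
    ),
    input_kind = "conv2d"
  )
}

small_generator <- function(seed = 11L, n_locations = 6L, n_years = 3L,
                            grid = c(12L, 12L), b = 8L, ...) {
  generator_config(n_locations = n_locations, n_years = n_years,
                   grid = grid, b = b, seed = seed, ...)
}

# rmse over the labeled (observed) records only
rmse_obs <- function(y, p) {
  k <- is.finite(y)
  rmse(y[k], p[k])
}
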
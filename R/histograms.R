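#' @title Histogram reduction of multispectral composite time series
#'
#' @description Raw county-scale imagery is reduced to per-band pixel-value
#' histograms under a permutation-invariance assumption: average yield
#' depends on the composition of pixel values over cropland, not on where
#' the pixels sit. Each composite becomes a `b x d` histogram matrix
#' (b bins, d bands) and a season of `T` composites stacks into a
#' `T x b x d` tensor that the networks consume.
#' @name histograms
NULL

#' Construct a composite frame
#'
#' One multispectral 8-day composite raster for a location-year at a given
#' time index. Bands are ordered reflectance 1-7, then day land-surface
#' temperature, then night land-surface temperature (d = 9 by default).
#'
#' @param bands Numeric array `H x W x d` of pixel values.
#' @param location_id Opaque location identifier.
#' @param year Integer year.
#' @param time_index Integer composite index in `1..T`.
#' @param valid_mask Logical `H x W` matrix, `TRUE` where the pixel is
#'   usable (defaults to finite pixels in every band).
#' @return A `composite_frame` object.
#' @export
composite_frame <- function(bands, location_id, year, time_index,
                            valid_mask = NULL) {
  if (length(dim(bands)) != 3L) stop("bands must be an H x W x d array")
  if (is.null(valid_mask)) {
    valid_mask <- apply(is.finite(bands), c(1L, 2L), all)
  }
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), dim(bands)[1:2])) {
    stop("valid_mask must be a logical matrix matching the spatial dimensions")
  }
  structure(
    list(bands = bands, location_id = location_id, year = as.integer(year),
         time_index = as.integer(time_index), valid_mask = valid_mask),
    class = "composite_frame"
  )
}

#' Construct a cropland mask
#'
#' @param mask Logical `H x W` matrix, `TRUE` on cropland pixels.
#' @param location_id Location identifier.
#' @param year Integer year.
#' @return A `cropland_mask` object.
#' @export
cropland_mask <- function(mask, location_id, year) {
  if (!is.logical(mask) || length(dim(mask)) != 2L) {
    stop("mask must be a logical matrix")
  }
  structure(list(mask = mask, location_id = location_id, year = as.integer(year)),
            class = "cropland_mask")
}

#' Compute per-band histogram bin edges from training frames
#'
#' Edges are placed per band; the default strategy spaces `b + 1` edges
#' linearly between the band's minimum and maximum over valid pixels of the
#' supplied frames. Only training-year frames should be passed here so that
#' bin placement never sees test data.
#'
#' @param training_frames List of [composite_frame()] objects, or a single
#'   frame.
#' @param b Integer bin count (default 32).
#' @param strategy Edge-placement strategy; `"linear"` (default) or
#'   `"fixed"`, the latter taking explicit `ranges`.
#' @param ranges For `strategy = "fixed"`: a `d x 2` matrix of per-band
#'   (min, max), e.g. known sensor-valid ranges.
#' @return A `binning_scheme` object with fields `edges` (list of length d,
#'   each a strictly increasing numeric vector of length `b + 1`), `b`, and
#'   `normalization`.
#' @export
compute_bin_edges <- function(training_frames, b = 32L,
                              strategy = c("linear", "fixed"), ranges = NULL) {
  strategy <- match.arg(strategy)
  b <- as.integer(b)
  if (b < 1L) stop("b must be >= 1")
  if (inherits(training_frames, "composite_frame")) {
    training_frames <- list(training_frames)
  }
  if (strategy == "fixed") {
    if (is.null(ranges) || ncol(ranges) != 2L) {
      stop("strategy = 'fixed' requires a d x 2 ranges matrix")
    }
    lo <- ranges[, 1L]; hi <- ranges[, 2L]
  } else {
    if (length(training_frames) == 0L) stop("no training frames supplied")
    d <- dim(training_frames[[1L]]$bands)[3L]
    lo <- rep(Inf, d); hi <- rep(-Inf, d)
    n_valid <- rep(0, d)
    for (fr in training_frames) {
      vm <- fr$valid_mask
      for (j in seq_len(d)) {
        px <- fr$bands[, , j][vm]
        if (length(px) == 0L) next
        if (any(!is.finite(px))) {
          stop("non-finite pixel values among valid pixels in band ", j)
        }
        n_valid[j] <- n_valid[j] + length(px)
        lo[j] <- min(lo[j], min(px))
        hi[j] <- max(hi[j], max(px))
      }
    }
    if (any(n_valid == 0L)) {
      stop("band(s) with zero valid pixels: ",
           paste(which(n_valid == 0L), collapse = ", "))
    }
  }
  edges <- lapply(seq_along(lo), function(j) {
    e <- seq(lo[j], hi[j], length.out = b + 1L)
    # a constant band would collapse all edges; widen symmetrically so the
    # scheme stays strictly increasing and the single value lands inside
    if (lo[j] == hi[j]) {
      half <- max(abs(lo[j]), 1) * 1e-6
      e <- seq(lo[j] - half, hi[j] + half, length.out = b + 1L)
    }
    e
  })
  binning_scheme(edges, normalization = "frequency")
}

#' Construct a binning scheme from explicit edges
#'
#' @param edges List of per-band strictly increasing numeric vectors, each of
#'   length `b + 1`.
#' @param normalization `"frequency"` (each time-band histogram column sums
#'   to 1) or `"count"` (raw pixel counts).
#' @return A `binning_scheme` object.
#' @export
binning_scheme <- function(edges, normalization = c("frequency", "count")) {
  normalization <- match.arg(normalization)
  if (!is.list(edges)) edges <- list(edges)
  b <- length(edges[[1L]]) - 1L
  for (j in seq_along(edges)) {
    e <- edges[[j]]
    if (length(e) != b + 1L) stop("all bands must share the same bin count")
    if (any(diff(e) <= 0)) {
      stop("edges for band ", j, " are not strictly increasing")
    }
  }
  structure(list(edges = edges, b = as.integer(b), normalization = normalization),
            class = "binning_scheme")
}

#' Histogram one composite frame over cropland
#'
#' Counts valid cropland pixels per half-open bin `[edge_i, edge_{i+1})`,
#' with the last bin closed on the right. Values below the first edge clamp
#' into bin 1 and above the last edge into bin `b`, so pixel mass is
#' conserved. Frequency normalization divides each band's column by its
#' pixel count; a band with no counted pixels yields an all-zero column with
#' a warning.
#'
#' @param frame A [composite_frame()].
#' @param cropland A [cropland_mask()] for the same location-year.
#' @param scheme A [binning_scheme()].
#' @return Numeric `b x d` matrix.
#' @export
frame_histogram <- function(frame, cropland, scheme) {
  stopifnot(inherits(frame, "composite_frame"),
            inherits(cropland, "cropland_mask"),
            inherits(scheme, "binning_scheme"))
  d <- dim(frame$bands)[3L]
  if (!identical(dim(cropland$mask), dim(frame$bands)[1:2])) {
    stop("cropland mask dimensions do not match the frame")
  }
  if (length(scheme$edges) != d) {
    stop("binning scheme covers ", length(scheme$edges), " bands, frame has ", d)
  }
  keep <- frame$valid_mask & cropland$mask
  b <- scheme$b
  out <- matrix(0, nrow = b, ncol = d)
  warned <- FALSE
  for (j in seq_len(d)) {
    px <- frame$bands[, , j][keep]
    px <- px[is.finite(px)]
    if (length(px) == 0L) {
      warned <- TRUE
      next
    }
    e <- scheme$edges[[j]]
    # findInterval with left-closed bins; clamp out-of-range into edge bins
    idx <- findInterval(px, e, left.open = FALSE, rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L
    idx[idx > b] <- b
    counts <- tabulate(idx, nbins = b)
    out[, j] <- if (scheme$normalization == "frequency") {
      counts / length(px)
    } else {
      counts
    }
  }
  if (warned) {
    warning("frame (", frame$location_id, ", ", frame$year, ", t=",
            frame$time_index, ") has a band with zero counted pixels; ",
            "emitting an all-zero histogram column")
  }
  out
}

#' Stack a season of frame histograms into a histogram tensor
#'
#' Frames are placed by their `time_index` (input order is irrelevant);
#' missing composites become all-zero slices with a warning, which the
#' downstream networks treat the same way as a pre-season cutoff.
#'
#' @param frames List of [composite_frame()] objects for one location-year.
#' @param cropland The location-year's [cropland_mask()].
#' @param scheme A [binning_scheme()].
#' @param T_steps Season length (default: the largest `time_index` present,
#'   or 30).
#' @return A `histogram_tensor` object: numeric `T x b x d` array `values`
#'   plus `location_id`, `year`, and `cutoff_index` (= `T` for a full
#'   season).
#' @export
build_histogram_tensor <- function(frames, cropland, scheme, T_steps = NULL) {
  if (inherits(frames, "composite_frame")) frames <- list(frames)
  if (length(frames) == 0L) stop("no frames supplied")
  tidx <- vapply(frames, function(f) f$time_index, integer(1L))
  if (anyDuplicated(tidx)) {
    stop("duplicate time_index values: ",
         paste(tidx[duplicated(tidx)], collapse = ", "))
  }
  if (is.null(T_steps)) T_steps <- max(max(tidx), 30L)
  T_steps <- as.integer(T_steps)
  if (any(tidx < 1L | tidx > T_steps)) stop("time_index outside 1..T")
  d <- dim(frames[[1L]]$bands)[3L]
  values <- array(0, dim = c(T_steps, scheme$b, d))
  for (i in seq_along(frames)) {
    values[tidx[i], , ] <- frame_histogram(frames[[i]], cropland, scheme)
  }
  missing_t <- setdiff(seq_len(T_steps), tidx)
  if (length(missing_t) > 0L) {
    warning("missing composites at time indices ",
            paste(missing_t, collapse = ", "), "; slices left all-zero")
  }
  histogram_tensor(values, frames[[1L]]$location_id, frames[[1L]]$year,
                   cutoff_index = T_steps)
}

#' Construct a histogram tensor from raw values
#'
#' @param values Numeric `T x b x d` array.
#' @param location_id Location identifier.
#' @param year Integer year.
#' @param cutoff_index Last time slice carrying data (`T` for a full
#'   season; slices past it are identically zero).
#' @return A `histogram_tensor` object.
#' @export
histogram_tensor <- function(values, location_id = NA, year = NA_integer_,
                             cutoff_index = dim(values)[1L]) {
  if (length(dim(values)) != 3L) stop("values must be a T x b x d array")
  if (any(values < 0)) stop("histogram values must be non-negative")
  structure(
    list(values = values, location_id = location_id, year = as.integer(year),
         cutoff_index = as.integer(cutoff_index)),
    class = "histogram_tensor"
  )
}

#' @export
print.histogram_tensor <- function(x, ...) {
  dv <- dim(x$values)
  cat(sprintf("<histogram_tensor %s/%s: T=%d b=%d d=%d cutoff=%d>\n",
              x$location_id, x$year, dv[1L], dv[2L], dv[3L], x$cutoff_index))
  invisible(x)
}

#' Truncate a histogram tensor for an in-season forecast date
#'
#' Slices whose composite start day-of-year exceeds the forecast date are
#' zeroed, emulating a prediction made before those composites exist. The
#' tensor shape is unchanged so a fixed-shape network can consume it.
#'
#' @param H A [histogram_tensor()].
#' @param forecast_doy Integer day-of-year of the forecast.
#' @param calendar Mapping from time index to composite start day-of-year
#'   (default [composite_calendar()]).
#' @return A `histogram_tensor` with the same shape, later slices zeroed,
#'   and `cutoff_index` set to the last retained slice (0 if none).
#' @export
truncate_season <- function(H, forecast_doy, calendar = composite_calendar()) {
  stopifnot(inherits(H, "histogram_tensor"))
  T_steps <- dim(H$values)[1L]
  if (length(calendar) < T_steps) {
    stop("calendar covers ", length(calendar), " indices; tensor has ", T_steps)
  }
  if (forecast_doy < 1L || forecast_doy > 366L) {
    stop("forecast_doy must be within the calendar year")
  }
  keep <- which(calendar[seq_len(T_steps)] <= forecast_doy)
  cutoff <- if (length(keep) == 0L) 0L else max(keep)
  values <- H$values
  if (cutoff < T_steps) {
    values[(cutoff + 1L):T_steps, , ] <- 0
  }
  histogram_tensor(values, H$location_id, H$year,
                   cutoff_index = min(cutoff, H$cutoff_index))
}
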
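#' @title Readers and writers
#'
#' @description Yield tables are CSV with columns `location_id`, `year`,
#' `crop` (corn/soybean), `yield_bu_per_acre`; rasters are multi-page
#' 32-bit float TIFF (one page per band, NaN as nodata); histogram tensors
#' cache as NPY arrays with a JSON sidecar carrying identity and bin-edge
#' provenance.
#' @name io
NULL

#' Read a county-level yield table
#'
#' Validates structure row by row: crop labels normalize to lowercase
#' `corn`/`soybean`, years must be 4-digit integers, yields strictly
#' positive. Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Tibble with columns `location_id`, `year`, `crop`,
#'   `yield_bu_per_acre`.
#' @export
read_yield_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("location_id", "year", "crop", "yield_bu_per_acre")
  if (!all(required %in% names(df))) {
    stop("yield table must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(df) == 0L) return(tibble::as_tibble(df[, required]))
  df$crop <- tolower(trimws(df$crop))
  line <- seq_len(nrow(df)) + 1L                 # +1 for the header line
  bad_crop <- !(df$crop %in% c("corn", "soybean"))
  bad_year <- !is.finite(df$year) | df$year != round(df$year) |
    df$year < 1000 | df$year > 9999
  bad_yield <- !is.finite(df$yield_bu_per_acre) | df$yield_bu_per_acre <= 0
  bad <- bad_crop | bad_year | bad_yield
  if (any(bad)) {
    stop("malformed yield rows at line(s): ",
         paste(line[bad], collapse = ", "),
         " (crop must be corn/soybean, year a 4-digit integer, ",
         "yield_bu_per_acre > 0)")
  }
  df$year <- as.integer(df$year)
  tibble::as_tibble(df[, required])
}

#' Write a yield table
#'
#' @param records Data frame with columns `location_id`, `year`, `crop`,
#'   `yield_bu_per_acre`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_yield_table <- function(records, path) {
  utils::write.csv(records[, c("location_id", "year", "crop",
                               "yield_bu_per_acre")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# wide paired yields (corn/soy columns) <-> long crop/yield records
yields_wide_to_long <- function(tab) {
  long <- rbind(
    data.frame(location_id = tab$location_id, year = tab$year, crop = "corn",
               yield_bu_per_acre = tab$corn),
    data.frame(location_id = tab$location_id, year = tab$year,
               crop = "soybean", yield_bu_per_acre = tab$soy)
  )
  long[is.finite(long$yield_bu_per_acre), ]
}

yields_long_to_wide <- function(records) {
  records$crop <- ifelse(records$crop == "soybean", "soy", records$crop)
  wide <- tidyr_pivot(records)
  wide
}

# minimal wide pivot without pulling in tidyr for one call
tidyr_pivot <- function(records) {
  key <- unique(records[, c("location_id", "year")])
  key$corn <- NA_real_
  key$soy <- NA_real_
  for (crop in c("corn", "soy")) {
    sub <- records[records$crop == crop, ]
    m <- match(paste(key$location_id, key$year),
               paste(sub$location_id, sub$year))
    key[[crop]] <- sub$yield_bu_per_acre[m]
  }
  tibble::as_tibble(key)
}

#' Write an evaluation report as tidy CSV
#'
#' One row per (model, year, forecast_date, crop, metric, value).
#'
#' @param report An `eval_report` from [run_forecast_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  long <- do.call(rbind, lapply(c("rmse", "mae", "mae_percent", "pearson_r"),
    function(m) {
      data.frame(model = report$model, year = report$test_year,
                 forecast_date = report$forecast_date, crop = report$crop,
                 metric = m, value = report[[m]], n = report$n)
    }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a multi-band raster as a multi-page TIFF with a scale sidecar
#'
#' TIFF pages store 32-bit values normalized to `[0.1, 1]` per band; the
#' physical per-band range lives in a JSON sidecar next to the file, and
#' non-finite pixels are encoded as the reserved code 0 (nodata). The
#' round trip preserves values to about 1e-9 of the band range.
#'
#' @param grid Numeric `H x W` matrix or `H x W x d` array.
#' @param path Output `.tif` path (the sidecar is `path` + `.json`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  if (length(dim(grid)) == 2L) dim(grid) <- c(dim(grid), 1L)
  d <- dim(grid)[3L]
  lo <- hi <- numeric(d)
  pages <- vector("list", d)
  for (j in seq_len(d)) {
    v <- grid[, , j]
    ok <- is.finite(v)
    if (!any(ok)) {
      lo[j] <- 0; hi[j] <- 0
      pages[[j]] <- matrix(0, nrow(v), ncol(v))
      next
    }
    lo[j] <- min(v[ok]); hi[j] <- max(v[ok])
    scale <- if (hi[j] > lo[j]) hi[j] - lo[j] else 1
    enc <- 0.1 + 0.9 * (v - lo[j]) / scale
    enc[!ok] <- 0
    pages[[j]] <- enc
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(band_min = lo, band_max = hi),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Read a multi-band raster written by [write_raster()]
#'
#' @param path `.tif` path.
#' @return List with `bands` (`H x W x d` array, `NA` at nodata) and
#'   `valid` (logical `H x W`, `FALSE` where any band is nodata).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$band_min)) {
    stop("raster sidecar bands do not match TIFF pages in ", path)
  }
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  bands <- array(NA_real_, c(H, W, length(pages)))
  for (j in seq_along(pages)) {
    x <- pages[[j]]
    nodata <- x < 0.05
    scale <- if (meta$band_max[j] > meta$band_min[j]) {
      meta$band_max[j] - meta$band_min[j]
    } else 1
    v <- meta$band_min[j] + (x - 0.1) / 0.9 * scale
    v[nodata] <- NA_real_
    bands[, , j] <- v
  }
  valid <- apply(!is.na(bands), c(1L, 2L), all)
  list(bands = bands, valid = valid)
}

# ---- NPY cache -------------------------------------------------------------

# Minimal NPY v1.0 (little-endian float64, C order) writer/reader for the
# histogram cache.
write_npy <- function(x, path) {
  stopifnot(is.array(x))
  shape <- dim(x)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%s), }",
                    paste0(paste(shape, collapse = ", "),
                           if (length(shape) == 1L) "," else ""))
  need <- 10L + nchar(header) + 1L
  pad <- (64L - need %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(aperm(x, rev(seq_along(shape)))), con, size = 8L,
           endian = "little")
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop("not an NPY file: ", path)
  }
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  if (!grepl("'<f8'", header)) stop("unsupported NPY dtype in ", path)
  if (grepl("'fortran_order': True", header)) {
    stop("fortran-order NPY not supported")
  }
  shape_str <- sub(".*'shape': \\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s|,$", "", shape_str), ",")[[1L]])
  x <- readBin(con, "double", prod(shape), size = 8L, endian = "little")
  aperm(array(x, rev(shape)), rev(seq_along(shape)))
}

#' Save histogram tensors to an NPY cache directory
#'
#' One `<location>_<year>.npy` per tensor plus a JSON sidecar carrying
#' location, year, cutoff index, and a digest of the bin edges so caches
#' built under different binning schemes cannot be mixed silently.
#'
#' @param data A `paired_dataset` (or tibble with `hist` list-column).
#' @param dir Output directory (created if missing).
#' @param scheme The [binning_scheme()] used (defaults to the dataset's).
#' @return `dir`, invisibly.
#' @export
save_histograms <- function(data, dir, scheme = attr(data, "scheme")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  digest <- edges_digest(scheme)
  for (i in seq_len(nrow(data))) {
    h <- data$hist[[i]]
    stem <- file.path(dir, paste0(h$location_id, "_", h$year))
    write_npy(h$values, paste0(stem, ".npy"))
    jsonlite::write_json(list(location_id = h$location_id, year = h$year,
                              cutoff_index = h$cutoff_index,
                              edges_digest = digest),
                         paste0(stem, ".json"), auto_unbox = TRUE)
  }
  jsonlite::write_json(list(edges = scheme$edges, b = scheme$b,
                            normalization = scheme$normalization),
                       file.path(dir, "scheme.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(as.data.frame(data[, c("location_id", "year", "corn",
                                          "soy")]),
                   file.path(dir, "yields.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a histogram cache directory written by [save_histograms()]
#'
#' @param dir Cache directory.
#' @return A `paired_dataset` tibble with the stored binning scheme
#'   attached.
#' @export
load_histograms <- function(dir) {
  sj <- jsonlite::read_json(file.path(dir, "scheme.json"),
                            simplifyVector = TRUE)
  scheme <- binning_scheme(if (is.matrix(sj$edges)) {
    lapply(seq_len(nrow(sj$edges)), function(i) sj$edges[i, ])
  } else sj$edges, normalization = sj$normalization)
  tab <- utils::read.csv(file.path(dir, "yields.csv"),
                         stringsAsFactors = FALSE)
  digest <- edges_digest(scheme)
  hists <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    stem <- file.path(dir, paste0(tab$location_id[i], "_", tab$year[i]))
    meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
    if (!identical(meta$edges_digest, digest)) {
      stop("bin-edge digest mismatch for ", stem,
           ": cache built under a different binning scheme")
    }
    hists[[i]] <- histogram_tensor(read_npy(paste0(stem, ".npy")),
                                   tab$location_id[i], tab$year[i],
                                   cutoff_index = meta$cutoff_index)
  }
  out <- tibble::as_tibble(tab)
  out$hist <- hists
  attr(out, "scheme") <- scheme
  class(out) <- c("paired_dataset", class(out))
  out
}

edges_digest <- function(scheme) {
  v <- unlist(scheme$edges)
  sprintf("%d:%.10g:%.10g:%.10g", length(v), sum(v), min(v), max(v))
}
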
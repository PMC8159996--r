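#' @title Synthetic county-scale data generator
#'
#' @description Emulates the structure of the real inputs — per-county
#' multispectral 8-day composites (7 reflectance bands plus day/night land
#' surface temperature), cropland masks, and paired county-level corn and
#' soybean yields — with a known generative model so every stage of the
#' pipeline can be tested without satellite downloads.
#'
#' Each location-year carries a standard-normal latent `z` (think of it as
#' the season's overall growing conditions). Pixel values of band `j` at
#' composite `t` over cropland are drawn around
#' `band_mean[j] + alpha[j] * g(t) * z`, where the nondecreasing season
#' ramp `g` makes the latent progressively more visible as the season
#' advances — which is what makes early-season forecasts genuinely harder.
#' Yields are `mean_c + sd_c * (rho * z + sqrt(1 - rho^2) * u_c) + noise`,
#' so `rho` controls how much signal the two crops share and therefore how
#' much a shared backbone can transfer between them. Default yield moments
#' match the observed Corn Belt summary statistics (corn 146.68 +/- 36.03,
#' soybean 45.02 +/- 10.08 bu/acre).
#' @name synthetic
NULL

#' Generator configuration
#'
#' @param n_locations,n_years Number of locations `L` and years `K`.
#' @param grid Spatial grid `c(H, W)` of the synthetic county rasters.
#' @param T_steps Composites per season (default 30).
#' @param b Bin count used when reducing to histograms (default 32).
#' @param band_mean Baseline per-band pixel means: plausible crop-canopy
#'   reflectances for bands 1-7 and Kelvin temperatures for day/night LST.
#' @param alpha Per-band effect of the latent on the pixel mean at full
#'   season ramp (healthier seasons: brighter near-infrared, darker red and
#'   shortwave-infrared, cooler canopy).
#' @param pixel_noise_sd Per-band pixel noise standard deviation.
#' @param season_ramp Nondecreasing weights `g(1..T)` scaling how visible
#'   the latent is at each composite (default linear 0 to 1).
#' @param corn_mean,corn_sd,soy_mean,soy_sd Yield moments (bu/acre).
#' @param rho Shared-latent weight in `[0, 1]`: correlation between the two
#'   crops' systematic yield components.
#' @param yield_noise_sd Length-2 vector, irreducible yield noise (corn,
#'   soy) in bu/acre; this is the error floor no predictor can beat.
#' @param corn_coverage,soy_coverage Probability that a location-year
#'   carries the crop's yield record (at least one is always kept).
#'   Defaults are calibrated to the observed record counts over the study
#'   region and period — 13,992 corn and 12,502 soybean records against
#'   1132 x 15 and 1076 x 15 possible location-years — so not every entry
#'   has both labels, as in the real data.
#' @param start_year First year label (default 2004).
#' @param seed Integer master seed; every location-year derives its own
#'   substream from it, so outputs are bit-identical for a given seed
#'   regardless of generation order.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_locations = 50L, n_years = 10L,
                             grid = c(64L, 64L), T_steps = 30L, b = 32L,
                             band_mean = c(0.05, 0.40, 0.03, 0.08, 0.30,
                                           0.20, 0.10, 302, 288),
                             alpha = c(-0.015, 0.06, -0.008, -0.012, 0.02,
                                       -0.025, -0.015, -2.5, -1.2),
                             pixel_noise_sd = c(rep(0.02, 7), 1.5, 1.2),
                             season_ramp = NULL,
                             corn_mean = 146.68, corn_sd = 36.03,
                             soy_mean = 45.02, soy_sd = 10.08,
                             rho = 0.8, yield_noise_sd = c(8, 2.5),
                             corn_coverage = 0.824, soy_coverage = 0.774,
                             start_year = 2004L, seed = 1L) {
  T_steps <- as.integer(T_steps)
  if (is.null(season_ramp)) {
    season_ramp <- if (T_steps == 1L) 1 else (seq_len(T_steps) - 1) / (T_steps - 1)
  }
  stopifnot(length(band_mean) == length(alpha),
            length(alpha) == length(pixel_noise_sd),
            length(season_ramp) == T_steps,
            all(diff(season_ramp) >= 0),
            all(pixel_noise_sd > 0), corn_sd > 0, soy_sd > 0,
            rho >= 0, rho <= 1, all(yield_noise_sd >= 0),
            corn_coverage > 0, corn_coverage <= 1,
            soy_coverage > 0, soy_coverage <= 1)
  structure(list(
    n_locations = as.integer(n_locations), n_years = as.integer(n_years),
    grid = as.integer(grid), T_steps = T_steps, b = as.integer(b),
    d = length(band_mean), band_mean = band_mean, alpha = alpha,
    pixel_noise_sd = pixel_noise_sd, season_ramp = season_ramp,
    corn_mean = corn_mean, corn_sd = corn_sd, soy_mean = soy_mean,
    soy_sd = soy_sd, rho = rho, yield_noise_sd = yield_noise_sd,
    corn_coverage = corn_coverage, soy_coverage = soy_coverage,
    start_year = as.integer(start_year), seed = as.integer(seed)
  ), class = "generator_config")
}

# deterministic per-location-year substream seed (kept below 2^31)
lk_seed <- function(cfg, l, k) {
  as.integer((as.numeric(cfg$seed) * 7919 + l * 100003 + k * 9973) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  code
}

# Draws everything for one location-year in a FIXED order:
# latents/yields, mask geometry, then per-band cropland pixels. Background
# (non-cropland) pixels come last so histogram-only streaming and full
# frame materialisation consume an identical RNG prefix.
gen_location_year <- function(cfg, l, k, materialize_frames = FALSE) {
  H <- cfg$grid[1L]; W <- cfg$grid[2L]
  T_steps <- cfg$T_steps; d <- cfg$d
  with_seed(lk_seed(cfg, l, k), {
    z <- stats::rnorm(1L)
    u <- stats::rnorm(2L)
    eps <- stats::rnorm(2L) * cfg$yield_noise_sd
    corn <- cfg$corn_mean + cfg$corn_sd *
      (cfg$rho * z + sqrt(1 - cfg$rho^2) * u[1L]) + eps[1L]
    soy <- cfg$soy_mean + cfg$soy_sd *
      (cfg$rho * z + sqrt(1 - cfg$rho^2) * u[2L]) + eps[2L]
    corn <- max(corn, 0.1)
    soy <- max(soy, 0.1)
    cov <- stats::runif(2L)
    has_corn <- cov[1L] <= cfg$corn_coverage
    has_soy <- cov[2L] <= cfg$soy_coverage
    if (!has_corn && !has_soy) has_corn <- TRUE
    if (!has_corn) corn <- NA_real_
    if (!has_soy) soy <- NA_real_
    # contiguous elliptical cropland region, jittered per location-year
    cy <- stats::runif(1L, 0.35, 0.65) * H
    cx <- stats::runif(1L, 0.35, 0.65) * W
    ry <- stats::runif(1L, 0.25, 0.42) * H
    rx <- stats::runif(1L, 0.25, 0.42) * W
    gy <- matrix(seq_len(H), H, W)
    gx <- matrix(seq_len(W), H, W, byrow = TRUE)
    mask <- ((gy - cy) / ry)^2 + ((gx - cx) / rx)^2 <= 1
    if (!any(mask)) mask[round(cy), round(cx)] <- TRUE
    n_mask <- sum(mask)
    mu_t <- outer(cfg$season_ramp * z, cfg$alpha)          # T x d
    crop_px <- vector("list", d)
    for (j in seq_len(d)) {
      mu <- cfg$band_mean[j] + mu_t[, j]
      crop_px[[j]] <- matrix(
        stats::rnorm(n_mask * T_steps, mean = rep(mu, each = n_mask),
                     sd = cfg$pixel_noise_sd[j]),
        nrow = n_mask, ncol = T_steps)
    }
    frames <- NULL
    if (materialize_frames) {
      # non-cropland background: latent-free, offset composition
      bg_mean <- cfg$band_mean + 3 * cfg$pixel_noise_sd
      n_bg <- H * W - n_mask
      bg_px <- vector("list", d)
      for (j in seq_len(d)) {
        bg_px[[j]] <- matrix(
          stats::rnorm(n_bg * T_steps, mean = bg_mean[j],
                       sd = cfg$pixel_noise_sd[j]),
          nrow = n_bg, ncol = T_steps)
      }
      frames <- vector("list", T_steps)
      for (t in seq_len(T_steps)) {
        bands <- array(0, dim = c(H, W, d))
        for (j in seq_len(d)) {
          plane <- matrix(0, H, W)
          plane[mask] <- crop_px[[j]][, t]
          plane[!mask] <- bg_px[[j]][, t]
          bands[, , j] <- plane
        }
        frames[[t]] <- composite_frame(bands, location_id = loc_id(l),
                                       year = cfg$start_year + k - 1L,
                                       time_index = t)
      }
    }
    list(z = z, corn = corn, soy = soy, mask = mask, crop_px = crop_px,
         frames = frames)
  })
}

loc_id <- function(l) sprintf("loc%04d", l)

#' Generate a full synthetic dataset with materialised rasters
#'
#' Produces composite frames, cropland masks, the yield table, and the
#' ground truth (latents and generative parameters). Intended for modest
#' `L x K`; for large training sets use [generate_histogram_dataset()],
#' which streams straight to histogram tensors without holding rasters.
#'
#' @param cfg A [generator_config()].
#' @return List with `frames` (list over location-years of lists of
#'   [composite_frame()]), `masks` (list of [cropland_mask()]), `yields`
#'   (tibble: location_id, year, corn, soy), and `truth` (tibble with the
#'   latent `z` per location-year plus the config).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_locations * cfg$n_years
  frames <- vector("list", n)
  masks <- vector("list", n)
  rows <- vector("list", n)
  i <- 0L
  for (l in seq_len(cfg$n_locations)) {
    for (k in seq_len(cfg$n_years)) {
      i <- i + 1L
      g <- gen_location_year(cfg, l, k, materialize_frames = TRUE)
      year <- cfg$start_year + k - 1L
      frames[[i]] <- g$frames
      masks[[i]] <- cropland_mask(g$mask, loc_id(l), year)
      rows[[i]] <- tibble::tibble(location_id = loc_id(l), year = year,
                                  corn = g$corn, soy = g$soy, z = g$z)
    }
  }
  tab <- dplyr::bind_rows(rows)
  list(frames = frames, masks = masks,
       yields = tab[, c("location_id", "year", "corn", "soy")],
       truth = structure(list(latents = tab[, c("location_id", "year", "z")],
                              config = cfg), class = "synthetic_truth"))
}

#' Generate only the yield table and latents
#'
#' Runs the same per-location-year random-number prefix as the full
#' generators but skips pixel synthesis, so the yields are bit-identical
#' to [generate_dataset()]'s at a fraction of the cost. Useful for
#' checking the configured moments at large `L x K`.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with `location_id`, `year`, `corn`, `soy`, `z`.
#' @export
generate_yield_table <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_locations * cfg$n_years
  loc <- integer(n); yr <- integer(n)
  corn <- numeric(n); soy <- numeric(n); z <- numeric(n)
  i <- 0L
  for (l in seq_len(cfg$n_locations)) {
    for (k in seq_len(cfg$n_years)) {
      i <- i + 1L
      with_seed(lk_seed(cfg, l, k), {
        zz <- stats::rnorm(1L)
        u <- stats::rnorm(2L)
        eps <- stats::rnorm(2L) * cfg$yield_noise_sd
        cc <- max(cfg$corn_mean + cfg$corn_sd *
                    (cfg$rho * zz + sqrt(1 - cfg$rho^2) * u[1L]) +
                    eps[1L], 0.1)
        ss <- max(cfg$soy_mean + cfg$soy_sd *
                    (cfg$rho * zz + sqrt(1 - cfg$rho^2) * u[2L]) +
                    eps[2L], 0.1)
        cov <- stats::runif(2L)
        has_corn <- cov[1L] <= cfg$corn_coverage
        has_soy <- cov[2L] <= cfg$soy_coverage
        if (!has_corn && !has_soy) has_corn <- TRUE
        corn[i] <- if (has_corn) cc else NA_real_
        soy[i] <- if (has_soy) ss else NA_real_
        z[i] <- zz
      })
      loc[i] <- l
      yr[i] <- cfg$start_year + k - 1L
    }
  }
  tibble::tibble(location_id = loc_id(loc), year = yr, corn = corn,
                 soy = soy, z = z)
}

# histogram a matrix of cropland pixel draws (n_mask x T) for one band
stream_band_hist <- function(px, edges, b, T_steps, frequency) {
  idx <- findInterval(px, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > b] <- b
  off <- rep(seq_len(T_steps) - 1L, each = nrow(px)) * b
  counts <- tabulate(as.vector(idx) + off, nbins = b * T_steps)
  h <- matrix(counts, nrow = b, ncol = T_steps)
  if (frequency) h <- h / nrow(px)
  h
}

#' Generate a paired histogram dataset directly (streaming)
#'
#' Streams each location-year's cropland pixels straight into histogram
#' tensors without materialising rasters, making training-scale datasets
#' (thousands of location-years) cheap. The pixel draws are bit-identical
#' to [generate_dataset()]'s for the same config, so this path and the
#' frame-by-frame pipeline can be cross-checked against each other.
#'
#' Bin edges follow the leakage rule: linear per-band min/max computed
#' from the training years only (a first streaming pass), unless an
#' explicit `scheme` is supplied.
#'
#' @param cfg A [generator_config()].
#' @param train_years Years whose pixels may inform bin edges (default: all
#'   years except the last three, mirroring the held-out-year protocol).
#' @param scheme Optional pre-computed [binning_scheme()].
#' @return A `paired_dataset`: tibble with columns `location_id`, `year`,
#'   `corn`, `soy`, `z`, and list-column `hist` of `histogram_tensor`
#'   objects; attributes `scheme` and `config`.
#' @export
generate_histogram_dataset <- function(cfg, train_years = NULL, scheme = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  if (is.null(train_years)) {
    train_years <- if (cfg$n_years > 3L) years[seq_len(cfg$n_years - 3L)] else years
  }
  if (is.null(scheme)) {
    lo <- rep(Inf, cfg$d); hi <- rep(-Inf, cfg$d)
    for (l in seq_len(cfg$n_locations)) {
      for (k in seq_len(cfg$n_years)) {
        if (!((cfg$start_year + k - 1L) %in% train_years)) next
        g <- gen_location_year(cfg, l, k)
        for (j in seq_len(cfg$d)) {
          r <- range(g$crop_px[[j]])
          lo[j] <- min(lo[j], r[1L]); hi[j] <- max(hi[j], r[2L])
        }
      }
    }
    edges <- lapply(seq_len(cfg$d), function(j) {
      seq(lo[j], hi[j], length.out = cfg$b + 1L)
    })
    scheme <- binning_scheme(edges, normalization = "frequency")
  }
  n <- cfg$n_locations * cfg$n_years
  hists <- vector("list", n)
  rows <- vector("list", n)
  i <- 0L
  for (l in seq_len(cfg$n_locations)) {
    for (k in seq_len(cfg$n_years)) {
      i <- i + 1L
      g <- gen_location_year(cfg, l, k)
      vals <- array(0, dim = c(cfg$T_steps, scheme$b, cfg$d))
      for (j in seq_len(cfg$d)) {
        vals[, , j] <- t(stream_band_hist(g$crop_px[[j]], scheme$edges[[j]],
                                          scheme$b, cfg$T_steps,
                                          scheme$normalization == "frequency"))
      }
      year <- cfg$start_year + k - 1L
      hists[[i]] <- histogram_tensor(vals, loc_id(l), year)
      rows[[i]] <- tibble::tibble(location_id = loc_id(l), year = year,
                                  corn = g$corn, soy = g$soy, z = g$z)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$hist <- hists
  attr(out, "scheme") <- scheme
  attr(out, "config") <- cfg
  class(out) <- c("paired_dataset", class(out))
  out
}

#' Linear reference predictor on per-(time, band) histogram means
#'
#' A transparent brute-force reference: each (time, band) slice of the
#' histogram tensor is collapsed to its distribution mean (sum of bin
#' midpoints weighted by frequency) and yields are fit by ordinary least
#' squares on those `T x d` features. Under the generator's linear yield
#' link this recovers the signal up to the irreducible yield noise, so its
#' held-out RMSE is the error floor learned models are compared against.
#'
#' @param train A `paired_dataset` to fit on.
#' @param scheme The [binning_scheme()] used to build the histograms
#'   (defaults to the dataset's attached scheme).
#' @return An `oracle_predictor` object with a [predict()] method taking a
#'   `paired_dataset` and returning a list with `corn` and `soy` vectors.
#' @export
oracle_predictor <- function(train, scheme = attr(train, "scheme")) {
  stopifnot(inherits(train, "paired_dataset"), !is.null(scheme))
  X <- hist_mean_features(train$hist, scheme)
  fit_one <- function(y) {
    keep <- is.finite(y)
    Xk <- cbind(1, X[keep, , drop = FALSE])
    XtX <- crossprod(Xk)
    Xty <- crossprod(Xk, y[keep])
    beta <- tryCatch(solve(XtX, Xty), error = function(e) {
      # singular design (rank-deficient or badly scaled): ridge-stabilized
      # fallback with a jitter proportional to the feature scale
      lam <- 1e-8 * mean(diag(XtX))
      repeat {
        b <- tryCatch(solve(XtX + diag(lam, ncol(Xk)), Xty),
                      error = function(e2) NULL)
        if (!is.null(b)) return(b)
        lam <- lam * 100
      }
    })
    as.vector(beta)
  }
  structure(list(beta_corn = fit_one(train$corn),
                 beta_soy = fit_one(train$soy), scheme = scheme),
            class = "oracle_predictor")
}

#' @export
predict.oracle_predictor <- function(object, newdata, ...) {
  X <- cbind(1, hist_mean_features(newdata$hist, object$scheme))
  list(corn = as.vector(X %*% object$beta_corn),
       soy = as.vector(X %*% object$beta_soy))
}

# collapse each (time, band) histogram slice to its distribution mean;
# all-zero slices (truncated or missing composites) give 0
hist_mean_features <- function(hists, scheme) {
  mids <- vapply(scheme$edges, function(e) {
    (e[-1L] + e[-length(e)]) / 2
  }, numeric(scheme$b))                                   # b x d
  v1 <- if (inherits(hists[[1L]], "histogram_tensor")) {
    hists[[1L]]$values
  } else hists[[1L]]
  Tn <- dim(v1)[1L]; d <- dim(v1)[3L]
  t(vapply(hists, function(h) {
    v <- if (inherits(h, "histogram_tensor")) h$values else h
    out <- matrix(0, Tn, d)
    for (j in seq_len(d)) {
      out[, j] <- v[, , j] %*% mids[, j]
    }
    as.vector(out)
  }, numeric(Tn * d)))
}
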
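test_that("bin edges are linear over training min/max, per band", {
  vals <- matrix(rep(0:31, length.out = 36), 6, 6)
  fr <- make_frame(list(vals, vals / 10))
  scheme <- compute_bin_edges(fr, b = 32L)
  expect_equal(scheme$edges[[1L]], seq(0, 32 - 1, length.out = 33))
  expect_equal(scheme$edges[[2L]], seq(0, 3.1, length.out = 33))

  one_bin <- compute_bin_edges(fr, b = 1L)
  expect_equal(one_bin$edges[[1L]], c(0, 31))

  for (b in c(1L, 3L, 17L)) {
    s <- compute_bin_edges(fr, b = b)
    for (e in s$edges) {
      expect_length(e, b + 1L)
      expect_true(all(diff(e) > 0))
    }
  }
})

test_that("bin edges reject empty bands and non-finite pixels", {
  fr <- make_frame(list(matrix(1, 4, 4)),
                   valid_mask = matrix(FALSE, 4, 4))
  expect_error(compute_bin_edges(fr, b = 4L), "zero valid pixels")
  bad <- make_frame(list(matrix(c(1, NA, 2, 3), 2, 2)),
                    valid_mask = matrix(TRUE, 2, 2))
  expect_error(compute_bin_edges(bad, b = 4L), "non-finite")
})

test_that("frame histogram bins pixels by the half-open convention", {
  px <- matrix(c(0.1, 0.3, 0.3, 0.9), 2, 2)
  fr <- make_frame(list(px))
  scheme <- binning_scheme(list(c(0, 0.25, 0.5, 0.75, 1)))
  h <- frame_histogram(fr, full_mask(2, 2), scheme)
  expect_equal(h[, 1L], c(0.25, 0.5, 0, 0.25))

  # point mass lands in a single bin
  fr1 <- make_frame(list(matrix(0.6, 3, 3)))
  h1 <- frame_histogram(fr1, full_mask(3, 3), scheme)
  expect_equal(h1[, 1L], c(0, 0, 1, 0))

  # out-of-range values clamp into the edge bins (mass conserved)
  fr2 <- make_frame(list(matrix(c(-5, 0.1, 2, 7), 2, 2)))
  h2 <- frame_histogram(fr2, full_mask(2, 2), scheme)
  expect_equal(sum(h2[, 1L]), 1)
  expect_equal(h2[1L, 1L], 0.5)
  expect_equal(h2[4L, 1L], 0.5)

  # the exact top edge falls in the last bin (closed on the right)
  fr3 <- make_frame(list(matrix(1, 2, 2)))
  h3 <- frame_histogram(fr3, full_mask(2, 2), scheme)
  expect_equal(h3[4L, 1L], 1)
})

test_that("histograms are invariant to spatial permutation of pixels", {
  set.seed(5)
  H <- 7L; W <- 9L
  vals1 <- matrix(runif(H * W), H, W)
  vals2 <- matrix(runif(H * W, 10, 20), H, W)
  vm <- matrix(runif(H * W) > 0.2, H, W)
  cm <- matrix(runif(H * W) > 0.3, H, W)
  scheme <- binning_scheme(list(seq(0, 1, length.out = 9),
                                seq(10, 20, length.out = 9)))
  base <- frame_histogram(make_frame(list(vals1, vals2), valid_mask = vm),
                          cropland_mask(cm, "locA", 2010L), scheme)
  for (i in 1:100) {
    p <- sample(H * W)
    pv1 <- matrix(vals1[p], H, W)
    pv2 <- matrix(vals2[p], H, W)
    pvm <- matrix(vm[p], H, W)
    pcm <- matrix(cm[p], H, W)
    h <- frame_histogram(make_frame(list(pv1, pv2), valid_mask = pvm),
                         cropland_mask(pcm, "locA", 2010L), scheme)
    expect_identical(h, base)
  }
})

test_that("frequency slices sum to one and count mode conserves pixel mass", {
  set.seed(8)
  cfg <- small_generator()
  ds <- generate_dataset(cfg)
  scheme <- compute_bin_edges(ds$frames[[1L]], b = 8L)
  cm <- ds$masks[[1L]]
  H <- build_histogram_tensor(ds$frames[[1L]], cm, scheme)
  sums <- apply(H$values, c(1L, 3L), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  scheme_c <- scheme
  scheme_c$normalization <- "count"
  Hc <- build_histogram_tensor(ds$frames[[1L]], cm, scheme_c)
  n_px <- sum(ds$frames[[1L]][[1L]]$valid_mask & cm$mask)
  expect_true(all(apply(Hc$values, c(1L, 3L), sum) == n_px))
})

test_that("zero counted pixels yield an all-zero column with a warning", {
  fr <- make_frame(list(matrix(1, 3, 3)))
  cm <- cropland_mask(matrix(FALSE, 3, 3), "locA", 2010L)
  scheme <- binning_scheme(list(c(0, 1, 2)))
  expect_warning(h <- frame_histogram(fr, cm, scheme), "zero counted")
  expect_equal(h, matrix(0, 2, 1))
})

test_that("tensor assembly places frames by time index and flags gaps", {
  set.seed(3)
  frames <- lapply(1:4, function(t) {
    make_frame(list(matrix(runif(9), 3, 3)), time_index = t)
  })
  cm <- full_mask(3, 3)
  scheme <- binning_scheme(list(seq(0, 1, length.out = 5)))
  H <- build_histogram_tensor(frames, cm, scheme, T_steps = 4L)
  expect_equal(dim(H$values), c(4L, 4L, 1L))
  expect_equal(H$cutoff_index, 4L)
  # order-insensitive placement
  H2 <- build_histogram_tensor(frames[c(3, 1, 4, 2)], cm, scheme,
                               T_steps = 4L)
  expect_identical(H$values, H2$values)
  # single frame keeps a leading unit axis
  H1 <- build_histogram_tensor(frames[[1L]], cm, scheme, T_steps = 1L)
  expect_equal(dim(H1$values), c(1L, 4L, 1L))
  expect_equal(H1$values[1L, , ],
               frame_histogram(frames[[1L]], cm, scheme)[, 1L])
  # duplicates rejected, gaps zero-filled with a warning
  expect_error(build_histogram_tensor(frames[c(1, 1)], cm, scheme),
               "duplicate")
  expect_warning(Hg <- build_histogram_tensor(frames[c(1, 3)], cm, scheme,
                                              T_steps = 3L), "missing")
  expect_true(all(Hg$values[2L, , ] == 0))
})

test_that("season truncation zeroes future slices at the documented cutoffs", {
  cal <- composite_calendar()
  expect_equal(unname(cal[1L]), 65L)
  expect_equal(unname(cal[30L]), 297L)
  set.seed(9)
  vals <- array(runif(30 * 4 * 2), c(30, 4, 2))
  H <- histogram_tensor(vals, "locA", 2010L)
  cutoffs <- vapply(default_forecast_dates(), function(doy) {
    truncate_season(H, doy)$cutoff_index
  }, integer(1L))
  expect_equal(unname(cutoffs), c(18L, 22L, 26L, 29L))

  # truncation zeroes exactly the slices past the cutoff
  Hj <- truncate_season(H, 204L)
  expect_true(all(Hj$values[19:30, , ] == 0))
  expect_identical(Hj$values[1:18, , ], vals[1:18, , ])

  # no-op after the final composite; all-zero before the first
  expect_identical(truncate_season(H, 365L)$values, vals)
  H0 <- truncate_season(H, 10L)
  expect_equal(H0$cutoff_index, 0L)
  expect_true(all(H0$values == 0))

  # idempotent, and cutoff monotone in the forecast date
  expect_identical(truncate_season(Hj, 204L), Hj)
  cuts <- vapply(seq(1L, 360L, by = 7L), function(doy) {
    truncate_season(H, doy)$cutoff_index
  }, integer(1L))
  expect_true(all(diff(cuts) >= 0))
})

test_that("forecast dates convert month/day to the stated days-of-year", {
  expect_equal(unname(default_forecast_dates()), c(204L, 235L, 266L, 296L))
  expect_error(forecast_doy(2L, 30L), "invalid")
  expect_error(truncate_season(histogram_tensor(array(0, c(3, 2, 1))),
                               100L, calendar = c(1L, 9L)), "calendar")
})
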
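test_that("window enumeration yields N - l + 1 windows in start order", {
  x <- rnorm(64)
  for (l in c(1, 2, 7, 63, 64)) {
    ws <- compute_window_stats(x, l)
    expect_identical(nrow(ws), as.integer(64 - l + 1))
    expect_identical(ws$start_index, 0:(64 - l))
  }
  expect_error(compute_window_stats(x, 0), class = "ramanglu_invalid_window")
  expect_error(compute_window_stats(x, 65), class = "ramanglu_invalid_window")
})

test_that("window mean and population variance match hand evaluation", {
  ws <- compute_window_stats(c(1, 2, 4), 2)
  expect_equal(ws$mean, c(1.5, 3.0))
  expect_equal(ws$variance, c(0.25, 1.0))

  cst <- compute_window_stats(rep(3.7, 20), 5)
  expect_true(all(cst$mean == 3.7))
  expect_true(all(cst$variance == 0))

  # population (1/l), not sample (1/(l-1)), normalization
  x <- c(2, 8, 4, 10)
  ws4 <- compute_window_stats(x, 4)
  expect_equal(ws4$variance, mean((x - mean(x))^2))
})

test_that("variance ties resolve to the smaller start index", {
  a <- new_spectrum(1:8, c(0, 0, 0, 0, 9, 0, 0, 0), label_code = 1)
  b <- new_spectrum(1:8, c(0, 0, 0, 0, 0, 0, 9, 0), label_code = 1)
  ds <- new_dataset(list(a, b), label_map = data.frame(concentration = 5, code = 1))
  mask <- select_hotspots(ds, l = 3, k = 1)
  # a's tied top windows start at 2,3,4 -> 2 wins; b's at 4,5 -> 4 wins
  expect_identical(mask$indices, c(2L, 3L, 4L, 5L, 6L))
})

test_that("selection matches the brute-force oracle on random arrays", {
  withr::with_seed(2024, {
    for (case in 1:60) {
      n <- sample(8:64, 1)
      l <- sample(seq_len(n), 1)
      k <- sample(seq_len(n - l + 1), 1)
      n_samples <- sample(1:3, 1)
      samples <- lapply(seq_len(n_samples), function(i) {
        x <- round(rnorm(n, 100, 20), 1)
        if (runif(1) < 0.3) x[sample(n, n %/% 2)] <- 100  # force ties
        pmax(0, x)
      })
      ds <- new_dataset(lapply(samples, function(x)
        new_spectrum(seq_len(n), x, label_code = 1)),
        label_map = data.frame(concentration = 5, code = 1))
      mask <- select_hotspots(ds, l = l, k = k)
      expect_identical(mask$indices, as.integer(oracle_hotspot_mask(samples, l, k)))
    }
  })
})

test_that("mask grows monotonically in k and covers everything for large k", {
  ds <- generate_dataset(levels = c(5, 20), replicates = 2,
                         params = tiny_params(), seed = 8)
  prev <- integer(0)
  for (k in c(1, 5, 20, 120)) {
    m <- select_hotspots(ds, l = 6, k = k)
    expect_true(all(prev %in% m$indices))
    prev <- m$indices
  }
  full <- select_hotspots(ds, l = 6, k = 251)  # k >= N - l + 1
  expect_identical(full$indices, 0:255)
})

test_that("the selected mask is invariant to global intensity rescaling", {
  ds <- generate_dataset(levels = c(5, 20), replicates = 2,
                         params = tiny_params(), seed = 9)
  scaled <- new_dataset(lapply(ds$spectra, function(s) {
    s$intensities <- s$intensities * 37.5
    s
  }), label_map = ds$label_map)
  m1 <- select_hotspots(ds, l = 10, k = 30)
  m2 <- select_hotspots(scaled, l = 10, k = 30)
  expect_identical(m1$indices, m2$indices)
})

test_that("apply_mask keeps the masked columns in ascending index order", {
  ds <- new_dataset(list(
    new_spectrum(1:8, c(10, 11, 12, 13, 14, 15, 16, 17), label_code = 1),
    new_spectrum(1:8, c(20, 21, 22, 23, 24, 25, 26, 27), label_code = 1)),
    label_map = data.frame(concentration = 5, code = 1))
  mask <- new_index_mask(c(2L, 3L, 4L, 5L, 6L), n_total = 8)
  red <- apply_mask(ds, mask)
  expect_identical(dim(red), c(2L, 5L))
  expect_identical(unname(red[1, ]), c(12, 13, 14, 15, 16))

  full <- new_index_mask(0:7, n_total = 8)
  expect_identical(unname(apply_mask(ds, full)), unname(dataset_matrix(ds)))

  wrong <- new_index_mask(0:3, n_total = 9)
  expect_error(apply_mask(ds, wrong), class = "ramanglu_axis_mismatch")
})

test_that("hotspot defaults on a full-size dataset keep under 2048 indices in runs", {
  ds <- generate_dataset(replicates = 1, params = generator_params(), seed = 3)
  mask <- select_hotspots(ds, l = 10, k = 500)
  expect_lte(length(mask$indices), 2048L)
  expect_lt(length(mask$indices), 2048L)  # the regime must not cover the axis
  seg <- mask_segments(mask)
  expect_true(all(seg$to - seg$from + 1L >= 10L))  # unions of length-10 windows
  expect_identical(sum(seg$to - seg$from + 1L), length(mask$indices))
})

test_that("masks round-trip through segments and JSON", {
  m <- new_index_mask(c(0L, 1L, 2L, 7L, 8L, 30L), n_total = 64, l = 3, k = 2)
  seg <- mask_segments(m)
  expect_identical(seg$from, c(0L, 7L, 30L))
  expect_identical(seg$to, c(2L, 8L, 30L))
  expect_identical(mask_from_segments(seg$from, seg$to, 64)$indices, m$indices)

  path <- withr::local_tempfile(fileext = ".json")
  write_mask_json(m, path)
  back <- read_mask_json(path)
  expect_identical(back$indices, m$indices)
  expect_identical(back$n_total, 64L)
  expect_identical(back$l, 3L)
  expect_identical(back$k, 2L)
})
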
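test_that("trial-set construction validates geometry and labels", {
  x <- toy_trials(n = 4, labels = c(1, 2, 3, 1), n_classes = 3)
  expect_s3_class(x, "eeg_trial_set")
  expect_equal(n_trials(x), 4)
  expect_equal(n_channels(x), 3)
  expect_equal(n_samples(x), 40)
  expect_error(eeg_trial_set(matrix(0, 2, 2), NULL, 100), "3-d array")
  expect_error(toy_trials(labels = c(1, 2)), "one entry per trial")
  expect_error(toy_trials(labels = rep(5, 5), n_classes = 4), "exceed")
  expect_error(eeg_trial_set(array(0, c(1, 2, 3)), NULL, -1), "positive")
})

test_that("channel selection keeps data, honours order, rejects unknowns", {
  x <- toy_trials()
  # identity case
  same <- select_channels(x, x$channel_names)
  expect_identical(same$data, x$data)
  # reorder: verified against manual indexing
  sel <- select_channels(x, c("ch03", "ch01"))
  expect_identical(sel$data[, 1, ], x$data[, 3, ])
  expect_identical(sel$data[, 2, ], x$data[, 1, ])
  expect_equal(sel$channel_names, c("ch03", "ch01"))
  expect_error(select_channels(x, c("ch01", "nope")), "nope")
})

test_that("crop_window slices cue-relative windows and checks bounds", {
  x <- toy_trials(t = 100, fs = 100)
  # manual-slice oracle: fs=100, [0, 1) s from trial start
  cr <- crop_window(x, 0, 1)
  expect_equal(n_samples(cr), 100)
  expect_identical(cr$data, x$data)
  cr2 <- crop_window(x, 0, 0.5)
  expect_identical(cr2$data, x$data[, , 1:50])
  # cue-relative window with explicit cue sample
  cr3 <- crop_window(x, -0.1, 0.2, cue_index = 20)
  expect_identical(cr3$data, x$data[, , 10:39])
  # standard motor-imagery epoch length
  hg <- toy_trials(n = 2, c = 2, t = 1200, fs = 250)
  expect_equal(n_samples(crop_window(hg, -0.5, 4, cue_index = 126)), 1125)
  expect_error(crop_window(x, 0, 0), "empty window")
  expect_error(crop_window(x, -0.5, 0.5, cue_index = 10), "trial 1")
})

test_that("resampling halves the sample count and keeps spectral peaks", {
  fs <- 500
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  sig <- sin(2 * pi * 10 * t)
  data <- array(0, c(2, 1, length(t)))
  data[1, 1, ] <- sig; data[2, 1, ] <- sig
  x <- eeg_trial_set(data, NULL, fs)
  y <- resample_trials(x, 250)
  expect_equal(n_samples(y), length(t) / 2)
  expect_equal(y$fs, 250)
  # FFT-peak oracle: the 10 Hz component must survive
  sp <- Mod(fft(y$data[1, 1, ]))
  freqs <- 250 * (0:(n_samples(y) - 1)) / n_samples(y)
  half <- 2:(n_samples(y) / 2)
  expect_equal(freqs[half][which.max(sp[half])], 10)
  # no-op resampling returns the input unchanged
  expect_identical(resample_trials(x, fs)$data, x$data)
})

test_that("the standard preprocessing chain yields the conventional trial
           geometry", {
  # 128-channel recording at 500 Hz, cue at 1 s: keep 44 motor channels,
  # crop [-0.5, 4] s around the cue, resample to 250 Hz -> (n, 44, 1125)
  set.seed(17)
  raw <- eeg_trial_set(array(rnorm(2 * 128 * 2750), c(2, 128, 2750)),
                       c(1L, 2L), fs = 500)
  keep <- raw$channel_names[seq(2, 128, by = 2)[1:44]]
  out <- resample_trials(
    crop_window(select_channels(raw, keep), -0.5, 4, cue_index = 501),
    250)
  expect_equal(dim(out$data), c(2L, 44L, 1125L))
  expect_equal(out$fs, 250)
  expect_identical(out$labels, c(1L, 2L))
})

test_that("preprocessing is order-stable and never touches labels", {
  x <- toy_trials(n = 6, labels = c(1, 2, 1, 2, 1, 2), n_classes = 2)
  a <- crop_window(select_channels(x, c("ch02", "ch01")), 0, 0.2)
  b <- select_channels(crop_window(x, 0, 0.2), c("ch02", "ch01"))
  expect_identical(a$data, b$data)
  expect_identical(a$labels, x$labels)
  expect_identical(b$labels, x$labels)
})

test_that("container round trip preserves everything", {
  x <- toy_trials(n = 5, labels = c(1, 2, 3, 4, 1))
  rds <- withr::local_tempfile(fileext = ".rds")
  write_trials(x, rds)
  y <- read_trials(rds)
  expect_identical(y$data, x$data)      # bitwise
  expect_identical(y$labels, x$labels)
  expect_identical(y$fs, x$fs)
  expect_identical(y$channel_names, x$channel_names)
  js <- withr::local_tempfile(fileext = ".json")
  write_trials(x, js)
  z <- read_trials(js)
  expect_identical(z$data, x$data)
  expect_identical(z$labels, x$labels)
})

test_that("malformed containers are rejected with context", {
  x <- toy_trials(n = 3, labels = c(1, 2, 3))
  js <- withr::local_tempfile(fileext = ".json")
  write_trials(x, js)
  obj <- jsonlite::fromJSON(js)
  obj$labels <- c(1, 2)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), js)
  expect_error(read_trials(js), "2 labels for 3 trials")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_trials(bad), "malformed")
  expect_error(read_trials(tempfile()), "no such file")
})

test_that("standardization freezes source statistics and is invertible", {
  x <- toy_trials(n = 8)
  st <- fit_channel_stats(x)
  z <- apply_channel_stats(x, st)
  for (ch in 1:3) {
    v <- z$data[, ch, ]
    expect_lt(abs(mean(v)), 1e-12)
    expect_equal(sd(as.vector(v)), 1, tolerance = 1e-10)
  }
  # frozen: applying source stats to other data uses the same numbers
  y <- toy_trials(n = 4, seed = 99)
  zy <- apply_channel_stats(y, st)
  expect_equal(zy$data[1, 1, ], (y$data[1, 1, ] - st$mean[1]) / st$sd[1])
})

test_that("withheld labels error on any access", {
  w <- withhold_labels()
  expect_error(length(w), "withheld")
  expect_error(w[1], "withheld")
  expect_error(as.integer(w), "withheld")
  expect_error(print(w), "withheld")
  pair <- fast_pair(n_trials = 3)
  expect_s3_class(pair$target_train$labels, "withheld_labels")
  expect_error(pair$target_train$labels[1], "withheld")
})
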
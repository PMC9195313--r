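test_that("ERP subtraction removes phase-locked content, keeps residual", {
  set.seed(30)
  nt <- 2662
  common <- rnorm(nt)
  arr <- array(rep(common, each = 5), c(5, 1, nt))
  ep <- make_epochs(arr)
  expect_lt(max(abs(subtract_erp(ep)$data)), 1e-10)
  ## with independent residuals, the residual variance survives
  arr2 <- arr + array(rnorm(5 * nt), c(5, 1, nt))
  res <- subtract_erp(make_epochs(arr2))
  expect_gt(var(as.vector(res$data)), 0.5)
})

test_that("decibel baselining is exact on constructed maps", {
  nt <- 300
  tt <- seq(-1.1, 1.5, length.out = nt)
  freqs <- morlet_frequencies()
  pw <- array(2, c(1, 1, 40, nt))
  tf <- structure(list(power = pw, freqs = freqs, t = tt, fs = 1024,
                       units = "uV^2", baseline_span = NULL,
                       kept_mask = matrix(TRUE, 1, 1),
                       category = "famous", channels = chan_meta(1)),
                  class = "fg_tfr")
  db <- baseline_db(tf)
  expect_equal(max(abs(db$power)), 0, tolerance = 1e-12)
  ## P = 10 B inside a window -> +10 dB there, 0 elsewhere
  tf2 <- tf
  win <- tt >= 0 & tt < 0.75
  tf2$power[1, 1, , win] <- 20
  db2 <- baseline_db(tf2)
  expect_true(all(abs(db2$power[1, 1, , win] - 10) < 1e-9))
  expect_true(all(abs(db2$power[1, 1, , !win]) < 1e-9))
  tf3 <- tf
  tf3$power[1, 1, 1, 5] <- 0
  expect_error(baseline_db(tf3), "nonpositive")
})

test_that("windowed gamma power uses the region-specific window", {
  nt <- 300
  tt <- seq(-1.1, 1.5, length.out = nt)
  freqs <- morlet_frequencies()
  mkdb <- function(region) {
    pw <- array(0, c(1, 1, 40, nt))
    pw[1, 1, freqs >= 45 & freqs <= 150, tt >= 0 & tt < 0.75] <- 3
    structure(list(power = pw, freqs = freqs, t = tt, fs = 1024,
                   units = "dB", baseline_span = c(-1.1, 0),
                   kept_mask = matrix(TRUE, 1, 1), category = "famous",
                   channels = chan_meta(1, region = region)),
              class = "fg_tfr")
  }
  ## early-window region sees the 3 dB block fully
  expect_equal(window_gamma_power(mkdb("amygdala"))$gamma_db, 3,
               tolerance = 1e-9)
  ## late-window region (hippocampus) only overlaps [250, 750) of it
  hi <- window_gamma_power(mkdb("hippocampus"))$gamma_db
  expect_lt(hi, 3)
  expect_gt(hi, 1)
  ## a 0 dB map scores 0
  z <- mkdb("fusiform"); z$power[] <- 0
  expect_equal(window_gamma_power(z)$gamma_db, 0)
  expect_error(region_gamma_window("thalamus"), "unknown region")
})

test_that("dB map of real epochs is zero-mean over the baseline and recovers bursts", {
  set.seed(31)
  fs <- 1024
  nt <- 2662
  tt <- seq(round(-1.1 * fs), round(1.5 * fs) - 1) / fs
  ntr <- 30
  arr <- array(0, c(ntr, 1, nt))
  win <- tt >= 0 & tt < 0.75
  for (i in seq_len(ntr)) {
    bg <- one_over_f_noise(nt, fs, 1.5, 20)
    p_bg <- var(fft_bandpass(bg, fs, 60, 90))
    burst <- band_noise(sum(win), fs, 60, 90) * tukey_window(sum(win), 0.2)
    burst <- burst * sqrt((10^(3 / 10) - 1) * p_bg / mean(burst^2))
    bg[win] <- bg[win] + burst
    arr[i, 1, ] <- bg
  }
  tf <- morlet_power(make_epochs(arr), decim = 4)
  expect_true(all(tf$power >= 0))
  db <- baseline_db(tfr_average(tf))
  bl <- db$t >= -1.1 & db$t < 0
  expect_lt(max(abs(rowMeans(db$power[1, 1, , bl]))), 1e-9)
  fi <- db$freqs >= 60 & db$freqs <= 90
  expect_equal(mean(db$power[1, 1, fi, db$t >= 0.1 & db$t < 0.65]), 3,
               tolerance = 0.4)
})
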
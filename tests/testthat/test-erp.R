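test_that("ERP of a single trial is that trial, baseline-corrected and flipped", {
  set.seed(20)
  nt <- 2662
  arr <- array(rnorm(nt), c(1, 1, nt))
  ep <- make_epochs(arr, reference = "fz_monopolar")
  erp <- compute_erp(ep)
  bl <- ep$t >= -1 & ep$t < 0
  expect_equal(erp$mean[1, ], -(arr[1, 1, ] - mean(arr[1, 1, bl])),
               tolerance = 1e-12)
  ## baseline span of the ERP averages to zero
  expect_lt(abs(mean(erp$mean[1, bl])), 1e-12)
})

test_that("antisymmetric trial pairs cancel after baseline correction", {
  set.seed(21)
  nt <- 2662
  x <- rnorm(nt)
  arr <- array(0, c(2, 1, nt))
  arr[1, 1, ] <- x
  arr[2, 1, ] <- -x + 13        # constant offsets are baseline-corrected away
  erp <- compute_erp(make_epochs(arr))
  expect_lt(max(abs(erp$mean)), 1e-10)
})

test_that("compute_erp respects category subsets, masks and errors", {
  set.seed(22)
  nt <- 2662
  arr <- array(rnorm(4 * nt), c(4, 1, nt))
  ep <- make_epochs(arr, category = c("famous", "mosaic", "famous", "mosaic"))
  expect_error(compute_erp(ep, "veiled"), "veiled")
  ep$kept_mask[3, 1] <- FALSE
  erp <- compute_erp(ep, "famous")
  expect_equal(erp$n_trials, 1L)  # only trial 1 remains
  ## ERP over all trials equals the kept-count-weighted mean of subset ERPs
  ep$kept_mask[] <- TRUE
  e_all <- compute_erp(ep)
  e_f <- compute_erp(ep, "famous")
  e_m <- compute_erp(ep, "mosaic")
  expect_equal(e_all$mean, (2 * e_f$mean + 2 * e_m$mean) / 4,
               tolerance = 1e-12)
})

test_that("peak windows are the three 80 ms spans and amplitudes behave", {
  w <- peak_windows()
  expect_equal(w$lo_ms, c(70, 200, 320))
  expect_equal(w$hi_ms, c(150, 280, 400))
  fs <- 1024
  nt <- 2662
  tt <- seq(round(-1.1 * fs), round(1.5 * fs) - 1) / fs
  ## -5 uV boxcar over the N240 window only
  arr <- array(0, c(1, 1, nt))
  arr[1, 1, tt >= 0.2 & tt < 0.28] <- -5
  ep <- make_epochs(arr, reference = "fz_monopolar")
  rows <- trial_peak_amplitudes(ep)
  expect_equal(nrow(rows), 3)
  expect_equal(rows$amplitude_uV[rows$peak == "N240"], 5, tolerance = 1e-9)
  expect_equal(rows$amplitude_uV[rows$peak == "N110"], 0, tolerance = 1e-9)
  expect_equal(rows$amplitude_uV[rows$peak == "N360"], 0, tolerance = 1e-9)
  ## a constant epoch scores zero everywhere
  arrc <- array(4, c(1, 1, nt))
  expect_equal(trial_peak_amplitudes(make_epochs(arrc))$amplitude_uV,
               rep(0, 3), tolerance = 1e-9)
})

test_that("trial amplitudes are linear and row counts conserve kept trials", {
  set.seed(23)
  nt <- 2662
  a1 <- array(rnorm(3 * nt), c(3, 1, nt))
  a2 <- array(rnorm(3 * nt), c(3, 1, nt))
  r1 <- trial_peak_amplitudes(make_epochs(a1))
  r2 <- trial_peak_amplitudes(make_epochs(a2))
  r12 <- trial_peak_amplitudes(make_epochs(a1 + a2))
  expect_equal(r12$amplitude_uV, r1$amplitude_uV + r2$amplitude_uV,
               tolerance = 1e-10)
  ep <- make_epochs(a1)
  ep$kept_mask[2, 1] <- FALSE
  rows <- trial_peak_amplitudes(ep)
  expect_equal(nrow(rows), 2 * 3)   # kept trials x windows
  expect_false(2 %in% rows$trial)
})
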
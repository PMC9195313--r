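test_that("phase and amplitude extraction track known signals", {
  fs <- 1024
  nt <- 2662
  tt <- seq(round(-1.1 * fs), round(1.5 * fs) - 1) / fs
  arr <- array(0, c(1, 1, nt))
  arr[1, 1, ] <- 4 * sin(2 * pi * 8 * tt)
  ep <- make_epochs(arr)
  pa <- extract_phase_amp(ep, 1, phase_freqs = 8, amp_freqs = 80)
  ## phase advances 2*pi per 125 ms at 8 Hz
  ph <- pa$phase[1, 1, ]
  un <- ph + cumsum(c(0, diff(ph) < -pi) * 2 * pi)
  slope <- unname(coef(lm(un ~ pa$t))[2])
  expect_equal(slope, 2 * pi * 8, tolerance = 0.02 * 2 * pi * 8)
  ## constant-envelope 80 Hz carrier: amplitude constant within 5% CV
  arr2 <- arr
  arr2[1, 1, ] <- 2 * cos(2 * pi * 80 * tt)
  pa2 <- extract_phase_amp(make_epochs(arr2), 1, phase_freqs = 8,
                           amp_freqs = 80)
  a <- pa2$amp[1, 1, ]
  expect_lt(sd(a) / mean(a), 0.05)
  expect_equal(mean(a), 2, tolerance = 0.05)
  ## doubling the signal doubles amplitude, leaves phase unchanged
  arr3 <- arr; arr3[1, 1, ] <- 2 * arr[1, 1, ]
  pa3 <- extract_phase_amp(make_epochs(arr3), 1, phase_freqs = 8,
                           amp_freqs = 80)
  expect_equal(pa3$amp, 2 * pa$amp, tolerance = 1e-9)
  expect_equal(pa3$phase, pa$phase, tolerance = 1e-9)
  expect_error(extract_phase_amp(ep, 1, phase_freqs = 2), "\\[3, 20\\]")
  expect_error(extract_phase_amp(ep, 1, amp_freqs = 300), "\\[45, 200\\]")
})

test_that("modulation index matches its direct definition and is rotation-invariant", {
  ep <- make_coupled_epochs(seed = 50, ntr = 12, depth = 0.8)
  pf <- c(5, 6, 7); af <- c(70, 75)
  pac <- pac_comodulogram(ep, 1, 2, phase_freqs = pf, amp_freqs = af,
                          n_surrogates = 20, seed = 1)
  ## brute-force oracle: concatenated mean vector length per pair
  ph <- extract_phase_amp(ep, 1, pf, 45)$phase
  am <- extract_phase_amp(ep, 2, 3, af)$amp
  for (p in seq_along(pf)) for (a in seq_along(af)) {
    phi <- as.vector(t(ph[, p, ]))
    amp <- as.vector(t(am[, a, ]))
    expect_equal(pac$mi[p, a], Mod(mean(amp * exp(1i * phi))),
                 tolerance = 1e-9)
    ## adding a constant phase offset rotates the mean vector, not its length
    expect_equal(Mod(mean(amp * exp(1i * (phi + 1.234)))),
                 pac$mi[p, a], tolerance = 1e-12)
  }
})

test_that("surrogate z is calibrated on uncoupled channels", {
  ep <- make_coupled_epochs(seed = 51, ntr = 40, depth = 0)
  pac <- pac_comodulogram(ep, 1, 2, n_surrogates = 200, seed = 2)
  ## 18 x 32 grid of z-scores: standard normal-ish under no coupling
  expect_lt(abs(mean(pac$z)), 0.2)
  expect_lt(abs(sd(pac$z) - 1), 0.2)
})

test_that("PSI is exactly antisymmetric and flags a pure delay correctly", {
  set.seed(52)
  fs <- 1024
  lagn <- round(0.015 * fs)
  nt <- 768
  s <- matrix(rnorm(40 * (nt + lagn)), 40)
  x <- s[, (lagn + 1):(lagn + nt)]   # x leads
  y <- s[, 1:nt]
  v <- cfc_psi(x, y, fs, 6)
  expect_gt(v, 0)
  expect_equal(cfc_psi(y, x, fs, 6), -v, tolerance = 1e-12)
  expect_error(cfc_psi(x[1:3, ], y[1:3, ], fs, 6), "few segments")
})

test_that("restricting PSI to the PAC mask behaves at the extremes", {
  psi <- structure(list(psi = matrix(1, 2, 3), z = matrix(3, 2, 3),
                        phase_freqs = c(5, 6), amp_freqs = c(60, 65, 70),
                        direction = "A->B", segment_s = 0.75, n_trials = 10),
                   class = "fg_psi")
  mkpac <- function(z) structure(
    list(mi = matrix(1, 2, 3), z = z, phase_freqs = c(5, 6),
         amp_freqs = c(60, 65, 70)), class = "fg_pac")
  full <- restrict_psi_to_pac(psi, mkpac(matrix(5, 2, 3)))
  expect_identical(full$z, psi$z)
  none <- restrict_psi_to_pac(psi, mkpac(matrix(-1, 2, 3)))
  expect_true(all(is.na(none$z)))
  one <- matrix(-1, 2, 3); one[2, 1] <- 4
  single <- restrict_psi_to_pac(psi, mkpac(one))
  expect_equal(sum(!is.na(single$z)), 1)
  bad <- mkpac(matrix(0, 2, 3)); bad$amp_freqs <- c(60, 65, 75)
  expect_error(restrict_psi_to_pac(psi, bad), "grids")
})

test_that("channel selection prefers the fewest rejected epochs", {
  arr <- array(rnorm(10 * 3 * 256), c(10, 3, 256))
  ep <- make_epochs(arr, t = seq_len(256) / 1024,
                    channels = chan_meta(3, region = "amygdala"))
  ep$kept_mask[1:3, 1] <- FALSE
  ep$kept_mask[1, 3] <- FALSE
  expect_equal(select_channel(ep, "amygdala"), 2L)
  expect_error(select_channel(ep, "fusiform"), "no channel")
})
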
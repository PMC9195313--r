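test_that("event schedule has one onset per stimulus with paradigm gaps", {
  cfg <- sim_config(n_per_category = 1, seed = 3)
  ev <- schedule_events(cfg)
  expect_equal(nrow(ev), 6)
  expect_setequal(ev$category, c("caucasian", "dark_skinned", "famous",
                                 "veiled", "masks", "mosaic"))
  gaps <- diff(ev$onset_s) * 1000
  expect_true(all(gaps >= 4600 & gaps <= 4800))
  expect_true(all(ev$duration_s == 1.5))
})

test_that("event schedule is deterministic under the seed", {
  cfg <- sim_config(n_per_category = 5, seed = 11)
  expect_identical(schedule_events(cfg), schedule_events(cfg))
  other <- schedule_events(sim_config(n_per_category = 5, seed = 12))
  expect_false(identical(schedule_events(cfg)$category, other$category))
})

test_that("noise-free evoked deflection averages to its nominal amplitude", {
  cfg <- sim_config(
    n_per_category = 5, regions = "amygdala",
    noise = list(one_over_f_exponent = 1.5, scale = 1e-9),
    erp_components = data.frame(region = "amygdala", group = "both",
                                category = "all", center_ms = 240,
                                width_ms = 60, amplitude_uV = -8),
    gamma_effects = default_gamma_effects()[0, ],
    coupling_specs = default_coupling_specs()[0, ], seed = 4)
  ev <- schedule_events(cfg)
  rec <- synthesize_recording(cfg, ev, "O1", "O")
  ep <- epoch_recording(rereference(rec, "fz_monopolar"), ev)
  erp <- compute_erp(ep)
  i240 <- which.min(abs(erp$t - 0.24))
  expect_equal(erp$mean[1, i240], 8, tolerance = 0.01)
  expect_equal(max(erp$mean[1, ]), 8, tolerance = 0.01)
})

test_that("induced gamma has random phase: gone from the average, present in power", {
  cfg <- sim_config(
    n_per_category = 40, regions = "amygdala",
    erp_components = default_erp_components()[0, ],
    gamma_effects = data.frame(region = "amygdala", group = "both",
                               category = "all", f_lo = 60, f_hi = 90,
                               win_lo_ms = 0, win_hi_ms = 750,
                               db_increase = 3),
    coupling_specs = default_coupling_specs()[0, ], seed = 5)
  ev <- schedule_events(cfg)
  rec <- synthesize_recording(cfg, ev, "O1", "O")
  ep <- epoch_recording(rereference(rec, "bipolar"), ev)
  win <- ep$t >= 0 & ep$t < 0.75
  band_power <- function(m) {
    apply(m, 1, function(x) var(fft_bandpass(x, ep$fs, 60, 90)[win]))
  }
  trials <- matrix(ep$data[, 1, ], nrow = dim(ep$data)[1])
  avg <- colMeans(trials)
  single <- mean(band_power(trials))
  averaged <- var(fft_bandpass(avg, ep$fs, 60, 90)[win])
  ## trial-average band power collapses to <= 10% of the single-trial mean
  expect_lt(averaged / single, 0.10)
  ## ERP subtraction keeps >= 90% of the injected single-trial band power
  resid <- subtract_erp(ep)
  single_resid <- mean(band_power(matrix(resid$data[, 1, ],
                                         nrow = dim(ep$data)[1])))
  expect_gt(single_resid / single, 0.90)
})

test_that("coupling injection is a no-op at depth zero and flips with roles", {
  set.seed(6)
  fs <- 1024
  n <- 40 * fs
  a <- one_over_f_noise(n, fs)
  b <- one_over_f_noise(n, fs)
  win <- cbind(1, 39)
  expect_identical(inject_coupling(a, b, fs, cbind(1, 1.75), 6, c(60, 90),
                                   0, 15), b)
  expect_error(inject_coupling(a, b, fs, cbind(1, 1.75), 6, c(60, 90),
                               0.5, 800), "lag")
  expect_error(inject_coupling(a, b, fs, cbind(1, 1.75), 2, c(60, 90),
                               0.5, 0), "phase_freq")
  ## phase of A modulates envelope of B, not vice versa
  b2 <- inject_coupling(a, b, fs, win, 6, c(60, 90), 0.9, 0)
  a2 <- inject_coupling(b, a, fs, win, 6, c(60, 90), 0.9, 0)
  idx <- (2 * fs):(38 * fs)
  phi_a <- Arg(morlet_transform(matrix(a), fs, 6)[1, 1, ])
  phi_b <- Arg(morlet_transform(matrix(b), fs, 6)[1, 1, ])
  env_b2 <- Mod(morlet_transform(matrix(b2), fs, 75)[1, 1, ])
  env_a2 <- Mod(morlet_transform(matrix(a2), fs, 75)[1, 1, ])
  r_fwd <- cor(cos(phi_a[idx]), env_b2[idx])
  r_rev <- cor(cos(phi_b[idx]), env_a2[idx])
  expect_gt(r_fwd, 0.3)
  expect_gt(r_rev, 0.3)
  ## the non-driving phases are uncorrelated with the envelopes
  expect_lt(abs(cor(cos(phi_a[idx]), env_a2[idx])), 0.1)
  expect_lt(abs(cor(cos(phi_b[idx]), env_b2[idx])), 0.1)
})

test_that("lagged coupling peaks at the injected lag", {
  set.seed(7)
  fs <- 1024
  n <- 60 * fs
  a <- one_over_f_noise(n, fs)
  b <- one_over_f_noise(n, fs)
  b2 <- inject_coupling(a, b, fs, cbind(1, 59), 6, c(60, 90), 0.8, 15)
  phi <- Arg(morlet_transform(matrix(a), fs, 6)[1, 1, ])
  env <- Mod(morlet_transform(matrix(b2), fs, 75)[1, 1, ])
  idx <- (2 * fs):(58 * fs)
  r_at <- function(lag_ms) {
    k <- round(lag_ms / 1000 * fs)
    cor(cos(phi[idx - k]), env[idx])
  }
  expect_gt(r_at(15), r_at(0))
  expect_gt(r_at(15), r_at(-15))
})

test_that("generate_study writes one EDF and events TSV per patient, reproducibly", {
  cfg <- sim_config(n_patients_per_group = 3, n_per_category = 1,
                    regions = c("amygdala", "fusiform"), seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man1 <- generate_study(cfg, d1)
  man2 <- generate_study(cfg, d2)
  expect_equal(nrow(man1), 6)
  expect_length(list.files(d1, pattern = "\\.edf$"), 6)
  for (i in seq_len(nrow(man1)))
    expect_identical(readLines(man1$events[i]), readLines(man2$events[i]))
  chans <- read.delim(attr(man1, "channels_tsv"))
  expect_true(all(c("O", "M") %in% chans$group))
  expect_false(anyNA(chans$group))
})
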
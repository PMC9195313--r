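# Builders for synthetic epoch sets used across the suite.

# Minimal channel metadata for n channels.
chan_meta <- function(n, region = "amygdala", patient = "O1", group = "O",
                      hemisphere = "L") {
  data.frame(name = paste0("CH", seq_len(n)), region = region,
             hemisphere = hemisphere, patient = patient, group = group,
             stringsAsFactors = FALSE)
}

# eeg_epochs object from a trials x channels x time array on the canonical
# [-1.1, 1.5) axis (or any axis given explicitly).
make_epochs <- function(arr, fs = 1024, t = NULL,
                        category = rep("famous", dim(arr)[1]),
                        channels = chan_meta(dim(arr)[2]),
                        reference = "bipolar") {
  if (is.null(t)) t <- seq(round(-1.1 * fs), length.out = dim(arr)[3]) / fs
  structure(list(data = arr, t = t, fs = fs, reference = reference,
                 kept_mask = matrix(TRUE, dim(arr)[1], dim(arr)[2]),
                 category = category, channels = channels),
            class = "eeg_epochs")
}

# Two-channel epoch set with lagged phase->amplitude coupling injected in
# the [0, 750) ms window of channel 2 (or reversed), one independent
# background realization per trial.
make_coupled_epochs <- function(seed, ntr, depth = 0.8, lag_ms = 15,
                                phase_freq = 6, amp_band = c(60, 90),
                                reverse = FALSE, fs = 1024) {
  set.seed(seed)
  nt <- round(2.6 * fs)
  dat <- array(0, c(ntr, 2, nt))
  win <- cbind(1.1, 1.85)   # trace seconds corresponding to t in [0, .75)
  for (i in seq_len(ntr)) {
    a <- one_over_f_noise(nt, fs, 1.5, 20)
    b <- one_over_f_noise(nt, fs, 1.5, 20)
    if (depth > 0) {
      if (!reverse)
        b <- inject_coupling(a, b, fs, win, phase_freq, amp_band, depth,
                             lag_ms)
      else
        a <- inject_coupling(b, a, fs, win, phase_freq, amp_band, depth,
                             lag_ms)
    }
    dat[i, 1, ] <- a
    dat[i, 2, ] <- b
  }
  make_epochs(dat, fs = fs,
              channels = data.frame(name = c("A", "B"),
                                    region = c("fusiform", "amygdala"),
                                    hemisphere = "L", patient = "O1",
                                    group = "O"))
}

# Simulated subject-level difference maps for the cluster test: iid
# standard-normal pixels, optionally with a constant block added over the
# gamma band x early window.
null_maps <- function(n, freqs, tt, effect = 0) {
  lapply(seq_len(n), function(i) {
    m <- matrix(stats::rnorm(length(freqs) * length(tt)), length(freqs))
    if (effect != 0) {
      fi <- freqs >= 45 & freqs <= 150
      ti <- tt >= 0 & tt <= 0.75
      m[fi, ti] <- m[fi, ti] + effect
    }
    m
  })
}
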
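## Induced-power analysis: ERP subtraction, Morlet wavelet decomposition
## over 40 log-spaced frequencies (1-200 Hz), decibel baselining against the
## 1100 ms pre-stimulus span, and windowed gamma-band power extraction.

#' The canonical 40-point logarithmic frequency axis, 1 to 200 Hz
#'
#' @param n number of frequencies
#' @param f_lo,f_hi endpoints (Hz)
#' @return numeric vector with exactly equal log spacing
#' @export
morlet_frequencies <- function(n = 40, f_lo = 1, f_hi = 200) {
  exp(seq(log(f_lo), log(f_hi), length.out = n))
}

#' Subtract the trial-average (ERP) from each epoch
#'
#' Removes everything phase-locked to stimulus onset so the subsequent
#' power analysis reflects induced, not evoked, activity. The per-channel
#' average over all kept trials is subtracted from each kept trial.
#'
#' @param ep an `eeg_epochs` object (bipolar-referenced for the canonical
#'   gamma path)
#' @return `eeg_epochs` of residuals
#' @export
subtract_erp <- function(ep) {
  d <- dim(ep$data)
  for (ch in seq_len(d[2])) {
    keep <- which(ep$kept_mask[, ch])
    if (length(keep) < 1) next
    avg <- colMeans(matrix(ep$data[keep, ch, ], ncol = d[3]))
    ep$data[keep, ch, ] <- sweep(matrix(ep$data[keep, ch, ], ncol = d[3]),
                                 2, avg)
  }
  ep
}

#' Morlet wavelet power of an epoch set
#'
#' FFT-based convolution with complex Morlet wavelets (cycles increasing
#' logarithmically with frequency, see [morlet_cycles()]); power is the
#' squared coefficient magnitude halved, i.e. a sinusoid of amplitude A
#' maps to its variance A^2/2 in uV^2. Epochs are reflect-padded inside the
#' transform so edges stay clean. The time axis may be decimated by
#' `decim` to keep maps compact.
#'
#' @param ep an `eeg_epochs` object
#' @param freqs frequency axis (Hz)
#' @param decim keep every `decim`-th time sample
#' @return object of class `fg_tfr`: power [trials, channels, freqs, time]
#'   (uV^2), freqs, t, fs, units, kept_mask, category, channels
#' @export
morlet_power <- function(ep, freqs = morlet_frequencies(), decim = 4L) {
  d <- dim(ep$data)
  ti <- seq.int(1L, d[3], by = decim)
  pw <- array(NA_real_, dim = c(d[1], d[2], length(freqs), length(ti)))
  for (ch in seq_len(d[2])) {
    co <- morlet_transform(t(matrix(ep$data[, ch, ], nrow = d[1], ncol = d[3])),
                           ep$fs, freqs)
    pw[, ch, , ] <- 0.5 * Mod(co[, , ti, drop = FALSE])^2
  }
  structure(list(power = pw, freqs = freqs, t = ep$t[ti], fs = ep$fs,
                 units = "uV^2", baseline_span = NULL,
                 kept_mask = ep$kept_mask, category = ep$category,
                 channels = ep$channels), class = "fg_tfr")
}

#' @export
print.fg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat("<fg_tfr>", d[1], "trials x", d[2], "channels x", d[3], "freqs x",
      d[4], "times;", x$units, "\n")
  invisible(x)
}

#' Average a time-frequency map over kept trials
#'
#' Raw power maps average in the power domain; decibel maps in the decibel
#' domain.
#'
#' @param tf an `fg_tfr`
#' @param categories categories to include (default all)
#' @return `fg_tfr` with a singleton trial dimension
#' @export
tfr_average <- function(tf, categories = unique(tf$category)) {
  d <- dim(tf$power)
  out <- array(NA_real_, dim = c(1, d[2], d[3], d[4]))
  sel <- tf$category %in% categories
  for (ch in seq_len(d[2])) {
    keep <- which(sel & tf$kept_mask[, ch])
    if (!length(keep)) stop("no kept trials to average on channel ", ch)
    out[1, ch, , ] <- apply(tf$power[keep, ch, , , drop = FALSE], c(3, 4),
                            mean)
  }
  tf$power <- out
  tf$kept_mask <- matrix(TRUE, 1, d[2])
  tf$category <- "average"
  tf
}

#' Decibel baseline normalization
#'
#' dB(t, f) = 10 log10(P(t, f) / B(f)) with the reference B(f) taken per
#' channel and frequency as the log-domain mean of trial-averaged power
#' over the pre-stimulus baseline span. Centring the baseline in the log
#' domain makes the dB map average exactly zero over the baseline; it
#' coincides with an arithmetic-mean reference as baseline variability
#' vanishes. Single-trial maps are converted with the same common B(f).
#'
#' @param tf an `fg_tfr` in uV^2
#' @param span baseline span in seconds, default [-1.1, 0)
#' @return `fg_tfr` in dB with `baseline_span` set
#' @export
baseline_db <- function(tf, span = c(-1.1, 0)) {
  if (tf$units != "uV^2") stop("baseline_db expects a raw power map")
  bl <- span_idx(tf$t, span[1], span[2])
  if (!length(bl)) stop("baseline span outside the epoch")
  d <- dim(tf$power)
  for (ch in seq_len(d[2])) {
    keep <- which(tf$kept_mask[, ch])
    pbar <- apply(tf$power[keep, ch, , , drop = FALSE], c(3, 4), mean)
    if (any(pbar[, bl] <= 0))
      stop("nonpositive baseline power on channel ", ch)
    logB <- rowMeans(log10(pbar[, bl, drop = FALSE]))      # per frequency
    tf$power[, ch, , ] <- 10 * (log10(tf$power[, ch, , , drop = FALSE]) -
                                  rep(logB, each = d[1]))
  }
  tf$units <- "dB"
  tf$baseline_span <- span
  tf
}

#' Windowed gamma-band power per trial
#'
#' Mean decibel power over 45-150 Hz and the region's assigned analysis
#' window (hippocampus: 250-1000 ms late-onset; amygdala, fusiform,
#' parahippocampal: 0-750 ms early-onset), one row per kept trial and
#' channel, with metadata for the mixed-effects models.
#'
#' @param tf an `fg_tfr` in dB
#' @param band gamma band (Hz)
#' @return data.frame: patient, group, hemisphere, region, channel, trial,
#'   category, gamma_db
#' @export
window_gamma_power <- function(tf, band = c(45, 150)) {
  if (tf$units != "dB") stop("window_gamma_power expects a dB map")
  fi <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  d <- dim(tf$power)
  res <- vector("list", d[2])
  for (ch in seq_len(d[2])) {
    region <- tf$channels$region[ch]
    win <- region_gamma_window(region)
    ti <- span_idx(tf$t, win[1], win[2])
    keep <- which(tf$kept_mask[, ch])
    if (!length(keep)) next
    vals <- apply(tf$power[keep, ch, fi, ti, drop = FALSE], 1, mean)
    info <- tf$channels[ch, ]
    res[[ch]] <- data.frame(
      patient = info$patient, group = info$group,
      hemisphere = info$hemisphere, region = region, channel = info$name,
      trial = keep, category = tf$category[keep], gamma_db = vals,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
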
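## Ingest, resampling, re-referencing, epoching, and the standard-deviation
## artifact rejection rule.

#' Read a recording and its event table
#'
#' Joins an EDF file with a channel-metadata TSV (columns channel, region,
#' hemisphere, patient, group) and an events TSV (columns onset_s,
#' category, duration_s). EDF channels without metadata are dropped with a
#' warning; metadata row order does not matter.
#'
#' @param edf_path EDF file
#' @param channels_tsv channel metadata TSV
#' @param events_tsv events TSV
#' @return list(recording = [eeg_recording()], events = data.frame)
#' @export
read_recording <- function(edf_path, channels_tsv, events_tsv) {
  for (p in c(edf_path, channels_tsv, events_tsv))
    if (!file.exists(p)) stop("missing file: ", p)
  raw <- read_edf(edf_path)
  if (!raw$fs %in% c(1024, 2048))
    stop("sampling rate ", raw$fs, " not in {1024, 2048}")
  meta <- read.delim(channels_tsv, stringsAsFactors = FALSE)
  ## channel names repeat across patients in a pooled metadata table;
  ## restrict to the EDF's patient when possible
  if ("patient" %in% names(meta) && raw$patient %in% meta$patient)
    meta <- meta[meta$patient == raw$patient, , drop = FALSE]
  ev <- read.delim(events_tsv, stringsAsFactors = FALSE)
  if (!nrow(ev)) stop("empty events table: ", events_tsv)
  keep <- raw$labels %in% meta$channel
  if (any(!keep))
    warning("dropping EDF channels without metadata: ",
            paste(raw$labels[!keep], collapse = ", "))
  if (!any(keep)) stop("no EDF channel matches the metadata table")
  labels <- raw$labels[keep]
  m <- meta[match(labels, meta$channel), ]
  chan <- data.frame(name = labels, region = m$region,
                     hemisphere = m$hemisphere, patient = m$patient,
                     group = m$group, stringsAsFactors = FALSE)
  rec <- eeg_recording(raw$data[keep, , drop = FALSE], raw$fs, chan)
  dur <- ncol(rec$data) / rec$fs
  if (any(ev$onset_s - 1.1 < 0 | ev$onset_s + 1.5 > dur))
    stop("event(s) outside recording: onsets ",
         paste(round(ev$onset_s[ev$onset_s - 1.1 < 0 | ev$onset_s + 1.5 > dur],
                     3), collapse = ", "))
  if (is.unsorted(ev$onset_s, strictly = TRUE))
    stop("event onsets must be strictly increasing")
  list(recording = rec, events = ev)
}

#' Down-sample a 2048 Hz recording to 1024 Hz
#'
#' Applies a zero-phase FIR anti-alias low-pass before decimating by two.
#' A 1024 Hz recording passes through unchanged; other rates are rejected.
#' Event onsets are expressed in seconds and are unaffected.
#'
#' @param rec an [eeg_recording()]
#' @return an [eeg_recording()] at 1024 Hz
#' @export
resample_to_1024 <- function(rec) {
  if (rec$fs == 1024) return(rec)
  if (rec$fs != 2048) stop("sampling rate ", rec$fs, " not in {1024, 2048}")
  h <- signal::fir1(128, 0.45)  # cutoff ~460 Hz at fs = 2048
  X <- t(apply(rec$data, 1, function(x) signal::filtfilt(h, x)))
  if (nrow(rec$data) == 1) X <- matrix(X, nrow = 1)
  eeg_recording(X[, seq(1, ncol(X), by = 2), drop = FALSE], 1024,
                rec$channels)
}

#' Re-reference a recording
#'
#' `fz_monopolar`: every depth channel minus the scalp Fz channel (Fz
#' itself is removed from the output). `bipolar`: adjacent-contact
#' differences within each (patient, region, hemisphere) electrode, named
#' "A-B"; region metadata is inherited and singleton contact groups are
#' dropped with a warning.
#'
#' @param rec an [eeg_recording()]
#' @param mode "fz_monopolar" or "bipolar"
#' @return an [eeg_recording()]
#' @export
rereference <- function(rec, mode = c("fz_monopolar", "bipolar")) {
  mode <- match.arg(mode)
  ch <- rec$channels
  depth <- ch$region != "scalp-Fz"
  if (mode == "fz_monopolar") {
    fz <- which(ch$name == "Fz" | ch$region == "scalp-Fz")
    if (!length(fz)) stop("fz_monopolar reference requires an Fz channel")
    X <- sweep(rec$data[depth, , drop = FALSE], 2, rec$data[fz[1], ])
    out <- eeg_recording(X, rec$fs, ch[depth, , drop = FALSE])
    out$reference <- "fz_monopolar"
    return(out)
  }
  key <- interaction(ch$patient, ch$region, ch$hemisphere, drop = TRUE)
  rows <- list(); dat <- list()
  for (g in levels(key)) {
    idx <- which(key == g & depth)
    if (!length(idx)) next
    if (length(idx) < 2) {
      warning("dropping singleton contact group for bipolar: ",
              ch$name[idx])
      next
    }
    for (j in seq_len(length(idx) - 1)) {
      a <- idx[j]; b <- idx[j + 1]
      dat[[length(dat) + 1]] <- rec$data[a, ] - rec$data[b, ]
      r <- ch[a, , drop = FALSE]
      r$name <- paste0(ch$name[a], "-", ch$name[b])
      rows[[length(rows) + 1]] <- r
    }
  }
  if (!length(dat)) stop("no bipolar pairs could be formed")
  out <- eeg_recording(do.call(rbind, dat), rec$fs, do.call(rbind, rows))
  out$reference <- "bipolar"
  out
}

#' Epoch a recording around stimulus onsets
#'
#' Half-open window [tmin, tmax) relative to each onset; the sample at (or
#' first sample after) the onset is t = 0. The default span serves both the
#' 1000 ms ERP baseline and the 1100 ms decibel baseline.
#'
#' @param rec an [eeg_recording()]
#' @param events event table with onset_s and category
#' @param tmin,tmax epoch span in seconds
#' @return object of class `eeg_epochs`: data (trials x channels x time),
#'   t, fs, reference, kept_mask, category, channels
#' @export
epoch_recording <- function(rec, events, tmin = -1.1, tmax = 1.5) {
  fs <- rec$fs
  n <- ncol(rec$data)
  smp <- seq.int(round(tmin * fs), round(tmax * fs) - 1L)
  tt <- smp / fs
  on_idx <- ceiling(events$onset_s * fs - 1e-9) + 1L
  lo <- on_idx + smp[1]; hi <- on_idx + smp[length(smp)]
  bad <- which(lo < 1 | hi > n)
  if (length(bad))
    stop("epoch window outside recording for event(s): ",
         paste(bad, collapse = ", "))
  arr <- array(0, dim = c(nrow(events), nrow(rec$data), length(smp)))
  for (i in seq_len(nrow(events)))
    arr[i, , ] <- rec$data[, (on_idx[i] + smp[1]):(on_idx[i] + smp[length(smp)]),
                           drop = FALSE]
  structure(list(
    data = arr, t = tt, fs = fs,
    reference = rec$reference %||% "raw",
    kept_mask = matrix(TRUE, nrow(events), nrow(rec$data)),
    category = events$category,
    channels = rec$channels), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs>", d[1], "trials x", d[2], "channels x", d[3],
      "samples [", min(x$t), ",", max(x$t) + 1 / x$fs, ") s,",
      x$reference, "reference;", sum(x$kept_mask), "/", length(x$kept_mask),
      "trial-channels kept\n")
  invisible(x)
}

#' Reject outlier epochs by the 2.5 x mean-SD rule
#'
#' Per channel: the standard deviation of every epoch over its full time
#' span is compared with the mean of those standard deviations across all
#' epochs; epochs exceeding `factor` times that mean are masked out (data
#' untouched). The rule is scale-invariant and applied independently per
#' channel.
#'
#' @param ep an `eeg_epochs` object
#' @param factor rejection multiplier (default 2.5)
#' @return `ep` with an updated `kept_mask`
#' @export
reject_outlier_epochs <- function(ep, factor = 2.5) {
  d <- dim(ep$data)
  if (d[1] < 2) stop("need at least 2 trials for outlier rejection")
  sds <- apply(ep$data, c(1, 2), stats::sd)      # trials x channels
  thr <- factor * colMeans(sds)
  keep <- sweep(sds, 2, thr, `<=`)
  ep$kept_mask <- keep
  dead <- colSums(keep) == 0
  if (any(dead))
    warning("all trials rejected on channel(s): ",
            paste(ep$channels$name[dead], collapse = ", "))
  ep
}

#' Band-pass filter epochs for ERP analysis
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass,
#' 0.5-20 Hz by default. Each trial is reflect-padded by one second before
#' filtering so filter transients stay outside the epoch.
#'
#' @param ep an `eeg_epochs` object
#' @param f_lo,f_hi band edges (Hz)
#' @return filtered `eeg_epochs`
#' @export
bandpass_erp <- function(ep, f_lo = 0.5, f_hi = 20) {
  bf <- signal::butter(4, c(f_lo, f_hi) / (ep$fs / 2), type = "pass")
  d <- dim(ep$data)
  pad <- min(d[3] - 1L, as.integer(ep$fs))
  for (ch in seq_len(d[2])) {
    m <- ep$data[, ch, ]
    if (d[1] == 1) m <- matrix(m, nrow = 1)
    for (i in seq_len(d[1])) {
      x <- m[i, ]
      xp <- c(x[pad:1], x, x[d[3]:(d[3] - pad + 1)])
      ep$data[i, ch, ] <- signal::filtfilt(bf, xp)[pad + seq_len(d[3])]
    }
  }
  ep
}

## Indices of the epoch time axis inside [lo, hi) seconds.
span_idx <- function(t, lo, hi) which(t >= lo - 1e-12 & t < hi - 1e-12)
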
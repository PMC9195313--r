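## Event-related potentials: per-trial baseline correction over the 1000 ms
## pre-stimulus span, kept-trial averaging, display sign flip (x -1, so
## negative deflections plot upward), and 80 ms peak-window amplitudes for
## the three nominal peaks N110 / N240 / N360.

#' Peak-window definitions
#'
#' 80 ms windows centred on the nominal peak latencies 110, 240 and 360 ms.
#'
#' @return data.frame with columns peak, lo_ms, hi_ms
#' @export
peak_windows <- function() {
  data.frame(peak = c("N110", "N240", "N360"),
             lo_ms = c(70, 200, 320), hi_ms = c(150, 280, 400))
}

## trials x time matrix of one channel, baseline-corrected per trial.
baseline_correct <- function(m, t, span = c(-1, 0)) {
  bl <- span_idx(t, span[1], span[2])
  m - rowMeans(m[, bl, drop = FALSE])
}

#' Compute an event-related potential
#'
#' Averages kept trials of the requested categories per channel, after
#' per-trial subtraction of the mean over the [-1, 0) s baseline, then
#' multiplies by -1 for display polarity.
#'
#' @param ep an `eeg_epochs` object (Fz-referenced, band-passed for the
#'   canonical ERP path)
#' @param categories categories to include (default: all present)
#' @return list of class `erp_waveform`: mean (channels x time, display
#'   sign), n_trials per channel, t, channels
#' @export
compute_erp <- function(ep, categories = unique(ep$category)) {
  missing_cat <- setdiff(categories, unique(ep$category))
  if (length(missing_cat))
    stop("no trials for category: ", paste(missing_cat, collapse = ", "))
  sel <- ep$category %in% categories
  d <- dim(ep$data)
  out <- matrix(0, d[2], d[3])
  nt <- integer(d[2])
  for (ch in seq_len(d[2])) {
    keep <- sel & ep$kept_mask[, ch]
    if (!any(keep))
      stop("no kept trials on channel ", ep$channels$name[ch],
           " for categories ", paste(categories, collapse = ", "))
    m <- matrix(ep$data[keep, ch, ], ncol = d[3])
    out[ch, ] <- -colMeans(baseline_correct(m, ep$t))
    nt[ch] <- sum(keep)
  }
  structure(list(mean = out, n_trials = nt, t = ep$t,
                 channels = ep$channels), class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat("<erp_waveform>", nrow(x$mean), "channels,",
      paste(range(x$n_trials), collapse = "-"), "trials/channel\n")
  invisible(x)
}

#' Trial-level peak-window amplitudes
#'
#' One row per kept trial x channel x peak window: the mean of the
#' baseline-corrected, sign-flipped signal over the window, with full
#' metadata for the mixed-effects models.
#'
#' @param ep an `eeg_epochs` object (band-passed, Fz-referenced, masked)
#' @param windows peak-window table, see [peak_windows()]
#' @return data.frame: patient, group, hemisphere, region, channel, trial,
#'   category, peak, amplitude_uV
#' @export
trial_peak_amplitudes <- function(ep, windows = peak_windows()) {
  d <- dim(ep$data)
  if (any(windows$hi_ms / 1000 > max(ep$t) + 1 / ep$fs) ||
      any(windows$lo_ms / 1000 < min(ep$t)))
    stop("peak window outside epoch span")
  win_idx <- lapply(seq_len(nrow(windows)), function(w)
    span_idx(ep$t, windows$lo_ms[w] / 1000, windows$hi_ms[w] / 1000))
  res <- vector("list", d[2])
  for (ch in seq_len(d[2])) {
    keep <- which(ep$kept_mask[, ch])
    if (!length(keep)) next
    m <- -baseline_correct(matrix(ep$data[keep, ch, ], ncol = d[3]), ep$t)
    amps <- vapply(win_idx, function(ii) rowMeans(m[, ii, drop = FALSE]),
                   numeric(length(keep)))
    info <- ep$channels[ch, ]
    res[[ch]] <- data.frame(
      patient = info$patient, group = info$group,
      hemisphere = info$hemisphere, region = info$region,
      channel = info$name,
      trial = rep(keep, times = nrow(windows)),
      category = rep(ep$category[keep], times = nrow(windows)),
      peak = rep(windows$peak, each = length(keep)),
      amplitude_uV = as.vector(amps), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
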
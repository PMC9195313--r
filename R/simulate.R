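## Synthetic two-group iEEG study generator. Per channel the signal is
## 1/f^alpha background + phase-locked evoked deflections + induced gamma
## bursts with random per-trial carrier phase, with optional lagged
## cross-regional phase-to-amplitude modulation applied afterwards.

#' Continuous multichannel recording
#'
#' @param data channels x samples matrix (uV)
#' @param fs sampling rate (Hz)
#' @param channels data.frame with columns name, region, hemisphere,
#'   patient, group
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, channels) {
  stopifnot(is.matrix(data), nrow(data) == nrow(channels))
  needed <- c("name", "region", "hemisphere", "patient", "group")
  if (!all(needed %in% names(channels)))
    stop("channel table must have columns: ", paste(needed, collapse = ", "))
  if (anyNA(data)) stop("recording contains NaN/NA samples")
  structure(list(data = data, fs = fs,
                 channels = as.data.frame(channels, stringsAsFactors = FALSE)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$fs, "Hz (", round(ncol(x$data) / x$fs, 1), "s )\n")
  invisible(x)
}

#' Schedule stimulus events
#'
#' Draws one onset per (category, repetition) with the categories in a
#' seed-determined random order. Consecutive onset-to-onset gaps are
#' stimulus duration + a uniform interstimulus interval + the fixation
#' cross; the recording is padded by 2 s at both ends so the earliest
#' pre-stimulus baseline exists.
#'
#' @param config a [sim_config()]
#' @param seed RNG seed; defaults to the config seed
#' @return data.frame (onset_s, category, duration_s) with attribute
#'   `recording_s`, the total recording duration in whole seconds
#' @export
schedule_events <- function(config, seed = config$seed) {
  if (config$n_per_category < 1)
    stop("configuration error: n_per_category must be >= 1")
  n_ev <- 6L * config$n_per_category
  with_seed(seed, {
    cats <- sample(rep(ALL_CATEGORIES, config$n_per_category))
    isi <- stats::runif(n_ev - 1, config$isi_range_ms[1],
                        config$isi_range_ms[2]) / 1000
    gaps <- config$stim_ms / 1000 + isi + config$fixation_ms / 1000
    onsets <- 2 + cumsum(c(0, gaps))
    ev <- data.frame(onset_s = onsets, category = cats,
                     duration_s = config$stim_ms / 1000)
    attr(ev, "recording_s") <- ceiling(onsets[n_ev] + config$stim_ms / 1000 + 2)
    ev
  })
}

#' Inject lagged cross-regional phase-amplitude coupling
#'
#' During the given post-stimulus windows, the content of `amp_sig` inside
#' `amp_band` is multiplied by `1 + depth * cos(phi(t - lag))`, where `phi`
#' is the Morlet phase of `phase_sig` at `phase_freq`. Ramped at window
#' edges so the modulation factor returns smoothly to 1.
#'
#' @param phase_sig numeric vector, the phase-providing channel
#' @param amp_sig numeric vector, the channel whose gamma envelope is
#'   modulated (returned modified)
#' @param fs sampling rate (Hz)
#' @param windows matrix/data.frame with columns start, end (seconds)
#' @param phase_freq modulating phase frequency, 3-20 Hz
#' @param amp_band length-2, modulated band within [45, 200] Hz
#' @param depth modulation depth in [0, 1]
#' @param lag_ms signed lag: positive means the amplitude envelope follows
#'   the phase by that many milliseconds
#' @param ramp_s edge-ramp duration (s)
#' @return modified `amp_sig`
#' @export
inject_coupling <- function(phase_sig, amp_sig, fs, windows, phase_freq,
                            amp_band, depth, lag_ms = 0, ramp_s = 0.05) {
  stopifnot(length(phase_sig) == length(amp_sig))
  if (phase_freq < 3 || phase_freq > 20)
    stop("phase_freq outside [3, 20] Hz")
  if (amp_band[1] < 45 || amp_band[2] > 200)
    stop("amp_band outside [45, 200] Hz")
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  windows <- as.matrix(windows)
  if (any(abs(lag_ms) / 1000 >= windows[, 2] - windows[, 1]))
    stop("lag exceeds window length")
  if (depth == 0) return(amp_sig)
  n <- length(amp_sig)
  phi <- Arg(morlet_transform(matrix(phase_sig), fs, phase_freq)[1, 1, ])
  lag <- round(lag_ms / 1000 * fs)
  idx <- ((seq_len(n) - 1 - lag) %% n) + 1  # phi at t - lag, circular at edges
  phi_l <- phi[idx]
  w <- numeric(n)
  for (r in seq_len(nrow(windows))) {
    i0 <- max(1L, floor(windows[r, 1] * fs) + 1L)
    i1 <- min(n, ceiling(windows[r, 2] * fs))
    w[i0:i1] <- pmax(w[i0:i1],
                     tukey_window(i1 - i0 + 1,
                                  alpha = min(1, 2 * ramp_s * fs / (i1 - i0 + 1))))
  }
  gamma_part <- fft_bandpass(amp_sig, fs, amp_band[1], amp_band[2])
  amp_sig + gamma_part * (depth * w * cos(phi_l))
}

#' Synthesize one patient's recording
#'
#' Builds every configured depth contact plus a scalp Fz channel. Evoked
#' deflections are identical across the contacts of a region (far-field
#' behaviour: visible against Fz, cancelled by bipolar derivation); induced
#' gamma bursts are independent per contact with random carrier phase and
#' are calibrated so their mean power over the burst window elevates the
#' channel's own band power by the configured number of decibels.
#' Cross-regional coupling uses the phase of the region's leading bipolar
#' pair (contact 1 minus contact 2) so the injected relation survives
#' bipolar re-referencing.
#'
#' @param config a [sim_config()]
#' @param events event table from [schedule_events()]
#' @param patient patient identifier (e.g. "O1")
#' @param group "O" or "M"
#' @param hemisphere "L" or "R"
#' @param seed RNG seed for this recording
#' @return an [eeg_recording()]
#' @export
synthesize_recording <- function(config, events, patient, group,
                                 hemisphere = "L",
                                 seed = derive_seed(config$seed, patient)) {
  fs <- config$fs
  dur <- attr(events, "recording_s")
  if (is.null(dur))
    dur <- ceiling(max(events$onset_s + events$duration_s) + 2)
  n <- as.integer(dur * fs)
  if (any(events$onset_s - 1.1 < 0 | events$onset_s + 1.5 > dur))
    stop("events outside recording duration")
  bad <- setdiff(unique(config$erp_components$region), REGIONS)
  if (length(bad)) stop("configuration error: unknown region label: ", bad[1])

  regs <- rep(config$regions, each = config$n_contacts)
  kk <- rep(seq_len(config$n_contacts), length(config$regions))
  chan <- data.frame(
    name = paste0(REGION_CODES[regs], kk, "_", hemisphere),
    region = regs, hemisphere = hemisphere, patient = patient, group = group,
    stringsAsFactors = FALSE)
  chan <- rbind(chan, data.frame(name = "Fz", region = "scalp-Fz",
                                 hemisphere = "Z", patient = patient,
                                 group = group))

  with_seed(seed, {
    X <- matrix(0, nrow(chan), n)
    for (ci in seq_len(nrow(chan))) {
      region <- chan$region[ci]
      sig <- one_over_f_noise(n, fs, config$noise$one_over_f_exponent,
                              if (region == "scalp-Fz")
                                config$noise$scale / 2 else config$noise$scale)
      if (region != "scalp-Fz") {
        ## deterministic, so identical on every contact of the region
        sig <- sig + evoked_component(config, events, region, group, fs, n)
        sig <- add_gamma_bursts(sig, config, events, region, group, fs)
      }
      X[ci, ] <- sig
    }
    X <- apply_coupling_specs(X, chan, config, events, fs)
    eeg_recording(X, fs, chan)
  })
}

## Sum of Gaussian-windowed deflections for all matching components/events.
evoked_component <- function(config, events, region, group, fs, n) {
  out <- numeric(n)
  comp <- config$erp_components
  comp <- comp[comp$region == region & group_matches(comp$group, group), ,
               drop = FALSE]
  if (!nrow(comp)) return(out)
  tt <- seq_len(n) / fs
  for (r in seq_len(nrow(comp))) {
    sigma <- comp$width_ms[r] / 1000 / 2.355  # width = FWHM
    ev <- events[category_matches(comp$category[r], events$category), ,
                 drop = FALSE]
    for (o in ev$onset_s) {
      mu <- o + comp$center_ms[r] / 1000
      i0 <- max(1L, floor((mu - 5 * sigma) * fs))
      i1 <- min(n, ceiling((mu + 5 * sigma) * fs))
      out[i0:i1] <- out[i0:i1] +
        comp$amplitude_uV[r] * exp(-(tt[i0:i1] - mu)^2 / (2 * sigma^2))
    }
  }
  out
}

## Add per-trial random-phase band-limited bursts, calibrated against the
## channel's pre-burst band power so the windowed mean power rises by
## db_increase decibels.
add_gamma_bursts <- function(sig, config, events, region, group, fs) {
  eff <- config$gamma_effects
  eff <- eff[eff$region == region & group_matches(eff$group, group), ,
             drop = FALSE]
  if (!nrow(eff)) return(sig)
  for (r in seq_len(nrow(eff))) {
    p_bg <- stats::var(fft_bandpass(sig, fs, eff$f_lo[r], eff$f_hi[r]))
    cfac <- 10^(eff$db_increase[r] / 10) - 1
    wlen <- round((eff$win_hi_ms[r] - eff$win_lo_ms[r]) / 1000 * fs)
    env <- tukey_window(wlen, alpha = 0.2)
    ev <- events[category_matches(eff$category[r], events$category), ,
                 drop = FALSE]
    for (o in ev$onset_s) {
      i0 <- floor((o + eff$win_lo_ms[r] / 1000) * fs) + 1L
      idx <- i0:(i0 + wlen - 1L)
      b <- band_noise(wlen, fs, eff$f_lo[r], eff$f_hi[r],
                      config$noise$one_over_f_exponent) * env
      b <- b * sqrt(cfac * p_bg / mean(b^2))
      sig[idx] <- sig[idx] + b
    }
  }
  sig
}

## Apply every coupling spec to the synthesized channel matrix. The phase
## source is the leading bipolar pair of the phase region (or its single
## contact); all contacts of the amplitude region are modulated jointly.
apply_coupling_specs <- function(X, chan, config, events, fs) {
  specs <- config$coupling_specs
  if (is.null(specs) || !nrow(specs)) return(X)
  for (r in seq_len(nrow(specs))) {
    pidx <- which(chan$region == specs$phase_region[r])
    aidx <- which(chan$region == specs$amp_region[r])
    if (!length(pidx) || !length(aidx)) next
    phase_sig <- if (length(pidx) >= 2) X[pidx[1], ] - X[pidx[2], ]
                 else X[pidx[1], ]
    ev <- events[category_matches(specs$categories[r], events$category), ,
                 drop = FALSE]
    if (!nrow(ev)) next
    win <- cbind(ev$onset_s, ev$onset_s + 0.75)
    for (ai in aidx) {
      X[ai, ] <- inject_coupling(phase_sig, X[ai, ], fs, win,
                                 specs$phase_freq_hz[r],
                                 c(specs$amp_lo[r], specs$amp_hi[r]),
                                 specs$modulation_depth[r], specs$lag_ms[r])
    }
  }
  X
}

#' Generate a complete synthetic study on disk
#'
#' Writes one EDF file and one events TSV per patient, plus a combined
#' channel-metadata TSV. Deterministic under the config seed. Hemisphere
#' alternates across patients within each group.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created if missing)
#' @return data.frame manifest with columns patient, group, hemisphere,
#'   edf, events; the channels TSV path is attached as attribute `channels_tsv`
#' @export
generate_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pts <- c(paste0("O", seq_len(config$n_patients_per_group)),
           paste0("M", seq_len(config$n_patients_per_group)))
  grp <- substr(pts, 1, 1)
  hemi <- rep(c("L", "R"), length.out = length(pts))
  chans <- list()
  rows <- list()
  for (i in seq_along(pts)) {
    ev <- schedule_events(config, seed = derive_seed(config$seed,
                                                     paste0("events_", pts[i])))
    rec <- synthesize_recording(config, ev, pts[i], grp[i], hemi[i])
    edf_path <- file.path(out_dir, paste0("sub-", pts[i], ".edf"))
    ev_path <- file.path(out_dir, paste0("sub-", pts[i], "_events.tsv"))
    tryCatch(write_edf(rec, edf_path),
             error = function(e) stop("failed writing ", edf_path, ": ",
                                      conditionMessage(e)))
    write.table(format(ev, digits = 10, trim = TRUE), ev_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    chans[[i]] <- rec$channels
    rows[[i]] <- data.frame(patient = pts[i], group = grp[i],
                            hemisphere = hemi[i], edf = edf_path,
                            events = ev_path, stringsAsFactors = FALSE)
  }
  ch_path <- file.path(out_dir, "channels.tsv")
  allchan <- do.call(rbind, chans)
  names(allchan)[names(allchan) == "name"] <- "channel"
  write.table(allchan, ch_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- do.call(rbind, rows)
  attr(manifest, "channels_tsv") <- ch_path
  manifest
}
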
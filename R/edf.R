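## Minimal EDF (European Data Format) I/O: ASCII header blocks plus 16-bit
## little-endian data records. Covers continuous recordings with a common
## sampling rate across signals and 1-second data records, which is all the
## pipeline produces and consumes. Physical unit is microvolts.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to an EDF file
#'
#' One data record per second; samples are scaled to the 16-bit digital
#' range over a symmetric physical range just covering each channel's
#' extremes, so the round-trip error is at most one digital quantum (LSB).
#' The recording is zero-padded to a whole number of records.
#'
#' @param rec an [eeg_recording()]
#' @param path output file path
#' @return `path`, invisibly; the per-channel LSB (uV) is attached as
#'   attribute `lsb`
#' @export
write_edf <- function(rec, path) {
  X <- rec$data
  nchan <- nrow(X)
  fs <- rec$fs
  nrec <- ceiling(ncol(X) / fs)
  if (ncol(X) < nrec * fs)
    X <- cbind(X, matrix(0, nchan, nrec * fs - ncol(X)))
  pmax <- pmax(apply(abs(X), 1, max), 1e-6)
  pmax <- signif(pmax * 1.0001, 7)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$channels$patient[1], 80),
    edf_field("facegamma synthetic iEEG", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (nchan + 1), 8),
    edf_field("", 44),
    edf_field(nrec, 8), edf_field("1", 8), edf_field(nchan, 4))
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(edf_field(rec$channels$name, 16), collapse = ""),
    paste(edf_field(rep("intracranial", nchan), 80), collapse = ""),
    paste(edf_field(rep("uV", nchan), 8), collapse = ""),
    paste(edf_field(formatC(-pmax, format = "g", digits = 6), 8), collapse = ""),
    paste(edf_field(formatC(pmax, format = "g", digits = 6), 8), collapse = ""),
    paste(edf_field(rep(dmin, nchan), 8), collapse = ""),
    paste(edf_field(rep(dmax, nchan), 8), collapse = ""),
    paste(edf_field(rep("none", nchan), 80), collapse = ""),
    paste(edf_field(rep(fs, nchan), 8), collapse = ""),
    paste(edf_field(rep("", nchan), 32), collapse = ""))
  writeChar(sig_hdr, con, eos = NULL)
  ## re-read the printed physical ranges so the stored scaling matches the
  ## header exactly
  pmax_r <- as.numeric(formatC(pmax, format = "g", digits = 6))
  gain <- (dmax - dmin) / (2 * pmax_r)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    dig <- round((t(X[, idx, drop = FALSE]) + rep(pmax_r, each = fs)) *
                   rep(gain, each = fs)) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(structure(path, lsb = 2 * pmax_r / (dmax - dmin)))
}

#' Read an EDF file
#'
#' @param path EDF file path
#' @return list with elements `data` (channels x samples, physical units),
#'   `fs` (per-signal sampling rate; scalar if common), `labels`
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient_id <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  nr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  X <- matrix(0, ns, nrec * nr[1])
  if (length(unique(nr)) != 1)
    stop("read_edf supports a common sampling rate only")
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = sum(nr), size = 2,
                   endian = "little", signed = TRUE)
    off <- 0
    for (s in seq_len(ns)) {
      X[s, ((r - 1) * nr[s] + 1):(r * nr[s])] <-
        (raw[(off + 1):(off + nr[s])] - dmin[s]) * gain[s] + pmin[s]
      off <- off + nr[s]
    }
  }
  list(data = X, fs = nr[1] / recdur, labels = labels,
       patient = patient_id)
}
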
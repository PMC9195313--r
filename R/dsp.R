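## Low-level signal machinery shared by the simulator and the analysis
## stages: spectrally shaped noise, brick-wall FFT band filters, and the
## complex Morlet transform used for all time-frequency, phase and
## amplitude estimation.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs the expression, restores the caller's RNG state.
#' With `seed = NULL` the expression runs on the ambient RNG stream.
#'
#' @param seed integer seed or NULL
#' @param code expression
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' 1/f^alpha background noise
#'
#' Gaussian noise shaped in the frequency domain so its power spectral
#' density falls off as f^-alpha, then rescaled to a target standard
#' deviation. This is the package's model of ongoing LFP background
#' activity.
#'
#' @param n number of samples
#' @param fs sampling rate (Hz)
#' @param exponent spectral exponent alpha (PSD ~ 1/f^alpha)
#' @param scale target standard deviation (uV)
#' @return numeric vector of length n
#' @export
one_over_f_noise <- function(n, fs, exponent = 1.5, scale = 20) {
  stopifnot(n > 1, fs > 0, exponent >= 0, scale >= 0)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)            # two-sided frequency magnitude
  g <- c(0, f[-1]^(-exponent / 2)) # kill DC
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  if (scale == 0) return(y * 0)
  scale * y / stats::sd(y)
}

#' Brick-wall FFT band-pass
#'
#' Zeroes all Fourier bins outside [f_lo, f_hi] (mirrored on the negative
#' axis). Used for exact band decompositions inside the simulator, where a
#' sharp spectral split is wanted rather than a causal filter.
#'
#' @param x numeric vector
#' @param fs sampling rate (Hz)
#' @param f_lo,f_hi band edges (Hz)
#' @return filtered vector, same length
#' @export
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  keep <- f >= f_lo & f <= f_hi
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' Band-limited spectrally shaped noise
#'
#' 1/f^alpha-shaped Gaussian noise restricted to [f_lo, f_hi], unit
#' variance. Carrier for induced gamma bursts: regenerating it per trial
#' gives a random carrier phase, so bursts vanish from the trial average
#' while contributing single-trial power.
#'
#' @inheritParams fft_bandpass
#' @param n number of samples
#' @param exponent spectral exponent within the band
#' @return numeric vector, unit variance
#' @export
band_noise <- function(n, fs, f_lo, f_hi, exponent = 1.5) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  g <- ifelse(f >= f_lo & f <= f_hi & f > 0, f^(-exponent / 2), 0)
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Tukey (raised-cosine-ramp) window
#'
#' Flat-topped window with cosine ramps covering a fraction `alpha` of its
#' length. Used as the induced-burst envelope so injected band power is
#' constant over the analysis window.
#'
#' @param n window length in samples
#' @param alpha total fraction of the window covered by the two ramps
#' @return numeric vector in [0, 1]
#' @export
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a2 <- alpha / 2
  lo <- t < a2
  hi <- t > 1 - a2
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / a2 - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + a2) / a2)))
  w
}

#' Wavelet cycle count for a frequency
#'
#' Logarithmically increasing number of cycles, 3 at 1 Hz to 10 at 200 Hz,
#' interpolated in log-log so any frequency grid uses a consistent
#' time-frequency trade-off.
#'
#' @param freqs frequencies (Hz)
#' @return cycle counts
#' @export
morlet_cycles <- function(freqs) {
  3 * freqs^(log(10 / 3) / log(200))
}

#' Complex Morlet wavelet transform (FFT convolution)
#'
#' Convolves each column of `mat` with analytic complex Morlet wavelets.
#' Wavelets are defined in the frequency domain as Gaussians of width
#' sigma_f = f / n_cycles with unit gain at the centre frequency doubled for
#' analyticity, so a sinusoid of amplitude A yields coefficient magnitude A.
#' Columns are reflect-padded by three standard deviations of the longest
#' wavelet before convolution, so edge ringing stays out of the returned
#' span.
#'
#' @param mat numeric matrix, time x series
#' @param fs sampling rate (Hz)
#' @param freqs centre frequencies (Hz)
#' @param n_cycles cycles per wavelet; default [morlet_cycles()]
#' @return complex array [series, freq, time]
#' @export
morlet_transform <- function(mat, fs, freqs, n_cycles = morlet_cycles(freqs)) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  ns <- ncol(mat)
  sigma_t <- n_cycles / (2 * pi * freqs)
  pad <- min(n - 1L, ceiling(3 * max(sigma_t) * fs))
  xp <- rbind(mat[pad:1, , drop = FALSE], mat,
              mat[n:(n - pad + 1), , drop = FALSE])
  nfft <- stats::nextn(nrow(xp), c(2, 3, 5))   # 5-smooth length for fast FFTs
  if (nfft > nrow(xp))
    xp <- rbind(xp, matrix(0, nfft - nrow(xp), ns))
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  Fx <- stats::mvfft(xp)
  out <- array(0i, dim = c(ns, length(freqs), n))
  pos <- fgrid <= fs / 2
  for (k in seq_along(freqs)) {
    sf <- freqs[k] / n_cycles[k]
    W <- 2 * exp(-(fgrid - freqs[k])^2 / (2 * sf^2))
    W[!pos] <- 0
    y <- stats::mvfft(Fx * W, inverse = TRUE) / nfft
    out[, k, ] <- t(y[pad + seq_len(n), , drop = FALSE])
  }
  out
}

#' Welch power spectral density estimate
#'
#' Averaged periodogram over Hann-tapered half-overlapping segments.
#' Used for spectral diagnostics of simulated background activity.
#'
#' @param x numeric vector
#' @param fs sampling rate (Hz)
#' @param nseg segment length in samples
#' @return data.frame with columns freq (Hz) and psd (power / Hz)
#' @export
welch_psd <- function(x, fs, nseg = 4096) {
  nseg <- min(nseg, length(x))
  step <- floor(nseg / 2)
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))
  u <- sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * u * fs)
  nf <- floor(nseg / 2)
  data.frame(freq = (seq_len(nf) - 1) * fs / nseg, psd = 2 * p[seq_len(nf)])
}
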
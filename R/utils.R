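#' @keywords internal
"_PACKAGE"

# Zero-phase Butterworth band-pass with odd reflection padding at both ends
# (scipy-style) so that filtfilt edge transients do not leak into slow bands.
zerophase_bandpass <- function(x, fs, hpf_hz, lpf_hz, order = 3) {
  nyq <- fs / 2
  if (!(hpf_hz > 0 && hpf_hz < lpf_hz && lpf_hz < nyq)) {
    stop("band edges must satisfy 0 < hpf < lpf < Nyquist (", nyq, " Hz)")
  }
  bf <- signal::butter(order, c(hpf_hz, lpf_hz) / nyq, type = "pass")
  n <- length(x)
  x <- x - mean(x)   # exact DC removal; avoids slow-pole startup transients
  npad <- min(n - 1L, max(3L * (length(bf$b) - 1L), ceiling(fs / hpf_hz)))
  if (npad > 0) {
    head_ext <- 2 * x[1] - x[seq(npad + 1L, 2L)]
    tail_ext <- 2 * x[n] - x[seq(n - 1L, n - npad)]
    xe <- c(head_ext, x, tail_ext)
  } else {
    xe <- x
  }
  y <- signal::filtfilt(bf, xe)
  y[seq(npad + 1L, npad + n)]
}

# Analytic signal via frequency-domain construction: zero negative
# frequencies, double positive ones. Returns complex vector.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Narrow-band unit-variance noise: white Gaussian noise band-passed to
# [hpf, lpf] and rescaled. Building block of the synthetic forward model.
narrowband_noise <- function(n, fs, hpf_hz = 0.01, lpf_hz = 0.1) {
  z <- zerophase_bandpass(stats::rnorm(n), fs, hpf_hz, lpf_hz)
  s <- stats::sd(z)
  if (s == 0) return(z)
  z / s
}

# Derive a stream of child seeds from one master seed; keeps every seed
# within 32-bit integer range.
child_seeds <- function(seed, n) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
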
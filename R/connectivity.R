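#' Average channel concentrations within ROIs
#'
#' Unweighted mean of the unpruned member channels of each ROI, per
#' chromophore. An ROI whose member channels are all pruned is flagged
#' invalid and its series set to `NA`.
#'
#' @param conc a `nirs_conc` object from [preprocess_recording()].
#' @param map a [roi_channel_map()].
#' @return list of class `roi_timeseries` with `series` (array
#'   `time x ROI x chromophore`), `n_channels` (unpruned members per ROI),
#'   `valid` (logical per ROI) and `sampling_rate_hz`.
#' @export
average_rois <- function(conc, map = roi_channel_map()) {
  stopifnot(inherits(conc, "nirs_conc"), !isTRUE(conc$excluded))
  chroms <- c("hbo", "hbr", "hbt")
  nt <- nrow(conc$hbo)
  nroi <- length(map)
  series <- array(NA_real_, c(nt, nroi, 3),
                  dimnames = list(NULL, names(map), c("HbO", "HbR", "HbT")))
  nch <- integer(nroi)
  for (r in seq_len(nroi)) {
    chans <- setdiff(map[[r]], conc$pruned_channels)
    nch[r] <- length(chans)
    if (length(chans) == 0) next
    for (k in 1:3) {
      X <- conc[[chroms[k]]][, chans, drop = FALSE]
      series[, r, k] <- rowMeans(X)
    }
  }
  structure(list(series = series, n_channels = nch, valid = nch > 0,
                 sampling_rate_hz = conc$sampling_rate_hz %||% 8.138),
            class = "roi_timeseries")
}

# Welch cross-spectral estimates with Hann windows.
welch_spectra <- function(x, y, fs, seglen_s = 120, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, round(seglen_s * fs))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  nf <- floor(nseg / 2) + 1L
  pxx <- pyy <- numeric(nf)
  pxy <- complex(nf)
  for (s in starts) {
    xi <- x[s:(s + nseg - 1L)]
    yi <- y[s:(s + nseg - 1L)]
    X <- stats::fft((xi - mean(xi)) * w)[seq_len(nf)]
    Y <- stats::fft((yi - mean(yi)) * w)[seq_len(nf)]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  freq <- (seq_len(nf) - 1) * fs / nseg
  list(freq = freq, pxx = pxx, pyy = pyy, pxy = pxy,
       n_segments = length(starts))
}

#' Band-averaged magnitude-squared coherence
#'
#' Welch-estimated magnitude-squared coherence
#' `|S_xy|^2 / (S_xx S_yy)` (Hann window, 120-s segments, 50% overlap by
#' default), averaged over the frequencies falling inside the analysis
#' band. Values are clipped to `[0, 1]`.
#'
#' @param x,y numeric series of equal length.
#' @param fs sampling rate, Hz.
#' @param band analysis band in Hz (default `c(0.01, 0.1)`).
#' @param seglen_s Welch segment length in seconds.
#' @param overlap fractional segment overlap.
#' @return scalar coherence in `[0, 1]`.
#' @export
coherence_fc <- function(x, y, fs, band = c(0.01, 0.1),
                         seglen_s = 120, overlap = 0.5) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate pair: constant input series has no spectrum")
  }
  sp <- welch_spectra(x, y, fs, seglen_s, overlap)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(sel)) stop("no Welch frequency bins inside the analysis band")
  coh <- Mod(sp$pxy[sel])^2 / (sp$pxx[sel] * sp$pyy[sel])
  min(1, max(0, mean(coh)))
}

#' Phase-locking value
#'
#' Band-limits both series to the analysis band, extracts instantaneous
#' phases from the analytic signal, and returns
#' `|mean(exp(i (phi_x - phi_y)))|` after discarding 5% of the samples at
#' each end (analytic-signal edge effects).
#'
#' @inheritParams coherence_fc
#' @param edge_trim fraction of samples dropped at each end.
#' @return scalar PLV in `[0, 1]`.
#' @export
plv_fc <- function(x, y, fs, band = c(0.01, 0.1), edge_trim = 0.05) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate pair: constant input series has no phase")
  }
  xb <- zerophase_bandpass(x, fs, band[1], band[2])
  yb <- zerophase_bandpass(y, fs, band[1], band[2])
  dphi <- Arg(analytic_signal(xb)) - Arg(analytic_signal(yb))
  n <- length(dphi)
  tr <- floor(edge_trim * n)
  keep <- seq(tr + 1L, n - tr)
  min(1, Mod(mean(exp(1i * dphi[keep]))))
}

#' Functional-connectivity matrix set for one subject
#'
#' Computes COH and PLV for every ROI pair and chromophore. Matrices are
#' symmetric with unit diagonal; pairs involving an invalid ROI, or
#' degenerate (constant) series, are stored as `NA`.
#'
#' @param roits a [average_rois()] result.
#' @param band analysis band, Hz.
#' @param seglen_s Welch segment length for COH, seconds.
#' @return array of class `fc_matrix_set`:
#'   `estimator (COH, PLV) x chromophore (HbO, HbR, HbT) x ROI x ROI`.
#' @export
fc_matrix_set <- function(roits, band = c(0.01, 0.1), seglen_s = 120) {
  stopifnot(inherits(roits, "roi_timeseries"))
  fs <- roits$sampling_rate_hz
  nroi <- dim(roits$series)[2]
  roin <- dimnames(roits$series)[[2]]
  out <- array(NA_real_, c(2, 3, nroi, nroi),
               dimnames = list(c("COH", "PLV"), c("HbO", "HbR", "HbT"),
                               roin, roin))
  for (k in 1:3) {
    for (i in seq_len(nroi)) out[, k, i, i] <- 1
    for (i in seq_len(nroi - 1)) {
      if (!roits$valid[i]) next
      xi <- roits$series[, i, k]
      for (j in seq(i + 1, nroi)) {
        if (!roits$valid[j]) next
        yj <- roits$series[, j, k]
        coh <- tryCatch(coherence_fc(xi, yj, fs, band, seglen_s),
                        error = function(e) NA_real_)
        plv <- tryCatch(plv_fc(xi, yj, fs, band),
                        error = function(e) NA_real_)
        out["COH", k, i, j] <- out["COH", k, j, i] <- coh
        out["PLV", k, i, j] <- out["PLV", k, j, i] <- plv
      }
    }
  }
  class(out) <- c("fc_matrix_set", class(out))
  out
}

#' Flatten an FC matrix set to named features
#'
#' Upper-triangle values in the fixed ordering estimator, then
#' chromophore, then ROI pair (i < j); names like `COH_HbO_ROI1_ROI2`.
#' A full 10-ROI montage yields 270 features (2 x 3 x 45).
#'
#' @param fc an [fc_matrix_set()] array.
#' @return named numeric vector.
#' @export
fc_features <- function(fc) {
  ests <- dimnames(fc)[[1]]
  chroms <- dimnames(fc)[[2]]
  roin <- dimnames(fc)[[3]]
  nroi <- length(roin)
  vals <- c()
  for (e in ests) {
    for (h in chroms) {
      for (i in seq_len(nroi - 1)) {
        for (j in seq(i + 1, nroi)) {
          v <- fc[e, h, i, j]
          names(v) <- paste(e, h, roin[i], roin[j], sep = "_")
          vals <- c(vals, v)
        }
      }
    }
  }
  vals
}
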
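#' Molar extinction coefficients for hemoglobin
#'
#' Compiled literature extinction coefficients of oxy- and deoxy-hemoglobin
#' at the two laser wavelengths of the device (780 and 850 nm), in
#' mM^-1 cm^-1. Shipping a fixed, named table makes concentration results
#' bit-reproducible against a declared coefficient set.
#'
#' @return 2x2 numeric matrix, rows `nm780`/`nm850`, columns `HbO`/`HbR`.
#' @export
hb_extinction_table <- function() {
  m <- matrix(
    c(0.7360, 1.1050,   # 780 nm: HbO, HbR
      1.0580, 0.6910),  # 850 nm: HbO, HbR
    nrow = 2, byrow = TRUE,
    dimnames = list(c("nm780", "nm850"), c("HbO", "HbR"))
  )
  attr(m, "units") <- "mM^-1 cm^-1"
  attr(m, "table_id") <- "nirscreen_hb_extinction_v1"
  m
}

#' Construct a raw fNIRS recording
#'
#' @param intensity numeric array `time x channel x wavelength` of raw
#'   continuous-wave intensities (arbitrary units, strictly positive).
#' @param sampling_rate_hz sampling rate in Hz (device default 8.138).
#' @param wavelengths_nm the two laser wavelengths (default `c(780, 850)`).
#' @param distance_cm source-detector separation in cm (default 3.0).
#' @param subject_id subject identifier.
#' @return object of class `nirs_recording`.
#' @export
raw_recording <- function(intensity, sampling_rate_hz = 8.138,
                          wavelengths_nm = c(780, 850),
                          distance_cm = 3.0, subject_id = "S1") {
  stopifnot(length(dim(intensity)) == 3)
  if (dim(intensity)[3] != 2L) stop("exactly two wavelengths are required")
  if (dim(intensity)[1] < 2L) stop("at least 2 time samples are required")
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    bad <- which(!is.finite(intensity) | intensity <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at sample %d, channel %d, wavelength %d",
                 bad[1], bad[2], bad[3]))
  }
  structure(
    list(intensity = intensity, sampling_rate_hz = sampling_rate_hz,
         wavelengths_nm = wavelengths_nm, distance_cm = distance_cm,
         subject_id = subject_id),
    class = "nirs_recording"
  )
}

#' Preprocessing configuration
#'
#' Bundles every tunable of the preprocessing chain with its default.
#' Defaults follow the standard Homer-style resting-state chain:
#' SNR pruning at 25 dB, motion detection with a 2-s sliding window and a
#' 4-s mask (50 x SD or 5 OD-unit excursions), spline correction with
#' smoothing parameter 0.99, a 0.01-0.1 Hz zero-phase band-pass, removal
#' of 1 principal component, and Beer-Lambert conversion with a partial
#' pathlength factor of 6 at 3.0 cm separation.
#'
#' @param snr_threshold_db channel pruning threshold in dB.
#' @param t_motion_s motion detection sliding-window length, seconds.
#' @param t_mask_s seconds masked on each side of a detected excursion.
#' @param stdev_thresh excursion threshold in units of baseline OD SD.
#' @param amp_thresh absolute excursion threshold in OD units.
#' @param spline_p smoothing-spline parameter in (0, 1].
#' @param hpf_hz,lpf_hz band-pass edges in Hz.
#' @param pca_remove number of principal components projected out.
#' @param ppf partial pathlength factor multiplying the geometric distance.
#' @param extinction 2x2 extinction matrix, see [hb_extinction_table()].
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(snr_threshold_db = 25, t_motion_s = 2,
                              t_mask_s = 4, stdev_thresh = 50,
                              amp_thresh = 5, spline_p = 0.99,
                              hpf_hz = 0.01, lpf_hz = 0.1, pca_remove = 1,
                              ppf = 6, extinction = hb_extinction_table()) {
  stopifnot(hpf_hz > 0, hpf_hz < lpf_hz, spline_p > 0, spline_p <= 1,
            ppf > 0, t_mask_s >= 0, pca_remove >= 0)
  if (abs(det(extinction)) < .Machine$double.eps) {
    stop("extinction matrix is singular")
  }
  structure(as.list(environment()), class = "preprocess_config")
}

#' Prune channels by raw-intensity signal-to-noise ratio
#'
#' A channel's SNR at one wavelength is `20 * log10(mean(I) / sd(I))` of
#' the raw intensity. A channel is pruned when its SNR falls below the
#' threshold at either wavelength; a perfectly constant channel has
#' infinite SNR and is kept.
#'
#' @param rec a [raw_recording()].
#' @param threshold_db pruning threshold in dB (default 25).
#' @return integer vector of pruned channel ids (possibly empty).
#' @export
prune_channels_by_snr <- function(rec, threshold_db = 25) {
  stopifnot(inherits(rec, "nirs_recording"))
  nch <- dim(rec$intensity)[2]
  snr <- channel_snr_db(rec)
  which(apply(snr < threshold_db, 1, any))
}

#' Per-channel, per-wavelength SNR in dB
#' @param rec a [raw_recording()].
#' @return numeric matrix `channel x wavelength`.
#' @export
channel_snr_db <- function(rec) {
  apply(rec$intensity, c(2, 3), function(x) {
    s <- stats::sd(x)
    if (s == 0) Inf else 20 * log10(mean(x) / s)
  })
}

#' Convert raw intensities to optical density
#'
#' `od(t) = -ln(I(t) / mean_t I(t))` per channel and wavelength; the
#' result is invariant to any positive rescaling of the intensities.
#'
#' @param rec a [raw_recording()].
#' @return numeric array `time x channel x wavelength` of optical density.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "nirs_recording"))
  I <- rec$intensity
  mu <- apply(I, c(2, 3), mean)
  od <- -log(sweep(I, c(2, 3), mu, "/"))
  dimnames(od) <- dimnames(I)
  od
}

# Running max/min over a centered-right sliding window of w samples,
# vectorised over shifts (O(n * w) with vector primitives only).
running_extrema <- function(x, w) {
  n <- length(x)
  mx <- x
  mn <- x
  if (w > 1) {
    for (k in seq_len(w - 1L)) {
      idx <- seq_len(n - k)
      shifted <- x[idx + k]
      mx[idx] <- pmax(mx[idx], shifted)
      mn[idx] <- pmin(mn[idx], shifted)
    }
  }
  list(max = mx, min = mn, valid = n - w + 1L)
}

#' Detect motion artifacts per channel
#'
#' Slides a `t_motion_s`-second window along each channel's optical
#' density; windows whose excursion (max minus min) exceeds either
#' `stdev_thresh` times the channel's baseline SD or `amp_thresh` OD
#' units are flagged, and the flag is dilated by `t_mask_s` seconds on
#' each side. The baseline SD is estimated in two passes: a first pass
#' with a robust (MAD-based) SD so that large artifacts do not inflate
#' their own threshold, then the SD is recomputed classically on the
#' samples the first pass left unflagged and the scan repeated. The returned
#' mask is the union over both wavelengths.
#'
#' @param od optical density array `time x channel x wavelength`.
#' @param fs sampling rate in Hz.
#' @param t_motion_s,t_mask_s,stdev_thresh,amp_thresh see
#'   [preprocess_config()].
#' @return logical matrix `time x channel`, `TRUE` where artifactual.
#' @export
detect_motion_artifacts_by_channel <- function(od, fs, t_motion_s = 2,
                                               t_mask_s = 4,
                                               stdev_thresh = 50,
                                               amp_thresh = 5) {
  if (t_mask_s < 0) stop("t_mask_s must be non-negative")
  w <- max(2L, round(t_motion_s * fs))
  pad <- round(t_mask_s * fs)
  nt <- dim(od)[1]
  nch <- dim(od)[2]
  mask <- matrix(FALSE, nt, nch)
  for (ch in seq_len(nch)) {
    for (wl in seq_len(dim(od)[3])) {
      x <- od[, ch, wl]
      sd1 <- stats::mad(x)
      if (!is.finite(sd1) || sd1 == 0) sd1 <- stats::sd(x)
      m1 <- scan_excursions(x, w, pad, sd1, stdev_thresh, amp_thresh)
      base_sd <- stats::sd(x[!m1])
      if (!is.finite(base_sd) || base_sd == 0) base_sd <- stats::sd(x)
      m2 <- scan_excursions(x, w, pad, base_sd, stdev_thresh, amp_thresh)
      mask[, ch] <- mask[, ch] | m2
    }
  }
  mask
}

scan_excursions <- function(x, w, pad, base_sd, stdev_thresh, amp_thresh) {
  n <- length(x)
  ex <- running_extrema(x, w)
  nv <- ex$valid
  thr <- min(stdev_thresh * base_sd, Inf)
  exc <- (ex$max - ex$min)[seq_len(nv)]
  hit <- exc > thr | exc > amp_thresh
  m <- logical(n)
  if (any(hit)) {
    for (i in which(hit)) {
      lo <- max(1L, i - pad)
      hi <- min(n, i + w - 1L + pad)
      m[lo:hi] <- TRUE
    }
  }
  m
}

#' Spline-based motion correction
#'
#' Within each contiguous flagged segment a smoothing spline (parameter
#' `spline_p`, where 1 is interpolation) is fitted and subtracted, so the
#' artifact waveform is removed while faster physiological content is
#' retained. Segments -- both corrected and the clean stretches between
#' them -- are then level-shifted in sequence so that neighbouring
#' segment means match over a short matching window, which removes
#' residual baseline jumps left by shift-type artifacts. Segments too
#' short to support a spline are linearly detrended instead.
#'
#' @param od optical density array `time x channel x wavelength`.
#' @param mask logical `time x channel` artifact mask.
#' @param fs sampling rate in Hz.
#' @param spline_p smoothing parameter in (0, 1].
#' @param match_window_s level-matching window in seconds. It should be
#'   long relative to the oscillations of interest so that genuine
#'   in-band signal averages out and only baseline discontinuities are
#'   removed when segments are re-anchored.
#' @return corrected array, same shape as `od`.
#' @export
spline_correct <- function(od, mask, fs, spline_p = 0.99,
                           match_window_s = 30) {
  stopifnot(nrow(mask) == dim(od)[1], ncol(mask) == dim(od)[2])
  out <- od
  for (ch in seq_len(dim(od)[2])) {
    if (!any(mask[, ch])) next
    for (wl in seq_len(dim(od)[3])) {
      out[, ch, wl] <- spline_correct_series(od[, ch, wl], mask[, ch],
                                             fs, spline_p, match_window_s)
    }
  }
  out
}

spline_correct_series <- function(x, mask, fs, spline_p, match_window_s = 30) {
  n <- length(x)
  r <- rle(as.vector(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- Map(function(s, e, flagged) list(idx = s:e, flagged = flagged),
              starts, ends, r$values)
  match_w <- max(1L, round(match_window_s * fs))
  corrected <- x
  # pass 1: remove the artifact waveform inside flagged segments
  for (sg in segs) {
    if (!sg$flagged) next
    idx <- sg$idx
    seg <- x[idx]
    fit <- fit_segment_trend(idx, seg, spline_p)
    corrected[idx] <- seg - fit
  }
  # pass 2: chain the segments back together by matching local levels
  prev_tail <- NULL
  for (sg in segs) {
    idx <- sg$idx
    if (!is.null(prev_tail)) {
      head_w <- min(length(idx), match_w)
      shift <- prev_tail - mean(corrected[idx[seq_len(head_w)]])
      corrected[idx] <- corrected[idx] + shift
    }
    tail_w <- min(length(idx), match_w)
    prev_tail <- mean(corrected[idx[seq(length(idx) - tail_w + 1L, length(idx))]])
  }
  corrected
}

fit_segment_trend <- function(idx, seg, spline_p) {
  if (length(seg) >= 8L && length(unique(seg)) > 3L) {
    # smoothing parameter p follows the csaps convention (penalty weight
    # (1-p)/p on the roughness integral in sample units); smooth.spline
    # rescales x to [0,1], which scales the roughness term by (n-1)^3
    lam <- (1 - spline_p) / spline_p / (length(seg) - 1)^3
    sf <- try(stats::smooth.spline(seq_along(seg), seg, lambda = lam,
                                   all.knots = TRUE, keep.data = FALSE),
              silent = TRUE)
    if (!inherits(sf, "try-error")) {
      return(stats::predict(sf, seq_along(seg))$y)
    }
  }
  # short / degenerate segment: linear detrend
  tt <- seq_along(seg)
  stats::fitted(stats::lm(seg ~ tt))
}

#' Zero-phase band-pass filter
#'
#' Third-order Butterworth band-pass applied forward and backward
#' (zero phase), with reflective padding so edge transients do not
#' contaminate the slow end of the passband.
#'
#' @param od array `time x channel x wavelength` (or a plain matrix /
#'   vector; filtering is along the first axis).
#' @param fs sampling rate, Hz.
#' @param hpf_hz,lpf_hz passband edges, Hz.
#' @return filtered object of the same shape.
#' @export
bandpass_filter <- function(od, fs, hpf_hz = 0.01, lpf_hz = 0.1) {
  if (is.null(dim(od))) {
    return(zerophase_bandpass(od, fs, hpf_hz, lpf_hz))
  }
  out <- od
  if (length(dim(od)) == 2) {
    for (j in seq_len(ncol(od))) {
      out[, j] <- zerophase_bandpass(od[, j], fs, hpf_hz, lpf_hz)
    }
  } else {
    for (ch in seq_len(dim(od)[2])) {
      for (wl in seq_len(dim(od)[3])) {
        out[, ch, wl] <- zerophase_bandpass(od[, ch, wl], fs, hpf_hz, lpf_hz)
      }
    }
  }
  out
}

#' Project out global principal components
#'
#' Removes the `pca_remove` largest-variance principal components of the
#' channel ensemble (per wavelength), the standard spatial filter for
#' superficial/global physiological contamination. Pruned channels are
#' excluded from the decomposition and passed through untouched.
#'
#' @param od array `time x channel x wavelength`.
#' @param pca_remove number of leading components to remove (0 = identity).
#' @param pruned integer vector of channel ids to exclude.
#' @return list with `od` (filtered array) and `removed_variance`
#'   (per-wavelength sum of the removed covariance eigenvalues).
#' @export
pca_filter <- function(od, pca_remove = 1, pruned = integer(0)) {
  if (pca_remove < 0) stop("pca_remove must be non-negative")
  keep <- setdiff(seq_len(dim(od)[2]), pruned)
  if (pca_remove >= length(keep)) {
    stop("pca_remove must be smaller than the number of unpruned channels")
  }
  out <- od
  removed <- numeric(dim(od)[3])
  if (pca_remove == 0) return(list(od = out, removed_variance = removed))
  for (wl in seq_len(dim(od)[3])) {
    X <- od[, keep, wl, drop = TRUE]
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc, nu = pca_remove, nv = pca_remove)
    k <- seq_len(pca_remove)
    Xclean <- Xc - sv$u[, k, drop = FALSE] %*%
      (diag(sv$d[k], nrow = pca_remove) %*% t(sv$v[, k, drop = FALSE]))
    out[, keep, wl] <- sweep(Xclean, 2, mu, "+")
    removed[wl] <- sum(sv$d[k]^2) / (nrow(X) - 1)
  }
  list(od = out, removed_variance = removed)
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Solves the modified Beer-Lambert system per channel and sample:
#' `dOD_w = (eps_HbO,w * dHbO + eps_HbR,w * dHbR) * d * ppf / 1000`
#' with concentrations in micromolar, extinction in mM^-1 cm^-1 and the
#' source-detector distance `d` in cm. `dHbT = dHbO + dHbR`.
#'
#' @param od array `time x channel x 2`.
#' @param ppf partial pathlength factor.
#' @param distance_cm source-detector separation, cm.
#' @param extinction 2x2 extinction matrix (rows: wavelengths).
#' @return object of class `nirs_conc`: list with `hbo`, `hbr`, `hbt`
#'   matrices (`time x channel`, micromolar).
#' @export
od_to_concentration <- function(od, ppf = 6, distance_cm = 3.0,
                                extinction = hb_extinction_table()) {
  if (abs(det(extinction)) < .Machine$double.eps) {
    stop("extinction matrix is singular")
  }
  nt <- dim(od)[1]; nch <- dim(od)[2]
  # effective pathlength in cm; /1000 converts mM-based extinction to uM
  L <- distance_cm * ppf / 1000
  Einv <- solve(extinction * L)
  hbo <- matrix(0, nt, nch)
  hbr <- matrix(0, nt, nch)
  for (ch in seq_len(nch)) {
    C <- Einv %*% t(od[, ch, ])   # 2 x time
    hbo[, ch] <- C[1, ]
    hbr[, ch] <- C[2, ]
  }
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                 pruned_channels = integer(0)),
            class = "nirs_conc")
}

#' Forward modified Beer-Lambert transform
#'
#' Maps concentration changes (micromolar) to optical density at the two
#' wavelengths; exact inverse of [od_to_concentration()].
#'
#' @param hbo,hbr matrices `time x channel` in micromolar.
#' @inheritParams od_to_concentration
#' @return array `time x channel x 2` of optical density.
#' @export
concentration_to_od <- function(hbo, hbr, ppf = 6, distance_cm = 3.0,
                                extinction = hb_extinction_table()) {
  L <- distance_cm * ppf / 1000
  od <- array(0, c(nrow(hbo), ncol(hbo), 2))
  for (wl in 1:2) {
    od[, , wl] <- (extinction[wl, "HbO"] * hbo +
                     extinction[wl, "HbR"] * hbr) * L
  }
  od
}

#' Run the full preprocessing chain on one recording
#'
#' Applies, in order: SNR channel pruning, intensity-to-OD conversion,
#' per-channel motion detection, spline correction, zero-phase band-pass
#' filtering, global PCA filtering, and Beer-Lambert conversion to
#' HbO/HbR/HbT concentration changes. A subject whose channels are all
#' pruned is marked excluded rather than raising an error.
#'
#' @param rec a [raw_recording()].
#' @param config a [preprocess_config()].
#' @param keep_intermediates if `TRUE`, every stage output is attached
#'   for audit under `$intermediates`.
#' @return object of class `nirs_conc` with elements `hbo`, `hbr`, `hbt`
#'   (`time x channel`), `pruned_channels`, `artifact_mask`, `excluded`
#'   flag and a `log` list (pruned channels, artifact seconds).
#' @export
preprocess_recording <- function(rec, config = preprocess_config(),
                                 keep_intermediates = FALSE) {
  stopifnot(inherits(rec, "nirs_recording"))
  fs <- rec$sampling_rate_hz
  pruned <- prune_channels_by_snr(rec, config$snr_threshold_db)
  nch <- dim(rec$intensity)[2]
  if (length(pruned) == nch) {
    res <- structure(list(hbo = NULL, hbr = NULL, hbt = NULL,
                          pruned_channels = pruned, artifact_mask = NULL,
                          excluded = TRUE,
                          log = list(pruned_channels = pruned,
                                     artifact_seconds = NA_real_)),
                     class = "nirs_conc")
    return(res)
  }
  od <- intensity_to_od(rec)
  mask <- detect_motion_artifacts_by_channel(
    od, fs, config$t_motion_s, config$t_mask_s,
    config$stdev_thresh, config$amp_thresh)
  od_spline <- spline_correct(od, mask, fs, config$spline_p)
  od_bp <- bandpass_filter(od_spline, fs, config$hpf_hz, config$lpf_hz)
  pf <- if (config$pca_remove > 0 && length(setdiff(seq_len(nch), pruned)) >
              config$pca_remove) {
    pca_filter(od_bp, config$pca_remove, pruned)
  } else {
    list(od = od_bp, removed_variance = c(0, 0))
  }
  conc <- od_to_concentration(pf$od, config$ppf, rec$distance_cm,
                              config$extinction)
  conc$pruned_channels <- pruned
  conc$artifact_mask <- mask
  conc$excluded <- FALSE
  conc$sampling_rate_hz <- fs
  conc$subject_id <- rec$subject_id
  conc$log <- list(
    pruned_channels = pruned,
    artifact_seconds = sum(mask) / fs / nch,
    pca_removed_variance = pf$removed_variance
  )
  if (keep_intermediates) {
    conc$intermediates <- list(od = od, mask = mask, od_spline = od_spline,
                               od_bandpassed = od_bp, od_pca = pf$od)
  }
  conc
}
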
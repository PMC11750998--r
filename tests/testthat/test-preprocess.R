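test_that("SNR pruning follows the 20*log10(mean/sd) rule", {
  n <- 2441
  tt <- (seq_len(n) - 1) / FS
  I <- array(100, c(n, 2, 2))
  I[, 1, 1] <- 100 + 0.1 * sin(2 * pi * 0.05 * tt)   # ~63 dB
  set.seed(4)
  I[, 2, 1] <- pmax(1, 100 + rnorm(n, 0, 20))        # ~14 dB
  rec <- raw_recording(I, sampling_rate_hz = FS)
  snr <- channel_snr_db(rec)
  expect_equal(snr[1, 1], 63, tolerance = 0.02)
  expect_lt(abs(snr[2, 1] - 14), 1.5)
  expect_equal(prune_channels_by_snr(rec, 25), 2L)
  # constant channel: sd = 0 treated as infinite SNR, kept
  expect_true(is.infinite(snr[1, 2]))
  expect_false(1L %in% prune_channels_by_snr(rec, 25))
})

test_that("optical density conversion is exact and scale invariant", {
  I <- array(100, c(4, 1, 2))
  I[, 1, 1] <- c(50, 150, 100, 100)   # mean 100; first sample = mean / 2
  rec <- raw_recording(I, sampling_rate_hz = FS)
  od <- intensity_to_od(rec)
  expect_equal(od[1, 1, 1], log(2))
  expect_equal(od[, 1, 2], rep(0, 4))   # constant intensity -> od == 0

  rec2 <- raw_recording(I * 37.5, sampling_rate_hz = FS)
  expect_equal(intensity_to_od(rec2), od)

  Ibad <- I; Ibad[2, 1, 1] <- -1
  expect_error(raw_recording(Ibad), "non-positive intensity")
})

test_that("motion detection flags inserted steps and SD excursions", {
  n <- floor(120 * FS)
  tt <- (seq_len(n) - 1) / FS
  smooth <- 0.005 * sin(2 * pi * 0.05 * tt)
  od <- array(smooth, c(n, 2, 2))
  # smooth low-amplitude signal: nothing flagged
  expect_false(any(detect_motion_artifacts_by_channel(od, FS)))

  # step of 10 od units (amp_thresh = 5) at t0
  t0 <- 500L
  od[t0:n, 1, 1] <- od[t0:n, 1, 1] + 10
  mask <- detect_motion_artifacts_by_channel(od, FS)
  flagged <- which(mask[, 1])
  pad <- round(4 * FS)
  expect_true(all(c(t0 - pad + 1, t0, t0 + pad - 1) %in% flagged))
  expect_lte(min(flagged), t0 - pad + 1)
  expect_false(any(mask[, 2]))

  # 60-SD excursion with stdev_thresh = 50 and huge amp_thresh
  od2 <- array(0, c(n, 1, 2))
  set.seed(1)
  od2[, 1, ] <- rnorm(2 * n, 0, 0.01)
  sd0 <- sd(od2[, 1, 1])
  od2[800:810, 1, 1] <- od2[800:810, 1, 1] + 60 * sd0
  m2 <- detect_motion_artifacts_by_channel(od2, FS, amp_thresh = Inf)
  expect_true(all(m2[800:810, 1]))
})

test_that("spline correction repairs baseline shifts and spikes", {
  n <- floor(300 * FS)
  tt <- (seq_len(n) - 1) / FS

  # empty mask: identity
  od0 <- array(rnorm(n * 2, 0, 0.001), c(n, 1, 2))
  expect_identical(spline_correct(od0, matrix(FALSE, n, 1), FS), od0)

  # +8 od step: pre/post 10-s baseline difference reduced by >= 90%
  x <- 0.01 * sin(2 * pi * 0.05 * tt)
  t0 <- 1200L
  x[t0:n] <- x[t0:n] + 8
  od <- array(x, c(n, 1, 2)); od[, , 2] <- x
  mask <- detect_motion_artifacts_by_channel(od, FS)
  corr <- spline_correct(od, mask, FS)
  i_pre <- (t0 - round(15 * FS)):(t0 - round(5 * FS))
  i_post <- (t0 + round(6 * FS)):(t0 + round(16 * FS))
  diff_before <- mean(x[i_post]) - mean(x[i_pre])
  diff_after <- mean(corr[i_post, 1, 1]) - mean(corr[i_pre, 1, 1])
  expect_lt(abs(diff_after), 0.1 * abs(diff_before))

  # 1-s spike on a sinusoid: corrected series tracks the clean sinusoid
  clean <- sin(2 * pi * 0.05 * tt)
  sp <- clean
  i0 <- round(100 * FS); i1 <- i0 + round(1 * FS)
  sp[i0:i1] <- sp[i0:i1] + 10 * sin(pi * seq(0, 1, length.out = i1 - i0 + 1))
  od2 <- array(sp, c(n, 1, 2)); od2[, , 2] <- sp
  m2 <- detect_motion_artifacts_by_channel(od2, FS)
  expect_true(any(m2[, 1]))
  c2 <- spline_correct(od2, m2, FS)
  expect_gte(cor(c2[, 1, 1], clean), 0.95)
})

test_that("band-pass is zero-phase with the documented gains", {
  n <- floor(300 * FS)
  tt <- (seq_len(n) - 1) / FS
  mid <- 500:1900
  y <- bandpass_filter(sin(2 * pi * 0.05 * tt), FS)
  expect_gte(max(abs(y[mid])), 0.95)
  expect_lte(max(abs(y[mid])), 1.05)
  y1 <- bandpass_filter(sin(2 * pi * 1.0 * tt), FS)
  expect_gte(-20 * log10(max(abs(y1[mid]))), 20)   # cardiac band down >= 20 dB
  expect_lt(max(abs(bandpass_filter(rep(5, n), FS))), 1e-6)
  # zero lag on a mid-band sinusoid
  cc <- ccf(y[mid], sin(2 * pi * 0.05 * tt)[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass_filter(y, FS, 0.01, 5), "Nyquist")
})

test_that("PCA filter removes the leading global component", {
  n <- 600
  set.seed(2)
  od <- array(rnorm(n * 8 * 2, 0, 0.1), c(n, 8, 2))
  expect_identical(pca_filter(od, 0)$od, od)

  g <- sin(2 * pi * 0.03 * (seq_len(n) - 1) / FS) * 3
  odc <- od
  for (ch in 1:8) odc[, ch, ] <- odc[, ch, ] + g
  mean_cor <- function(X) mean(cor(X)[upper.tri(diag(8))])
  expect_gt(mean_cor(odc[, , 1]), 0.9)
  pf <- pca_filter(odc, 1)
  expect_lt(mean_cor(pf$od[, , 1]), 0.2)
  # removed variance equals the top covariance eigenvalue
  ev <- eigen(cov(odc[, , 1]), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pf$removed_variance[1], ev[1], tolerance = 1e-8)
  expect_error(pca_filter(od, -1), "non-negative")
  expect_error(pca_filter(od, 8))
})

test_that("Beer-Lambert conversion round-trips and conserves HbT", {
  # (1.0, -0.3) uM forward then inverse -> recovered to 1e-9
  hbo <- matrix(1.0, 3, 2); hbr <- matrix(-0.3, 3, 2)
  od <- concentration_to_od(hbo, hbr)
  conc <- od_to_concentration(od)
  expect_equal(conc$hbo, hbo, tolerance = 1e-9)
  expect_equal(conc$hbr, hbr, tolerance = 1e-9)

  # arbitrary concentration pairs round-trip; HbT = HbO + HbR exactly
  set.seed(11)
  hbo <- matrix(rnorm(200), 50, 4); hbr <- matrix(rnorm(200), 50, 4)
  conc <- od_to_concentration(concentration_to_od(hbo, hbr))
  expect_lt(max(abs(conc$hbo - hbo)), 1e-9)
  expect_identical(conc$hbt, conc$hbo + conc$hbr)

  z <- od_to_concentration(array(0, c(5, 2, 2)))
  expect_true(all(z$hbo == 0) && all(z$hbr == 0) && all(z$hbt == 0))
  expect_error(od_to_concentration(od, extinction = matrix(1, 2, 2)),
               "singular")
})

test_that("the full chain is scale invariant and excludes dead subjects", {
  rec <- make_clean_recording(n = 800)
  cfg <- preprocess_config()
  c1 <- preprocess_recording(rec, cfg)
  rec2 <- raw_recording(rec$intensity * 12.3, sampling_rate_hz = FS)
  c2 <- preprocess_recording(rec2, cfg)
  expect_equal(c1$hbo, c2$hbo, tolerance = 1e-3)
  expect_identical(c1$hbt, c1$hbo + c1$hbr)

  # every channel pure noise below 25 dB -> subject excluded, not an error
  set.seed(3)
  Ibad <- array(pmax(1, 100 + rnorm(500 * 48 * 2, 0, 20)), c(500, 48, 2))
  cbad <- preprocess_recording(raw_recording(Ibad, sampling_rate_hz = FS))
  expect_true(cbad$excluded)

  # pruning is idempotent
  p1 <- prune_channels_by_snr(rec)
  expect_identical(prune_channels_by_snr(rec, 25), p1)
})

test_that("with and without PCA the outputs differ only in a rank-1 subspace", {
  rec <- make_clean_recording(n = 800)
  c1 <- preprocess_recording(rec, preprocess_config(pca_remove = 1),
                             keep_intermediates = TRUE)
  d <- c1$intermediates$od_pca[, , 1] - c1$intermediates$od_bandpassed[, , 1]
  sv <- svd(d, nu = 0, nv = 0)$d
  expect_gt(sv[1], 0)
  expect_lt(sv[2] / sv[1], 1e-8)
})
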
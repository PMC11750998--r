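# Shared fixtures, built in code.

FS <- 8.138

# unit-variance band-limited (0.01-0.1 Hz) noise series
narrowband_series <- function(n) {
  z <- bandpass_filter(stats::rnorm(n), FS)
  z / stats::sd(z)
}

# small clean recording wrapper: a known concentration pattern pushed
# through the forward Beer-Lambert map, no nuisance
make_clean_recording <- function(n = 500, nch = 48, seed = 1) {
  set.seed(seed)
  hbo <- matrix(0, n, nch)
  tt <- (seq_len(n) - 1) / FS
  for (ch in seq_len(nch)) {
    hbo[, ch] <- 0.5 * sin(2 * pi * 0.05 * tt + ch / 10)
  }
  hbr <- -0.3 * hbo
  od <- concentration_to_od(hbo, hbr)
  raw_recording(1000 * exp(-od), sampling_rate_hz = FS)
}

# feature table with a controllable group effect on the first n_eff columns
make_feature_table <- function(n_per_group = 15, n_feat = 8, effect = 0,
                               n_eff = 3, seed = 1, groups = c("NC", "SCD", "MCI"),
                               with_scores = FALSE) {
  set.seed(seed)
  n <- n_per_group * length(groups)
  g <- rep(groups, each = n_per_group)
  M <- matrix(stats::rnorm(n * n_feat), n, n_feat)
  shift <- (seq_along(groups) - 1) / (length(groups) - 1) * effect
  for (k in seq_len(n_eff)) {
    M[, k] <- M[, k] + shift[match(g, groups)]
  }
  colnames(M) <- paste0("COH_HbO_ROI1_ROI", seq_len(n_feat) + 1)
  out <- data.frame(subject_id = sprintf("s%03d", seq_len(n)), group = g,
                    stringsAsFactors = FALSE)
  out <- cbind(out, M)
  if (with_scores) {
    for (sc in c("mmse", "tmt_a", "tmt_b", "bnt", "hvlt", "cdt")) {
      out[[sc]] <- stats::rnorm(n) + shift[match(g, groups)]
    }
  }
  out
}

# tiny synthetic cohort (full montage, short but FC-capable recordings)
make_tiny_cohort <- function(sizes = c(NC = 2, SCD = 2, MCI = 2), seed = 7,
                             ...) {
  generate_cohort(cohort_config(group_sizes = sizes, seed = seed, ...))
}
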
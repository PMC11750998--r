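#' Neuropsychological score distribution table
#'
#' Group-wise means and standard deviations of the six screening tests
#' (MMSE, TMT-A, TMT-B, BNT, HVLT, CDT) for the NC, SCD and MCI groups,
#' together with each instrument's score bounds and whether it is
#' integer-valued. These defaults drive the synthetic score generator.
#'
#' @return data.frame with columns `test`, `group`, `mean`, `sd`,
#'   `lower`, `upper`, `integer`.
#' @export
score_distribution_table <- function() {
  tests <- c("mmse", "tmt_a", "tmt_b", "bnt", "hvlt", "cdt")
  bounds <- data.frame(
    test = tests,
    lower = c(0, 0, 0, 0, 0, 0),
    upper = c(30, Inf, Inf, 30, 36, 10),
    integer = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  means <- rbind(
    NC  = c(28.91, 40.73, 59.51, 27.29, 26.91, 9.33),
    SCD = c(28.35, 57.41, 86.45, 25.41, 21.85, 8.73),
    MCI = c(25.49, 98.22, 186.31, 20.63, 13.50, 7.50)
  )
  sds <- rbind(
    NC  = c(1.20, 12.47, 22.59, 1.65, 3.27, 0.71),
    SCD = c(1.30, 19.85, 28.51, 2.67, 4.23, 1.10),
    MCI = c(2.56, 45.44, 102.84, 4.04, 5.13, 1.63)
  )
  out <- do.call(rbind, lapply(rownames(means), function(g) {
    data.frame(test = tests, group = g, mean = means[g, ], sd = sds[g, ],
               row.names = NULL)
  }))
  merge(out, bounds, by = "test", sort = FALSE)
}

#' Default ground-truth ROI coupling matrices per group
#'
#' A compound-symmetric background coupling of `base` on every ROI pair,
#' raised on the three pairs where group differences are injected
#' (ROI1-ROI3, ROI2-ROI7, ROI4-ROI7), ordered MCI > SCD > NC to emulate
#' compensatory connectivity enhancement along the cognitive-decline
#' continuum. Matrices are symmetric with unit diagonal and are nudged
#' to the nearest positive-definite correlation matrix if needed.
#'
#' @param base background coupling for all pairs.
#' @param levels named vector of coupling on the enhanced pairs per group.
#' @return named list of 10x10 matrices (`NC`, `SCD`, `MCI`).
#' @export
default_group_coupling <- function(base = 0.3,
                                   levels = c(NC = 0.30, SCD = 0.45,
                                              MCI = 0.60)) {
  enhanced <- list(c(1, 3), c(2, 7), c(4, 7))
  lapply(levels, function(v) {
    C <- matrix(base, 10, 10)
    diag(C) <- 1
    for (p in enhanced) {
      C[p[1], p[2]] <- C[p[2], p[1]] <- v
    }
    make_positive_definite(C)
  })
}

make_positive_definite <- function(C, eps = 1e-6) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) > eps) return(C)
  v <- pmax(e$values, eps)
  M <- e$vectors %*% diag(v) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(M)))
  D %*% M %*% D
}

#' Synthetic cohort configuration
#'
#' @param group_sizes named integer vector of subjects per group
#'   (default `c(NC = 48, SCD = 65, MCI = 90)`).
#' @param duration_s recording length in seconds (default 300, i.e. the
#'   5-minute resting-state protocol).
#' @param sampling_rate_hz device sampling rate (default 8.138 Hz).
#' @param coupling named list of 10x10 ground-truth coupling matrices,
#'   one per group.
#' @param nuisance_amplitudes named vector of cardiac (~1 Hz),
#'   respiratory (~0.25 Hz), Mayer-wave (~0.1 Hz) and linear-drift
#'   amplitudes, expressed relative to the clean hemodynamic OD SD.
#' @param artifact_rate expected motion events per minute per subject.
#' @param noise_sd white measurement noise SD in OD units.
#' @param hbo_amp_um SD of the injected ROI Delta-HbO signal, micromolar.
#' @param hbr_ratio HbR is generated as `-hbr_ratio * HbO` plus
#'   independent narrowband noise.
#' @param score_table score distributions, see
#'   [score_distribution_table()].
#' @param seed master seed; every derived random stream is a function of
#'   it, so a config + seed pair fully determines the cohort.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(NC = 48, SCD = 65, MCI = 90),
                          duration_s = 300, sampling_rate_hz = 8.138,
                          coupling = default_group_coupling(),
                          nuisance_amplitudes = c(cardiac = 0.5,
                                                  respiratory = 0.3,
                                                  mayer = 0.3, drift = 0.5),
                          artifact_rate = 0.5, noise_sd = 0.002,
                          hbo_amp_um = 0.5, hbr_ratio = 0.3,
                          score_table = score_distribution_table(),
                          seed = 1L) {
  if (duration_s <= 0 || sampling_rate_hz <= 0) {
    stop("duration_s and sampling_rate_hz must be positive")
  }
  if (floor(duration_s * sampling_rate_hz) < 2) {
    stop("configuration yields fewer than 2 samples")
  }
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  for (g in names(coupling)) {
    check_coupling(coupling[[g]])
  }
  structure(as.list(environment()), class = "cohort_config")
}

check_coupling <- function(C) {
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8))) {
    stop("coupling matrix must be symmetric")
  }
  if (any(abs(diag(C) - 1) > 1e-8)) stop("coupling diagonal must be 1")
  if (any(C < -1e-12 | C > 1 + 1e-12)) stop("coupling values must lie in [0, 1]")
  invisible(TRUE)
}

#' Generate one synthetic resting-state recording
#'
#' Forward model: latent narrowband (0.01-0.1 Hz) ROI signals with the
#' requested correlation structure (Cholesky mixing of independent
#' narrowband sources, so a shared source is weighted by the coupling
#' value), copied to member channels as Delta-HbO; Delta-HbR is
#' anticorrelated scaled HbO plus independent narrowband noise. The
#' concentrations are pushed through the forward Beer-Lambert transform
#' to two-wavelength optical density, to which cardiac / respiratory /
#' Mayer oscillations, a linear drift, motion artifacts (spikes and
#' baseline shifts) and white noise are added; intensities are
#' `I0 * exp(-od)`, hence strictly positive.
#'
#' @param coupling symmetric 10x10 coupling matrix with unit diagonal.
#' @param config a [cohort_config()].
#' @param seed integer seed for this recording.
#' @param subject_id subject identifier.
#' @return list with `recording` (a [raw_recording()]), `clean_roi_hbo`
#'   (`time x 10` injected micromolar series), and `artifacts`
#'   (data.frame of injected events: channel, onset_s, duration_s, type,
#'   amplitude_od).
#' @export
generate_recording <- function(coupling, config, seed,
                               subject_id = "S1") {
  check_coupling(coupling)
  set.seed(as.integer(seed))
  fs <- config$sampling_rate_hz
  n <- floor(config$duration_s * fs)
  map <- roi_channel_map()
  nch <- n_montage_channels()

  # latent coupled ROI dynamics
  Z <- sapply(1:10, function(i) narrowband_noise(n, fs))
  U <- chol(make_positive_definite(coupling))
  X <- Z %*% U                               # time x 10, cov = coupling
  hbo <- matrix(0, n, nch)
  for (r in seq_along(map)) {
    hbo[, map[[r]]] <- config$hbo_amp_um * X[, r]
  }
  hbr <- -config$hbr_ratio * hbo +
    0.2 * config$hbo_amp_um *
      sapply(seq_len(nch), function(i) narrowband_noise(n, fs))

  od <- concentration_to_od(hbo, hbr)
  od_sd <- max(apply(od, c(2, 3), stats::sd))

  # physiological nuisance + drift, random phase per channel/wavelength
  tt <- (seq_len(n) - 1) / fs
  na <- config$nuisance_amplitudes
  freqs <- c(cardiac = 1.0, respiratory = 0.25, mayer = 0.1)
  for (ch in seq_len(nch)) {
    for (wl in 1:2) {
      comp <- numeric(n)
      for (f in names(freqs)) {
        comp <- comp + na[[f]] * od_sd *
          sin(2 * pi * freqs[[f]] * tt + stats::runif(1, 0, 2 * pi))
      }
      comp <- comp + na[["drift"]] * od_sd *
        stats::runif(1, -1, 1) * (tt / config$duration_s)
      od[, ch, wl] <- od[, ch, wl] + comp
    }
  }

  # motion artifacts: spikes and baseline shifts, Poisson event times
  n_events <- stats::rpois(1, config$artifact_rate * config$duration_s / 60)
  artifacts <- data.frame(channel = integer(0), onset_s = numeric(0),
                          duration_s = numeric(0), type = character(0),
                          amplitude_od = numeric(0))
  if (n_events > 0) {
    for (ev in seq_len(n_events)) {
      ch <- sample.int(nch, 1)
      onset <- stats::runif(1, 0, config$duration_s - 2)
      type <- sample(c("spike", "shift"), 1)
      amp <- sample(c(-1, 1), 1) * stats::runif(1, 5, 20) * od_sd
      dur <- stats::runif(1, 0.5, 2)
      i0 <- max(1L, round(onset * fs))
      if (type == "spike") {
        len <- max(2L, round(dur * fs))
        i1 <- min(n, i0 + len - 1L)
        shape <- sin(pi * seq(0, 1, length.out = i1 - i0 + 1L))
        od[i0:i1, ch, ] <- od[i0:i1, ch, ] + amp * shape
      } else {
        od[i0:n, ch, ] <- od[i0:n, ch, ] + amp
        dur <- NA_real_
      }
      artifacts <- rbind(artifacts,
                         data.frame(channel = ch, onset_s = onset,
                                    duration_s = dur, type = type,
                                    amplitude_od = amp))
    }
  }

  if (config$noise_sd > 0) {
    od <- od + array(stats::rnorm(length(od), 0, config$noise_sd), dim(od))
  }

  intensity <- 1000 * exp(-od)
  rec <- raw_recording(intensity, sampling_rate_hz = fs,
                       subject_id = subject_id)
  list(recording = rec,
       clean_roi_hbo = config$hbo_amp_um * X,
       artifacts = artifacts)
}

#' Generate synthetic neuropsychological scores
#'
#' Scores are drawn from normal distributions with the configured group
#' mean and SD, clipped to the instrument bounds, and rounded for
#' integer-valued tests.
#'
#' @param group one of `"NC"`, `"SCD"`, `"MCI"` (must appear in `table`).
#' @param n number of subjects.
#' @param table a [score_distribution_table()].
#' @param seed integer seed.
#' @return data.frame with one column per test.
#' @export
generate_scores <- function(group, n, table = score_distribution_table(),
                            seed = 1L) {
  if (!group %in% table$group) stop("unknown group: ", group)
  set.seed(as.integer(seed))
  tab <- table[table$group == group, ]
  out <- lapply(seq_len(nrow(tab)), function(i) {
    x <- stats::rnorm(n, tab$mean[i], tab$sd[i])
    x <- pmin(pmax(x, tab$lower[i]), tab$upper[i])
    if (tab$integer[i]) x <- round(x)
    x
  })
  names(out) <- tab$test
  as.data.frame(out)
}

#' Generate a full synthetic cohort
#'
#' One recording plus one score row per subject, with per-subject seeds
#' derived deterministically from the master seed: the same config and
#' seed reproduce the cohort bitwise.
#'
#' @param config a [cohort_config()].
#' @return list of class `nirs_cohort` with `recordings` (named list),
#'   `scores` (data.frame: subject_id, group, six test columns), and
#'   `ground_truth` (per subject: group, coupling, injected clean ROI
#'   HbO, artifact table).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$group_sizes)
  total <- sum(config$group_sizes)
  seeds <- child_seeds(config$seed, total + length(groups))
  rec_seeds <- seeds[seq_len(total)]
  score_seeds <- seeds[total + seq_along(groups)]

  recordings <- list()
  ground_truth <- list()
  scores <- NULL
  k <- 0
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ng <- config$group_sizes[[g]]
    if (ng == 0) next
    sc <- generate_scores(g, ng, config$score_table, score_seeds[gi])
    ids <- sprintf("%s%03d", g, seq_len(ng))
    sc <- cbind(data.frame(subject_id = ids, group = g,
                           stringsAsFactors = FALSE), sc)
    scores <- rbind(scores, sc)
    for (i in seq_len(ng)) {
      k <- k + 1
      gr <- generate_recording(config$coupling[[g]], config, rec_seeds[k],
                               subject_id = ids[i])
      recordings[[ids[i]]] <- gr$recording
      ground_truth[[ids[i]]] <- list(group = g,
                                     coupling = config$coupling[[g]],
                                     clean_roi_hbo = gr$clean_roi_hbo,
                                     artifacts = gr$artifacts)
    }
  }
  rownames(scores) <- NULL
  structure(list(recordings = recordings, scores = scores,
                 ground_truth = ground_truth, config = config),
            class = "nirs_cohort")
}
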
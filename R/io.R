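#' Write a recording to a plain-text container
#'
#' Lightweight text format: `#key=value` header lines (sampling rate,
#' wavelengths, distance, subject id) followed by a tab-separated matrix
#' with one column per channel x wavelength (`w780_ch01`, ...,
#' `w850_ch48`).
#'
#' @param rec a [raw_recording()].
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  nch <- dim(rec$intensity)[2]
  hdr <- c(
    sprintf("#sampling_rate_hz=%.17g", rec$sampling_rate_hz),
    sprintf("#wavelengths_nm=%s", paste(rec$wavelengths_nm, collapse = ",")),
    sprintf("#distance_cm=%.17g", rec$distance_cm),
    sprintf("#subject_id=%s", rec$subject_id),
    sprintf("#n_channels=%d", nch)
  )
  M <- cbind(rec$intensity[, , 1], rec$intensity[, , 2])
  colnames(M) <- c(sprintf("w%d_ch%02d", rec$wavelengths_nm[1], 1:nch),
                   sprintf("w%d_ch%02d", rec$wavelengths_nm[2], 1:nch))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path.
#' @param expected_rate_hz if non-`NULL`, the stored sampling rate must
#'   match within 1e-6 Hz.
#' @return a [raw_recording()].
#' @export
read_recording <- function(path, expected_rate_hz = NULL) {
  lines <- readLines(path, n = 10)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- list()
  for (h in hdr_lines) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
  }
  wls <- as.numeric(strsplit(hdr$wavelengths_nm, ",")[[1]])
  if (length(wls) != 2) stop("recording must contain exactly two wavelengths")
  rate <- as.numeric(hdr$sampling_rate_hz)
  if (!is.null(expected_rate_hz) && abs(rate - expected_rate_hz) > 1e-6) {
    stop(sprintf("sampling rate mismatch: file has %g Hz, expected %g Hz",
                 rate, expected_rate_hz))
  }
  M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   comment.char = "#"))
  nch <- as.integer(hdr$n_channels)
  intensity <- array(0, c(nrow(M), nch, 2))
  intensity[, , 1] <- M[, 1:nch]
  intensity[, , 2] <- M[, nch + 1:nch]
  raw_recording(intensity, sampling_rate_hz = rate, wavelengths_nm = wls,
                distance_cm = as.numeric(hdr$distance_cm),
                subject_id = hdr$subject_id)
}

#' Write the screening report
#'
#' Column order follows the screening table layout (task, model, ACC,
#' EACC, SPC, SEN, AUC, CI bounds) plus provenance columns; metric
#' values are rendered to 3 decimals.
#'
#' @param report a [full_screen()] data.frame.
#' @param path output path (extension-independent).
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("task", "model", "feature_set", "fold_scheme", "ACC", "EACC",
            "SPC", "SEN", "AUC", "CI_low", "CI_high", "n", "seed", "n_perm")
  rep2 <- report[, intersect(cols, names(report)), drop = FALSE]
  num <- intersect(c("ACC", "EACC", "SPC", "SEN", "AUC", "CI_low", "CI_high"),
                   names(rep2))
  for (cn in num) rep2[[cn]] <- round(rep2[[cn]], 3)
  if (format == "csv") {
    utils::write.csv(rep2, path, row.names = FALSE)
  } else {
    jsonlite::write_json(rep2, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Compute per-subject FC feature tables for a whole cohort
#'
#' Preprocesses every recording, averages ROIs, computes the FC matrix
#' sets and assembles the `fc_only` and `fc_plus_neuro` feature tables.
#' Subjects excluded by SNR pruning are dropped (and listed in the
#' `excluded` attribute).
#'
#' @param cohort a [generate_cohort()] result (or an equivalent list with
#'   `recordings` and `scores`).
#' @param pre_config a [preprocess_config()].
#' @param band analysis band in Hz.
#' @param seglen_s Welch segment length for COH.
#' @param verbose print one line per subject?
#' @return list with `fc_only`, `fc_plus_neuro` feature tables and
#'   `fc_list` (per-subject [fc_matrix_set()] arrays).
#' @export
cohort_feature_table <- function(cohort, pre_config = preprocess_config(),
                                 band = c(0.01, 0.1), seglen_s = 120,
                                 verbose = FALSE) {
  fc_list <- list()
  excluded <- character(0)
  for (id in names(cohort$recordings)) {
    conc <- preprocess_recording(cohort$recordings[[id]], pre_config)
    if (isTRUE(conc$excluded)) {
      excluded <- c(excluded, id)
      next
    }
    roits <- average_rois(conc)
    fc_list[[id]] <- fc_matrix_set(roits, band, seglen_s)
    if (verbose) {
      message(sprintf("%s: %d channels pruned, %.1f artifact s/channel", id,
                      length(conc$pruned_channels),
                      conc$log$artifact_seconds))
    }
  }
  scores <- cohort$scores[cohort$scores$subject_id %in% names(fc_list), ]
  out <- list(
    fc_only = build_feature_table(fc_list, scores, include_scores = FALSE),
    fc_plus_neuro = build_feature_table(fc_list, scores,
                                        include_scores = TRUE),
    fc_list = fc_list
  )
  attr(out, "excluded") <- excluded
  out
}

#' Run the end-to-end pipeline
#'
#' simulate -> preprocess -> connectivity -> group statistics ->
#' classifier screen -> report, writing each stage's artifact (CSV/JSON
#' text files) plus a manifest with the config hash and seed into
#' `out_dir`. A single seed governs all randomness.
#'
#' @param config a [cohort_config()] (the simulated cohort to analyse).
#' @param out_dir output directory (created if missing).
#' @param pre_config a [preprocess_config()].
#' @param models,k,n_perm screening settings, see [full_screen()].
#' @param reducer_config see [fit_fold()].
#' @param seed master seed.
#' @return (invisibly) list with `stats`, `report`, and the artifact
#'   paths.
#' @export
run_pipeline <- function(config, out_dir,
                         pre_config = preprocess_config(),
                         models = c("LDA", "LR", "SVM"), k = 10,
                         n_perm = 0, reducer_config = list(var_threshold = 0),
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- seed
  cohort <- generate_cohort(config)
  scores_path <- file.path(out_dir, "cohort_scores.csv")
  utils::write.csv(cohort$scores, scores_path, row.names = FALSE)

  ft <- cohort_feature_table(cohort, pre_config)
  feats_path <- file.path(out_dir, "features_fc_plus_neuro.csv")
  utils::write.csv(ft$fc_plus_neuro, feats_path, row.names = FALSE)

  stats_tab <- run_group_analysis(ft$fc_only)
  stats_path <- file.path(out_dir, "group_stats.csv")
  utils::write.csv(stats_tab, stats_path, row.names = FALSE)

  report <- full_screen(ft[c("fc_only", "fc_plus_neuro")], models = models,
                        k = k, n_perm = n_perm, seed = seed,
                        reducer_config = reducer_config)
  report_csv <- file.path(out_dir, "screen_report.csv")
  write_report(report, report_csv, "csv")
  report_json <- file.path(out_dir, "screen_report.json")
  write_report(report, report_json, "json")

  manifest <- list(
    package_version = as.character(utils::packageVersion("nirscreen")),
    seed = seed,
    n_subjects = length(cohort$recordings),
    excluded = attr(ft, "excluded"),
    files = vapply(c(scores_path, feats_path, stats_path, report_csv,
                     report_json),
                   function(p) unname(tools::md5sum(p)), character(1))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(stats = stats_tab, report = report,
                 paths = c(scores = scores_path, features = feats_path,
                           stats = stats_path, report = report_csv)))
}
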
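#' z-score normalization of one feature
#'
#' `(x - mean(x)) / sd(x)` using the sample SD. Applied per connection
#' across subjects before the ANOVA when the normality gate fails.
#'
#' @param values numeric vector, `length >= 2`, non-constant.
#' @return normalized vector.
#' @export
normalize_feature <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero-variance feature cannot be normalized")
  (values - mean(values)) / s
}

#' One-way fixed-effects ANOVA
#'
#' Classical F test of equal group means, `F = MS_between / MS_within`
#' with `df = (k - 1, N - k)`.
#'
#' @param groups list of numeric vectors, one per group (each `n >= 2`).
#' @return list with `F`, `df1`, `df2`, `p`, and `msw` (within-group mean
#'   square, reused by the LSD post hoc).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs at least 2 observations")
  }
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  N <- length(x); k <- nlevels(g)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ns <- tabulate(g)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((x - means[g])^2)
  df1 <- k - 1L; df2 <- N - k
  msw <- ssw / df2
  if (msw == 0) stop("degenerate: zero within-group variance")
  Fv <- (ssb / df1) / msw
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE), msw = msw)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with the usual monotonicity enforcement
#' (cumulative minimum from the largest p down); delegates to
#' [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Fisher LSD post-hoc t test
#'
#' Pairwise t statistic using the omnibus ANOVA's pooled within-group
#' mean square:
#' `t = (mean_a - mean_b) / sqrt(MSW * (1/n_a + 1/n_b))`, `df = N - k`.
#'
#' @param groups list of numeric vectors (all groups of the omnibus ANOVA).
#' @param pair integer pair: indices of the two groups to contrast.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
lsd_posthoc <- function(groups, pair) {
  a <- groups[[pair[1]]]; b <- groups[[pair[2]]]
  fit <- anova_oneway(groups)
  se <- sqrt(fit$msw * (1 / length(a) + 1 / length(b)))
  tv <- (mean(a) - mean(b)) / se
  list(t = tv, df = fit$df2,
       p = 2 * stats::pt(abs(tv), fit$df2, lower.tail = FALSE))
}

#' Group-difference analysis over all connections
#'
#' For every FC feature column: a Shapiro-Wilk normality gate decides
#' whether the feature is z-score transformed; a three-group one-way
#' ANOVA is run; p-values are BH-adjusted within each (estimator,
#' chromophore) family (or pooled, per `fdr_family`); the three LSD-t
#' pairwise contrasts are computed wherever the corrected ANOVA p falls
#' below `alpha`. Subjects missing a feature are dropped for that
#' connection only (pairwise-complete).
#'
#' @param features data.frame with a `group` column and FC feature
#'   columns named `ESTIMATOR_CHROMOPHORE_ROIi_ROIj`.
#' @param fdr_family `"per"` (within each estimator x chromophore family,
#'   the default) or `"pooled"` (all connections at once).
#' @param alpha significance gate for the post hoc (default 0.05).
#' @param normality_alpha Shapiro-Wilk level for the z-transform gate.
#' @return data.frame: estimator, chromophore, roi_i, roi_j, n, F, df1,
#'   df2, p_raw, p_fdr, and `t_<a>_<b>` / `p_<a>_<b>` columns for the
#'   three pairwise contrasts (NA unless p_fdr < alpha).
#' @export
run_group_analysis <- function(features, fdr_family = c("per", "pooled"),
                               alpha = 0.05, normality_alpha = 0.05) {
  fdr_family <- match.arg(fdr_family)
  stopifnot("group" %in% names(features))
  glev <- unique(as.character(features$group))
  if (length(glev) != 3) stop("exactly three groups are required")
  fc_cols <- grep("^[A-Za-z]+_[A-Za-z]+_ROI[0-9]+_ROI[0-9]+$",
                  names(features), value = TRUE)
  if (length(fc_cols) == 0) stop("no FC feature columns found")

  rows <- lapply(fc_cols, function(col) {
    parts <- strsplit(col, "_")[[1]]
    x <- features[[col]]
    ok <- is.finite(x)
    x <- x[ok]; g <- as.character(features$group)[ok]
    res <- data.frame(estimator = parts[1], chromophore = parts[2],
                      roi_i = parts[3], roi_j = parts[4], n = length(x),
                      F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                      p_raw = NA_real_, stringsAsFactors = FALSE)
    if (length(x) < 6 || stats::sd(x) == 0 ||
        any(table(factor(g, glev)) < 2)) {
      return(res)
    }
    sw_p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
    if (sw_p < normality_alpha) x <- normalize_feature(x)
    groups <- split(x, factor(g, glev))
    fit <- tryCatch(anova_oneway(groups), error = function(e) NULL)
    if (is.null(fit)) return(res)
    res$F <- fit$F; res$df1 <- fit$df1; res$df2 <- fit$df2
    res$p_raw <- fit$p
    attr(res, "groups") <- groups
    res
  })
  out <- do.call(rbind, lapply(rows, function(r) r))
  fam <- if (fdr_family == "per") {
    paste(out$estimator, out$chromophore)
  } else {
    rep("all", nrow(out))
  }
  out$p_fdr <- NA_real_
  for (f in unique(fam)) {
    sel <- fam == f & is.finite(out$p_raw)
    if (any(sel)) out$p_fdr[sel] <- fdr_adjust(out$p_raw[sel])
  }

  pairs <- utils::combn(3, 2)
  for (pc in seq_len(ncol(pairs))) {
    a <- glev[pairs[1, pc]]; b <- glev[pairs[2, pc]]
    out[[paste0("t_", a, "_", b)]] <- NA_real_
    out[[paste0("p_", a, "_", b)]] <- NA_real_
  }
  for (i in seq_along(rows)) {
    if (!is.finite(out$p_fdr[i]) || out$p_fdr[i] >= alpha) next
    groups <- attr(rows[[i]], "groups")
    for (pc in seq_len(ncol(pairs))) {
      ph <- lsd_posthoc(groups, pairs[, pc])
      a <- glev[pairs[1, pc]]; b <- glev[pairs[2, pc]]
      out[[paste0("t_", a, "_", b)]][i] <- ph$t
      out[[paste0("p_", a, "_", b)]][i] <- ph$p
    }
  }
  out
}
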
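#' Per-probe paired differential methylation tests
#'
#' Stage 1 of the discovery pipeline: for every probe with complete data,
#' tests the tumor-vs-normal methylation difference across matched pairs.
#' The default is a two-sided paired t-test on beta values: with paired
#' differences `d` over `n` pairs, `statistic = mean(d) / (sd(d)/sqrt(n))`
#' and the p-value comes from the t distribution with `n - 1` degrees of
#' freedom. For a two-group design this is equivalent to a one-way ANOVA
#' (F = t^2) while respecting the matched design. q-values are
#' Benjamini-Hochberg adjusted p-values ([adjust_bh()]).
#'
#' Probes with any missing value in the contrast are excluded (a message
#' reports the count). A probe whose differences have zero variance gets
#' statistic 0 and p = 1 when the mean difference is also zero, and the
#' smallest representable positive p (with a message) otherwise.
#'
#' @param beta Numeric probes x samples matrix of methylation fractions.
#' @param sheet Sample sheet pairing the columns (see
#'   [validate_sample_sheet()]); every pair must have both conditions
#'   among the matrix columns and at least 2 complete pairs are required.
#' @param method `"paired"` (default) or `"welch"` for an unpaired
#'   two-sample Welch t-test.
#' @param scale `"beta"` (default) tests methylation fractions directly;
#'   `"mvalue"` tests `log2(beta/(1-beta))` (means and delta_beta are
#'   always reported on the beta scale).
#' @return Data frame with one row per tested probe: `probe_id`,
#'   `mean_normal`, `mean_tumor`, `delta_beta` (tumor minus normal),
#'   `statistic`, `p`, `q`, `significant` (all `FALSE` until
#'   [filter_significant()] is applied).
#' @examples
#' cfg <- cohort_config(n_background_genes = 5, noise_precision = 100)
#' eff <- default_ptccrcc_effects()
#' ch <- simulate_cohort(build_manifest(cfg, eff), eff, cfg)
#' head(test_probes(ch$beta, ch$sheet))
#' @export
test_probes <- function(beta, sheet, method = c("paired", "welch"),
                        scale = c("beta", "mvalue")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  .assert(is.matrix(beta) && is.numeric(beta), "beta must be a numeric matrix")
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(sheet$sample_id, colnames(beta))
  .assert(length(miss) == 0L,
          "sample(s) in sheet absent from beta matrix: ",
          paste(miss, collapse = ", "))
  pairs <- unique(sheet$pair_id)
  .assert(length(pairs) >= 2L, "need at least 2 complete pairs")
  norm_cols <- vapply(pairs, function(p)
    sheet$sample_id[sheet$pair_id == p & sheet$condition == "normal"],
    character(1))
  tum_cols <- vapply(pairs, function(p)
    sheet$sample_id[sheet$pair_id == p & sheet$condition == "tumor"],
    character(1))
  Nm <- beta[, norm_cols, drop = FALSE]
  Tm <- beta[, tum_cols, drop = FALSE]

  complete <- rowSums(is.na(Nm)) == 0L & rowSums(is.na(Tm)) == 0L
  if (any(!complete)) {
    message(sum(!complete), " probe(s) with missing values excluded")
    Nm <- Nm[complete, , drop = FALSE]
    Tm <- Tm[complete, , drop = FALSE]
  }
  n <- length(pairs)
  mean_normal <- rowMeans(Nm)
  mean_tumor <- rowMeans(Tm)

  if (scale == "mvalue") {
    logit2 <- function(x) {
      x <- pmin(pmax(x, 0.001), 0.999)
      log2(x / (1 - x))
    }
    Ns <- logit2(Nm)
    Ts <- logit2(Tm)
  } else {
    Ns <- Nm; Ts <- Tm
  }

  if (method == "paired") {
    D <- Ts - Ns
    md <- rowMeans(D)
    sdd <- sqrt(rowSums((D - md)^2) / (n - 1L))
    statistic <- ifelse(sdd > 0, md / (sdd / sqrt(n)), ifelse(md == 0, 0, Inf * sign(md)))
    p <- ifelse(is.finite(statistic),
                2 * pt(-abs(statistic), df = n - 1L),
                .Machine$double.xmin)
    p[statistic == 0 & sdd == 0] <- 1
    degen <- sum(sdd == 0 & md != 0)
    if (degen > 0) {
      message(degen, " probe(s) with zero-variance nonzero differences; ",
              "p set to smallest positive value")
    }
  } else {
    mN <- rowMeans(Ns); mT <- rowMeans(Ts)
    vN <- rowSums((Ns - mN)^2) / (n - 1L)
    vT <- rowSums((Ts - mT)^2) / (n - 1L)
    se2 <- vN / n + vT / n
    statistic <- ifelse(se2 > 0, (mT - mN) / sqrt(se2),
                        ifelse(mT == mN, 0, Inf * sign(mT - mN)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((vN / n)^2 / (n - 1L) + (vT / n)^2 / (n - 1L)),
                 n - 1L)
    p <- ifelse(is.finite(statistic), 2 * pt(-abs(statistic), df = df),
                .Machine$double.xmin)
    p[statistic == 0] <- 1
  }

  res <- data.frame(
    probe_id = rownames(Nm),
    mean_normal = mean_normal,
    mean_tumor = mean_tumor,
    delta_beta = mean_tumor - mean_normal,
    statistic = statistic,
    p = p,
    q = adjust_bh(p),
    significant = FALSE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate correction, returned in input order
#' (delegates to [stats::p.adjust()] with `method = "BH"` after input
#' validation).
#'
#' @param p_values Numeric vector of p-values in `[0,1]`.
#' @return q-values in input order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.04))
#' @export
adjust_bh <- function(p_values) {
  .assert(is.numeric(p_values), "p_values must be numeric")
  bad <- which(!is.na(p_values) & (p_values < 0 | p_values > 1))
  .assert(length(bad) == 0L,
          "p-value(s) outside [0,1] at position(s): ",
          paste(head(bad, 5L), collapse = ", "))
  p.adjust(p_values, method = "BH")
}

#' Row-wise z-score matrix for heatmap display
#'
#' Standardizes each probe row to mean 0 and sample SD 1 (the transform
#' behind tumor/normal methylome heatmaps). Constant rows map to all
#' zeros; a message reports how many.
#'
#' @param beta Numeric matrix with at least 2 columns.
#' @return Matrix of the same shape with row z-scores.
#' @export
zscore_rows <- function(beta) {
  .assert(is.matrix(beta) && is.numeric(beta), "beta must be a numeric matrix")
  .assert(ncol(beta) >= 2L, "need at least 2 samples to z-score rows")
  mu <- rowMeans(beta)
  sdev <- sqrt(rowSums((beta - mu)^2) / (ncol(beta) - 1L))
  const <- sdev == 0
  if (any(const)) message(sum(const), " constant row(s) mapped to zeros")
  sdev[const] <- 1
  z <- (beta - mu) / sdev
  z[const, ] <- 0
  z
}

#' Filter probe test results by adjusted significance
#'
#' Retains probes with `q < alpha` and flags them significant; `alpha = 1`
#' retains everything. The retained count is reported in a message.
#'
#' @param results Output of [test_probes()].
#' @param alpha Significance level on the BH-adjusted q (default 0.01).
#' @return The significant subset of `results` with `significant = TRUE`.
#' @export
filter_significant <- function(results, alpha = 0.01) {
  .assert(is.data.frame(results) && all(c("q") %in% names(results)),
          "results must be a probe test table with a 'q' column")
  .assert(.is_number(alpha) && alpha > 0 && alpha <= 1,
          "alpha must lie in (0, 1]")
  keep <- if (alpha >= 1) rep(TRUE, nrow(results)) else results$q < alpha
  out <- results[keep, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  message(nrow(out), " of ", nrow(results), " probes significant at q < ",
          alpha)
  rownames(out) <- NULL
  out
}
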
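#' Paired t-test on pre/post measurements
#'
#' Thin wrapper around [stats::t.test()] for subject-paired comparisons,
#' returning the quantities the summary tables need. Two-sided throughout,
#' no multiple-testing correction (per-ROI p-values are reported
#' uncorrected, a deliberate faithful-reporting choice). Degenerate
#' zero-variance differences with a non-zero mean are an error rather
#' than `p = 0`; identical vectors give `t = 0, p = 1`.
#'
#' @param pre,post Numeric vectors of equal length (n >= 2), paired by
#'   subject; the test is on `post - pre`.
#' @return A list: `t`, `df`, `p`, `mean_diff`, `se`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(2, 3, 5))
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, se = 0))
    }
    stop("differences have zero variance with non-zero mean; ",
         "paired t is undefined", call. = FALSE)
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate),
       se = unname(tt$stderr))
}

#' Pearson correlation with optional covariate adjustment
#'
#' With no covariates, the plain Pearson correlation (via
#' [stats::cor.test()]). With covariates, the partial correlation by the
#' residual method: `x` and `y` are each regressed on the covariates and
#' the residuals are correlated, with `df = n - 2 - k` for `k` covariates;
#' the p-value comes from the usual t transform of `r` at that df.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates `NULL`, or a numeric vector / matrix / data.frame of
#'   covariates (one column per covariate, full column rank required).
#' @return A list: `r`, `p`, `df`, `n`, and the residuals `rx`, `ry`
#'   (equal to centered `x`, `y` when no covariates are given).
#' @export
#' @examples
#' correlation_with_covariate(rnorm(20), rnorm(20))
correlation_with_covariate <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (is.null(covariates) || (is.data.frame(covariates) && !ncol(covariates))) {
    if (n < 3) stop("need n >= 3", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson")
    return(list(r = unname(ct$estimate), p = ct$p.value,
                df = unname(ct$parameter), n = n,
                rx = x - mean(x), ry = y - mean(y)))
  }
  Z <- as.matrix(as.data.frame(covariates))
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > number of covariates + 2", call. = FALSE)
  if (qr(cbind(1, Z))$rank < k + 1) {
    stop("covariates are rank deficient", call. = FALSE)
  }
  rx <- stats::resid(stats::lm(x ~ Z))
  ry <- stats::resid(stats::lm(y ~ Z))
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, n = n,
       rx = rx, ry = ry)
}

#' Group summary row for one session and region
#'
#' Inter-subject mean and standard error (`SD/sqrt(n)`) of the relative
#' signal change and concentration for one (session, ROI) cell of a
#' cohort table, the two-sided p-value of the change versus the
#' pre-injection state (a one-sample t of the per-subject changes against
#' zero, equivalent to the paired test on the underlying signals), and
#' summary timings. A timing or concentration cell is reported as `NA`
#' when more than `na_fraction` of subjects have it undefined, mirroring
#' the convention of not reporting timings for non-significant changes.
#'
#' @param cohort Long-format cohort as produced by [simulate_cohort()].
#' @param session Session label present in `cohort$session`.
#' @param roi Region present in `cohort$roi`.
#' @param na_fraction Maximum tolerated fraction of undefined values in a
#'   cell before the cell itself becomes `NA` (default 0.5).
#' @return A one-row data.frame: `session`, `roi`, `n`, `delta_s_mean`,
#'   `delta_s_se`, `p_vs_pre`, `gd_mean`, `gd_se`, `t_onset_mean`,
#'   `t_onset_se`, `ttp_mean`, `ttp_se`.
#' @export
summary_table <- function(cohort, session, roi, na_fraction = 0.5) {
  rows <- cohort[cohort$session == session & cohort$roi == roi, ]
  if (nrow(rows) < 2) {
    stop("need at least 2 subjects for session/roi: ", session, "/", roi,
         call. = FALSE)
  }
  if (anyDuplicated(rows$subject)) {
    stop("duplicated subject IDs in cohort cell", call. = FALSE)
  }
  mse <- function(v) {
    ok <- !is.na(v)
    if (mean(ok) < 1 - na_fraction || sum(ok) < 2) {
      return(c(NA_real_, NA_real_))
    }
    c(mean(v[ok]), stats::sd(v[ok]) / sqrt(sum(ok)))
  }
  ds <- mse(rows$delta_s)
  gd <- mse(rows$gd)
  on <- mse(rows$t_onset)
  tp <- mse(rows$ttp)
  p <- if (stats::sd(rows$delta_s) == 0) {
    if (all(rows$delta_s == 0)) 1 else NA_real_
  } else {
    stats::t.test(rows$delta_s, mu = 0)$p.value
  }
  data.frame(session = session, roi = roi, n = nrow(rows),
             delta_s_mean = ds[1], delta_s_se = ds[2], p_vs_pre = p,
             gd_mean = gd[1], gd_se = gd[2],
             t_onset_mean = on[1], t_onset_se = on[2],
             ttp_mean = tp[1], ttp_se = tp[2])
}

#' Full cohort summary across sessions and regions
#'
#' Applies [summary_table()] to every (session, ROI) combination present
#' in the cohort.
#'
#' @inheritParams summary_table
#' @return A data.frame with one row per session x ROI.
#' @export
cohort_summary_table <- function(cohort, na_fraction = 0.5) {
  combos <- unique(cohort[c("session", "roi")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    summary_table(cohort, combos$session[i], combos$roi[i], na_fraction)
  }))
  rownames(out) <- NULL
  out
}
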
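# Paired exposure-change statistics: geometric means, geometric mean
# ratios with t-based confidence intervals on the log scale, and the
# bioequivalence classification of the GMR interval.

#' Geometric mean with a t-based confidence interval
#'
#' `gm = exp(mean(log x))`; the interval is
#' `exp(mean(log x) +/- t_{n-1} * se(log x))`.
#'
#' @param values Positive numeric vector, length >= 2.
#' @param level Confidence level as a fraction (default 0.95).
#' @return Object of class `geomean_ci`: `gm`, `ci_low`, `ci_high`,
#'   `level`, `n`.
#' @export
geomean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("sample-size error: need at least 2 values", call. = FALSE)
  if (any(values <= 0)) {
    stop("domain error: geometric mean requires positive values", call. = FALSE)
  }
  lx <- log(values)
  m <- mean(lx)
  se <- stats::sd(lx) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  structure(list(gm = exp(m), ci_low = exp(m - tq * se),
                 ci_high = exp(m + tq * se), level = level, n = n),
            class = "geomean_ci")
}

#' @export
print.geomean_ci <- function(x, ...) {
  cat(sprintf("<geomean_ci> GM %.4g (%g%% CI %.4g-%.4g), n = %d\n",
              x$gm, 100 * x$level, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Paired geometric mean ratio with confidence interval and p-value
#'
#' The standard exposure-change statistic for a paired drug-interaction
#' design: a paired t procedure on `d_i = log(treated_i) - log(baseline_i)`.
#' `gmr = exp(mean d)`, CI `exp(mean d +/- t_{n-1} * se(d))` (90% by
#' default, the bioequivalence convention), and a two-sided p-value for
#' mean d = 0.  When subjects are named, pairs are matched by name and
#' incomplete pairs dropped listwise.
#'
#' @param baseline,treated Positive per-subject values; either both named
#'   (matched by name) or both unnamed of equal length (matched by position).
#' @param level Confidence level (default 0.90).
#' @return Object of class `gmr_result`: `gmr`, `ci_low`, `ci_high`,
#'   `level`, `p_value`, `n_pairs`, `degenerate` (TRUE when all paired log
#'   differences are identical so the t statistic is undefined).
#' @export
gmr_paired <- function(baseline, treated, level = 0.90) {
  if (!is.null(names(baseline)) && !is.null(names(treated))) {
    common <- intersect(names(baseline), names(treated))
    if (length(common) < 2L) {
      stop("pairing error: fewer than 2 matched subjects", call. = FALSE)
    }
    baseline <- baseline[common]; treated <- treated[common]
  } else if (length(baseline) != length(treated)) {
    stop("pairing error: unmatched subject sets (unequal lengths, no names)",
         call. = FALSE)
  }
  keep <- !is.na(baseline) & !is.na(treated)
  baseline <- baseline[keep]; treated <- treated[keep]
  n <- length(baseline)
  if (n < 2L) stop("sample-size error: need at least 2 complete pairs",
                   call. = FALSE)
  if (any(baseline <= 0) || any(treated <= 0)) {
    stop("domain error: GMR requires positive values", call. = FALSE)
  }
  d <- log(treated) - log(baseline)
  m <- mean(d)
  sdd <- stats::sd(d)
  se <- sdd / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  degenerate <- sdd == 0
  p <- if (degenerate) NA_real_ else 2 * stats::pt(-abs(m / se), df = n - 1)
  structure(list(gmr = exp(m), ci_low = exp(m - tq * se),
                 ci_high = exp(m + tq * se), level = level,
                 p_value = p, n_pairs = n, degenerate = degenerate),
            class = "gmr_result")
}

#' @export
print.gmr_result <- function(x, ...) {
  cat(sprintf("<gmr_result> GMR %.4g (%g%% CI %.4g-%.4g), p = %.3g, n = %d\n",
              x$gmr, 100 * x$level, x$ci_low, x$ci_high, x$p_value, x$n_pairs))
  invisible(x)
}

#' Classify a GMR confidence interval against bioequivalence bounds
#'
#' @param result A [gmr_paired()] result.
#' @param bounds The no-effect bounds, default the regulatory 0.80-1.25.
#' @return `"within"` (CI inside the bounds), `"above"` (entirely above),
#'   `"below"` (entirely below) or `"straddles"`.
#' @export
bioequivalence_flag <- function(result, bounds = c(0.80, 1.25)) {
  stopifnot(inherits(result, "gmr_result"))
  if (result$ci_low >= bounds[1] && result$ci_high <= bounds[2]) "within"
  else if (result$ci_low > bounds[2]) "above"
  else if (result$ci_high < bounds[1]) "below"
  else "straddles"
}

#' Regression between two sets of exposure ratios
#'
#' Ordinary least squares of one set of per-subject exposure ratios on
#' another (log scale by default), e.g. statin AUC ratios against the
#' midazolam CYP3A4-probe ratios, to ask whether the interaction tracks
#' enzyme inhibition across subjects.
#'
#' @param x_ratios,y_ratios Positive numeric vectors of equal length >= 3.
#' @param log_scale Regress on log ratios (default `TRUE`).
#' @return List with `r2`, `p` (two-sided slope p-value), `slope`, `n`.
#' @export
log_ratio_regression <- function(x_ratios, y_ratios, log_scale = TRUE) {
  if (length(x_ratios) != length(y_ratios)) {
    stop("pairing error: unequal lengths", call. = FALSE)
  }
  n <- length(x_ratios)
  if (n < 3L) stop("sample-size error: need at least 3 pairs", call. = FALSE)
  if (log_scale) {
    if (any(x_ratios <= 0) || any(y_ratios <= 0)) {
      stop("domain error: log-scale regression requires positive ratios",
           call. = FALSE)
    }
    x <- log(x_ratios); y <- log(y_ratios)
  } else {
    x <- x_ratios; y <- y_ratios
  }
  if (stats::sd(x) == 0) {
    stop("degenerate-regression error: zero variance in x", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r2 = sm$r.squared, p = sm$coefficients["x", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)["x"]), n = n)
}

#' GMR table over an NCA results table
#'
#' For every analyte and exposure measure, pairs the baseline and
#' ritonavir-day-5 values by subject and computes the GMR with 90% CI,
#' p-value and bioequivalence flag — the machine-readable counterpart of a
#' forest plot of exposure changes.
#'
#' @param nca_df A data frame from [nca_table()].
#' @param parameters Columns to compare (default the main exposure measures).
#' @param level Confidence level (default 0.90).
#' @param occasions Length-2 character: reference then test occasion.
#' @return A data frame, one row per analyte x parameter.
#' @export
gmr_table <- function(nca_df, parameters = c("auc_inf", "cmax", "t_half"),
                      level = 0.90,
                      occasions = c("baseline", "ritonavir_day5")) {
  stopifnot(is.data.frame(nca_df))
  out <- list()
  for (an in unique(nca_df$analyte)) {
    sub <- nca_df[nca_df$analyte == an, ]
    for (par in parameters) {
      b <- sub[sub$occasion == occasions[1], ]
      t <- sub[sub$occasion == occasions[2], ]
      bv <- stats::setNames(b[[par]], b$subject)
      tv <- stats::setNames(t[[par]], t$subject)
      res <- tryCatch(gmr_paired(bv, tv, level = level),
                      error = function(e) NULL)
      if (is.null(res)) next
      out[[length(out) + 1L]] <- data.frame(
        analyte = an, parameter = par, gmr = res$gmr,
        ci_low = res$ci_low, ci_high = res$ci_high,
        p_value = res$p_value, n_pairs = res$n_pairs,
        flag = bioequivalence_flag(res), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
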
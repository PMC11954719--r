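# Noncompartmental analysis of single-dose concentration-time profiles.
# Conventions: lin-up/log-down trapezoid (Phoenix-compatible default),
# terminal slope from the adjusted-R2-maximising contiguous terminal subset
# (>= 3 points, Cmax excluded), AUCinf tail from the regression-predicted
# last concentration.

#' Fit the terminal log-linear slope of a profile
#'
#' Performs log-linear least squares on terminal observations to estimate
#' the terminal rate constant \eqn{\lambda_z} and half-life
#' \eqn{t_{1/2} = \ln 2 / \lambda_z}.  With `selection = "best_adj_r2"`
#' every contiguous terminal subset of at least 3 points strictly after
#' Tmax is scanned and the fit maximising adjusted R-squared is returned
#' (ties broken towards more points).  `selection = "manual"` fits all
#' eligible points inside `time_range`.
#'
#' @param profile An LLOQ-processed [concentration_profile()].
#' @param selection `"best_adj_r2"` or `"manual"`.
#' @param time_range Length-2 numeric, required for manual selection.
#' @return Object of class `lambda_z_fit`: `lambda_z` (1/h), `t_half` (h),
#'   `n_points`, `adj_r2`, `time_range`, `intercept_log`.
#' @export
fit_lambda_z <- function(profile, selection = c("best_adj_r2", "manual"),
                         time_range = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  selection <- match.arg(selection)
  rec <- profile$records[!profile$records$blq & profile$records$conc > 0, ]
  if (nrow(rec) == 0) stop("empty-profile error: no positive observations",
                           call. = FALSE)
  tmax <- rec$time[which.max(rec$conc)]
  term <- rec[rec$time > tmax, ]
  if (selection == "manual") {
    if (is.null(time_range) || length(time_range) != 2L) {
      stop("manual selection requires time_range = c(start, end)", call. = FALSE)
    }
    term <- term[term$time >= time_range[1] & term$time <= time_range[2], ]
  }
  if (nrow(term) < 3L) {
    stop("insufficient-data error: fewer than 3 eligible terminal points",
         call. = FALSE)
  }

  fit_one <- function(tt, lc) {
    n <- length(tt)
    fit <- stats::lm.fit(cbind(1, tt), lc)
    slope <- fit$coefficients[2]
    r2 <- 1 - sum(fit$residuals^2) / sum((lc - mean(lc))^2)
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    list(slope = slope, intercept = fit$coefficients[1], adj_r2 = adj, n = n)
  }

  lc <- log(term$conc)
  if (selection == "manual") {
    cands <- list(c(1L, nrow(term)))
  } else {
    cands <- lapply(seq_len(nrow(term) - 2L), function(i) c(i, nrow(term)))
  }
  fits <- lapply(cands, function(idx) {
    f <- fit_one(term$time[idx[1]:idx[2]], lc[idx[1]:idx[2]])
    f$range <- c(term$time[idx[1]], term$time[idx[2]])
    f
  })
  fits <- Filter(function(f) {
    is.finite(f$slope) && f$slope < 0 && is.finite(f$adj_r2)
  }, fits)
  if (!length(fits)) {
    stop("no-terminal-phase error: no declining terminal fit found",
         call. = FALSE)
  }
  adj <- vapply(fits, `[[`, numeric(1), "adj_r2")
  npts <- vapply(fits, `[[`, numeric(1), "n")
  best_adj <- max(adj)
  # Phoenix-style tie rule: within 1e-4 of the best adjusted R2, prefer more points
  eligible <- which(adj >= best_adj - 1e-4)
  best <- eligible[which.max(npts[eligible])]
  f <- fits[[best]]
  structure(
    list(lambda_z = unname(-f$slope), t_half = unname(log(2) / -f$slope),
         n_points = f$n, adj_r2 = unname(f$adj_r2), time_range = f$range,
         intercept_log = unname(f$intercept)),
    class = "lambda_z_fit"
  )
}

#' @export
print.lambda_z_fit <- function(x, ...) {
  cat(sprintf("<lambda_z_fit> lambda_z %.5g /h (t1/2 %.4g h), %d points [%g, %g] h, adj R2 %.4f\n",
              x$lambda_z, x$t_half, x$n_points, x$time_range[1], x$time_range[2],
              x$adj_r2))
  invisible(x)
}

# interpolate concentration at time t inside the observed range,
# log interpolation on strictly falling positive segments, else linear
.interp_conc <- function(time, conc, t) {
  if (t <= time[1]) return(conc[1])
  i <- findInterval(t, time)
  if (t == time[i]) return(conc[i])
  t1 <- time[i]; t2 <- time[i + 1]; c1 <- conc[i]; c2 <- conc[i + 1]
  frac <- (t - t1) / (t2 - t1)
  if (c1 > c2 && c2 > 0) c1 * (c2 / c1)^frac else c1 + frac * (c2 - c1)
}

.segment_auc <- function(t1, t2, c1, c2, linlog = TRUE) {
  dt <- t2 - t1
  if (linlog && c1 > c2 && c2 > 0) dt * (c1 - c2) / log(c1 / c2)
  else dt * (c1 + c2) / 2
}

#' Partial AUC by the lin-up/log-down trapezoid method
#'
#' Piecewise trapezoid integration of a concentration-time profile over
#' `[t_start, t_end]`: linear when the concentration rises or is constant,
#' logarithmic when strictly falling between two positive values (the exact
#' integral of the mono-exponential through the two points), with a linear
#' fallback when an endpoint is zero.  Interval ends inside a sampling
#' segment are handled by matching interpolation.
#'
#' @param profile An LLOQ-processed [concentration_profile()].
#' @param t_start,t_end Interval bounds in hours, inside the observed range.
#' @param method `"linlog"` (default) or `"linear"` (pure linear trapezoid).
#' @return Partial AUC in h*ng/mL (or h*nmol/L for molar profiles).
#' @export
auc_linlog <- function(profile, t_start, t_end, method = c("linlog", "linear")) {
  stopifnot(inherits(profile, "concentration_profile"))
  method <- match.arg(method)
  linlog <- method == "linlog"
  rec <- profile$records[!profile$records$blq, ]
  if (t_start >= t_end) stop("t_start must be < t_end", call. = FALSE)
  if (t_start < rec$time[1] || t_end > rec$time[nrow(rec)]) {
    stop("extrapolation error: interval [", t_start, ", ", t_end,
         "] outside observed range", call. = FALSE)
  }
  time <- rec$time; conc <- rec$conc
  inner <- time > t_start & time < t_end
  tt <- c(t_start, time[inner], t_end)
  cc <- c(.interp_conc(time, conc, t_start), conc[inner],
          .interp_conc(time, conc, t_end))
  sum(vapply(seq_len(length(tt) - 1L), function(i) {
    .segment_auc(tt[i], tt[i + 1], cc[i], cc[i + 1], linlog)
  }, numeric(1)))
}

#' Apparent oral clearance from dose and AUC
#'
#' CL/F = dose / AUCinf, converted to mL/min: with dose in ng and AUC in
#' h*ng/mL the quotient is mL/h, divided by 60.
#'
#' @param dose_ng Dose in ng.
#' @param auc_inf AUC extrapolated to infinity, h*ng/mL.
#' @return CL/F in mL/min.
#' @export
cl_f_from_auc <- function(dose_ng, auc_inf) dose_ng / auc_inf / 60

#' Apparent terminal volume of distribution from CL/F and half-life
#'
#' Vz/F = (CL/F) / lambda_z with lambda_z = ln 2 / t_half, converted to L.
#'
#' @param cl_f_ml_min CL/F in mL/min.
#' @param t_half Terminal half-life in hours.
#' @return Vz/F in litres.
#' @export
vz_f_from_cl <- function(cl_f_ml_min, t_half) {
  cl_f_ml_min * 60 * t_half / log(2) / 1000
}

#' Noncompartmental summary of a single-dose profile
#'
#' Computes Cmax and Tmax (ties broken to the earliest time), AUC to the
#' last quantifiable observation, the terminal slope fit, AUC extrapolated
#' to infinity (`auc_last + C_last_pred / lambda_z`, with the
#' regression-predicted last concentration by default), extrapolated
#' percentage, CL/F, Vz/F, AUC over a dosing interval `tau` and any
#' requested partial AUCs.  Terminal-slope failures are tolerated: the
#' dependent fields are left `NA` and the result flagged.
#'
#' @param profile An LLOQ-processed [concentration_profile()].
#' @param tau Optional dosing interval (h) for AUCtau.
#' @param partial_intervals Optional list of length-2 numeric vectors.
#' @param selection,time_range Passed to [fit_lambda_z()].
#' @param last_pred Use the lambda-z-regression prediction at the last time
#'   for the extrapolated tail (default `TRUE`); `FALSE` uses the observed
#'   last concentration.
#' @param method AUC method, `"linlog"` or `"linear"`.
#' @return Object of class `nca_result`.
#' @export
nca_summary <- function(profile, tau = NULL, partial_intervals = list(),
                        selection = "best_adj_r2", time_range = NULL,
                        last_pred = TRUE, method = "linlog") {
  stopifnot(inherits(profile, "concentration_profile"))
  rec <- profile$records[!profile$records$blq, ]
  if (nrow(rec) == 0 || all(rec$conc == 0)) {
    stop("empty-profile error: no quantifiable concentrations", call. = FALSE)
  }
  imax <- which.max(rec$conc)            # which.max returns the first (earliest) tie
  cmax <- rec$conc[imax]; tmax <- rec$time[imax]
  pos <- which(rec$conc > 0)
  ilast <- pos[length(pos)]
  tlast <- rec$time[ilast]; clast <- rec$conc[ilast]
  auc_last <- auc_linlog(profile, rec$time[1], tlast, method = method)

  lz <- tryCatch(
    fit_lambda_z(profile, selection = selection, time_range = time_range),
    error = function(e) e
  )
  flag <- NULL
  if (inherits(lz, "error")) {
    flag <- conditionMessage(lz)
    lz <- NULL
  }
  auc_inf <- cl_f <- vz_f <- auc_extrap_pct <- NA_real_
  if (!is.null(lz)) {
    c_tail <- if (last_pred) exp(lz$intercept_log - lz$lambda_z * tlast) else clast
    auc_inf <- auc_last + c_tail / lz$lambda_z
    auc_extrap_pct <- 100 * (auc_inf - auc_last) / auc_inf
    cl_f <- cl_f_from_auc(profile$dose_ng, auc_inf)
    vz_f <- vz_f_from_cl(cl_f, lz$t_half)
  }
  auc_tau <- if (!is.null(tau)) {
    auc_linlog(profile, rec$time[1], min(tau, tlast), method = method)
  } else NA_real_
  partial <- lapply(partial_intervals, function(iv) {
    auc_linlog(profile, iv[1], iv[2], method = method)
  })
  names(partial) <- vapply(partial_intervals, function(iv) {
    paste0(iv[1], "-", iv[2])
  }, character(1))

  structure(
    list(subject_id = profile$subject_id, analyte = profile$analyte$name,
         occasion = profile$occasion, dose_ng = profile$dose_ng,
         unit = profile$unit,
         cmax = cmax, tmax = tmax, tlast = tlast, clast = clast,
         auc_last = auc_last, auc_inf = auc_inf,
         auc_extrap_pct = auc_extrap_pct,
         lambda_z_fit = lz, t_half = if (is.null(lz)) NA_real_ else lz$t_half,
         cl_f = cl_f, vz_f = vz_f, auc_tau = auc_tau,
         partial_aucs = partial, flag = flag),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s/%s/%s: Cmax %.4g at %g h, AUClast %.4g, AUCinf %.4g, CL/F %.4g mL/min\n",
              x$subject_id, x$analyte, x$occasion, x$cmax, x$tmax,
              x$auc_last, x$auc_inf, x$cl_f))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Dose-normalised partial AUC
#'
#' Scales a partial AUC to a reference dose assuming linear kinetics, as
#' done for microdosed CYP3A4 probe exposures (e.g. the 2-4 h window of a
#' midazolam microdose normalised to 1 ug).
#'
#' @param result An [nca_summary()] result containing the interval.
#' @param interval Length-2 numeric naming the partial AUC.
#' @param reference_dose_ng Reference dose in ng.
#' @return Partial AUC scaled to the reference dose.
#' @export
dose_normalized_auc <- function(result, interval, reference_dose_ng) {
  stopifnot(inherits(result, "nca_result"))
  key <- paste0(interval[1], "-", interval[2])
  if (!key %in% names(result$partial_aucs)) {
    stop("key error: partial AUC for interval ", key, " not present",
         call. = FALSE)
  }
  result$partial_aucs[[key]] * reference_dose_ng / result$dose_ng
}

#' Total HMG-CoA reductase inhibitory activity
#'
#' Potency-weighted sum of molar exposures over an analyte family,
#' \eqn{\sum_i w_i \cdot AUC_{\infty,i}}, in h*nmol/L.  All inputs must be
#' on the molar scale.
#'
#' @param results List of elements `list(analyte = analyte_spec, auc = molar
#'   AUC, unit = "h*nmol/L")`; `unit` may be omitted and defaults to molar.
#' @return Weighted sum in h*nmol/L (0 for an empty list).
#' @export
total_inhibitory_activity <- function(results) {
  if (!length(results)) return(0)
  vals <- vapply(results, function(r) {
    unit <- if (is.null(r$unit)) "h*nmol/L" else r$unit
    if (!identical(unit, "h*nmol/L")) {
      stop("unit error: molar AUC (h*nmol/L) required, got ", unit,
           call. = FALSE)
    }
    r$analyte$potency_weight * r$auc
  }, numeric(1))
  sum(vals)
}

#' Tidy NCA table for a whole dataset
#'
#' Applies [apply_lloq()] and [nca_summary()] to every profile and binds
#' the scalar measures into one data frame, one row per subject x analyte
#' x occasion.
#'
#' @param dataset A [trial_dataset()].
#' @param lloq_rule Passed to [apply_lloq()].
#' @param ... Passed to [nca_summary()].
#' @return A data frame.
#' @export
nca_table <- function(dataset, lloq_rule = "zero_before_tmax_drop_after", ...) {
  stopifnot(inherits(dataset, "trial_dataset"))
  rows <- lapply(dataset$profiles, function(p) {
    res <- tryCatch(nca_summary(apply_lloq(p, lloq_rule), ...),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(subject = res$subject_id, analyte = res$analyte,
               occasion = res$occasion, dose_ng = res$dose_ng,
               cmax = res$cmax, tmax = res$tmax,
               auc_last = res$auc_last, auc_inf = res$auc_inf,
               auc_extrap_pct = res$auc_extrap_pct, t_half = res$t_half,
               cl_f = res$cl_f, vz_f = res$vz_f, auc_tau = res$auc_tau,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
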
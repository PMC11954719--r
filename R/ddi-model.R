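# Semi-mechanistic statin/ritonavir interaction model.
#
# Structure: two-compartment disposition with zero-order absorption into the
# central compartment.  Ritonavir irreversibly inactivates CYP3A; the amount
# of functional enzyme in gut and liver follows a turnover ODE
#   dE/dt = k_deg * (1 - E) - k_inact * R(t) * E,    E(0) = 1,
# with R(t) the ritonavir presence function (square wave covering 12 h per
# dose by default, i.e. continuous coverage under BID dosing).  The gut
# enzyme state at a statin dose time modulates that dose's input:
#   F(t) = f_rel_base / (theta_f + (1 - theta_f) * E_gut(t))
#   D(t) = d0 * (1 + (theta_d - 1) * (1 - E_gut(t)))
# anchored so E = 1 gives the baseline bioavailability and absorption
# duration and E = 0 gives the full-inhibition factors 1/theta_f and
# theta_d.  Elimination is constant by default; with use_cl_modulation the
# liver state scales clearance analogously through theta_cl.
#
# Because the disposition system is linear and F, D, CL are frozen at each
# dose time, both the enzyme ODE (piecewise-constant forcing) and the
# plasma model (zero-order input into a linear two-compartment system)
# admit exact closed-form solutions, which is what this file implements;
# an adaptive ODE integrator serves as the independent cross-check in the
# test suite.

#' Model parameters for the statin-ritonavir interaction model
#'
#' @param cl_f_base Apparent baseline clearance CL/F, L/h.
#' @param vc_f Apparent central volume Vc/F, L.
#' @param q_f Apparent inter-compartmental clearance Q/F, L/h.
#' @param vp_f Apparent peripheral volume Vp/F, L.
#' @param d0 Baseline zero-order absorption duration, h.
#' @param f_rel_base Baseline relative bioavailability (reference 1).
#' @param theta_f Bioavailability denominator at full inhibition, in (0, 1];
#'   the fitted trial value is 0.57 (full-inhibition exposure factor
#'   1/0.57 = 1.75).
#' @param theta_d Absorption-duration multiplier at full inhibition, >= 1;
#'   the fitted trial value is 1.71.
#' @param k_deg Enzyme turnover (degradation/synthesis) rate, 1/h; default
#'   0.03/h, the conventional ~23 h CYP3A turnover half-life.
#' @param k_inact Inactivation rate scale while ritonavir is present, 1/h;
#'   default 0.3/h drives the gut enzyme below 10% within 24 h of BID
#'   coverage.
#' @param theta_cl Clearance multiplier at full hepatic inhibition, in
#'   (0, 1]; only used when `use_cl_modulation = TRUE` (1 = inert liver).
#' @param use_cl_modulation Couple clearance to the liver enzyme state
#'   (default `FALSE`: no additional effect on elimination).
#' @param rito_coverage_h Duration of ritonavir presence per dose for the
#'   square-wave driver, h (default 12, i.e. BID coverage).
#' @param rito_driver `"square"` (default) or `"onecomp"` (exponentially
#'   decaying presence per dose, capped at 1).
#' @param rito_ke Elimination rate for the one-compartment driver, 1/h.
#' @param iiv_omega Named log-normal SDs for inter-individual variability
#'   on `f_rel`, `cl_f`, `vc_f` (used by the trial generator).
#' @param sigma_prop Proportional residual error SD (generator default 0.15).
#' @return Object of class `ddi_params`.
#' @export
ddi_params <- function(cl_f_base = 561, vc_f = 3500, q_f = 500, vp_f = 2420,
                       d0 = 1.25, f_rel_base = 1,
                       theta_f = 0.57, theta_d = 1.71,
                       k_deg = 0.03, k_inact = 0.3,
                       theta_cl = 1, use_cl_modulation = FALSE,
                       rito_coverage_h = 12,
                       rito_driver = c("square", "onecomp"), rito_ke = 0.116,
                       iiv_omega = c(f_rel = 0.4, cl_f = 0.4, vc_f = 0.4),
                       sigma_prop = 0.15) {
  rito_driver <- match.arg(rito_driver)
  p <- list(cl_f_base = cl_f_base, vc_f = vc_f, q_f = q_f, vp_f = vp_f,
            d0 = d0, f_rel_base = f_rel_base, theta_f = theta_f,
            theta_d = theta_d, k_deg = k_deg, k_inact = k_inact,
            theta_cl = theta_cl, use_cl_modulation = use_cl_modulation,
            rito_coverage_h = rito_coverage_h, rito_driver = rito_driver,
            rito_ke = rito_ke, iiv_omega = iiv_omega,
            sigma_prop = sigma_prop)
  validate_ddi_params(p)
  structure(p, class = "ddi_params")
}

validate_ddi_params <- function(p) {
  pos <- c("cl_f_base", "vc_f", "q_f", "vp_f", "d0", "f_rel_base", "k_deg",
           "rito_coverage_h", "rito_ke")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("ddi_params: ", nm, " must be positive and finite", call. = FALSE)
    }
  }
  if (!is.finite(p$k_inact) || p$k_inact < 0) {
    stop("ddi_params: k_inact must be >= 0", call. = FALSE)
  }
  if (!is.finite(p$theta_f) || p$theta_f <= 0 || p$theta_f > 1) {
    stop("ddi_params: theta_f must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(p$theta_d) || p$theta_d < 1) {
    stop("ddi_params: theta_d must be >= 1", call. = FALSE)
  }
  if (!is.finite(p$theta_cl) || p$theta_cl <= 0 || p$theta_cl > 1) {
    stop("ddi_params: theta_cl must lie in (0, 1]", call. = FALSE)
  }
  if (any(p$iiv_omega < 0) || p$sigma_prop < 0) {
    stop("ddi_params: variability terms must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ddi_params <- function(x, ...) {
  cat(sprintf(paste0("<ddi_params> CL/F %.4g L/h, Vc/F %.4g L, Q/F %.4g L/h, ",
                     "Vp/F %.4g L, D0 %.3g h\n  theta_f %.3g, theta_d %.3g, ",
                     "k_deg %.3g /h, k_inact %.3g /h, CL modulation: %s\n"),
              x$cl_f_base, x$vc_f, x$q_f, x$vp_f, x$d0, x$theta_f, x$theta_d,
              x$k_deg, x$k_inact, x$use_cl_modulation))
  invisible(x)
}

#' Dose events
#'
#' @param time Dose times, h (may be negative relative to the observation
#'   clock, e.g. ritonavir doses preceding the day-5 statin dose).
#' @param drug `"statin"` or `"ritonavir"`.
#' @param amount Dose amounts in ng (positive).
#' @return A data frame of class `dose_events`.
#' @export
dose_events <- function(time, drug, amount) {
  drug <- match.arg(drug, c("statin", "ritonavir"), several.ok = FALSE)
  if (any(!is.finite(time))) stop("dose times must be finite", call. = FALSE)
  if (any(!is.finite(amount) | amount <= 0)) {
    stop("dose amounts must be positive", call. = FALSE)
  }
  out <- data.frame(time = time, drug = drug, amount = amount)
  out <- out[order(out$time), , drop = FALSE]
  class(out) <- c("dose_events", "data.frame")
  out
}

# union of ritonavir coverage intervals for the square-wave driver
.rito_intervals <- function(times, coverage) {
  if (!length(times)) return(matrix(numeric(0), ncol = 2))
  times <- sort(times)
  starts <- times
  ends <- times + coverage
  m_start <- starts[1]; m_end <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= m_end) m_end <- max(m_end, ends[i])
    else { out[[length(out) + 1L]] <- c(m_start, m_end)
           m_start <- starts[i]; m_end <- ends[i] }
  }
  out[[length(out) + 1L]] <- c(m_start, m_end)
  do.call(rbind, out)
}

# ritonavir presence R(t), vectorised over t
.rito_presence <- function(params, rito_times, t) {
  if (!length(rito_times)) return(rep(0, length(t)))
  if (params$rito_driver == "square") {
    iv <- .rito_intervals(rito_times, params$rito_coverage_h)
    res <- rep(0, length(t))
    for (k in seq_len(nrow(iv))) {
      res[t >= iv[k, 1] & t < iv[k, 2]] <- 1
    }
    res
  } else {
    res <- rep(0, length(t))
    for (td in rito_times) {
      on <- t >= td
      res[on] <- res[on] + exp(-params$rito_ke * (t[on] - td))
    }
    pmin(res, 1)
  }
}

# Exact enzyme state under piecewise-constant R(t).  Within a segment with
# constant R: k = k_deg + k_inact * R, E_ss = k_deg / k,
# E(t) = E_ss + (E0 - E_ss) * exp(-k dt).  For the one-compartment driver
# R(t) varies continuously; segments are subdivided on a fine grid and
# treated as constant (error << 1e-6 at the default step).
.enzyme_at <- function(params, rito_times, times, origin = NULL) {
  if (is.null(origin)) {
    origin <- min(c(times, rito_times, 0))
  }
  query <- sort(unique(times))
  if (!length(rito_times) || params$k_inact == 0) {
    return(rep(1, length(times)))
  }
  if (params$rito_driver == "square") {
    iv <- .rito_intervals(rito_times, params$rito_coverage_h)
    brk <- sort(unique(c(origin, as.vector(iv), query)))
  } else {
    brk <- sort(unique(c(origin, rito_times, query,
                         seq(origin, max(query), by = 0.05))))
  }
  brk <- brk[brk >= origin & brk <= max(query)]
  mid <- (brk[-length(brk)] + brk[-1]) / 2
  rmid <- .rito_presence(params, rito_times, mid)
  e <- numeric(length(brk)); e[1] <- 1
  for (i in seq_along(mid)) {
    k <- params$k_deg + params$k_inact * rmid[i]
    ess <- params$k_deg / k
    e[i + 1] <- ess + (e[i] - ess) * exp(-k * (brk[i + 1] - brk[i]))
  }
  e_query <- e[match(query, brk)]
  e_query[match(times, query)]
}

#' Enzyme turnover trajectory under a ritonavir schedule
#'
#' Solves the turnover ODE `dE/dt = k_deg (1 - E) - k_inact R(t) E` for the
#' gut and liver enzyme pools, starting from the uninhibited state E = 1 at
#' the earliest event/query time.  Under the default square-wave presence
#' the solution is exact (piecewise exponential segments).
#'
#' @param params A [ddi_params()].
#' @param ritonavir_events [dose_events()] (or a numeric vector of dose
#'   times) for the perpetrator; empty means no inhibition.
#' @param times Sorted query times, h.
#' @return Data frame with columns `time`, `e_gut`, `e_liver` (fractions in
#'   (0, 1]).
#' @export
enzyme_trajectory <- function(params, ritonavir_events, times) {
  stopifnot(inherits(params, "ddi_params"))
  rt <- if (is.numeric(ritonavir_events)) ritonavir_events
        else ritonavir_events$time
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  e <- .enzyme_at(params, rt, times)
  data.frame(time = times, e_gut = e, e_liver = e)
}

# closed-form concentration (ng/L per the amount unit) in the central
# compartment of a two-compartment system receiving a zero-order input of
# total amount `famt` over duration `dur` starting at t = 0
.conc2cpt_zo <- function(t, famt, dur, cl, vc, q, vp) {
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  if (alpha - beta < 1e-12 * alpha) {  # degenerate repeated root; nudge
    beta <- beta * (1 - 1e-9)
  }
  ca <- (alpha - k21) / (alpha - beta) / vc
  cb <- (k21 - beta) / (alpha - beta) / vc
  r0 <- famt / dur
  res <- numeric(length(t))
  during <- t > 0 & t <= dur
  after <- t > dur
  if (any(during)) {
    td <- t[during]
    res[during] <- r0 * (ca / alpha * (1 - exp(-alpha * td)) +
                         cb / beta * (1 - exp(-beta * td)))
  }
  if (any(after)) {
    ta <- t[after]
    res[after] <- r0 * (ca / alpha * (exp(-alpha * (ta - dur)) - exp(-alpha * ta)) +
                        cb / beta * (exp(-beta * (ta - dur)) - exp(-beta * ta)))
  }
  res
}

# the two disposition eigenvalues (alpha, beta), exported for diagnostics
#' Disposition eigenvalues of the two-compartment system
#'
#' @param params A [ddi_params()].
#' @return Named numeric: `alpha` (fast) and `beta` (slow, the terminal
#'   rate constant) in 1/h.
#' @export
disposition_eigenvalues <- function(params) {
  k10 <- params$cl_f_base / params$vc_f
  k12 <- params$q_f / params$vc_f
  k21 <- params$q_f / params$vp_f
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  c(alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

#' Simulate plasma concentrations under statin and ritonavir dosing
#'
#' Each statin dose enters the central compartment at a zero-order rate for
#' duration `D(t_d)`, carrying bioavailability `F(t_d)`, both frozen at the
#' gut enzyme state at that dose's time (see the model description above);
#' doses superpose linearly.  Elimination is constant unless
#' `use_cl_modulation` couples it to the liver enzyme state at the dose
#' time through `theta_cl`.
#'
#' @param params A [ddi_params()].
#' @param statin_events [dose_events()] for the statin (amounts in ng).
#' @param ritonavir_events [dose_events()] for ritonavir (may be empty or
#'   `NULL`).
#' @param times Observation times, h.
#' @return Numeric vector of central-compartment concentrations in ng/mL.
#' @export
simulate_concentrations <- function(params, statin_events, ritonavir_events,
                                    times) {
  stopifnot(inherits(params, "ddi_params"))
  rt <- if (is.null(ritonavir_events)) numeric(0)
        else if (is.numeric(ritonavir_events)) ritonavir_events
        else ritonavir_events$time
  if (is.null(statin_events) || nrow(statin_events) == 0) {
    return(rep(0, length(times)))
  }
  st <- statin_events$time
  e_dose <- .enzyme_at(params, rt, st,
                       origin = min(c(st, rt, times)))
  .simulate_with_e(params, statin_events, e_dose, times)
}

# superpose the closed-form dose responses given precomputed gut enzyme
# states at the statin dose times (shared by the fitting hot path)
.simulate_with_e <- function(params, statin_events, e_dose, times) {
  st <- statin_events$time
  conc <- rep(0, length(times))
  for (i in seq_along(st)) {
    eg <- e_dose[i]
    f <- params$f_rel_base / (params$theta_f + (1 - params$theta_f) * eg)
    dur <- params$d0 * (1 + (params$theta_d - 1) * (1 - eg))
    cl <- params$cl_f_base
    if (params$use_cl_modulation) {
      cl <- cl * (params$theta_cl + (1 - params$theta_cl) * eg)
    }
    conc <- conc + .conc2cpt_zo(times - st[i],
                                statin_events$amount[i] * f, dur,
                                cl, params$vc_f, params$q_f, params$vp_f)
  }
  conc / 1000  # ng/L -> ng/mL
}

#' Standard trial sampling schedule
#'
#' Times (h after the statin dose) at which plasma was sampled in the
#' paired single-dose design: predose, then 15/30/45 min and 1-49 h.
#'
#' @return Numeric vector of 17 times.
#' @export
trial_sampling_times <- function() {
  c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 24, 25, 48, 49)
}

#' Ritonavir BID schedule relative to the day-5 statin dose
#'
#' 100 mg twice daily on days 1-5, expressed on the clock where the statin
#' dose (morning of day 5) is t = 0: doses at -96, -84, ..., 0, 12 h.
#'
#' @param amount_ng Per-dose ritonavir amount in ng (default 100 mg).
#' @return A [dose_events()] data frame.
#' @export
ritonavir_bid_day5 <- function(amount_ng = 1e8) {
  dose_events(seq(-96, 12, by = 12), "ritonavir", amount_ng)
}

#' Day-5 vs baseline exposure ratio predicted by the model
#'
#' Simulates the paired trial design (single statin dose alone; single
#' statin dose on day 5 of ritonavir BID days 1-5), runs noncompartmental
#' analysis on both simulated profiles at the given sampling schedule, and
#' returns the day-5/baseline AUCinf and Cmax ratios.
#'
#' @param params A [ddi_params()].
#' @param trial_schedule Sampling times after each statin dose (default
#'   [trial_sampling_times()]).
#' @param dose_ng Statin dose (default 10 mg).
#' @return List with `auc_ratio`, `cmax_ratio` and the two `nca_result`s.
#' @export
day5_exposure_ratio <- function(params, trial_schedule = trial_sampling_times(),
                                dose_ng = 1e7) {
  stopifnot(inherits(params, "ddi_params"))
  spec <- analyte_spec("statin_model", molar_mass = 558.64, lloq = 1e-12)
  statin <- dose_events(0, "statin", dose_ng)
  base_conc <- simulate_concentrations(params, statin, NULL, trial_schedule)
  day5_conc <- simulate_concentrations(params, statin, ritonavir_bid_day5(),
                                       trial_schedule)
  mk <- function(conc, occ) {
    concentration_profile("model", spec, occ, dose_ng,
                          time = trial_schedule, conc = conc)
  }
  base_nca <- nca_summary(mk(base_conc, "baseline"))
  day5_nca <- nca_summary(mk(day5_conc, "ritonavir_day5"))
  list(auc_ratio = day5_nca$auc_inf / base_nca$auc_inf,
       cmax_ratio = day5_nca$cmax / base_nca$cmax,
       baseline = base_nca, day5 = day5_nca)
}
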
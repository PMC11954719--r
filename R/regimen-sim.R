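# Multi-day dosing-scheme simulation.  Conventions: the statin is dosed
# once daily at hour 0 of each day; ritonavir at hours 0 and 12 of days
# 1-5; a 10-day daily run-in at the original dose establishes steady state
# (~26 terminal half-lives of ~9 h) before the scenario starts on day 1.

.named_scenarios <- c("a_no_adjustment", "b_interruption",
                      "c_every_second_day", "d_half_days1_10",
                      "e_quarter_days1_7", "f_mixed")

#' Build a named or custom dosing scenario
#'
#' The named scenarios are the six alternative statin schedules during a
#' 5-day ritonavir course:
#' * `a_no_adjustment` — full dose every day;
#' * `b_interruption` — no statin on days 1-7, full dose resuming day 8
#'   (2 days after the end of ritonavir);
#' * `c_every_second_day` — full dose every second day (days 1, 3, 5, 7),
#'   daily from day 8;
#' * `d_half_days1_10` — half dose on days 1-10, full dose after;
#' * `e_quarter_days1_7` — quarter dose on days 1-7, full dose after;
#' * `f_mixed` — full day 1, half day 2, quarter days 3-6, half days 7-9,
#'   full from day 10.
#'
#' @param name One of the scenario names above or `"custom"`.
#' @param original_dose_mg The patient's maintenance dose, mg.
#' @param horizon_days Number of scenario days to expand (default 21).
#' @param ritonavir_days Days with ritonavir BID (default 1:5).
#' @param run_in_days Steady-state lead-in at full dose (default 10 days,
#'   about 26 terminal half-lives, so residual accumulation is below 1e-6).
#' @param fractions For `"custom"`: numeric vector of daily dose fractions
#'   (recycled/padded with 1 up to the horizon).
#' @return Object of class `dose_scenario` with the day-by-day dose list.
#' @export
build_scenario <- function(name, original_dose_mg, horizon_days = 21,
                           ritonavir_days = 1:5, run_in_days = 10,
                           fractions = NULL) {
  if (!name %in% c(.named_scenarios, "custom")) {
    stop("lookup error: unknown scenario '", name, "'", call. = FALSE)
  }
  if (original_dose_mg <= 0) stop("original_dose_mg must be positive",
                                  call. = FALSE)
  fr <- rep(1, horizon_days)
  if (name == "b_interruption") fr[1:7] <- 0
  if (name == "c_every_second_day") fr[c(2, 4, 6)] <- 0
  if (name == "d_half_days1_10") fr[1:10] <- 0.5
  if (name == "e_quarter_days1_7") fr[1:7] <- 0.25
  if (name == "f_mixed") fr[1:9] <- c(1, 0.5, 0.25, 0.25, 0.25, 0.25,
                                      0.5, 0.5, 0.5)
  if (name == "custom") {
    if (is.null(fractions)) stop("custom scenario needs fractions",
                                 call. = FALSE)
    fr <- rep(1, horizon_days)
    fr[seq_along(fractions)] <- fractions
  }
  if (any(fr %% 0.25 > 1e-9 & name != "custom")) {
    stop("named scenarios only use fractions 0, 0.25, 0.5, 1", call. = FALSE)
  }
  if (any(fr > 0 & fr < 0.5 & fr %% 0.5 > 0)) {
    message("note: fractions below one half require quartering tablets")
  }
  structure(list(name = name, original_dose_mg = original_dose_mg,
                 fractions = fr, horizon_days = horizon_days,
                 ritonavir_days = ritonavir_days,
                 run_in_days = run_in_days),
            class = "dose_scenario")
}

#' @export
print.dose_scenario <- function(x, ...) {
  cat(sprintf("<dose_scenario> %s, %g mg: days 1-%d fractions %s...\n",
              x$name, x$original_dose_mg, min(10, x$horizon_days),
              paste(x$fractions[1:min(10, x$horizon_days)], collapse = " ")))
  invisible(x)
}

#' Simulate a dosing scenario and summarise daily exposure
#'
#' Runs the run-in to steady state (verified: the last two pre-scenario
#' days' AUC24 must agree within 1%), applies the scenario's statin doses
#' and ritonavir course, and returns per-day Cmax, Cmin and AUC24 together
#' with their ratios against the unperturbed steady-state day.
#'
#' @param params A [ddi_params()].
#' @param scenario A [build_scenario()] result.
#' @param grid_dt Evaluation grid step, h (default 0.1).
#' @param subtherapeutic_frac A day counts as subtherapeutic when its AUC24
#'   falls below this fraction of the baseline steady-state AUC24
#'   (default 0.5).
#' @return Object of class `exposure_metrics`: `per_day` data frame (`day`,
#'   `cmax`, `cmin`, `auc24`, `cmax_ratio`, `auc_ratio`), the baseline-day
#'   metrics, `peak_cmax_ratio`, `peak_auc_ratio`, `subtherapeutic_days`.
#' @export
run_scenario <- function(params, scenario, grid_dt = 0.1,
                         subtherapeutic_frac = 0.5) {
  stopifnot(inherits(params, "ddi_params"), inherits(scenario, "dose_scenario"))
  dose_ng <- scenario$original_dose_mg * 1e6
  run_in <- scenario$run_in_days
  # statin doses: run-in at full dose, then the scenario fractions
  st_times <- c(-(run_in:1) * 24,
                ((which(scenario$fractions > 0)) - 1) * 24)
  st_amts <- c(rep(dose_ng, run_in),
               dose_ng * scenario$fractions[scenario$fractions > 0])
  statin <- dose_events(st_times, "statin", st_amts)
  rito_times <- as.vector(vapply(scenario$ritonavir_days,
                                 function(d) (d - 1) * 24 + c(0, 12),
                                 numeric(2)))
  rito <- dose_events(sort(rito_times), "ritonavir", 1e8)

  t0 <- -2 * 24  # include the two last run-in days for the steady-state check
  grid <- seq(t0, scenario$horizon_days * 24, by = grid_dt)
  conc <- simulate_concentrations(params, statin, rito, grid)

  day_metrics <- function(day) {  # day 0 = last run-in day [-24, 0]
    lo <- (day - 1) * 24; hi <- day * 24
    sel <- grid >= lo & grid <= hi
    tt <- grid[sel]; cc <- conc[sel]
    auc <- sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
    c(cmax = max(cc), cmin = min(cc), auc24 = auc)
  }
  ss_check <- rbind(day_metrics(-1), day_metrics(0))
  drift <- abs(ss_check[2, "auc24"] / ss_check[1, "auc24"] - 1)
  if (drift > 0.01) {
    stop(sprintf("steady-state error: run-in not converged (AUC24 drift %.2f%%)",
                 100 * drift), call. = FALSE)
  }
  base <- day_metrics(0)
  days <- seq_len(scenario$horizon_days)
  m <- t(vapply(days, day_metrics, numeric(3)))
  per_day <- data.frame(day = days, cmax = m[, "cmax"], cmin = m[, "cmin"],
                        auc24 = m[, "auc24"],
                        cmax_ratio = m[, "cmax"] / base[["cmax"]],
                        auc_ratio = m[, "auc24"] / base[["auc24"]])
  structure(list(per_day = per_day,
                 baseline = as.list(base),
                 peak_cmax_ratio = max(per_day$cmax_ratio),
                 peak_auc_ratio = max(per_day$auc_ratio),
                 subtherapeutic_days = sum(per_day$auc24 <
                                             subtherapeutic_frac * base[["auc24"]]),
                 scenario = scenario$name,
                 grid_dt = grid_dt,
                 subtherapeutic_frac = subtherapeutic_frac),
            class = "exposure_metrics")
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf("<exposure_metrics> scenario %s: peak Cmax ratio %.3g, peak AUC24 ratio %.3g, %d subtherapeutic day(s)\n",
              x$scenario, x$peak_cmax_ratio, x$peak_auc_ratio,
              x$subtherapeutic_days))
  invisible(x)
}

#' Dose-adjustment recommendation during a ritonavir course
#'
#' Encodes the recommended statin adjustment for a 5-day
#' nirmatrelvir/ritonavir course: 10 mg maintenance — keep the original
#' dose; 20 mg — take half; 40 mg or more — take a quarter; the reduction
#' holds until 2 days after ritonavir ends, then the original dose resumes.
#' Arbitrary positive doses are mapped to the nearest rule (<= 10
#' unchanged, < 40 half, >= 40 quarter) with a note.
#'
#' @param maintenance_dose_mg The patient's maintenance dose, mg.
#' @param ritonavir_end_day Last ritonavir day (default 5); the original
#'   dose resumes on `ritonavir_end_day + 3` (i.e. after 2 reduced days
#'   post-course).
#' @return List with `rule` (`"unchanged"`, `"half"`, `"quarter"`),
#'   `reduced_dose_mg`, `reduced_days`, `resume_day`, `daily_dose_mg`
#'   (days 1 to resume day) and a human-readable `description`.
#' @export
recommend_dose <- function(maintenance_dose_mg, ritonavir_end_day = 5) {
  if (!is.numeric(maintenance_dose_mg) || length(maintenance_dose_mg) != 1L ||
      !is.finite(maintenance_dose_mg) || maintenance_dose_mg <= 0) {
    stop("domain error: maintenance dose must be a positive number",
         call. = FALSE)
  }
  standard <- maintenance_dose_mg %in% c(10, 20, 40, 80)
  rule <- if (maintenance_dose_mg <= 10) "unchanged"
          else if (maintenance_dose_mg < 40) "half"
          else "quarter"
  if (!standard) {
    message(sprintf("nearest rule applied for non-standard dose %g mg: %s",
                    maintenance_dose_mg, rule))
  }
  frac <- switch(rule, unchanged = 1, half = 0.5, quarter = 0.25)
  resume_day <- ritonavir_end_day + 3
  reduced_days <- if (rule == "unchanged") integer(0)
                  else seq_len(resume_day - 1)
  daily <- rep(maintenance_dose_mg, resume_day)
  daily[reduced_days] <- maintenance_dose_mg * frac
  description <- if (rule == "unchanged") {
    sprintf("Maintain the original %g mg dose throughout the ritonavir course.",
            maintenance_dose_mg)
  } else {
    sprintf(paste0("Take %s of the original dose (%g mg) from day 1 until ",
                   "2 days after the end of ritonavir (through day %d); ",
                   "resume %g mg from day %d."),
            rule, maintenance_dose_mg * frac, resume_day - 1,
            maintenance_dose_mg, resume_day)
  }
  list(maintenance_dose_mg = maintenance_dose_mg, rule = rule,
       reduced_dose_mg = maintenance_dose_mg * frac,
       reduced_days = reduced_days, resume_day = resume_day,
       daily_dose_mg = daily, description = description)
}
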
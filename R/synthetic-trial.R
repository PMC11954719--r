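# Seeded virtual-trial generator.  Emulates the paired single-dose design:
# 8 subjects, 10 mg statin on two occasions (baseline; day 5 of ritonavir
# 100 mg BID), the 17-point sampling schedule, log-normal inter-individual
# variability on bioavailability/clearance/central volume, proportional
# residual error, and LLOQ censoring.

# evaluate expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the virtual trial generator
#'
#' @param n_subjects Number of subjects (default 8, the trial's arm size).
#' @param sampling_times Sampling schedule in hours after the statin dose
#'   (default [trial_sampling_times()]).
#' @param statin `"atorvastatin_mechanistic"` (the turnover model) or
#'   `"rosuvastatin_empirical"` (one-compartment first-order absorption in
#'   which ritonavir accelerates absorption and contracts the apparent
#'   volume, elevating Cmax and advancing Tmax while leaving CL/F — hence
#'   AUC — unchanged).
#' @param dose_mg Statin dose in mg (default 10).
#' @param params A [ddi_params()] for the mechanistic model.
#' @param rosu Parameters of the empirical rosuvastatin model: `cl_f` (L/h),
#'   `v_f` (L), `ka` (1/h), and the ritonavir-occasion multipliers
#'   `rito_ka_mult`, `rito_v_mult`.
#' @param omega Named log-normal IIV SDs on `f_rel`, `cl_f`, `vc_f`.
#' @param sigma_prop Proportional residual error SD (default 0.15).
#' @param lloq_censor Censor below the analyte LLOQ and flag BLQ
#'   (default `TRUE`).
#' @param outlier Optional outlier spec, a list with `subject_index` and
#'   `factor`, passed to [inject_outlier()] after generation.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   dataset.
#' @return Object of class `trial_generator_config`.
#' @export
trial_config <- function(n_subjects = 8,
                         sampling_times = trial_sampling_times(),
                         statin = c("atorvastatin_mechanistic",
                                    "rosuvastatin_empirical"),
                         dose_mg = 10,
                         params = ddi_params(),
                         rosu = list(cl_f = 257, v_f = 4042, ka = 0.65,
                                     rito_ka_mult = 9.2, rito_v_mult = 0.62),
                         omega = c(f_rel = 0.4, cl_f = 0.4, vc_f = 0.4),
                         sigma_prop = 0.15, lloq_censor = TRUE,
                         outlier = NULL, seed = 1L) {
  statin <- match.arg(statin)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (is.unsorted(sampling_times, strictly = TRUE)) {
    stop("sampling_times must be strictly increasing", call. = FALSE)
  }
  if (any(omega < 0)) stop("domain error: omega must be >= 0", call. = FALSE)
  if (sigma_prop < 0) stop("sigma_prop must be >= 0", call. = FALSE)
  stopifnot(inherits(params, "ddi_params"))
  structure(list(n_subjects = as.integer(n_subjects),
                 sampling_times = sampling_times, statin = statin,
                 dose_mg = dose_mg, params = params, rosu = rosu,
                 omega = omega, sigma_prop = sigma_prop,
                 lloq_censor = lloq_censor, outlier = outlier,
                 seed = as.integer(seed)),
            class = "trial_generator_config")
}

#' Draw individual model parameters for one subject
#'
#' Multiplies the population relative bioavailability, apparent clearance
#' and apparent central volume by independent log-normal deviates
#' `exp(omega * z)`.  Deterministic given `(seed, subject_index)` and
#' independent of any other randomness.
#'
#' @param config A [trial_config()].
#' @param subject_index Subject number in `1:n_subjects`.
#' @return A [ddi_params()] for that subject.
#' @export
sample_individual_params <- function(config, subject_index) {
  stopifnot(inherits(config, "trial_generator_config"))
  if (subject_index < 1 || subject_index > config$n_subjects) {
    stop("subject_index out of range", call. = FALSE)
  }
  z <- .with_seed(config$seed, {
    matrix(stats::rnorm(config$n_subjects * 3), ncol = 3)
  })[subject_index, ]
  p <- config$params
  om <- config$omega
  p$f_rel_base <- p$f_rel_base * exp(om[["f_rel"]] * z[1])
  p$cl_f_base <- p$cl_f_base * exp(om[["cl_f"]] * z[2])
  p$vc_f <- p$vc_f * exp(om[["vc_f"]] * z[3])
  validate_ddi_params(p)
  p
}

# deterministic per-subject noiseless concentration curves for both occasions
.predict_subject <- function(config, params_i, times) {
  dose_ng <- config$dose_mg * 1e6
  if (config$statin == "atorvastatin_mechanistic") {
    statin <- dose_events(0, "statin", dose_ng)
    list(
      baseline = simulate_concentrations(params_i, statin, NULL, times),
      ritonavir_day5 = simulate_concentrations(params_i, statin,
                                               ritonavir_bid_day5(), times)
    )
  } else {
    r <- config$rosu
    # carry the IIV drawn on the mechanistic slots over to the empirical model
    scale <- list(cl = params_i$cl_f_base / config$params$cl_f_base,
                  v = params_i$vc_f / config$params$vc_f,
                  f = params_i$f_rel_base / config$params$f_rel_base)
    onec <- function(t, cl, v, ka, f) {
      ke <- cl / v
      out <- rep(0, length(t))
      on <- t > 0
      out[on] <- f * dose_ng * ka / (v * (ka - ke)) *
        (exp(-ke * t[on]) - exp(-ka * t[on])) / 1000
      out
    }
    cl <- r$cl_f * scale$cl; v <- r$v_f * scale$v
    list(
      baseline = onec(times, cl, v, r$ka, scale$f),
      ritonavir_day5 = onec(times, cl, v * r$rito_v_mult,
                            r$ka * r$rito_ka_mult, scale$f)
    )
  }
}

#' Generate a virtual paired trial dataset
#'
#' For each subject, simulates the baseline occasion (single statin dose)
#' and the ritonavir occasion (statin on day 5 of ritonavir BID days 1-5),
#' applies proportional residual noise (`C_obs = C * exp(sigma * z)`, the
#' log-normal form), censors at the analyte LLOQ when requested, and
#' records full generator provenance in the dataset metadata.
#'
#' @param config A [trial_config()].
#' @return A [trial_dataset()].
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_generator_config"))
  analyte <- if (config$statin == "atorvastatin_mechanistic") {
    default_analyte_table()[["atorvastatin"]]
  } else {
    default_analyte_table()[["rosuvastatin"]]
  }
  times <- config$sampling_times
  dose_ng <- config$dose_mg * 1e6
  profiles <- .with_seed(config$seed + 500009L, {
    out <- list()
    for (i in seq_len(config$n_subjects)) {
      params_i <- sample_individual_params(config, i)
      pred <- .predict_subject(config, params_i, times)
      for (occ in c("baseline", "ritonavir_day5")) {
        conc <- pred[[occ]]
        if (config$sigma_prop > 0) {
          conc <- conc * exp(config$sigma_prop * stats::rnorm(length(conc)))
        }
        blq <- rep(FALSE, length(conc))
        if (config$lloq_censor) {
          blq <- conc < analyte$lloq
          conc[blq] <- NA_real_
        }
        out[[length(out) + 1L]] <- concentration_profile(
          sprintf("S%02d", i), analyte, occ, dose_ng,
          time = times, conc = conc, blq = blq)
      }
    }
    out
  })
  ds <- trial_dataset(profiles, metadata = list(
    generator = "statinddi::generate_trial",
    statin = config$statin, n_subjects = config$n_subjects,
    dose_mg = config$dose_mg, sigma_prop = config$sigma_prop,
    omega = as.list(config$omega), lloq_censor = config$lloq_censor,
    seed = config$seed))
  if (!is.null(config$outlier)) {
    ds <- inject_outlier(ds,
                         subject = sprintf("S%02d", config$outlier$subject_index),
                         factor = config$outlier$factor)
  }
  ds
}

#' Inject an exposure-direction outlier into a dataset
#'
#' Rescales one subject's ritonavir-occasion concentrations, emulating the
#' participant whose exposure paradoxically fell during ritonavir (a
#' homozygous carrier of poor-function OATP1B1 alleles).  With
#' `mode = "target_ratio"` (default) the occasion is rescaled so that the
#' subject's day-5/baseline AUC ratio equals `factor` (default 0.45); with
#' `mode = "scale"` the concentrations are simply multiplied by `factor`.
#'
#' @param dataset A [trial_dataset()].
#' @param subject Subject id to modify.
#' @param factor Target AUC ratio or plain multiplier.
#' @param mode `"target_ratio"` or `"scale"`.
#' @return The modified [trial_dataset()].
#' @export
inject_outlier <- function(dataset, subject, factor = 0.45,
                           mode = c("target_ratio", "scale")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  mode <- match.arg(mode)
  ids <- vapply(dataset$profiles, `[[`, character(1), "subject_id")
  occ <- vapply(dataset$profiles, `[[`, character(1), "occasion")
  if (!subject %in% ids) {
    stop("lookup error: unknown subject ", subject, call. = FALSE)
  }
  i_day5 <- which(ids == subject & occ == "ritonavir_day5")
  if (!length(i_day5)) {
    stop("lookup error: no ritonavir occasion for subject ", subject,
         call. = FALSE)
  }
  scale <- factor
  if (mode == "target_ratio") {
    i_base <- which(ids == subject & occ == "baseline")
    if (!length(i_base)) {
      stop("lookup error: no baseline occasion for subject ", subject,
           call. = FALSE)
    }
    auc_of <- function(p) {
      res <- nca_summary(apply_lloq(p))
      if (is.finite(res$auc_inf)) res$auc_inf else res$auc_last
    }
    ratio_now <- auc_of(dataset$profiles[[i_day5]]) /
      auc_of(dataset$profiles[[i_base]])
    scale <- factor / ratio_now
  }
  for (k in i_day5) {
    p <- dataset$profiles[[k]]
    conc <- p$records$conc * scale
    blq <- p$records$blq
    if (isTRUE(dataset$metadata$lloq_censor)) {
      blq <- blq | (!is.na(conc) & conc < p$analyte$lloq)
      conc[blq] <- NA_real_
    }
    dataset$profiles[[k]] <- concentration_profile(
      p$subject_id, p$analyte, p$occasion, p$dose_ng,
      time = p$records$time, conc = conc, blq = blq, unit = p$unit)
  }
  dataset$metadata$outlier <- list(subject = subject, factor = factor,
                                   mode = mode)
  dataset
}
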
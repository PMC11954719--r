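test_that("generation is fully deterministic given config and seed", {
  cfg <- trial_config(n_subjects = 4, seed = 17)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(generate_trial(cfg), f1)
  write_dataset(generate_trial(cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # a different seed changes the data
  f3 <- tempfile(fileext = ".csv")
  write_dataset(generate_trial(trial_config(n_subjects = 4, seed = 18)), f3)
  expect_false(identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f3))))
})

test_that("individual parameter draws honour omega and the seed contract", {
  cfg0 <- trial_config(omega = c(f_rel = 0, cl_f = 0, vc_f = 0), seed = 2)
  p1 <- sample_individual_params(cfg0, 1)
  p5 <- sample_individual_params(cfg0, 5)
  expect_equal(p1$cl_f_base, cfg0$params$cl_f_base)
  expect_equal(p1$cl_f_base, p5$cl_f_base)

  cfg <- trial_config(seed = 2)
  a <- sample_individual_params(cfg, 3)
  b <- sample_individual_params(cfg, 3)
  expect_identical(a, b)

  # law of large numbers on the log-scale SD
  cfg_big <- trial_config(n_subjects = 10000,
                          omega = c(f_rel = 0, cl_f = 0.3, vc_f = 0),
                          seed = 99)
  logcl <- vapply(1:10000, function(i) {
    log(sample_individual_params(cfg_big, i)$cl_f_base)
  }, numeric(1))
  expect_lt(abs(stats::sd(logcl) - 0.3), 0.01)
})

test_that("noise-free generation equals the deterministic model output", {
  cfg <- trial_config(n_subjects = 2,
                      omega = c(f_rel = 0, cl_f = 0, vc_f = 0),
                      sigma_prop = 0, lloq_censor = FALSE, seed = 5)
  ds <- generate_trial(cfg)
  statin <- dose_events(0, "statin", 1e7)
  tt <- cfg$sampling_times
  expected_base <- simulate_concentrations(cfg$params, statin, NULL, tt)
  expected_day5 <- simulate_concentrations(cfg$params, statin,
                                           ritonavir_bid_day5(), tt)
  for (p in ds$profiles) {
    expected <- if (p$occasion == "baseline") expected_base else expected_day5
    expect_equal(p$records$conc, expected, tolerance = 1e-12)
  }
})

test_that("LLOQ censoring flags exactly the sub-LLOQ concentrations", {
  cfg_on <- trial_config(n_subjects = 4, seed = 31, lloq_censor = TRUE)
  cfg_off <- trial_config(n_subjects = 4, seed = 31, lloq_censor = FALSE)
  ds_on <- generate_trial(cfg_on)
  ds_off <- generate_trial(cfg_off)
  lloq <- ator()$lloq
  for (i in seq_along(ds_on$profiles)) {
    raw <- ds_off$profiles[[i]]$records$conc
    cen <- ds_on$profiles[[i]]$records
    expect_equal(cen$blq, raw < lloq)
    expect_true(all(is.na(cen$conc[cen$blq])))
    expect_equal(cen$conc[!cen$blq], raw[raw >= lloq])
  }
})

test_that("NCA on noise-free baseline profiles recovers each subject's CL/F", {
  cfg <- trial_config(n_subjects = 4, sigma_prop = 0, lloq_censor = FALSE,
                      seed = 12)
  ds <- generate_trial(cfg)
  for (i in 1:4) {
    p_i <- sample_individual_params(cfg, i)
    prof <- Filter(function(p) p$subject_id == sprintf("S%02d", i) &&
                     p$occasion == "baseline", ds$profiles)[[1]]
    res <- nca_summary(prof)
    # the generator's apparent clearance folds in the subject's F_rel draw
    cl_apparent <- p_i$cl_f_base / p_i$f_rel_base * 1000 / 60
    expect_lt(abs(res$cl_f / cl_apparent - 1), 0.05)
  }
})

test_that("cohort GMR is consistent with the generator's built-in ratio", {
  built_in <- day5_exposure_ratio(ddi_params())$auc_ratio
  set.seed(1)
  gmrs <- vapply(1:25, function(s) {
    ds <- generate_trial(trial_config(seed = 2000 + s))
    gmr_table(nca_table(ds), parameters = "auc_inf")$gmr
  }, numeric(1))
  expect_lt(abs(mean(gmrs) / built_in - 1), 0.15)
})

test_that("empirical rosuvastatin cohorts leave AUC unchanged but raise Cmax", {
  covered <- 0
  n_seeds <- 200
  cmax_gmrs <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    ds <- generate_trial(trial_config(statin = "rosuvastatin_empirical",
                                      seed = 5000 + s))
    tab <- gmr_table(nca_table(ds), parameters = c("auc_inf", "cmax"))
    auc_row <- tab[tab$parameter == "auc_inf", ]
    if (auc_row$ci_low <= 1 && auc_row$ci_high >= 1) covered <- covered + 1
    cmax_gmrs[s] <- tab$gmr[tab$parameter == "cmax"]
  }
  expect_gte(covered / n_seeds, 0.85)
  # Cmax roughly doubles (the trial saw +94%)
  expect_gt(median(cmax_gmrs), 1.5)
  expect_lt(median(cmax_gmrs), 2.5)
})

test_that("outlier injection targets the requested AUC ratio", {
  cfg <- trial_config(n_subjects = 6, seed = 77)
  ds <- generate_trial(cfg)

  unchanged <- inject_outlier(ds, "S03", factor = 1.0, mode = "scale")
  for (i in seq_along(ds$profiles)) {
    expect_equal(unchanged$profiles[[i]]$records$conc,
                 ds$profiles[[i]]$records$conc)
  }

  out <- inject_outlier(ds, "S03", factor = 0.45, mode = "target_ratio")
  tab <- nca_table(out)
  s3 <- tab[tab$subject == "S03", ]
  ratio <- s3$auc_inf[s3$occasion == "ritonavir_day5"] /
    s3$auc_inf[s3$occasion == "baseline"]
  # re-censoring after the rescale perturbs the NCA slightly
  expect_equal(ratio, 0.45, tolerance = 0.1)

  # excluding the injected subject moves the cohort GMR upward
  gmr_all <- gmr_table(tab, parameters = "auc_inf")$gmr
  gmr_excl <- gmr_table(tab[tab$subject != "S03", ],
                        parameters = "auc_inf")$gmr
  expect_gt(gmr_excl, gmr_all)

  expect_error(inject_outlier(ds, "S99"), "lookup error")
})
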
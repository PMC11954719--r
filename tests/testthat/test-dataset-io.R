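test_that("CSV loading parses records, flags BLQ cells and converts doses", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("subject,analyte,occasion,time_h,conc_ng_ml,dose_mg",
               "S01,atorvastatin,baseline,0,0,10",
               "S01,atorvastatin,baseline,1,5,10",
               "S01,atorvastatin,baseline,2,3,10",
               "S01,atorvastatin,baseline,4,BLQ,10",
               "S01,atorvastatin,baseline,8,,10"), csv)
  ds <- load_dataset(csv)
  expect_length(ds$profiles, 1)
  p <- ds$profiles[[1]]
  expect_equal(nrow(p$records), 5)
  expect_equal(p$dose_ng, 1e7)
  expect_equal(p$records$conc[1:3], c(0, 5, 3))
  expect_true(all(p$records$blq[4:5]))
  expect_true(all(is.na(p$records$conc[4:5])))
})

test_that("malformed datasets are rejected with informative errors", {
  bad_col <- tempfile(fileext = ".csv")
  writeLines(c("subject,analyte,occasion,time_h,conc_ng_ml",
               "S01,atorvastatin,baseline,0,1"), bad_col)
  expect_error(load_dataset(bad_col), "missing column.*dose_mg")

  neg_time <- tempfile(fileext = ".csv")
  writeLines(c("subject,analyte,occasion,time_h,conc_ng_ml,dose_mg",
               "S01,atorvastatin,baseline,-1,1,10"), neg_time)
  expect_error(load_dataset(neg_time), "time in data row\\(s\\) 1")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("subject,analyte,occasion,time_h,conc_ng_ml,dose_mg",
               "S01,atorvastatin,baseline,1,1,10",
               "S01,atorvastatin,baseline,1,2,10"), dup)
  expect_error(load_dataset(dup), "duplicated.*row\\(s\\) 2")

  unk <- tempfile(fileext = ".csv")
  writeLines(c("subject,analyte,occasion,time_h,conc_ng_ml,dose_mg",
               "S01,notastatin,baseline,1,1,10"), unk)
  expect_error(load_dataset(unk), "unknown analyte.*notastatin")
})

test_that("write_dataset / load_dataset round-trip is the identity", {
  ds <- generate_trial(trial_config(n_subjects = 3, seed = 7))
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  ds2 <- load_dataset(f)
  expect_equal(length(ds2$profiles), length(ds$profiles))
  key <- function(p) paste(p$subject_id, p$occasion)
  p2 <- ds2$profiles[order(vapply(ds2$profiles, key, character(1)))]
  p1 <- ds$profiles[order(vapply(ds$profiles, key, character(1)))]
  for (i in seq_along(p1)) {
    expect_equal(p2[[i]]$subject_id, p1[[i]]$subject_id)
    expect_equal(p2[[i]]$occasion, p1[[i]]$occasion)
    expect_equal(p2[[i]]$dose_ng, p1[[i]]$dose_ng)
    expect_equal(p2[[i]]$records$time, p1[[i]]$records$time)
    expect_equal(p2[[i]]$records$conc, p1[[i]]$records$conc, tolerance = 1e-12)
    expect_equal(p2[[i]]$records$blq, p1[[i]]$records$blq)
  }
})

test_that("BLQ rules transform records as defined", {
  p <- make_profile(c(0, 1, 2), c(NA, 5, NA), blq = c(TRUE, FALSE, TRUE))
  z <- apply_lloq(p, "zero_before_tmax_drop_after")
  expect_equal(z$records$time, c(0, 1))
  expect_equal(z$records$conc, c(0, 5))
  d <- apply_lloq(p, "drop_all")
  expect_equal(d$records$time, 1)
  expect_equal(d$records$conc, 5)
  h <- apply_lloq(p, "half_lloq")
  expect_equal(h$records$conc, c(0.05, 5, 0.05))

  all_blq <- make_profile(c(0, 1), c(NA, NA), blq = c(TRUE, TRUE))
  expect_error(apply_lloq(all_blq), "empty-profile")
})

test_that("BLQ handling never adds records nor changes quantifiable values", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    conc <- round(stats::rlnorm(n, 0, 1), 3)
    blq <- conc < stats::quantile(conc, 0.3)
    conc[blq] <- NA
    if (all(blq)) next
    p <- make_profile(seq_len(n), conc, blq = blq)
    for (rule in c("zero_before_tmax_drop_after", "drop_all", "half_lloq")) {
      out <- apply_lloq(p, rule)
      expect_lte(nrow(out$records), nrow(p$records))
      common <- intersect(p$records$time[!p$records$blq], out$records$time)
      expect_equal(out$records$conc[match(common, out$records$time)],
                   p$records$conc[match(common, p$records$time)])
    }
  }
})

test_that("molar conversion follows conc * 1000 / M and is linear", {
  spec <- analyte_spec("x", molar_mass = 558.64, lloq = 0.1)
  p <- make_profile(c(1, 2), c(558.64, 0), analyte = spec)
  m <- to_molar(p)
  expect_equal(m$records$conc, c(1000, 0))
  expect_equal(m$unit, "nmol/L")

  # round trip and linearity
  set.seed(1)
  conc <- stats::rlnorm(5)
  p1 <- make_profile(1:5, conc, analyte = spec)
  back <- to_mass(to_molar(p1))
  expect_equal(back$records$conc, conc, tolerance = 1e-12)
  p2 <- make_profile(1:5, 3 * conc, analyte = spec)
  expect_equal(to_molar(p2)$records$conc, 3 * to_molar(p1)$records$conc,
               tolerance = 1e-12)
})
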
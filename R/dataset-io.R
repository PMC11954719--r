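#' Construct a concentration-time profile
#'
#' One subject x analyte x occasion plasma concentration time series.
#' Times are hours after the statin dose; concentrations are ng/mL (or
#' nmol/L after [to_molar()]).  Below-limit-of-quantification (BLQ)
#' observations carry `blq = TRUE` and a missing concentration.
#'
#' @param subject_id Subject identifier (string).
#' @param analyte An [analyte_spec()].
#' @param occasion `"baseline"` or `"ritonavir_day5"` (other labels allowed
#'   but ignored by the paired statistics).
#' @param dose_ng Administered statin dose in ng (positive).
#' @param time Numeric vector of sampling times (h), strictly increasing.
#' @param conc Numeric vector of concentrations; `NA` allowed for BLQ rows.
#' @param blq Logical vector of BLQ flags (default: all `FALSE`).
#' @param unit Concentration unit tag, `"ng/mL"` or `"nmol/L"`.
#'
#' @return Object of class `concentration_profile` with a `records`
#'   data frame (`time`, `conc`, `blq`).
#' @export
concentration_profile <- function(subject_id, analyte, occasion, dose_ng,
                                  time, conc, blq = rep(FALSE, length(time)),
                                  unit = "ng/mL") {
  stopifnot(inherits(analyte, "analyte_spec"))
  subject_id <- as.character(subject_id)
  occasion <- as.character(occasion)
  if (!is.numeric(dose_ng) || length(dose_ng) != 1L || !is.finite(dose_ng) ||
      dose_ng <= 0) {
    stop("dose_ng must be a positive finite number", call. = FALSE)
  }
  if (length(time) != length(conc) || length(time) != length(blq)) {
    stop("time, conc and blq must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]; blq <- as.logical(blq)[ord]
  if (anyDuplicated(time)) {
    stop("duplicate sampling times in profile: ",
         paste(unique(time[duplicated(time)]), collapse = ", "), call. = FALSE)
  }
  bad <- !blq & (!is.finite(conc) | conc < 0)
  if (any(bad)) {
    stop("non-BLQ concentrations must be finite and non-negative (times ",
         paste(time[bad], collapse = ", "), ")", call. = FALSE)
  }
  conc[blq] <- NA_real_
  structure(
    list(subject_id = subject_id, analyte = analyte, occasion = occasion,
         dose_ng = dose_ng, unit = unit,
         records = data.frame(time = time, conc = conc, blq = blq)),
    class = "concentration_profile"
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("<concentration_profile> subject %s, %s, %s: %d records (%s), dose %.3g ng\n",
              x$subject_id, x$analyte$name, x$occasion,
              nrow(x$records), x$unit, x$dose_ng))
  invisible(x)
}

#' Construct a trial dataset
#'
#' @param profiles List of [concentration_profile()] objects; the
#'   (subject, analyte, occasion) triples must be unique.
#' @param metadata Free-form named list (generator provenance, seed, ...).
#' @return Object of class `trial_dataset`.
#' @export
trial_dataset <- function(profiles, metadata = list()) {
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, logical(1), "concentration_profile")))
  keys <- vapply(profiles, function(p) {
    paste(p$subject_id, p$analyte$name, p$occasion, sep = "|")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (subject, analyte, occasion) triples: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "), call. = FALSE)
  }
  structure(list(profiles = profiles, metadata = metadata),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d profiles, %d subjects\n",
              length(x$profiles),
              length(unique(vapply(x$profiles, `[[`, character(1), "subject_id")))))
  invisible(x)
}

#' Load a trial dataset from CSV
#'
#' Expected header: `subject,analyte,occasion,time_h,conc_ng_ml,dose_mg`.
#' A `conc_ng_ml` cell that is empty or the literal `"BLQ"` marks a
#' below-quantification observation.  Doses are converted mg -> ng.
#'
#' @param path CSV file path.
#' @param analyte_table Named list of [analyte_spec()]s used to resolve the
#'   `analyte` column (default [default_analyte_table()]).
#' @return A [trial_dataset()].
#' @export
load_dataset <- function(path, analyte_table = default_analyte_table()) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("subject", "analyte", "occasion", "time_h", "conc_ng_ml", "dose_mg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("dataset format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$dose_mg <- suppressWarnings(as.numeric(df$dose_mg))
  if (any(is.na(df$dose_mg) | df$dose_mg <= 0)) {
    stop("dataset validation error: non-positive or non-numeric dose in data row(s) ",
         paste(which(is.na(df$dose_mg) | df$dose_mg <= 0), collapse = ", "),
         call. = FALSE)
  }
  conc_raw <- trimws(as.character(df$conc_ng_ml))
  blq <- conc_raw == "" | toupper(conc_raw) == "BLQ" | is.na(df$conc_ng_ml)
  conc <- suppressWarnings(as.numeric(conc_raw))
  unparsed <- which(!blq & is.na(conc))
  if (length(unparsed)) {
    stop("dataset validation error: unparseable concentration in data row(s) ",
         paste(unparsed, collapse = ", "), call. = FALSE)
  }
  time_h <- suppressWarnings(as.numeric(df$time_h))
  if (any(is.na(time_h) | time_h < 0)) {
    stop("dataset validation error: negative or non-numeric time in data row(s) ",
         paste(which(is.na(time_h) | time_h < 0), collapse = ", "), call. = FALSE)
  }
  if (any(!blq & conc < 0)) {
    stop("dataset validation error: negative concentration in data row(s) ",
         paste(which(!blq & conc < 0), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(df$analyte), names(analyte_table))
  if (length(unknown)) {
    stop("analyte lookup error: unknown analyte(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- interaction(df$subject, df$analyte, df$occasion, drop = TRUE)
  dup <- duplicated(data.frame(key, time_h))
  if (any(dup)) {
    stop("dataset validation error: duplicated (subject, analyte, occasion, time) in data row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  profiles <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    dose_mg <- unique(df$dose_mg[idx])
    if (length(dose_mg) != 1L) {
      stop("dataset validation error: inconsistent dose within profile ",
           as.character(key[idx[1]]), call. = FALSE)
    }
    concentration_profile(
      subject_id = df$subject[idx[1]],
      analyte = analyte_table[[df$analyte[idx[1]]]],
      occasion = df$occasion[idx[1]],
      dose_ng = dose_mg * 1e6,
      time = time_h[idx], conc = conc[idx], blq = blq[idx]
    )
  })
  trial_dataset(unname(profiles), metadata = list(source = path))
}

#' Write a trial dataset to CSV
#'
#' Inverse of [load_dataset()]: emits the same dialect, with BLQ records
#' written as the literal `"BLQ"`.
#'
#' @param dataset A [trial_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  rows <- lapply(dataset$profiles, function(p) {
    data.frame(
      subject = p$subject_id,
      analyte = p$analyte$name,
      occasion = p$occasion,
      time_h = p$records$time,
      conc_ng_ml = ifelse(p$records$blq, "BLQ",
                          format(p$records$conc, digits = 15, trim = TRUE,
                                 scientific = FALSE)),
      dose_mg = p$dose_ng / 1e6,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a BLQ handling rule to a profile
#'
#' @param profile A [concentration_profile()].
#' @param rule One of:
#'   * `"zero_before_tmax_drop_after"` (default): BLQ before the first
#'     quantifiable observation becomes concentration 0; BLQ at or after it
#'     is excluded — the common NCA convention.
#'   * `"drop_all"`: every BLQ record is excluded.
#'   * `"half_lloq"`: every BLQ record is set to LLOQ/2.
#' @return A new `concentration_profile` with BLQ records resolved.
#' @export
apply_lloq <- function(profile,
                       rule = c("zero_before_tmax_drop_after", "drop_all",
                                "half_lloq")) {
  stopifnot(inherits(profile, "concentration_profile"))
  rule <- match.arg(rule)
  rec <- profile$records
  if (all(rec$blq)) {
    stop("empty-profile error: all records are BLQ for subject ",
         profile$subject_id, call. = FALSE)
  }
  keep <- rep(TRUE, nrow(rec))
  conc <- rec$conc
  if (rule == "zero_before_tmax_drop_after") {
    first_q <- which(!rec$blq)[1]
    pre <- rec$blq & seq_len(nrow(rec)) < first_q
    conc[pre] <- 0
    keep <- !rec$blq | pre
  } else if (rule == "drop_all") {
    keep <- !rec$blq
  } else {
    conc[rec$blq] <- profile$analyte$lloq / 2
  }
  concentration_profile(profile$subject_id, profile$analyte, profile$occasion,
                        profile$dose_ng,
                        time = rec$time[keep], conc = conc[keep],
                        blq = rep(FALSE, sum(keep)), unit = profile$unit)
}

#' Convert a profile between mass and molar concentration units
#'
#' `to_molar()` maps ng/mL -> nmol/L via `conc * 1000 / molar_mass`;
#' `to_mass()` inverts it.
#'
#' @param profile A [concentration_profile()].
#' @return A new profile with converted concentrations and updated unit tag.
#' @export
to_molar <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (identical(profile$unit, "nmol/L")) return(profile)
  mm <- profile$analyte$molar_mass
  if (is.null(mm) || !is.finite(mm) || mm <= 0) {
    stop("configuration error: molar_mass unset for ", profile$analyte$name,
         call. = FALSE)
  }
  out <- profile
  out$records$conc <- profile$records$conc * 1000 / mm
  out$unit <- "nmol/L"
  out
}

#' @rdname to_molar
#' @export
to_mass <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (identical(profile$unit, "ng/mL")) return(profile)
  mm <- profile$analyte$molar_mass
  out <- profile
  out$records$conc <- profile$records$conc * mm / 1000
  out$unit <- "ng/mL"
  out
}
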
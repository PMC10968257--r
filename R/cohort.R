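#' @importFrom stats rnorm runif rbinom coef lm pnorm dnorm sd quantile median
#' @importFrom utils read.csv write.csv head tail
NULL

#' Cohort column names
#'
#' One row per paired same-day visual field / OCT visit. Column order is part
#' of the file contract: readers validate it, writers emit exactly this order.
#'
#' @return Character vector of the 322 column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "eye_id", "test_date", "age",
    "fp_rate", "fn_rate", "fixation_loss_rate", "signal_strength", "md",
    dls_cols(), rnfl_cols())
}

#' @rdname cohort_columns
#' @export
dls_cols <- function() sprintf("dls_%02d", 0:51)

#' @rdname cohort_columns
#' @export
rnfl_cols <- function() sprintf("rnfl_%03d", 0:255)

# ---- domain constructors -------------------------------------------------

#' Construct and validate a single visual-field test
#'
#' @param test_date Decimal years.
#' @param dls 52 differential light sensitivities (dB), grid order of
#'   [vf_grid_24_2()]. Values must be finite and within the storage range
#'   \[-5, 50\] dB.
#' @param md Mean deviation (dB).
#' @param fp_rate,fn_rate,fixation_loss_rate Reliability indices, fractions in
#'   \[0, 1\].
#' @return An object of class `vf_test`.
#' @export
vf_test <- function(test_date, dls, md, fp_rate, fn_rate, fixation_loss_rate) {
  stopifnot(length(dls) == 52, all(is.finite(dls)),
            all(dls >= -5), all(dls <= 50))
  for (r in c(fp_rate, fn_rate, fixation_loss_rate)) {
    stopifnot(is.finite(r), r >= 0, r <= 1)
  }
  structure(list(test_date = test_date, dls = as.numeric(dls), md = md,
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 fixation_loss_rate = fixation_loss_rate),
            class = "vf_test")
}

#' Construct and validate a single OCT test
#'
#' @param test_date Decimal years.
#' @param rnfl_profile 256 RNFL thickness samples (um); sample i sits at
#'   angle 360*i/256 degrees around the optic nerve head, angle 0 at the
#'   temporal reference, counter-clockwise for right eyes.
#' @param signal_strength Integer 0-10.
#' @return An object of class `oct_test` with mean thickness in `$mrnflt`.
#' @export
oct_test <- function(test_date, rnfl_profile, signal_strength) {
  stopifnot(length(rnfl_profile) == 256, all(is.finite(rnfl_profile)),
            all(rnfl_profile >= 0), all(rnfl_profile <= 300),
            signal_strength >= 0, signal_strength <= 10)
  structure(list(test_date = test_date,
                 rnfl_profile = as.numeric(rnfl_profile),
                 signal_strength = as.integer(signal_strength),
                 mrnflt = mean(rnfl_profile)),
            class = "oct_test")
}

#' Pair a same-day VF and OCT test for one eye
#'
#' @param patient_id,eye_id Identifiers.
#' @param age Age at testing (years, > 0).
#' @param vf A [vf_test()].
#' @param oct An [oct_test()].
#' @return An object of class `paired_visit`.
#' @export
paired_visit <- function(patient_id, eye_id, age, vf, oct) {
  stopifnot(inherits(vf, "vf_test"), inherits(oct, "oct_test"),
            isTRUE(all.equal(vf$test_date, oct$test_date)), age > 0)
  structure(list(patient_id = patient_id, eye_id = eye_id, age = age,
                 vf = vf, oct = oct),
            class = "paired_visit")
}

#' Time-ordered series of paired visits for one eye
#'
#' @param visits List of [paired_visit()] objects, strictly increasing in
#'   test date and sharing one `eye_id`.
#' @return An object of class `eye_series`.
#' @export
eye_series <- function(visits) {
  stopifnot(length(visits) >= 1,
            all(vapply(visits, inherits, logical(1), "paired_visit")))
  dates <- vapply(visits, function(v) v$vf$test_date, numeric(1))
  stopifnot(all(diff(dates) > 0))
  ids <- vapply(visits, function(v) as.character(v$eye_id), character(1))
  stopifnot(length(unique(ids)) == 1)
  structure(list(eye_id = visits[[1]]$eye_id,
                 patient_id = visits[[1]]$patient_id,
                 visits = visits),
            class = "eye_series")
}

#' Flatten paired-visit objects into a cohort data frame
#'
#' @param series A list of [eye_series()] objects.
#' @return A data.frame in the schema of [cohort_columns()].
#' @export
series_to_cohort <- function(series) {
  rows <- lapply(series, function(s) {
    do.call(rbind, lapply(s$visits, function(v) {
      row <- data.frame(patient_id = v$patient_id, eye_id = v$eye_id,
                        test_date = v$vf$test_date, age = v$age,
                        fp_rate = v$vf$fp_rate, fn_rate = v$vf$fn_rate,
                        fixation_loss_rate = v$vf$fixation_loss_rate,
                        signal_strength = v$oct$signal_strength,
                        md = v$vf$md, stringsAsFactors = FALSE)
      row[dls_cols()] <- as.list(v$vf$dls)
      row[rnfl_cols()] <- as.list(v$oct$rnfl_profile)
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, cohort_columns()]
}

#' Validate a cohort data frame against the file schema
#'
#' Checks column names and order, same-day pairing (one date per row by
#' construction), sorted unique visit dates within each eye, and basic value
#' ranges. Reliability indices may be `NA` (flagged later by the filters as
#' incomplete metadata); sensitivities and thicknesses must be finite or `NA`
#' (a missing RNFL sample marks the visit for exclusion, not an error).
#'
#' @param cohort A data.frame.
#' @return The cohort, invisibly, or an error.
#' @export
validate_cohort <- function(cohort) {
  if (!identical(names(cohort), cohort_columns())) {
    stop("cohort columns do not match the schema (names/order)")
  }
  stopifnot(all(is.finite(cohort$test_date)), all(cohort$age > 0, na.rm = TRUE))
  for (e in unique(cohort$eye_id)) {
    d <- cohort$test_date[cohort$eye_id == e]
    if (any(diff(sort(d)) <= 0)) {
      stop("duplicate or non-increasing test dates within eye ", e)
    }
  }
  dls <- as.matrix(cohort[dls_cols()])
  if (any(dls < -5 | dls > 50, na.rm = TRUE)) stop("dls outside [-5, 50] dB")
  rn <- as.matrix(cohort[rnfl_cols()])
  if (any(rn < 0 | rn > 300, na.rm = TRUE)) stop("rnfl outside [0, 300] um")
  invisible(cohort)
}

#' Mean RNFL thickness per cohort row
#'
#' @param cohort Cohort data.frame.
#' @return Numeric vector of mean profile thickness (um), NA where a profile
#'   sample is missing.
#' @export
cohort_mrnflt <- function(cohort) {
  rowMeans(as.matrix(cohort[rnfl_cols()]))
}

#' Mean deviation from pointwise sensitivities
#'
#' Defined here as the unweighted mean of pointwise total deviations
#' (measured minus age-corrected normal). Device MD weights locations by
#' normative variance, which requires a proprietary database; the unweighted
#' mean preserves the dB/year semantics of MD trend analysis.
#'
#' @param dls 52 sensitivities (dB).
#' @param normative 52 age-corrected normal values (dB), e.g.
#'   [normative_dls()].
#' @return Mean deviation (dB).
#' @export
#' @examples
#' compute_md(rep(28, 52), rep(30, 52))  # -2
compute_md <- function(dls, normative) {
  if (length(dls) != 52 || length(normative) != 52) {
    stop("compute_md expects two vectors of length 52")
  }
  mean(dls - normative)
}

# ---- reliability filters -------------------------------------------------

#' Apply visit- and eye-level reliability filters
#'
#' Visit-level criteria: false-positive and false-negative rates < 15%,
#' fixation losses < 33%, OCT signal strength >= 7, and a complete RNFL
#' profile (no missing samples). Visits with any missing reliability field
#' are rejected as malformed input ("incomplete-metadata"), not as
#' unreliable. After visit filtering, any eye whose first surviving visit has
#' MD worse than -20 dB is excluded entirely (floor effect in advanced
#' disease); the baseline test is taken among reliable tests only, which is
#' why the eye-level rule runs second.
#'
#' @param cohort Cohort data.frame ([cohort_columns()] schema).
#' @return A list with `cohort` (surviving rows) and `log` (data.frame with
#'   `eye_id`, `test_date`, `reason`), one log entry per removed visit.
#'   Reasons: `incomplete-metadata`, `vf-unreliable`, `oct-unreliable`,
#'   `rnfl-missing`, `baseline-md`.
#' @export
apply_reliability_filters <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  rel <- cohort[c("fp_rate", "fn_rate", "fixation_loss_rate", "signal_strength")]
  incomplete <- !stats::complete.cases(rel)
  vf_bad <- !incomplete & (cohort$fp_rate >= 0.15 | cohort$fn_rate >= 0.15 |
                             cohort$fixation_loss_rate >= 0.33)
  oct_bad <- !incomplete & !vf_bad & cohort$signal_strength < 7
  rnfl_bad <- !incomplete & !vf_bad & !oct_bad &
    !apply(is.finite(as.matrix(cohort[rnfl_cols()])), 1, all)

  reason <- rep(NA_character_, nrow(cohort))
  reason[incomplete] <- "incomplete-metadata"
  reason[vf_bad] <- "vf-unreliable"
  reason[oct_bad] <- "oct-unreliable"
  reason[rnfl_bad] <- "rnfl-missing"

  keep <- is.na(reason)
  kept <- cohort[keep, , drop = FALSE]

  # eye-level baseline-MD exclusion on the filtered series
  if (nrow(kept) > 0) {
    for (e in unique(kept$eye_id)) {
      idx <- which(kept$eye_id == e)
      first <- idx[which.min(kept$test_date[idx])]
      if (is.finite(kept$md[first]) && kept$md[first] < -20) {
        sel <- which(cohort$eye_id == e & is.na(reason))
        reason[sel] <- "baseline-md"
      }
    }
  }

  keep <- is.na(reason)
  log <- data.frame(eye_id = cohort$eye_id[!keep],
                    test_date = cohort$test_date[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  rownames(log) <- NULL
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(cohort = out, log = log)
}

# ---- file IO -------------------------------------------------------------

#' Read / write a cohort CSV with its JSON sidecar
#'
#' The sidecar stores the [normalization_spec()] and grid-enumeration
#' metadata next to the data so a cohort file is self-describing. Readers
#' accept plain or gzipped CSV and validate the column contract. Input files
#' carrying the full 54-point grid (columns `dls_00..dls_53`) have the two
#' blind-spot columns dropped on read.
#'
#' @param cohort Cohort data.frame.
#' @param path CSV path (a `.gz` suffix gzips on write).
#' @param spec A [normalization_spec()] stored in the sidecar.
#' @param sidecar Path of the JSON sidecar; default replaces the csv
#'   extension with `.json`.
#' @return `read_cohort`: a list with `cohort` and `spec`;
#'   `write_cohort`: the main path, invisibly.
#' @export
write_cohort <- function(cohort, path, spec = normalization_spec(),
                         sidecar = sidecar_path(path)) {
  validate_cohort(cohort)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.csv(cohort, con, row.names = FALSE)
  meta <- list(
    normalization = unclass(spec),
    grid = list(pattern = "24-2", n_points = 52,
                order = "row-major, superior row first, left to right",
                blind_spot_indices_54 = blind_spot_indices_54(),
                orientation = "right-eye; left eyes mirrored at read time"),
    rnfl = list(n_samples = 256,
                angle = "360*i/256 deg, 0 = temporal, counter-clockwise (right eye)")
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, sidecar = sidecar_path(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  full54 <- sprintf("dls_%02d", 0:53)
  if (all(full54 %in% names(df))) {
    drop <- sprintf("dls_%02d", blind_spot_indices_54())
    df <- df[, setdiff(names(df), drop)]
    keepers <- setdiff(full54, drop)
    names(df)[match(keepers, names(df))] <- dls_cols()
  }
  validate_cohort(df[, cohort_columns()])
  df <- df[, cohort_columns()]
  spec <- normalization_spec()
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$normalization)) {
      n <- meta$normalization
      spec <- normalization_spec(
        dls = c(n$dls[1], n$dls[2]),
        rnfl = c(n$rnfl[1], n$rnfl[2]),
        age = c(n$age[1], n$age[2]))
    }
  }
  list(cohort = df, spec = spec)
}

sidecar_path <- function(path) {
  sub("\\.csv(\\.gz)?$", ".json", path)
}
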
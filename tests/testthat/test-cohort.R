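test_that("domain constructors enforce their invariants", {
  expect_error(vf_test(2015, rep(28, 51), -2, 0.1, 0.1, 0.1))
  expect_error(vf_test(2015, c(rep(28, 51), 60), -2, 0.1, 0.1, 0.1))
  expect_error(vf_test(2015, rep(28, 52), -2, 1.2, 0.1, 0.1))
  vf <- vf_test(2015, rep(28, 52), -2, 0.1, 0.1, 0.1)
  expect_error(oct_test(2015, rep(90, 255), 9))
  oct <- oct_test(2015, rep(90, 256), 9)
  expect_equal(oct$mrnflt, 90, tolerance = 1e-9)
  # same-day pairing
  oct2 <- oct_test(2016, rep(90, 256), 9)
  expect_error(paired_visit("P1", "E1", 60, vf, oct2))
  pv <- paired_visit("P1", "E1", 60, vf, oct)
  expect_s3_class(pv, "paired_visit")
  # strictly increasing dates in a series
  vf_b <- vf_test(2015, rep(28, 52), -2, 0.1, 0.1, 0.1)
  oct_b <- oct_test(2015, rep(90, 256), 9)
  pv_b <- paired_visit("P1", "E1", 60, vf_b, oct_b)
  expect_error(eye_series(list(pv, pv_b)))
})

test_that("compute_md is the mean pointwise total deviation", {
  norm <- normative_dls(60)
  expect_equal(compute_md(norm, norm), 0)
  expect_equal(compute_md(norm - 5, norm), -5)
  dev <- c(rep(-2, 26), rep(-4, 26))
  expect_equal(compute_md(norm + dev, norm), -3)
  expect_error(compute_md(rep(28, 51), norm))
})

test_that("one violation per criterion excludes exactly that visit", {
  rows <- list(
    clean_visit_row("E1", test_date = 2015.0),
    clean_visit_row("E1", test_date = 2015.5, fp = 0.20),
    clean_visit_row("E1", test_date = 2016.0, fn = 0.20),
    clean_visit_row("E1", test_date = 2016.5, fl = 0.40),
    clean_visit_row("E1", test_date = 2017.0, ss = 5),
    clean_visit_row("E1", test_date = 2017.5,
                    rnfl = c(NA, rep(90, 255)))
  )
  res <- apply_reliability_filters(bind_rows_list(rows))
  expect_equal(nrow(res$cohort), 1)
  expect_equal(res$cohort$test_date, 2015.0)
  expect_equal(nrow(res$log), 5)
  expect_equal(sort(res$log$reason),
               sort(c("vf-unreliable", "vf-unreliable", "vf-unreliable",
                      "oct-unreliable", "rnfl-missing")))
})

test_that("boundary reliability values are excluded (strict thresholds)", {
  ok <- clean_visit_row("E1", test_date = 2015, fp = 0.149)
  at <- clean_visit_row("E1", test_date = 2016, fp = 0.15)
  res <- apply_reliability_filters(bind_rows_list(list(ok, at)))
  expect_equal(nrow(res$cohort), 1)
  expect_equal(res$log$reason, "vf-unreliable")
})

test_that("missing reliability metadata is its own reason code", {
  bad <- clean_visit_row("E1", test_date = 2015)
  bad$fp_rate <- NA_real_
  res <- apply_reliability_filters(bind_rows_list(list(
    bad, clean_visit_row("E1", test_date = 2016))))
  expect_equal(res$log$reason, "incomplete-metadata")
})

test_that("baseline-MD exclusion uses the first reliable visit", {
  # unreliable first visit at -25 dB; first reliable visit at -10 dB: kept
  rows_keep <- list(
    clean_visit_row("E1", test_date = 2015, md = -25, fp = 0.3),
    clean_visit_row("E1", test_date = 2016, md = -10),
    clean_visit_row("E1", test_date = 2017, md = -11)
  )
  res <- apply_reliability_filters(bind_rows_list(rows_keep))
  expect_equal(nrow(res$cohort), 2)
  # reliable first visit at -25 dB: whole eye excluded
  rows_drop <- list(
    clean_visit_row("E2", test_date = 2015, md = -25),
    clean_visit_row("E2", test_date = 2016, md = -10)
  )
  res2 <- apply_reliability_filters(bind_rows_list(rows_drop))
  expect_equal(nrow(res2$cohort), 0)
  expect_true(all(res2$log$reason == "baseline-md"))
})

test_that("filtering is idempotent and conserves visits", {
  sim <- simulate_cohort(sim_config(n_patients = 12, unreliable_rate = 0.3,
                                    rnfl_na_rate = 0.05, seed = 5))
  res1 <- apply_reliability_filters(sim$cohort)
  expect_equal(nrow(res1$cohort) + nrow(res1$log), nrow(sim$cohort))
  res2 <- apply_reliability_filters(res1$cohort)
  expect_equal(res2$cohort, res1$cohort)
  expect_equal(nrow(res2$log), 0)
  # a fully-compliant cohort passes unchanged
  clean <- simulate_cohort(noise_free_config(n_patients = 3, seed = 2))$cohort
  res3 <- apply_reliability_filters(clean)
  expect_equal(res3$cohort, clean, ignore_attr = TRUE)
})

test_that("cohort CSV round-trips with its sidecar", {
  sim <- simulate_cohort(noise_free_config(n_patients = 2, seed = 3))
  path <- file.path(tempdir(), "cohort_rt.csv")
  write_cohort(sim$cohort, path, spec = normalization_spec())
  expect_true(file.exists(sidecar_path <- sub("csv$", "json", path)))
  rt <- read_cohort(path)
  expect_equal(rt$cohort$md, sim$cohort$md, tolerance = 1e-12)
  expect_equal(as.matrix(rt$cohort[dls_cols()]),
               as.matrix(sim$cohort[dls_cols()]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_s3_class(rt$spec, "normalization_spec")
  unlink(c(path, sidecar_path))
})

test_that("54-point exports lose the blind-spot columns on read", {
  row <- clean_visit_row("E1")
  # rebuild a 54-column export: insert two blind-spot columns
  dls52 <- as.numeric(row[dls_cols()])
  dls54 <- append(append(dls52, 0, after = 25), 0, after = 34)
  df54 <- row[setdiff(names(row), dls_cols())]
  df54[sprintf("dls_%02d", 0:53)] <- as.list(dls54)
  # order columns as a device export would: meta, dls, rnfl
  df54 <- df54[, c("patient_id", "eye_id", "test_date", "age", "fp_rate",
                   "fn_rate", "fixation_loss_rate", "signal_strength", "md",
                   sprintf("dls_%02d", 0:53), rnfl_cols())]
  path <- file.path(tempdir(), "cohort54.csv")
  write.csv(df54, path, row.names = FALSE)
  rt <- read_cohort(path)
  expect_equal(as.numeric(rt$cohort[1, dls_cols()]), dls52)
  unlink(path)
})
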
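# shared fixtures, all generated in code

# a quiet, mild cohort: diffuse defects, no measurement noise, no artifacts,
# every visit reliable -- latent MD trajectories are exactly linear
noise_free_config <- function(n_patients = 10, seed = 1, ...) {
  base <- list(n_patients = n_patients,
               vf_noise_sd = 0, vf_global_noise_sd = 0, rnfl_noise_sd = 0,
               artifact_rate = 0, unreliable_rate = 0, rnfl_na_rate = 0,
               baseline_md_mean = -2, baseline_md_sd = 0.8,
               baseline_md_range = c(-6, 1),
               archetype_probs = c(superior_arcuate = 0, inferior_arcuate = 0,
                                   nasal_step = 0, diffuse = 1),
               seed = seed)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# one fully-compliant cohort row built by hand
clean_visit_row <- function(eye_id = "E1", patient_id = "P1",
                            test_date = 2015.0, age = 60,
                            md = -2, dls = rep(28, 52),
                            rnfl = rep(90, 256),
                            fp = 0.05, fn = 0.05, fl = 0.1, ss = 9) {
  row <- data.frame(patient_id = patient_id, eye_id = eye_id,
                    test_date = test_date, age = age,
                    fp_rate = fp, fn_rate = fn, fixation_loss_rate = fl,
                    signal_strength = ss, md = md,
                    stringsAsFactors = FALSE)
  row[dls_cols()] <- as.list(dls)
  row[rnfl_cols()] <- as.list(rnfl)
  row[, cohort_columns()]
}

# a cohort data frame from per-visit arguments
bind_rows_list <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# synthetic eye series with linear MD for progression tests: annual visits,
# given slope, constant field shape
linear_md_eye <- function(eye_id, slope, n_visits = 9, interval = 1,
                          md0 = -2, start = 2010, age0 = 60) {
  rows <- lapply(seq_len(n_visits) - 1, function(j) {
    t <- j * interval
    norm <- normative_dls(age0 + t)
    dls <- norm + (md0 + slope * t)
    clean_visit_row(eye_id = eye_id, patient_id = paste0("pat_", eye_id),
                    test_date = start + t, age = age0 + t,
                    md = md0 + slope * t, dls = pmin(pmax(dls, 0), 50))
  })
  bind_rows_list(rows)
}
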
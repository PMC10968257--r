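#' Configuration for the longitudinal synthetic cohort
#'
#' Defaults are calibrated to the demographics and progression-rate
#' distributions of a typical tertiary glaucoma clinic population: baseline
#' age 63.7 (SD 11.8) years, follow-up 7.7 (SD 1.7) years with roughly ten
#' visits per eye, baseline mean deviation -3.2 (SD 5.8) dB, a
#' stable/progressor MD-slope mixture with overall mean near -0.2 dB/year,
#' and baseline mean RNFL thickness near 79 um.
#'
#' The structure-function gain (`sf_gain`, um of sector RNFL loss per dB of
#' regional field loss) is a free calibration knob: no quantitative value is
#' published for it, and cross-sectional and longitudinal estimates disagree.
#' The default of 1.5 um/dB, with per-eye variability in the healthy profile,
#' reproduces both the baseline thickness and a plausible thickness slope.
#'
#' @param n_patients Number of patients.
#' @param second_eye_prob Probability that a patient contributes both eyes.
#' @param followup_mean,followup_sd,followup_min Follow-up length (years).
#' @param visit_interval,visit_jitter Mean spacing between visits and the SD
#'   of its jitter (years).
#' @param baseline_age_mean,baseline_age_sd Age at first visit (years).
#' @param baseline_md_mean,baseline_md_sd,baseline_md_range Baseline MD (dB);
#'   draws are truncated to the range (default keeps eyes above the -20 dB
#'   exclusion floor).
#' @param prog_fraction Mixture weight of the progressor component.
#' @param stable_slope_mean,stable_slope_sd,prog_slope_mean,prog_slope_sd
#'   True MD slope components (dB/year); progressor draws are truncated below
#'   -0.5 dB/year.
#' @param vf_noise_sd Test-retest SD of pointwise sensitivity (dB) at normal
#'   sensitivity; perimetric variability grows in damaged regions, so the SD
#'   inflates by `vf_noise_inflation` per dB of latent sensitivity below
#'   25 dB.
#' @param vf_noise_inflation Heteroscedasticity slope (fraction per dB).
#' @param vf_global_noise_sd SD (dB) of the per-test global sensitivity
#'   fluctuation shared by all 52 locations (the "long-term fluctuation" of
#'   perimetry: attention, fatigue and criterion shifts move the whole field
#'   up or down between sessions). Pointwise noise alone would leave MD with
#'   an implausibly small test-retest SD of about 0.3 dB because independent
#'   errors average out across locations; the global component restores the
#'   roughly 1 dB session-to-session MD variability seen clinically. Like the
#'   lens-rim artifact it has no structural correlate.
#' @param rnfl_noise_sd Measurement SD of each RNFL profile sample (um).
#' @param rnfl_floor Floor thickness (um): residual glial tissue below which
#'   the profile does not thin.
#' @param sf_gain Structure-function gain (um per dB), see above.
#' @param rnfl_healthy_mean,rnfl_healthy_sd Per-eye mean level of the healthy
#'   double-hump profile (um).
#' @param rnfl_amp_mean,rnfl_amp_sd Per-eye amplitude of the superior /
#'   inferior humps (um).
#' @param artifact_rate Per-visit probability of a trial-lens-rim artifact: a
#'   fixed-depth depression of the peripheral ring of points with no
#'   structural correlate.
#' @param artifact_depth Artifact depression (dB).
#' @param unreliable_rate Fraction of visits drawn to fail a reliability
#'   criterion (false positives/negatives, fixation losses, or OCT signal).
#' @param rnfl_na_rate Per-visit probability of a corrupted RNFL sample.
#' @param archetype_probs Sampling weights of the defect archetypes
#'   (superior arcuate, inferior arcuate, nasal step, diffuse).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 100,
                       second_eye_prob = 0.8,
                       followup_mean = 7.7, followup_sd = 1.7,
                       followup_min = 4,
                       visit_interval = 0.8, visit_jitter = 0.08,
                       baseline_age_mean = 63.7, baseline_age_sd = 11.8,
                       baseline_md_mean = -3.2, baseline_md_sd = 5.8,
                       baseline_md_range = c(-19.5, 2),
                       prog_fraction = 0.25,
                       stable_slope_mean = 0, stable_slope_sd = 0.15,
                       prog_slope_mean = -0.8, prog_slope_sd = 0.25,
                       vf_noise_sd = 2.0, vf_noise_inflation = 0.06,
                       vf_global_noise_sd = 0.8,
                       rnfl_noise_sd = 2.0,
                       rnfl_floor = 50,
                       sf_gain = 1.5,
                       rnfl_healthy_mean = 83.5, rnfl_healthy_sd = 10,
                       rnfl_amp_mean = 28, rnfl_amp_sd = 4,
                       artifact_rate = 0.1, artifact_depth = 5,
                       unreliable_rate = 0.05,
                       rnfl_na_rate = 0.005,
                       archetype_probs = c(superior_arcuate = 0.3,
                                           inferior_arcuate = 0.3,
                                           nasal_step = 0.2,
                                           diffuse = 0.2),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$vf_noise_sd >= 0, cfg$rnfl_noise_sd >= 0,
            cfg$visit_interval > 0, cfg$followup_sd >= 0,
            cfg$prog_fraction >= 0, cfg$prog_fraction <= 1,
            all(cfg$archetype_probs >= 0), sum(cfg$archetype_probs) > 0)
  cfg$archetype_probs <- cfg$archetype_probs / sum(cfg$archetype_probs)
  structure(cfg, class = "sim_config")
}

#' Regional weight masks of the visual-field defect archetypes
#'
#' Each archetype is a length-52 weight vector with unit mean, so an eye with
#' baseline MD `d` and archetype mask `w` has pointwise baseline total
#' deviation `w * d` and its MD equals `d` exactly. The library (superior
#' arcuate, inferior arcuate, nasal step, diffuse) is an invented but
#' clinically recognizable set; users can extend it by supplying their own
#' masks of unit mean.
#'
#' @return Named list of numeric vectors of length 52, each with mean 1.
#' @export
defect_archetypes <- function() {
  g <- vf_grid_24_2()
  arc <- function(sign) {
    w <- rep(0.2, 52)
    hemi <- if (sign > 0) g$y > 0 else g$y < 0
    w[hemi] <- 1.0
    w[hemi & g$ecc >= 9 & g$ecc <= 25] <- 2.5
    w / mean(w)
  }
  nasal <- rep(0.3, 52)
  nasal[g$x <= -15] <- 1.0
  nasal[g$x <= -15 & g$y > 0] <- 3.5
  list(
    superior_arcuate = arc(+1),
    inferior_arcuate = arc(-1),
    nasal_step = nasal / mean(nasal),
    diffuse = rep(1, 52)
  )
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Simulate a longitudinal paired VF/OCT cohort
#'
#' Each eye draws a baseline age, follow-up length, defect archetype and true
#' MD slope. The latent pointwise field declines linearly in time: half of
#' the progression deepens the baseline defect pattern, half is diffuse
#' (defects both deepen and spread), so the latent MD trajectory is exactly
#' linear with the drawn slope. RNFL sectors derive from regional field loss
#' through the structure-function map with gain `sf_gain`, clamped at the
#' floor, plus Gaussian measurement noise. Observed sensitivities add
#' heteroscedastic test-retest noise and, on artifact visits, a fixed
#' depression of the peripheral ring with no structural correlate.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (data.frame in the [cohort_columns()] schema)
#'   and `truth`: `eyes` (per-eye true slope, archetype, baseline values and
#'   healthy-profile parameters) and `visits` (row-aligned with `cohort`:
#'   latent MD, artifact mask, latent noise-free sensitivities and profile as
#'   `latent_dls_*` / `latent_rnfl_*` columns).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  arch <- defect_archetypes()
  g <- vf_grid_24_2()
  theta <- 360 * (0:255) / 256
  prof_sec <- rnfl_profile_sectors()
  map <- onh_sector_map()
  sectors <- levels(map$sector)
  pts_in_sector <- lapply(sectors, function(s) which(map$sector == s))
  names(pts_in_sector) <- sectors

  cohort_rows <- list()
  truth_rows <- list()
  eye_rows <- list()

  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%03d", p)
    n_eyes <- 1L + rbinom(1, 1, cfg$second_eye_prob)
    base_age_p <- rtrunc_norm(1, cfg$baseline_age_mean, cfg$baseline_age_sd,
                              30, 89)
    for (side in c("OD", "OS")[seq_len(n_eyes)]) {
      eid <- paste0(pid, "_", side)
      followup <- rtrunc_norm(1, cfg$followup_mean, cfg$followup_sd,
                              cfg$followup_min, 10.6)
      d0 <- rtrunc_norm(1, cfg$baseline_md_mean, cfg$baseline_md_sd,
                        cfg$baseline_md_range[1], cfg$baseline_md_range[2])
      progressor <- runif(1) < cfg$prog_fraction
      slope <- if (progressor) {
        rtrunc_norm(1, cfg$prog_slope_mean, cfg$prog_slope_sd, -Inf, -0.5)
      } else {
        rnorm(1, cfg$stable_slope_mean, cfg$stable_slope_sd)
      }
      a_name <- sample(names(cfg$archetype_probs), 1,
                       prob = cfg$archetype_probs)
      w_base <- arch[[a_name]]
      w_prog <- 0.5 * w_base + 0.5

      c0 <- rnorm(1, cfg$rnfl_healthy_mean, cfg$rnfl_healthy_sd)
      c1 <- rnorm(1, cfg$rnfl_amp_mean, cfg$rnfl_amp_sd)
      healthy <- c0 + c1 * cos(2 * (theta - 90) * pi / 180)

      # visit grid
      gaps <- pmax(0.3, rnorm(40, cfg$visit_interval, cfg$visit_jitter))
      t_rel <- c(0, cumsum(gaps))
      t_rel <- t_rel[t_rel <= followup]
      if (length(t_rel) < 4) t_rel <- seq(0, followup, length.out = 4)
      base_date <- 2008 + runif(1) * 6
      age0 <- base_age_p + runif(1, -1, 1)

      artifact <- runif(length(t_rel)) < cfg$artifact_rate
      for (j in seq_along(t_rel)) {
        t <- t_rel[j]
        age_t <- age0 + t
        norm_t <- normative_dls(age_t)
        td <- w_base * d0 + w_prog * slope * t
        latent_dls <- pmax(0, norm_t + td)
        latent_md <- compute_md(latent_dls, norm_t)

        # sector losses from regional (latent) field loss
        loss <- vapply(sectors, function(s) {
          max(0, -mean(td[pts_in_sector[[s]]]))
        }, numeric(1))
        latent_rnfl <- pmax(cfg$rnfl_floor,
                            healthy - cfg$sf_gain * loss[as.integer(prof_sec)])

        sd_pt <- cfg$vf_noise_sd *
          (1 + cfg$vf_noise_inflation * pmax(0, 25 - latent_dls))
        dls <- latent_dls + rnorm(52, 0, 1) * sd_pt +
          rnorm(1, 0, cfg$vf_global_noise_sd)
        if (artifact[j]) dls <- dls - cfg$artifact_depth * g$rim
        dls <- pmin(pmax(dls, 0), 50)
        rnfl <- pmin(pmax(latent_rnfl + rnorm(256, 0, cfg$rnfl_noise_sd),
                          0), 300)

        # reliability indices
        fp <- runif(1, 0, 0.12); fn <- runif(1, 0, 0.12)
        fl <- runif(1, 0, 0.28); ss <- sample(7:10, 1)
        if (runif(1) < cfg$unreliable_rate) {
          mode <- sample(4, 1)
          if (mode == 1) fp <- runif(1, 0.15, 0.35)
          if (mode == 2) fn <- runif(1, 0.15, 0.35)
          if (mode == 3) fl <- runif(1, 0.33, 0.6)
          if (mode == 4) ss <- sample(3:6, 1)
        }
        if (runif(1) < cfg$rnfl_na_rate) rnfl[sample(256, 1)] <- NA_real_

        row <- data.frame(patient_id = pid, eye_id = eid,
                          test_date = base_date + t, age = age_t,
                          fp_rate = fp, fn_rate = fn,
                          fixation_loss_rate = fl, signal_strength = ss,
                          md = compute_md(dls, norm_t),
                          stringsAsFactors = FALSE)
        row[dls_cols()] <- as.list(dls)
        row[rnfl_cols()] <- as.list(rnfl)
        cohort_rows[[length(cohort_rows) + 1L]] <- row

        trow <- data.frame(eye_id = eid, test_date = base_date + t,
                           latent_md = latent_md, artifact = artifact[j],
                           stringsAsFactors = FALSE)
        trow[sprintf("latent_dls_%02d", 0:51)] <- as.list(latent_dls)
        trow[sprintf("latent_rnfl_%03d", 0:255)] <- as.list(latent_rnfl)
        truth_rows[[length(truth_rows) + 1L]] <- trow
      }
      eye_rows[[length(eye_rows) + 1L]] <- data.frame(
        eye_id = eid, patient_id = pid, true_md_slope = slope,
        progressor = progressor, baseline_md = d0, archetype = a_name,
        baseline_age = age0, followup_years = max(t_rel),
        healthy_c0 = c0, healthy_c1 = c1, stringsAsFactors = FALSE)
    }
  }

  cohort <- do.call(rbind, cohort_rows)
  rownames(cohort) <- NULL
  cohort <- cohort[, cohort_columns()]
  truth_visits <- do.call(rbind, truth_rows)
  rownames(truth_visits) <- NULL
  eyes <- do.call(rbind, eye_rows)
  rownames(eyes) <- NULL
  list(cohort = cohort, truth = list(eyes = eyes, visits = truth_visits))
}
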
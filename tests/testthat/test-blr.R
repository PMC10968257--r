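test_that("OLS slope matches exact lines and two-point cases", {
  s <- ols_slope(0:3, 3 - 0.5 * (0:3))
  expect_equal(s$slope, -0.5, tolerance = 1e-12)
  expect_equal(s$variance, 0, tolerance = 1e-12)
  s2 <- ols_slope(c(0, 1), c(0, -1))
  expect_equal(s2$slope, -1)
  expect_equal(s2$variance, 0)
  expect_error(ols_slope(rep(2, 3), 1:3), "identical")
  expect_error(ols_slope(1, 1))
})

test_that("OLS slope and variance agree with the lm oracle", {
  set.seed(17)
  for (i in 1:10) {
    t <- sort(runif(8, 0, 6))
    y <- -0.4 * t + rnorm(8, 0, 0.8)
    s <- ols_slope(t, y)
    fit <- lm(y ~ t)
    expect_equal(s$slope, unname(coef(fit)[2]), tolerance = 1e-9)
    expect_equal(s$variance, unname(vcov(fit)[2, 2]), tolerance = 1e-9)
    expect_equal(s$intercept, unname(coef(fit)[1]), tolerance = 1e-9)
  }
})

test_that("the structural prior scales the thickness slope by kappa", {
  t <- 0:4
  expect_equal(fit_structure_prior(t, rep(85, 5), kappa = 0.2)$mean, 0)
  p <- fit_structure_prior(t, 90 - 1 * t, kappa = 0.2)
  expect_equal(p$mean, -0.2, tolerance = 1e-12)
  expect_equal(p$variance, 0, tolerance = 1e-12)
  set.seed(23)
  m <- 90 - 0.8 * t + rnorm(5, 0, 1)
  p2 <- fit_structure_prior(t, m, kappa = 0.3, se_kappa = 0.05)
  o <- ols_slope(t, m)
  expect_equal(p2$mean, 0.3 * o$slope, tolerance = 1e-9)
  expect_equal(p2$variance, 0.09 * o$variance + 0.0025 * o$slope^2,
               tolerance = 1e-9)
  expect_error(fit_structure_prior(0, 85, kappa = 0.2), "prior-unavailable")
})

test_that("posterior slope is the conjugate-normal precision-weighted mean", {
  mk <- function(m, v) list(slope = m, variance = v, n_points = 5)
  # equal variances: midpoint
  expect_equal(posterior_slope(mk(-0.2, 0.02),
                               list(mean = -0.4, variance = 0.02))$slope,
               -0.3, tolerance = 1e-12)
  # forced arithmetic
  p <- posterior_slope(mk(-0.6, 0.04), list(mean = -0.1, variance = 0.01))
  expect_equal(p$slope, -0.2, tolerance = 1e-12)
  expect_equal(p$variance, 1 / (1 / 0.04 + 1 / 0.01), tolerance = 1e-12)
  # uninformative prior returns the likelihood exactly
  u <- posterior_slope(mk(-0.37, 0.029), list(mean = NA, variance = Inf))
  expect_identical(u$slope, -0.37)
  expect_identical(u$variance, 0.029)
  expect_error(posterior_slope(mk(0, Inf), list(mean = 0, variance = Inf)))
})

test_that("posterior mean is convex and posterior variance contracts", {
  set.seed(31)
  for (i in 1:200) {
    m_l <- rnorm(1); m_p <- rnorm(1)
    v_l <- runif(1, 1e-4, 1); v_p <- runif(1, 1e-4, 1)
    p <- posterior_slope(list(slope = m_l, variance = v_l, n_points = 4),
                         list(mean = m_p, variance = v_p))
    expect_gte(p$slope, min(m_l, m_p) - 1e-12)
    expect_lte(p$slope, max(m_l, m_p) + 1e-12)
    expect_lte(p$variance, min(v_l, v_p) + 1e-12)
  }
})

test_that("classification threshold is strict", {
  t <- 0:4
  kappa <- 0.1
  # exact posterior slope of -0.5 must read stable
  md_flat <- rep(-3, 5)
  expect_false(blr_classify(t, md_flat, rep(85, 5), threshold = -0.5,
                            kappa = kappa)$progressing)
  res <- blr_classify(t, -3 - 0.5 * t, 85 - 5 * t, threshold = -0.5,
                      kappa = kappa)
  # likelihood -0.5 exactly, prior -0.5 exactly -> posterior -0.5: stable
  expect_equal(res$posterior$slope, -0.5, tolerance = 1e-12)
  expect_false(res$progressing)
  res2 <- blr_classify(t, -3 - 0.6 * t, 85 - 6 * t, threshold = -0.5,
                       kappa = kappa)
  expect_true(res2$progressing)
})

test_that("a plateaued RNFL biases the posterior toward stability", {
  cfg <- sim_config(n_patients = 60, seed = 203,
                    baseline_md_mean = -14, baseline_md_sd = 1.5,
                    baseline_md_range = c(-18, -11),
                    prog_fraction = 1, prog_slope_mean = -1, prog_slope_sd = 0,
                    sf_gain = 4, rnfl_healthy_mean = 68, rnfl_healthy_sd = 2,
                    vf_noise_sd = 1, rnfl_noise_sd = 1,
                    artifact_rate = 0, unreliable_rate = 0, rnfl_na_rate = 0,
                    archetype_probs = c(superior_arcuate = 0,
                                        inferior_arcuate = 0, nasal_step = 0,
                                        diffuse = 1))
  sim <- simulate_cohort(cfg)
  coh <- sim$cohort
  kap <- estimate_kappa(coh)
  mrnflt <- cohort_mrnflt(coh)
  lik <- c(); post <- c()
  for (e in unique(coh$eye_id)) {
    sel <- coh$eye_id == e
    t <- coh$test_date[sel] - min(coh$test_date[sel])
    l <- ols_slope(t, coh$md[sel])
    b <- blr_classify(t, coh$md[sel], mrnflt[sel],
                      kappa = kap$kappa, se_kappa = kap$se_kappa)
    lik <- c(lik, l$slope); post <- c(post, b$posterior$slope)
  }
  expect_gte(length(lik), 100)
  # floor-locked structure pulls the posterior toward zero (less negative)
  expect_gt(mean(post - lik), 0)
  expect_lt(mean(lik), -0.8)  # sanity: eyes really are progressing
})
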
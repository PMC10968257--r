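#' Ordinary least-squares trend slope with sampling variance
#'
#' Closed-form simple linear regression of `values` on `times`: slope
#' `Sxy / Sxx` and sampling variance `sigma2 / Sxx`, where `sigma2` is the
#' residual mean square (RSS / (n - 2)). With two points the fit is exact and
#' the variance is reported as zero.
#'
#' @param times Observation times (years), at least two distinct.
#' @param values Measurements (e.g. MD in dB, or mean RNFL thickness in um).
#' @return An object of class `slope_estimate`: list with `slope`,
#'   `variance`, `intercept`, `n_points`.
#' @export
#' @examples
#' ols_slope(0:3, 3 - 0.5 * (0:3))$slope  # -0.5
ols_slope <- function(times, values) {
  keep <- is.finite(times) & is.finite(values)
  t <- times[keep]; y <- values[keep]
  n <- length(t)
  if (n < 2) stop("need at least two observations")
  if (max(t) - min(t) <= 0) stop("all times identical")
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  slope <- sxy / sxx
  intercept <- ym - slope * tm
  rss <- sum((y - intercept - slope * t)^2)
  sigma2 <- if (n > 2) rss / (n - 2) else 0
  structure(list(slope = slope, variance = sigma2 / sxx,
                 intercept = intercept, n_points = n),
            class = "slope_estimate")
}

#' Structural prior on the MD progression rate
#'
#' Regresses the eye's mean RNFL thickness on time within the truncated
#' window and converts the structural slope to functional units with the
#' conversion coefficient `kappa` (dB per um): prior mean
#' `kappa * structural slope`; prior variance `kappa^2 * slope variance`
#' plus, when the uncertainty of `kappa` is supplied, a first-order
#' propagation term `se_kappa^2 * slope^2`.
#'
#' @param times,mrnflt Observation times (years) and mean RNFL thickness
#'   (um) within the window.
#' @param kappa Conversion coefficient (dB per um), e.g. from
#'   [estimate_kappa()].
#' @param se_kappa Standard error of `kappa` (0 disables propagation).
#' @return An object of class `structure_prior`: list with `mean`,
#'   `variance`, `kappa`, `n_points`.
#' @export
fit_structure_prior <- function(times, mrnflt, kappa, se_kappa = 0) {
  keep <- is.finite(times) & is.finite(mrnflt)
  if (sum(keep) < 2) stop("prior-unavailable: need at least two OCT visits")
  s <- ols_slope(times[keep], mrnflt[keep])
  structure(list(mean = kappa * s$slope,
                 variance = kappa^2 * s$variance + se_kappa^2 * s$slope^2,
                 kappa = kappa, n_points = s$n_points),
            class = "structure_prior")
}

#' Population conversion coefficient between thickness and sensitivity
#'
#' Cross-sectional regression of MD on mean RNFL thickness over all training
#' visits: the population structure-function slope (dB per um) used to map
#' structural progression rates into functional units, mirroring the use of
#' population information in Bayesian regression approaches. Override it via
#' the `kappa` argument of the classification functions when an external
#' estimate is preferred.
#'
#' @param cohort Training cohort data.frame.
#' @return List with `kappa` (dB/um) and `se_kappa`.
#' @export
estimate_kappa <- function(cohort) {
  m <- cohort_mrnflt(cohort)
  s <- ols_slope(m, cohort$md)
  list(kappa = s$slope, se_kappa = sqrt(s$variance))
}

#' Precision-weighted posterior progression rate
#'
#' Conjugate-normal combination of the functional (likelihood) slope and the
#' structural prior: posterior mean is the precision-weighted average of the
#' two means, posterior variance the inverse summed precision, so data with
#' lower variability receives more weight. A zero variance denotes certainty
#' (that component is returned unchanged); an infinite prior variance is the
#' uninformative limit and returns the likelihood estimate exactly.
#'
#' @param likelihood A `slope_estimate` (from [ols_slope()] on MD).
#' @param prior A `structure_prior` (or any list with `mean`, `variance`).
#' @return A `slope_estimate` with the posterior `slope` and `variance`.
#' @export
#' @examples
#' l <- ols_slope(0:4, -0.2 * (0:4) + c(0.01, -0.02, 0, 0.02, -0.01))
#' posterior_slope(l, list(mean = -0.1, variance = 0.01))
posterior_slope <- function(likelihood, prior) {
  m_l <- likelihood$slope %||% likelihood$mean
  v_l <- likelihood$variance
  m_p <- prior$mean
  v_p <- prior$variance
  stopifnot(is.finite(m_l), is.finite(m_p) || is.infinite(v_p),
            v_l >= 0, v_p >= 0)
  if (is.infinite(v_l) && is.infinite(v_p)) {
    stop("both variances infinite: no information to combine")
  }
  if (is.infinite(v_p)) {
    # uninformative prior: the likelihood estimate is returned exactly
    return(structure(list(slope = m_l, variance = v_l,
                          n_points = likelihood$n_points),
                     class = "slope_estimate"))
  }
  if (is.infinite(v_l)) {
    return(structure(list(slope = m_p, variance = v_p,
                          n_points = likelihood$n_points),
                     class = "slope_estimate"))
  }
  if (v_l == 0 && v_p == 0) {
    # two exact statements; the functional measurement is primary
    return(structure(list(slope = m_l, variance = 0,
                          n_points = likelihood$n_points),
                     class = "slope_estimate"))
  }
  if (v_l == 0) {
    post_m <- m_l; post_v <- 0
  } else if (v_p == 0) {
    post_m <- m_p; post_v <- 0
  } else {
    w_l <- 1 / v_l; w_p <- 1 / v_p
    post_v <- 1 / (w_l + w_p)
    post_m <- (m_l * w_l + m_p * w_p) * post_v
  }
  structure(list(slope = post_m, variance = post_v,
                 n_points = likelihood$n_points),
            class = "slope_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian progression call for one truncated series
#'
#' Combines the MD slope (likelihood) with the structural prior over the
#' same truncated window and labels the eye as progressing when the
#' posterior slope is strictly worse than the threshold. When fewer than two
#' OCT visits fall in the window the prior is unavailable and the likelihood
#' alone decides (flagged in the result).
#'
#' @param times Visit times (years, relative to window start).
#' @param md MD values (dB).
#' @param mrnflt Mean RNFL thickness values (um).
#' @param truncate_at Use only visits with `times <= truncate_at` (years).
#' @param threshold Progression threshold (dB/year), default -0.5.
#' @param kappa,se_kappa Conversion coefficient, see [estimate_kappa()].
#' @return List with `progressing` (logical), `posterior` (slope_estimate),
#'   `likelihood`, `prior` (NULL if unavailable), `prior_used` (logical).
#' @export
blr_classify <- function(times, md, mrnflt, truncate_at = Inf,
                         threshold = -0.5, kappa, se_kappa = 0) {
  keep <- times <= truncate_at + 1e-9
  t <- times[keep]; y <- md[keep]; m <- mrnflt[keep]
  lik <- ols_slope(t, y)
  prior <- tryCatch(fit_structure_prior(t, m, kappa, se_kappa),
                    error = function(e) NULL)
  post <- if (is.null(prior)) lik else posterior_slope(lik, prior)
  list(progressing = post$slope < threshold,
       posterior = post, likelihood = lik, prior = prior,
       prior_used = !is.null(prior))
}
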
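#' Dispersal-kernel spread from isolation-by-distance (1-D habitat)
#'
#' Rousset's one-dimensional relation between the slope of the regression
#' of linearized F_ST on distance and the dispersal kernel:
#' \deqn{\sigma = \frac{1}{\sqrt{4 D_e m}},}
#' where `de` is linear effective density (individuals/km) and `m` the IBD
#' slope (per km); sigma comes out in km.
#'
#' @param de Linear effective density, individuals/km (`> 0`).
#' @param m IBD regression slope, per km; must be positive (a flat or
#'   negative slope carries no kernel information).
#' @return Sigma in km.
#' @examples
#' sigma_point(58.7, 5.393e-5) # 8.89 km
#' @export
sigma_point <- function(de, m) {
  if (de <= 0) abort("de must be positive", class = "ibd_domain")
  if (m <= 0) abort("IBD slope must be positive for a kernel estimate",
                    class = "ibd_undefined_kernel")
  1 / sqrt(4 * de * m)
}

#' Fit the chi-squared sampler for Nb uncertainty
#'
#' The LD-based Nb estimate often has a finite lower confidence bound but
#' an infinite upper one; its sampling uncertainty is represented by a
#' scaled chi-squared variable \eqn{N_b^* = \hat N_b X/\nu},
#' \eqn{X \sim \chi^2_\nu} (mean \eqn{\hat N_b}), with the degrees of
#' freedom \eqn{\nu} chosen so that the 2.5th percentile of \eqn{N_b^*}
#' equals the reported lower bound. Solved by monotone root-finding to
#' relative tolerance 1e-8.
#'
#' @param nb_hat Point estimate of Nb (`> 0`).
#' @param nb_ci_low Lower 95% bound (`0 < nb_ci_low < nb_hat`).
#' @param percentile Percentile of the scaled chi-squared matched to the
#'   lower bound: 0.025 (default) treats the reported bound as the lower
#'   end of a two-sided 95% interval; 0.05 treats it as a one-sided 95%
#'   bound (appropriate when the upper bound is infinite).
#' @param df_cap Above this fitted df the interval is effectively
#'   zero-width and a degenerate (point-mass) sampler is signalled by
#'   returning `Inf`.
#' @return Degrees of freedom (possibly `Inf`).
#' @examples
#' fit_chi2_nb_sampler(6942, 779.5) # about 3.8
#' @export
fit_chi2_nb_sampler <- function(nb_hat, nb_ci_low, percentile = 0.025,
                                df_cap = 1e6) {
  if (!(nb_ci_low > 0 && nb_ci_low < nb_hat)) {
    abort("need 0 < nb_ci_low < nb_hat", class = "ibd_no_solution")
  }
  target <- nb_ci_low / nb_hat
  f <- function(df) qchisq(percentile, df) / df - target
  # qchisq(p, df)/df increases monotonically from ~0 to 1 with df
  if (f(df_cap) < 0) return(Inf)
  lo <- 1e-6
  while (f(lo) > 0) lo <- lo / 10
  uniroot(f, c(lo, df_cap), tol = 1e-11)$root
}

#' Monte-Carlo error propagation for the dispersal spread
#'
#' Propagates the uncertainty of every input of the sigma chain by
#' sampling: the Nb/Ne ratio from a normal distribution, the IBD slope
#' from a normal distribution, and Nb from the fitted scaled chi-squared
#' distribution. Each accepted draw is pushed through the same
#' deterministic chain as the point estimate
#' (bias adjustment -> Ne -> linear density -> sigma); draws with a
#' non-positive slope or ratio, or a non-positive adjustment denominator,
#' are rejected and redrawn so the draw count is preserved. The reported
#' `sigma_point` comes from the deterministic point parameters, not the
#' draw mean; the interval is the 2.5th/97.5th percentile of the draws.
#'
#' The Nb sampler has two parameterizations sharing one fitted degrees of
#' freedom `df` (see [fit_chi2_nb_sampler()]):
#' * `"reciprocal"` (default): the estimated drift signal, which scales as
#'   `1/Nb`, is resampled as a mean-preserving scaled chi-squared, giving
#'   `Nb* = nb_hat * df / X` with `X ~ chi-squared(df)`. This is the
#'   natural error model for an LD-based estimate (the measured quantity
#'   is the squared correlation, not Nb itself) and carries the heavy
#'   upper Nb tail implied by an infinite upper confidence bound.
#' * `"scale"`: `Nb* = nb_hat * X / df`, a mean-preserving chi-squared on
#'   the Nb scale itself (sensitivity alternative).
#'
#' By default `df` is fitted treating the reported interval as a
#' one-sided 95% bound (`percentile = 0.05`), since an interval with an
#' infinite upper endpoint is effectively one-sided; set
#' `ci_one_sided = FALSE` for the two-sided (2.5%) reading.
#'
#' @param nb_hat,nb_ci_low Nb point estimate and lower 95% bound.
#' @param ratio_mean,ratio_sd Normal distribution of the Nb/Ne ratio.
#' @param m_mean,m_se Normal distribution of the IBD slope (per km).
#' @param region_length Study-region length, km.
#' @param n_draws Number of Monte-Carlo draws (default 1e6).
#' @param seed Optional integer seed.
#' @param chi2_form `"reciprocal"` (default) or `"scale"`; see Details.
#' @param ci_one_sided Fit `df` at the 5% point (default `TRUE`) or the
#'   2.5% point.
#' @param max_reject_rate Error out if more than this fraction of raw
#'   draws is rejected (signals inconsistent inputs). Default 0.1.
#' @return A `sigma_estimate`: list with `sigma_point`, `ci_low`,
#'   `ci_high`, `draws`, `n_draws`, `n_rejected`, `df`, `seed`, and the
#'   input configuration.
#' @export
propagate_sigma <- function(nb_hat, nb_ci_low, ratio_mean, ratio_sd,
                            m_mean, m_se, region_length,
                            n_draws = 1e6, seed = NULL,
                            chi2_form = c("reciprocal", "scale"),
                            ci_one_sided = TRUE,
                            max_reject_rate = 0.1) {
  chi2_form <- match.arg(chi2_form)
  if (!is.null(seed)) set.seed(seed)
  if (n_draws < 1) abort("n_draws must be >= 1", class = "ibd_domain")

  df <- fit_chi2_nb_sampler(nb_hat, nb_ci_low,
                            percentile = if (ci_one_sided) 0.05 else 0.025)

  draw_nb <- function(n) {
    if (!is.finite(df)) return(rep(nb_hat, n))
    x <- rchisq(n, df)
    if (chi2_form == "scale") nb_hat * x / df else nb_hat * df / x
  }

  sigma_chain <- function(nb, ratio, m) {
    denom <- 1.26 - 0.323 * ratio
    ne <- nb / denom / ratio
    de <- ne / region_length
    1 / sqrt(4 * de * m)
  }

  draws <- numeric(0)
  n_rejected <- 0L
  n_total <- 0L
  while (length(draws) < n_draws) {
    need <- n_draws - length(draws)
    ratio <- rnorm(need, ratio_mean, ratio_sd)
    m <- rnorm(need, m_mean, m_se)
    nb <- draw_nb(need)
    ok <- m > 0 & ratio > 0 & (1.26 - 0.323 * ratio) > 0 & nb > 0
    n_total <- n_total + need
    n_rejected <- n_rejected + sum(!ok)
    draws <- c(draws, sigma_chain(nb[ok], ratio[ok], m[ok]))
    if (n_total > 10 * n_draws) {
      abort("rejection rate far above tolerance; inputs inconsistent",
            class = "ibd_config")
    }
  }
  if (n_rejected / n_total > max_reject_rate) {
    abort(sprintf("rejected %.1f%% of draws (limit %.0f%%): inputs inconsistent",
                  100 * n_rejected / n_total, 100 * max_reject_rate),
          class = "ibd_config")
  }

  ratio_pt <- ratio_mean
  de_pt <- (nb_hat / (1.26 - 0.323 * ratio_pt) / ratio_pt) / region_length
  qs <- unname(quantile(draws, c(0.025, 0.975)))
  structure(list(
    sigma_point = sigma_point(de_pt, m_mean),
    ci_low = qs[1], ci_high = qs[2],
    draws = draws, n_draws = length(draws), n_rejected = n_rejected,
    df = df, seed = seed, chi2_form = chi2_form,
    config = list(nb_hat = nb_hat, nb_ci_low = nb_ci_low,
                  ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                  m_mean = m_mean, m_se = m_se,
                  region_length = region_length)
  ), class = "sigma_estimate")
}

#' Fraction of dispersal-spread draws at or above a threshold
#'
#' Used to compare the estimated kernel against point estimates from other
#' species: the fraction of Monte-Carlo sigma draws greater than or equal
#' to a threshold spread.
#'
#' @param est A `sigma_estimate` from [propagate_sigma()], or a numeric
#'   vector of draws.
#' @param threshold Spread threshold, km.
#' @return Proportion in `[0, 1]`.
#' @export
exceedance_fraction <- function(est, threshold) {
  draws <- if (inherits(est, "sigma_estimate")) est$draws else est
  if (length(draws) == 0L) abort("no draws", class = "ibd_degenerate")
  mean(draws >= threshold)
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat(sprintf("Dispersal spread sigma = %.2f km, 95%% MC interval [%.2f, %.2f] km\n",
              x$sigma_point, x$ci_low, x$ci_high))
  cat(sprintf("  %d draws (%d rejected), chi2 df = %.3g (%s form)\n",
              x$n_draws, x$n_rejected, x$df, x$chi2_form))
  invisible(x)
}

#' @export
tidy.sigma_estimate <- function(x, ...) {
  tibble::tibble(sigma_point = x$sigma_point, ci_low = x$ci_low,
                 ci_high = x$ci_high, n_draws = x$n_draws,
                 n_rejected = x$n_rejected, chi2_df = x$df)
}

#' @export
glance.sigma_estimate <- function(x, ...) tidy(x)
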
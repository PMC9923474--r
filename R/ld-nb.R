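#' Effective number of breeders from linkage disequilibrium
#'
#' Single-sample estimator of the effective number of breeders from the
#' linkage disequilibrium between unlinked loci. For every locus pair and
#' every pair of retained alleles, Burrows' composite disequilibrium is
#' computed over the individuals typed at both loci:
#' \eqn{\hat\Delta = \mathrm{cov}(X, Y)/2} (sample covariance of the two
#' allele-dosage vectors, which carries the S/(S-1) correction), and the
#' squared correlation
#' \eqn{\hat r^2 = \hat\Delta^2 / (\pi_A \pi_B)} with
#' \eqn{\pi_A = p_A(1-p_A) + D_A}, where \eqn{D_A} is the within-locus
#' departure of homozygote frequency from \eqn{p_A^2} (the within-individual
#' correction, so the estimator does not assume random mating within the
#' sample). Comparisons are pooled as a weighted mean with weights equal to
#' the pairwise-complete sample size S.
#'
#' The sampling expectation
#' \eqn{E[\hat r^2_S] = 1/S + 3.19/S^2} (S >= 30) or
#' \eqn{0.0018 + 0.907/S + 4.44/S^2} (S < 30)
#' is subtracted to give the drift signal `r2_prime`, which is inverted to
#' the effective number of breeders:
#' random mating \eqn{\hat N_b = (1/3 + \sqrt{1/9 - 2.76 r^2{}'})/(2 r^2{}')},
#' monogamy \eqn{\hat N_b = (2/3 + \sqrt{4/9 - 7.2 r^2{}'})/(2 r^2{}')}.
#' A non-positive `r2_prime` (or negative discriminant) means no detectable
#' drift signal and yields an infinite estimate.
#'
#' The confidence interval is a delete-one-locus-pair jackknife on
#' `r2_prime` with normal-theory percentiles, transformed through the
#' monotone inversion; the upper bound is reported as infinite whenever the
#' jackknife lower bound of `r2_prime` is non-positive.
#'
#' Alleles with pooled frequency below `pcrit` are screened out before any
#' comparison (rare alleles upwardly bias r^2).
#'
#' @param g A [genotypes] object; all its individuals are pooled (pool only
#'   sites you consider one population).
#' @param pcrit Critical allele frequency (default 0.02).
#' @param mating_model `"monogamy"` or `"random"`.
#' @param level Confidence level for the jackknife interval (default 0.95).
#' @return An `nb_estimate`: list with `nb_point`, `ci_low`, `ci_high`,
#'   `r2_mean`, `r2_expected_sample`, `r2_prime`, `harmonic_S`,
#'   `n_locus_pairs`, `n_comparisons`, `pcrit`, `mating_model`,
#'   `n_individuals`.
#' @export
ld_nb <- function(g, pcrit = 0.02, mating_model = c("monogamy", "random"),
                  level = 0.95) {
  mating_model <- match.arg(mating_model)
  w <- gt_wide(g)
  loci <- loci_of(g)
  n_ind <- length(w$id)

  # pooled allele screening per locus
  retained <- lapply(loci, function(l) {
    a <- c(w$a1[, l], w$a2[, l])
    a <- a[a > 0L]
    if (length(a) == 0L) return(integer(0))
    tab <- table(a) / length(a)
    as.integer(names(tab)[tab >= pcrit & tab < 1])
  })
  names(retained) <- loci
  usable <- loci[vapply(retained, length, 1L) >= 1L &
                   vapply(loci, function(l) {
                     a <- c(w$a1[, l], w$a2[, l]); length(unique(a[a > 0L])) > 1L
                   }, logical(1))]
  if (length(usable) < 2L) {
    if (all(vapply(retained, length, 1L) == 0L)) {
      abort("pcrit screened out every allele", class = "ibd_pcrit")
    }
    abort("fewer than two usable polymorphic loci", class = "ibd_insufficient")
  }

  pairs <- combn(usable, 2L)
  per_pair <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    l1 <- pairs[1, k]; l2 <- pairs[2, k]
    ok <- w$a1[, l1] > 0L & w$a1[, l2] > 0L
    S <- sum(ok)
    if (S < 3L) next
    D1 <- dosage_matrix(w$a1[ok, l1], w$a2[ok, l1], retained[[l1]])
    D2 <- dosage_matrix(w$a1[ok, l2], w$a2[ok, l2], retained[[l2]])
    if (is.null(D1) || is.null(D2)) next
    delta <- stats::cov(D1, D2) / 2
    pi1 <- dosage_pi(D1); pi2 <- dosage_pi(D2)
    r2 <- sweep(sweep(delta^2, 1L, pi1, "/"), 2L, pi2, "/")
    keep <- is.finite(r2)
    if (!any(keep)) next
    e_r2 <- if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
    m <- sum(keep)
    per_pair[[k]] <- c(w_sum = m * S, wr2_sum = S * sum(r2[keep]),
                       we_sum = m * S * e_r2, S = S, m = m)
  }
  per_pair <- per_pair[!vapply(per_pair, is.null, logical(1))]
  if (length(per_pair) == 0L) {
    abort("no locus pair with usable overlapping individuals",
          class = "ibd_insufficient")
  }
  pp <- do.call(rbind, per_pair)

  agg <- function(rows) {
    r2_mean <- sum(pp[rows, "wr2_sum"]) / sum(pp[rows, "w_sum"])
    e_mean <- sum(pp[rows, "we_sum"]) / sum(pp[rows, "w_sum"])
    c(r2_mean = r2_mean, e_mean = e_mean, r2p = r2_mean - e_mean)
  }
  all_rows <- seq_len(nrow(pp))
  full <- agg(all_rows)
  r2p <- unname(full["r2p"])
  nb_point <- invert_r2prime(r2p, mating_model)

  # delete-one-locus-pair jackknife on r2'
  if (nrow(pp) >= 3L) {
    theta <- vapply(all_rows, function(i) unname(agg(all_rows[-i])["r2p"]),
                    numeric(1))
    npp <- length(theta)
    se <- sqrt((npp - 1) / npp * sum((theta - mean(theta))^2))
    z <- qnorm(1 - (1 - level) / 2)
    r2p_lo <- r2p - z * se
    r2p_hi <- r2p + z * se
    ci_low <- invert_r2prime(r2p_hi, mating_model)   # monotone decreasing
    ci_high <- invert_r2prime(r2p_lo, mating_model)
  } else {
    ci_low <- NA_real_; ci_high <- NA_real_
  }

  structure(list(
    nb_point = nb_point, ci_low = ci_low, ci_high = ci_high,
    r2_mean = unname(full["r2_mean"]),
    r2_expected_sample = unname(full["e_mean"]),
    r2_prime = r2p,
    harmonic_S = nrow(pp) / sum(1 / pp[, "S"]),
    n_locus_pairs = nrow(pp),
    n_comparisons = sum(pp[, "m"]),
    pcrit = pcrit, mating_model = mating_model, n_individuals = n_ind
  ), class = "nb_estimate")
}

# individuals x retained-alleles dosage matrix; drops alleles monomorphic
# within this subset; NULL when nothing remains
dosage_matrix <- function(a1, a2, alleles) {
  if (length(alleles) == 0L) return(NULL)
  D <- vapply(alleles, function(A) (a1 == A) + (a2 == A),
              numeric(length(a1)))
  D <- matrix(D, nrow = length(a1))
  p <- colMeans(D) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) return(NULL)
  D[, keep, drop = FALSE]
}

dosage_pi <- function(D) {
  p <- colMeans(D) / 2
  hom <- colMeans(D == 2)
  p * (1 - p) + (hom - p^2)
}

# map drift signal r2' to Nb under the mating-model constants
invert_r2prime <- function(r2p, mating_model) {
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  disc <- if (mating_model == "random") 1 / 9 - 2.76 * r2p else 4 / 9 - 7.2 * r2p
  if (disc < 0) return(Inf)
  base <- if (mating_model == "random") 1 / 3 else 2 / 3
  nb <- (base + sqrt(disc)) / (2 * r2p)
  if (nb <= 0) Inf else nb
}

#' @export
print.nb_estimate <- function(x, ...) {
  cat(sprintf("LD Nb estimate (%s mating, pcrit = %g): %s\n",
              x$mating_model, x$pcrit, format(round(x$nb_point, 1))))
  cat(sprintf("  jackknife CI [%s, %s];  r2' = %.3e over %d locus pairs (S_harm = %.1f)\n",
              format(round(x$ci_low, 1)), format(round(x$ci_high, 1)),
              x$r2_prime, x$n_locus_pairs, x$harmonic_S))
  invisible(x)
}

#' @export
tidy.nb_estimate <- function(x, ...) {
  tibble::tibble(nb_point = x$nb_point, ci_low = x$ci_low, ci_high = x$ci_high,
                 r2_mean = x$r2_mean, r2_expected_sample = x$r2_expected_sample,
                 r2_prime = x$r2_prime, harmonic_S = x$harmonic_S,
                 n_locus_pairs = x$n_locus_pairs,
                 n_comparisons = x$n_comparisons,
                 pcrit = x$pcrit, mating_model = x$mating_model,
                 n_individuals = x$n_individuals)
}

#' @export
glance.nb_estimate <- function(x, ...) tidy(x)
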
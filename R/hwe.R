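#' Hardy-Weinberg exact test (Monte-Carlo probability test)
#'
#' Exact probability test for departure from Hardy-Weinberg proportions at
#' one locus in one site, after Guo & Thompson: a Markov chain walks over
#' diploid genotype tables with the observed allele counts held fixed, and
#' the p-value is the probability mass of tables whose conditional
#' probability is at most that of the observed table. The walk swaps allele
#' copies between two random individuals; because the null conditional
#' distribution of tables corresponds to a uniformly random pairing of the
#' `2n` allele copies, the swap chain has exactly that stationary law and
#' every proposal is accepted.
#'
#' The chain runs `burn_in` discarded steps, then `batches` batches of
#' `iters_per_batch` steps; the p-value is the mean of the per-batch
#' estimates and a between-batch standard error is attached.
#'
#' @param g A [genotypes] object.
#' @param locus,site Locus name and site id.
#' @param batches,iters_per_batch,burn_in Chain schedule (defaults match
#'   common Genepop settings: 20 x 5000 after 10000 burn-in).
#' @param seed Optional integer seed for reproducibility.
#' @return Monte-Carlo p-value in `(0, 1]` with attribute `"se"`;
#'   `NA_real_` for a monomorphic locus (not applicable, not an error).
#' @export
hwe_exact_test <- function(g, locus, site, batches = 20,
                           iters_per_batch = 5000, burn_in = 10000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- g$locus == locus & g$site == site & g$a1 > 0L
  a1 <- g$a1[rows]; a2 <- g$a2[rows]
  n <- length(a1)
  if (n < 2L) abort("need at least two typed individuals", class = "ibd_degenerate")
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NA_real_)
  k <- length(alleles)
  A <- matrix(c(match(a1, alleles), match(a2, alleles)),
              nrow = 2L, byrow = TRUE)

  # log conditional probability of a genotype table given allele counts,
  # up to a constant: -sum(lfactorial(n_ij)) + H*log(2)
  gt_index <- function(x, y) (pmin(x, y) - 1L) * k + pmax(x, y)
  counts <- tabulate(gt_index(A[1, ], A[2, ]), nbins = k * k)
  n_het <- sum(A[1, ] != A[2, ])
  sumlf <- sum(lfactorial(counts))
  obs <- -sumlf + n_het * log(2)
  cur <- obs
  tol <- 1e-9

  total_iters <- burn_in + batches * iters_per_batch
  u <- sample.int(n, total_iters, replace = TRUE)
  v <- sample.int(n - 1L, total_iters, replace = TRUE)
  v <- ifelse(v >= u, v + 1L, v)  # v != u
  su <- sample.int(2L, total_iters, replace = TRUE)
  sv <- sample.int(2L, total_iters, replace = TRUE)

  batch_means <- numeric(batches)
  hits <- 0L
  iter_in_batch <- 0L
  batch_i <- 0L
  for (t in seq_len(total_iters)) {
    iu <- u[t]; iv <- v[t]
    au <- A[su[t], iu]; av <- A[sv[t], iv]
    if (au != av) {
      gu_old <- gt_index(A[1, iu], A[2, iu])
      gv_old <- gt_index(A[1, iv], A[2, iv])
      het_before <- (A[1, iu] != A[2, iu]) + (A[1, iv] != A[2, iv])
      # swap one allele copy between the two individuals
      A[su[t], iu] <- av; A[sv[t], iv] <- au
      gu_new <- gt_index(A[1, iu], A[2, iu])
      gv_new <- gt_index(A[1, iv], A[2, iv])
      het_after <- (A[1, iu] != A[2, iu]) + (A[1, iv] != A[2, iv])
      for (idx in c(gu_old, gv_old)) {
        sumlf <- sumlf - lfactorial(counts[idx])
        counts[idx] <- counts[idx] - 1L
        sumlf <- sumlf + lfactorial(counts[idx])
      }
      for (idx in c(gu_new, gv_new)) {
        sumlf <- sumlf - lfactorial(counts[idx])
        counts[idx] <- counts[idx] + 1L
        sumlf <- sumlf + lfactorial(counts[idx])
      }
      n_het <- n_het + het_after - het_before
      cur <- -sumlf + n_het * log(2)
    }
    if (t > burn_in) {
      hits <- hits + (cur <= obs + tol)
      iter_in_batch <- iter_in_batch + 1L
      if (iter_in_batch == iters_per_batch) {
        batch_i <- batch_i + 1L
        batch_means[batch_i] <- hits / iters_per_batch
        hits <- 0L
        iter_in_batch <- 0L
      }
    }
  }
  p <- mean(batch_means)
  p <- max(p, 1 / (batches * iters_per_batch))  # never report exactly 0
  attr(p, "se") <- sd(batch_means) / sqrt(batches)
  p
}

#' Hardy-Weinberg tests for every locus within every site
#'
#' Runs [hwe_exact_test()] independently per locus and site, the standard
#' screen before between-site statistics. Monomorphic combinations are
#' reported as `NA` and excluded from any summary.
#'
#' @inheritParams hwe_exact_test
#' @return A tibble with columns `site`, `locus`, `p_value`, `se`.
#' @export
hwe_test_all <- function(g, batches = 20, iters_per_batch = 5000,
                         burn_in = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(site = sites_of(g), locus = loci_of(g))
  res <- purrr::pmap(grid, function(site, locus) {
    p <- tryCatch(hwe_exact_test(g, locus, site, batches, iters_per_batch,
                                 burn_in),
                  ibd_degenerate = function(e) NA_real_)
    tibble::tibble(site = site, locus = locus,
                   p_value = as.numeric(p),
                   se = attr(p, "se") %||% NA_real_)
  })
  dplyr::bind_rows(res)
}
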
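#' Pairwise Weir-Cockerham F_ST between sites
#'
#' Multilocus pairwise theta, the Weir & Cockerham (1984) variance-component
#' estimator of F_ST, for every pair of sites. For each locus and each
#' allele the three components are computed for the two-site comparison:
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals); the multilocus estimate is the ratio of sums,
#' `theta = sum(a) / sum(a + b + c)` over all alleles and loci (the Genepop
#' convention, which is stable for weakly polymorphic loci). Loci
#' monomorphic across a pair contribute nothing. Negative estimates are
#' reported as computed, not truncated to zero.
#'
#' @param g A [genotypes] object with at least two sites.
#' @return An `fst_matrix` object: list with `theta` (labeled symmetric
#'   matrix, zero diagonal), and `components` (tibble of per-pair,
#'   per-locus sums of a, b, c for audit). Use [as.matrix()] or [tidy()].
#' @export
pairwise_fst <- function(g) {
  sites <- sites_of(g)
  if (length(sites) < 2L) abort("need at least two sites", class = "ibd_degenerate")
  w <- gt_wide(g)
  loci <- loci_of(g)
  theta <- matrix(0, length(sites), length(sites),
                  dimnames = list(sites, sites))
  comp <- list()
  for (i in seq_along(sites)[-length(sites)]) {
    for (j in (i + 1L):length(sites)) {
      rows1 <- w$site == sites[i]
      rows2 <- w$site == sites[j]
      per_locus <- lapply(loci, function(l) {
        x1a <- w$a1[rows1, l]; x1b <- w$a2[rows1, l]
        x2a <- w$a1[rows2, l]; x2b <- w$a2[rows2, l]
        ok1 <- x1a > 0L; ok2 <- x2a > 0L
        cc <- wc_pair_locus(x1a[ok1], x1b[ok1], x2a[ok2], x2b[ok2])
        if (is.null(cc)) NULL else
          tibble::tibble(site1 = sites[i], site2 = sites[j], locus = l,
                         a = cc[1], b = cc[2], c = cc[3])
      })
      per_locus <- dplyr::bind_rows(per_locus)
      if (nrow(per_locus) == 0L) {
        abort(sprintf("sites %s and %s share no usable polymorphic locus",
                      sites[i], sites[j]), class = "ibd_undefined_pair")
      }
      denom <- sum(per_locus$a + per_locus$b + per_locus$c)
      theta[i, j] <- theta[j, i] <- sum(per_locus$a) / denom
      comp[[length(comp) + 1L]] <- per_locus
    }
  }
  structure(list(theta = theta, components = dplyr::bind_rows(comp)),
            class = "fst_matrix")
}

# Weir-Cockerham (1984) a, b, c for one locus, two populations, summed over
# alleles. Inputs are the two allele columns per population, complete calls
# only. Returns NULL when the locus is unusable (fewer than 2 copies in a
# population or monomorphic across the pair).
wc_pair_locus <- function(x1a, x1b, x2a, x2b) {
  n1 <- length(x1a); n2 <- length(x2a)
  if (n1 < 1L || n2 < 1L || n1 + n2 < 3L) return(NULL)
  alleles <- sort(unique(c(x1a, x1b, x2a, x2b)))
  if (length(alleles) < 2L) return(NULL)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  out <- c(a = 0, b = 0, c = 0)
  for (A in alleles) {
    d1 <- (x1a == A) + (x1b == A)
    d2 <- (x2a == A) + (x2b == A)
    p1 <- mean(d1) / 2; p2 <- mean(d2) / 2
    h1 <- mean(d1 == 1L); h2 <- mean(d2 == 1L)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    out <- out + c(a, b, cc)
  }
  out
}

#' @export
as.matrix.fst_matrix <- function(x, ...) x$theta

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("<fst_matrix> %d sites, theta range [%.4g, %.4g]\n",
              nrow(x$theta), min(x$theta[upper.tri(x$theta)]),
              max(x$theta[upper.tri(x$theta)])))
  print(round(x$theta, 4))
  invisible(x)
}

#' @describeIn pairwise_fst one row per unordered site pair with `theta`
#'   and `linearized` (theta / (1 - theta)).
#' @param x An `fst_matrix` object.
#' @param ... Unused.
#' @export
tidy.fst_matrix <- function(x, ...) {
  m <- x$theta
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    site1 = rownames(m)[idx[, 1]],
    site2 = colnames(m)[idx[, 2]],
    theta = m[idx],
    linearized = linearize_fst(m[idx])
  )
}
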
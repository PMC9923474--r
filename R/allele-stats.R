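#' Allele frequencies at one locus in one site
#'
#' Tallies allele counts over the non-missing genotypes of one site at one
#' locus. `n_typed` is the number of diploid individuals with a complete
#' call, so counts always sum to `2 * n_typed`.
#'
#' @param g A [genotypes] object.
#' @param locus,site Locus name and site id.
#' @return A tibble with columns `locus`, `site`, `allele`, `count`,
#'   `freq`, `n_typed`.
#' @export
allele_frequencies <- function(g, locus, site) {
  if (!locus %in% loci_of(g)) abort(paste0("unknown locus: ", locus),
                                    class = "ibd_lookup")
  if (!site %in% sites_of(g)) abort(paste0("unknown site: ", site),
                                    class = "ibd_lookup")
  rows <- g$locus == locus & g$site == site
  a <- c(g$a1[rows], g$a2[rows])
  a <- a[a > 0L]
  if (length(a) == 0L) {
    abort(sprintf("no typed individuals at locus %s in site %s", locus, site),
          class = "ibd_degenerate")
  }
  tab <- table(a)
  tibble::tibble(
    locus = locus, site = site,
    allele = as.integer(names(tab)),
    count = as.integer(tab),
    freq = as.integer(tab) / sum(tab),
    n_typed = sum(tab) %/% 2L
  )
}

#' Expected heterozygosity
#'
#' Gene diversity from an allele-frequency table: plain
#' \eqn{H_e = 1 - \sum p_i^2}, or Nei's small-sample unbiased version
#' \eqn{\frac{2n}{2n-1}(1 - \sum p_i^2)} where `n` is the number of typed
#' diploids.
#'
#' @param freqs Output of [allele_frequencies()] (one locus, one site).
#' @param unbiased Apply the `2n/(2n-1)` correction? Default `TRUE`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
expected_heterozygosity <- function(freqs, unbiased = TRUE) {
  n <- freqs$n_typed[1]
  he <- 1 - sum(freqs$freq^2)
  if (unbiased) {
    if (n < 2L) abort("unbiased He undefined for a single individual",
                      class = "ibd_degenerate")
    he <- 2 * n / (2 * n - 1) * he
  }
  he
}

#' Linearized genetic distance
#'
#' Maps F_ST to F_ST / (1 - F_ST), the genetic distance whose regression
#' on geographic distance is linear under one-dimensional
#' isolation-by-distance theory.
#'
#' @param fst Numeric (scalar, vector or matrix), each value `< 1`.
#' @return Same shape as `fst`.
#' @export
linearize_fst <- function(fst) {
  if (any(fst >= 1)) abort("F_ST = 1 linearizes to infinity", class = "ibd_infinite")
  fst / (1 - fst)
}
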
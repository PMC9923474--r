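# fixtures built in code; no binary data

# per-site sample sizes of the anemonefish survey the package emulates
table2_counts <- c(
  "1" = 20, "2" = 21, "7" = 16, "8" = 16, "9" = 17, "10" = 21,
  "11" = 19, "13" = 4, "14" = 2, "15" = 1, "19" = 20, "22" = 2
)
ibd_region_sites <- c("1", "2", "7", "8", "9", "10", "11")

make_table2_genotypes <- function(seed = 42, n_loci = 16) {
  set.seed(seed)
  loci <- sprintf("loc%02d", seq_len(n_loci))
  rows <- lapply(names(table2_counts), function(s) {
    n <- table2_counts[[s]]
    tibble::tibble(
      id = sprintf("site%s_%02d", s, rep(seq_len(n), each = n_loci)),
      site = s,
      locus = rep(loci, n),
      a1 = sample(101:112, n * n_loci, replace = TRUE),
      a2 = sample(101:112, n * n_loci, replace = TRUE)
    )
  })
  genotypes(dplyr::bind_rows(rows), loci = loci, sites = names(table2_counts))
}

random_genotypes <- function(n_sites = 3, n_per_site = 8, n_loci = 5,
                             n_alleles = 6, missing_rate = 0.05, seed = 1) {
  set.seed(seed)
  loci <- sprintf("L%d", seq_len(n_loci))
  sites <- sprintf("site%d", seq_len(n_sites))
  rows <- lapply(sites, function(s) {
    n <- n_per_site
    a1 <- sample(seq(10, 10 + n_alleles - 1), n * n_loci, replace = TRUE)
    a2 <- sample(seq(10, 10 + n_alleles - 1), n * n_loci, replace = TRUE)
    miss <- runif(n * n_loci) < missing_rate
    a1[miss] <- 0L; a2[miss] <- 0L
    tibble::tibble(
      id = sprintf("%s_%02d", s, rep(seq_len(n), each = n_loci)),
      site = s, locus = rep(loci, n), a1 = a1, a2 = a2
    )
  })
  genotypes(dplyr::bind_rows(rows), loci = loci, sites = sites)
}

# independent Weir-Cockerham (1984) two-population oracle, written from the
# published component formulas over explicit genotype-category counts; a
# second route, deliberately structured unlike the package implementation
oracle_wc_theta <- function(pop1, pop2) {
  # popX: list of length-2 numeric vectors (one genotype per individual),
  # one locus; returns c(a_sum, b_sum, c_sum, theta)
  n1 <- length(pop1); n2 <- length(pop2)
  alleles <- sort(unique(unlist(c(pop1, pop2))))
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  tot <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    cnt <- function(pop) sum(vapply(pop, function(gt) sum(gt == al), 0))
    het <- function(pop) sum(vapply(pop, function(gt) sum(gt == al) == 1, TRUE))
    p1 <- cnt(pop1) / (2 * n1); p2 <- cnt(pop2) / (2 * n2)
    h1 <- het(pop1) / n1; h2 <- het(pop2) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (ssq - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ssq * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ssq * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    tot <- tot + c(a, b, cc)
  }
  c(tot, theta = unname(tot["a"] / sum(tot)))
}

# build a genotypes object for two sites at one locus from genotype lists
two_site_one_locus <- function(pop1, pop2, locus = "L1") {
  mk <- function(pop, s) tibble::tibble(
    id = sprintf("%s_%d", s, seq_along(pop)), site = s, locus = locus,
    a1 = vapply(pop, `[`, 0, 1), a2 = vapply(pop, `[`, 0, 2)
  )
  genotypes(dplyr::bind_rows(mk(pop1, "A"), mk(pop2, "B")),
            loci = locus, sites = c("A", "B"))
}

# exact Hardy-Weinberg probability-test p-value for a biallelic sample, by
# full enumeration of genotype tables with the observed allele counts
oracle_hwe_biallelic <- function(nAA, nAa, naa) {
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  n <- nAA + nAa + naa
  tab_p <- function(het) {
    AA <- (nA - het) / 2; aa <- (na - het) / 2
    exp(lfactorial(n) + lfactorial(nA) + lfactorial(na) + het * log(2) -
          lfactorial(2 * n) - lfactorial(AA) - lfactorial(het) - lfactorial(aa))
  }
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  hets <- hets[(nA - hets) %% 2 == 0 & (nA - hets) >= 0 & (na - hets) >= 0]
  probs <- vapply(hets, tab_p, 0)
  p_obs <- tab_p(nAa)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# brute-force Mantel p over all n! simultaneous relabelings of A
oracle_mantel_exhaustive <- function(A, B, tail = "greater") {
  n <- nrow(A)
  perms <- ibdkernel:::all_permutations(n)
  vb <- B[lower.tri(B)]
  r_obs <- cor(A[lower.tri(A)], vb)
  rs <- apply(perms, 1, function(p) cor(A[p, p][lower.tri(A)], vb))
  hit <- switch(tail, greater = rs >= r_obs - 1e-12, less = rs <= r_obs + 1e-12)
  list(r = r_obs, p = mean(hit))
}

sym_mat <- function(x, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- x
  m + t(m)
}
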
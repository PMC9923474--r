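test_that("allele frequencies match an exhaustive tally", {
  g <- two_site_one_locus(list(c(5, 5), c(5, 5)), list(c(1, 2), c(2, 2)))
  fA <- allele_frequencies(g, "L1", "A")
  expect_equal(fA$freq, 1)
  expect_equal(fA$n_typed[1], 2)
  fB <- allele_frequencies(g, "L1", "B")
  expect_equal(fB$freq[fB$allele == 1], 0.25)
  expect_equal(fB$freq[fB$allele == 2], 0.75)

  g2 <- random_genotypes(seed = 3)
  for (s in sites_of(g2)) {
    fr <- allele_frequencies(g2, "L2", s)
    # brute-force tally over the genotype list
    rows <- g2[g2$locus == "L2" & g2$site == s, ]
    pool <- c(rows$a1, rows$a2); pool <- pool[pool > 0]
    for (k in seq_len(nrow(fr))) {
      expect_equal(fr$count[k], sum(pool == fr$allele[k]))
    }
    expect_equal(sum(fr$count), 2 * fr$n_typed[1])
    expect_equal(sum(fr$freq), 1)
  }

  expect_error(allele_frequencies(g2, "nope", "site1"), class = "ibd_lookup")
})

test_that("expected heterozygosity follows the gene-diversity formulas", {
  g <- two_site_one_locus(list(c(5, 5), c(5, 5)), list(c(1, 2), c(1, 2)))
  expect_equal(expected_heterozygosity(allele_frequencies(g, "L1", "A"),
                                       unbiased = FALSE), 0)
  fB <- allele_frequencies(g, "L1", "B")   # p = 0.5
  expect_equal(expected_heterozygosity(fB, unbiased = FALSE), 0.5)
  expect_equal(expected_heterozygosity(fB, unbiased = TRUE), 4 / 3 * 0.5)

  # four equifrequent alleles: 1 - 4 * 0.25^2
  g4 <- two_site_one_locus(list(c(1, 2), c(3, 4)), list(c(1, 1), c(1, 1)))
  expect_equal(expected_heterozygosity(allele_frequencies(g4, "L1", "A"),
                                       unbiased = FALSE), 0.75)
  # unbiased exceeds plain for finite samples
  expect_gt(expected_heterozygosity(fB, TRUE),
            expected_heterozygosity(fB, FALSE))
})

test_that("F_ST linearization is F/(1-F)", {
  expect_equal(linearize_fst(0), 0)
  expect_equal(linearize_fst(0.5), 1)
  expect_equal(linearize_fst(-0.006), -0.006 / 1.006)
  expect_equal(round(linearize_fst(-0.006), 6), -0.005964)
  expect_error(linearize_fst(1), class = "ibd_infinite")
})

test_that("pairwise theta matches the variance-component oracle", {
  popA <- list(c(1, 1), c(1, 2), c(2, 2))
  popB <- list(c(2, 2), c(2, 2), c(1, 2))
  g <- two_site_one_locus(popA, popB)
  ours <- pairwise_fst(g)
  orc <- oracle_wc_theta(popA, popB)
  expect_equal(as.matrix(ours)["A", "B"], unname(orc["theta"]), tolerance = 1e-12)
  expect_equal(sum(ours$components$a), unname(orc["a"]), tolerance = 1e-12)

  popC <- list(c(1, 1), c(1, 1), c(1, 2), c(1, 3))
  popD <- list(c(2, 2), c(1, 2), c(2, 3), c(3, 3))
  g2 <- two_site_one_locus(popC, popD)
  orc2 <- oracle_wc_theta(popC, popD)
  expect_equal(as.matrix(pairwise_fst(g2))["A", "B"], unname(orc2["theta"]),
               tolerance = 1e-12)
})

test_that("theta hits the fixation endpoints", {
  # complete differentiation
  fixed <- two_site_one_locus(list(c(1, 1), c(1, 1), c(1, 1)),
                              list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(as.matrix(pairwise_fst(fixed))["A", "B"], 1)

  # two large samples from one allele pool: theta near zero
  set.seed(5)
  n <- 250
  draw <- function(s) tibble::tibble(
    id = sprintf("%s_%d", s, seq_len(n)), site = s, locus = "L1",
    a1 = sample(1:4, n, TRUE, prob = c(.4, .3, .2, .1)),
    a2 = sample(1:4, n, TRUE, prob = c(.4, .3, .2, .1)))
  g <- genotypes(dplyr::bind_rows(draw("A"), draw("B")),
                 loci = "L1", sites = c("A", "B"))
  expect_lt(abs(as.matrix(pairwise_fst(g))["A", "B"]), 0.01)
})

test_that("theta is symmetric, zero-diagonal and invariant to relabeling", {
  g <- random_genotypes(n_sites = 4, n_per_site = 10, seed = 9)
  th <- as.matrix(pairwise_fst(g))
  expect_equal(th, t(th))
  expect_equal(unname(diag(th)), rep(0, 4))
  expect_true(all(is.finite(th)))

  # site order flip
  tbl <- tibble::as_tibble(g)
  g_rev <- genotypes(tbl, loci = loci_of(g), sites = rev(sites_of(g)))
  th_rev <- as.matrix(pairwise_fst(g_rev))
  expect_equal(th_rev[sites_of(g), sites_of(g)], th)

  # allele code relabeling (bijective map)
  remap <- function(a) ifelse(a == 0L, 0L, 100L - a)
  tbl2 <- dplyr::mutate(tbl, a1 = remap(a1), a2 = remap(a2))
  expect_equal(as.matrix(pairwise_fst(genotypes(tbl2, loci = loci_of(g),
                                                sites = sites_of(g)))), th)
})

test_that("undefined pairs and degenerate inputs error cleanly", {
  one_site <- two_site_one_locus(list(c(1, 2)), list(c(1, 2)))
  one_site <- filter_sites(one_site, 1)
  g1 <- genotypes(tibble::as_tibble(one_site)[one_site$site == "A", ],
                  loci = "L1", sites = "A")
  expect_error(pairwise_fst(g1), class = "ibd_degenerate")

  # monomorphic across the pair: no usable locus
  mono <- two_site_one_locus(list(c(1, 1), c(1, 1)), list(c(1, 1), c(1, 1)))
  expect_error(pairwise_fst(mono), class = "ibd_undefined_pair")
})
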
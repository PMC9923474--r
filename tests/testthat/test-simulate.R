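test_that("expected slope and sigma are algebraic inverses", {
  expect_equal(expected_ibd_slope(0.25, 1), 1)
  expect_equal(signif(expected_ibd_slope(58.7, 8.9), 3), 5.38e-5)
  # consistent with the dispersal-spread relation at 2 significant figures
  expect_equal(signif(expected_ibd_slope(58.7, 8.9), 2), signif(5.393e-5, 2))
  set.seed(101)
  for (i in 1:20) {
    de <- runif(1, 1, 500); s <- runif(1, 0.5, 50)
    expect_equal(sigma_point(de, expected_ibd_slope(de, s)), s,
                 tolerance = 1e-12)
  }
})

test_that("simulator configuration is validated", {
  expect_error(stepping_stone_config(n_demes = 1), class = "ibd_domain")
  expect_error(stepping_stone_config(sigma = 0), class = "ibd_domain")
  expect_error(stepping_stone_config(mu = 0.5), class = "ibd_domain")
  expect_error(stepping_stone_config(sample_sites = c(1, 99)),
               class = "ibd_domain")
  expect_error(stepping_stone_config(n_demes = 4, deme_size = 5,
                                     sample_sites = 2, sample_n = 6),
               class = "ibd_domain")
  expect_warning(stepping_stone_config(n_demes = 4, deme_spacing = 1,
                                       sigma = 50, sample_sites = c(1, 3),
                                       deme_size = 30, sample_n = 5),
                 "IBD regime")
  expect_error(stepping_stone_config(corridor_demes = c(2, 2)),
               class = "ibd_domain")
})

test_that("simulated samples are complete diploid tables within bounds", {
  cfg <- stepping_stone_config(n_demes = 5, deme_size = 40, sigma = 4,
                               deme_spacing = 2, n_loci = 6, burn_in = 60,
                               sample_sites = c(1, 3, 5), sample_n = 12)
  sim <- simulate_stepping_stone(cfg, seed = 5)
  g <- sim$genotypes
  expect_equal(n_individuals(g), 36)
  expect_equal(site_sizes(g)$n, rep(12, 3))
  expect_equal(length(loci_of(g)), 6)
  # every allele copy present and inside the reflecting bounds
  expect_true(all(g$a1 >= cfg$allele_min & g$a2 <= cfg$allele_max))
  expect_equal(nrow(g), 36 * 6)
  expect_equal(sim$truth$de_true, 20)
  expect_equal(sim$truth$expected_slope,
               expected_ibd_slope(20, 4))
  # reproducible per seed
  sim2 <- simulate_stepping_stone(cfg, seed = 5)
  expect_true(gt_equal(g, sim2$genotypes))
})

test_that("dispersal kernel columns are proper distributions", {
  kc <- ibdkernel:::dispersal_kernel_cum(10, 5, 8)
  expect_equal(dim(kc), c(10, 10))
  expect_equal(unname(kc[10, ]), rep(1, 10))
  expect_true(all(diff(kc[, 4]) >= 0))
  # corridor moves mass between the designated demes
  kc2 <- ibdkernel:::dispersal_kernel_cum(10, 5, 8, c(1, 10), 0.3)
  p_far <- kc2[10, 1] - kc2[9, 1]   # P(parent deme 10 | offspring deme 1)
  expect_gt(p_far, 0.29)
})

test_that("panmixia and isolation limits bracket the stepping stone", {
  # island limit: uniform kernel, differentiation vanishes
  isl <- suppressWarnings(
    stepping_stone_config(n_demes = 4, deme_spacing = 1, deme_size = 100,
                          sigma = 1e6, n_loci = 8, mu = 1e-3,
                          burn_in = 200, sample_sites = c(1, 4),
                          sample_n = 40))
  g_isl <- simulate_stepping_stone(isl, seed = 7)$genotypes
  th_isl <- as.matrix(pairwise_fst(g_isl))[1, 2]
  expect_lt(abs(th_isl), 0.02)

  # isolation limit: essentially no migration, differentiation builds up
  iso_short <- stepping_stone_config(n_demes = 2, deme_spacing = 100,
                                     deme_size = 60, sigma = 1e-3, n_loci = 8,
                                     mu = 1e-3, burn_in = 30,
                                     sample_sites = c(1, 2), sample_n = 30)
  th_short <- as.matrix(pairwise_fst(
    simulate_stepping_stone(iso_short, seed = 8)$genotypes))[1, 2]
  iso_long <- iso_short
  iso_long$burn_in <- 400
  th_long <- as.matrix(pairwise_fst(
    simulate_stepping_stone(iso_long, seed = 8)$genotypes))[1, 2]
  expect_gt(th_long, th_short)
  expect_gt(th_long, 0.2)
})

test_that("diversity rises with mutation rate and population size", {
  mean_he <- function(mu, N, seed) {
    cfg <- suppressWarnings(
      stepping_stone_config(n_demes = 2, deme_spacing = 1, deme_size = N,
                            sigma = 1e6, n_loci = 10, mu = mu,
                            burn_in = 600, sample_sites = c(1, 2),
                            sample_n = min(N, 30)))
    g <- simulate_stepping_stone(cfg, seed = seed)$genotypes
    mean(vapply(loci_of(g), function(l) {
      f <- allele_frequencies(g, l, "s01")
      expected_heterozygosity(f, unbiased = FALSE)
    }, 0))
  }
  expect_gt(mean_he(5e-3, 60, 21), mean_he(1e-4, 60, 21))
  expect_gt(mean_he(2e-3, 150, 22), mean_he(2e-3, 25, 22))
})

test_that("fixture suite files are coherent and re-readable", {
  cfg <- stepping_stone_config(n_demes = 12, deme_spacing = 10, deme_size = 40,
                               sigma = 8, n_loci = 6, burn_in = 80,
                               sample_sites = c(2, 5, 8, 11), sample_n = 10,
                               corridor_demes = c(2, 11))
  out <- withr::local_tempdir()
  paths <- make_fixture_suite(cfg, out, seed = 3)
  expect_true(all(file.exists(unlist(paths))))

  g <- read_genepop(paths$genepop)
  expect_equal(n_individuals(g), 40)
  st <- read_site_table(paths$site_table)
  expect_identical(st$site_id, sites_of(g))

  D <- read_distance_matrix(paths$distance)
  gaps <- abs(outer(cfg$sample_sites, cfg$sample_sites, "-"))
  expect_equal(unname(unclass(D)[, ]), gaps * cfg$deme_spacing,
               ignore_attr = TRUE)

  C <- read_connectivity(paths$connectivity)
  # decays with distance except along the designated corridor
  expect_equal(unname(C["s02", "s11"]), 0.2)
  off <- unclass(C)["s02", c("s05", "s08")]
  expect_true(all(diff(off) < 0))

  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$de_true, 4)
  expect_equal(truth$sigma_true, 8)
})

test_that("an anomalous corridor weakens IBD until its site is excluded", {
  cfg <- stepping_stone_config(n_demes = 12, deme_spacing = 10, deme_size = 80,
                               sigma = 6, n_loci = 12, mu = 1e-3,
                               burn_in = 600,
                               sample_sites = c(2, 4, 6, 8, 10, 12),
                               sample_n = 20,
                               corridor_demes = c(2, 12),
                               corridor_strength = 0.4)
  sim <- simulate_stepping_stone(cfg, seed = 14)
  g <- sim$genotypes
  pos <- (cfg$sample_sites - 1) * cfg$deme_spacing
  D <- outer(pos, pos, function(a, b) abs(a - b))
  dimnames(D) <- list(sites_of(g), sites_of(g))
  lin <- linearize_fst(as.matrix(pairwise_fst(g)))

  r_all <- mantel(dist_matrix(D, "geographic_km"),
                  dist_matrix(lin, "linearized_fst"))$r
  keep <- setdiff(sites_of(g), "s12")
  r_excl <- mantel(dist_matrix(D[keep, keep], "geographic_km"),
                   dist_matrix(lin[keep, keep], "linearized_fst"))$r
  expect_gt(r_excl, r_all)
})
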
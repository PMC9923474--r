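#' Configuration for the stepping-stone genotype simulator
#'
#' Ground-truth parameters for a forward-time one-dimensional
#' stepping-stone population of diploid, stepwise-mutating microsatellite
#' genotypes. Defaults describe a coastline-like system with linear
#' effective density 50 diploids/km and dispersal spread 8 km: 40 demes 5
#' km apart, 250 diploids each, 16 loci mutating at 5e-4 per generation,
#' and seven sampled sites of 20 fish spaced 25 km apart in the interior.
#'
#' @param n_demes Number of demes on the line.
#' @param deme_spacing Distance between adjacent demes, km.
#' @param deme_size Diploids per deme (so true linear density is
#'   `deme_size / deme_spacing`).
#' @param sigma Gaussian dispersal spread, km (`> 0`); a very large value
#'   approaches an island model.
#' @param n_loci Number of unlinked microsatellite loci.
#' @param mu Stepwise mutation rate per locus per generation, in
#'   `[0, 0.01]`.
#' @param allele_min,allele_max Repeat-code bounds (mutations reflect at
#'   the bounds; keep below 1000 for 3-digit Genepop coding).
#' @param burn_in Generations simulated before sampling.
#' @param sample_sites Deme indices (1-based) to sample.
#' @param sample_n Individuals sampled per site, without replacement.
#' @param monogamy Pair parents monogamously within each generation?
#' @param corridor_demes Optional pair of deme indices joined by an
#'   anomalous dispersal corridor (a jet-like current short-circuiting the
#'   coastline); `NULL` (default) for a pure stepping-stone.
#' @param corridor_strength Fraction of offspring in each corridor deme
#'   whose parents come from the opposite corridor deme.
#' @return A `stepping_stone_config` (validated list).
#' @export
stepping_stone_config <- function(n_demes = 40, deme_spacing = 5,
                                  deme_size = 250, sigma = 8,
                                  n_loci = 16, mu = 5e-4,
                                  allele_min = 120, allele_max = 180,
                                  burn_in = 2000,
                                  sample_sites = seq(5, 35, by = 5),
                                  sample_n = 20, monogamy = FALSE,
                                  corridor_demes = NULL,
                                  corridor_strength = 0.25) {
  if (n_demes < 2) abort("need at least 2 demes", class = "ibd_domain")
  if (sigma <= 0) abort("sigma must be positive", class = "ibd_domain")
  if (mu < 0 || mu > 0.01) abort("mu must lie in [0, 0.01]", class = "ibd_domain")
  if (any(sample_sites < 1 | sample_sites > n_demes)) {
    abort("sample_sites must be deme indices", class = "ibd_domain")
  }
  if (sample_n > deme_size) abort("sample_n exceeds deme size", class = "ibd_domain")
  if (allele_min >= allele_max) abort("allele bounds reversed")
  if (!is.null(corridor_demes)) {
    if (length(corridor_demes) != 2L ||
        any(corridor_demes < 1 | corridor_demes > n_demes) ||
        corridor_demes[1] == corridor_demes[2]) {
      abort("corridor_demes must be two distinct deme indices",
            class = "ibd_domain")
    }
    if (corridor_strength <= 0 || corridor_strength >= 1) {
      abort("corridor_strength must lie in (0, 1)", class = "ibd_domain")
    }
  }
  habitat <- (n_demes - 1) * deme_spacing
  if (sigma > habitat / 2) {
    warn("kernel spread comparable to habitat length: IBD regime violated")
  }
  structure(list(n_demes = n_demes, deme_spacing = deme_spacing,
                 deme_size = deme_size, sigma = sigma, n_loci = n_loci,
                 mu = mu, allele_min = allele_min, allele_max = allele_max,
                 burn_in = burn_in, sample_sites = sample_sites,
                 sample_n = sample_n, monogamy = monogamy,
                 corridor_demes = corridor_demes,
                 corridor_strength = corridor_strength),
            class = "stepping_stone_config")
}

# discretized Gaussian dispersal kernel, renormalized at the habitat edges
# so density stays spatially constant; returns cumulative columns. An
# optional corridor mixes a fixed fraction of each corridor deme's parent
# draws over to the opposite corridor deme.
dispersal_kernel_cum <- function(n_demes, spacing, sigma,
                                 corridor_demes = NULL,
                                 corridor_strength = 0) {
  pos <- (seq_len(n_demes) - 1) * spacing
  K <- outer(pos, pos, function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
  K <- sweep(K, 2L, colSums(K), "/")  # column d: P(parent deme | offspring d)
  if (!is.null(corridor_demes)) {
    for (k in 1:2) {
      d <- corridor_demes[k]; src <- corridor_demes[3 - k]
      K[, d] <- (1 - corridor_strength) * K[, d]
      K[src, d] <- K[src, d] + corridor_strength
    }
  }
  apply(K, 2L, cumsum)
}

#' Simulate genotypes under a 1-D stepping-stone model
#'
#' Runs the forward Wright-Fisher stepping-stone simulation described in
#' [stepping_stone_config()] (non-overlapping generations, Gaussian
#' dispersal of natal deme, stepwise mutation reflecting at the repeat
#' bounds) and samples the configured sites. Allele states start uniform
#' within the bounds, giving high standing diversity that relaxes toward
#' drift-mutation balance during burn-in.
#'
#' @param cfg A [stepping_stone_config()].
#' @param seed Optional integer seed.
#' @return List with `genotypes` (a [genotypes] object; sites named
#'   `s<deme>`) and `truth` (list: `de_true` = diploids/km, `sigma_true`,
#'   `expected_slope` = `1/(4 de sigma^2)`, plus the config).
#' @export
simulate_stepping_stone <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "stepping_stone_config"))
  if (!is.null(seed)) set.seed(seed)
  n_total <- cfg$n_demes * cfg$deme_size
  a1 <- matrix(sample(cfg$allele_min:cfg$allele_max, n_total * cfg$n_loci,
                      replace = TRUE), n_total, cfg$n_loci)
  a2 <- matrix(sample(cfg$allele_min:cfg$allele_max, n_total * cfg$n_loci,
                      replace = TRUE), n_total, cfg$n_loci)
  kc <- dispersal_kernel_cum(cfg$n_demes, cfg$deme_spacing, cfg$sigma,
                             cfg$corridor_demes, cfg$corridor_strength)
  out <- sim_stepping_stone_cpp(a1, a2, cfg$n_demes, cfg$deme_size, kc,
                                cfg$mu, cfg$allele_min, cfg$allele_max,
                                cfg$burn_in, cfg$monogamy)
  deme_of <- rep(seq_len(cfg$n_demes), each = cfg$deme_size)
  loci <- sprintf("L%02d", seq_len(cfg$n_loci))
  keep <- unlist(lapply(cfg$sample_sites, function(d) {
    sample(which(deme_of == d), cfg$sample_n)
  }))
  site <- sprintf("s%02d", rep(cfg$sample_sites, each = cfg$sample_n))
  id <- sprintf("%s_%03d", site, unlist(lapply(cfg$sample_sites,
                                               function(d) seq_len(cfg$sample_n))))
  g <- gt_from_wide(out$a1[keep, , drop = FALSE], out$a2[keep, , drop = FALSE],
                    id = id, site = site, loci = loci,
                    sites = sprintf("s%02d", cfg$sample_sites))
  de_true <- cfg$deme_size / cfg$deme_spacing
  list(genotypes = g,
       truth = list(de_true = de_true, sigma_true = cfg$sigma,
                    expected_slope = expected_ibd_slope(de_true, cfg$sigma),
                    config = cfg))
}

#' Expected isolation-by-distance slope
#'
#' The algebraic inverse of [sigma_point()]: the slope of linearized F_ST
#' on distance expected in a one-dimensional habitat with linear effective
#' density `de` and dispersal spread `sigma`,
#' \eqn{m = 1/(4 D_e \sigma^2)}.
#'
#' @param de Linear effective density, individuals/km.
#' @param sigma Dispersal spread, km.
#' @return Slope per km.
#' @export
expected_ibd_slope <- function(de, sigma) {
  if (de <= 0 || sigma <= 0) abort("need positive inputs", class = "ibd_domain")
  1 / (4 * de * sigma^2)
}

#' Write a coherent synthetic fixture set
#'
#' Simulates genotypes and writes every file the analysis pipeline
#' consumes, all derived from the same configuration: a Genepop file, a
#' site table with coordinates along a model coastline, a geographic
#' distance matrix (deme spacing times index gap), a synthetic
#' connectivity matrix that decays exponentially with distance
#' (`exp(-d/lambda)`) except for one anomalous high-connectivity corridor
#' between the designated pair (mimicking a jet current short-circuiting
#' the coastline), a visual-survey table, and the ground-truth record as
#' JSON. All synthetic; seeded and reproducible.
#'
#' @param cfg A [stepping_stone_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param lambda Connectivity decay length, km.
#' @param corridor Length-2 character vector of site ids joined by the
#'   anomalous corridor; defaults to the two outermost sampled sites.
#' @param corridor_prob Connectivity assigned to the corridor pair.
#' @param n_surveys,survey_meanlog,survey_sdlog Lognormal visual-survey
#'   density generator (fish/km^2).
#' @return Invisibly, a named list of the file paths.
#' @export
make_fixture_suite <- function(cfg, out_dir, seed = 1, lambda = 40,
                               corridor = NULL, corridor_prob = 0.2,
                               n_surveys = 20, survey_meanlog = log(350),
                               survey_sdlog = 0.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sim <- simulate_stepping_stone(cfg)
  g <- sim$genotypes
  sites <- sites_of(g)
  pos <- (cfg$sample_sites - 1) * cfg$deme_spacing

  paths <- list(
    genepop = file.path(out_dir, "genotypes.gen"),
    site_table = file.path(out_dir, "sites.csv"),
    distance = file.path(out_dir, "distance_km.csv"),
    connectivity = file.path(out_dir, "connectivity.csv"),
    surveys = file.path(out_dir, "surveys.csv"),
    truth = file.path(out_dir, "truth.json")
  )

  write_genepop(g, paths$genepop)

  st <- tibble::tibble(
    site_id = sites, name = sites, island = "model-coast",
    longitude = 120 + pos / 111.32, latitude = 10,
    in_ibd_region = TRUE
  )
  readr::write_csv(st, paths$site_table)

  D <- outer(pos, pos, function(a, b) abs(a - b))
  dimnames(D) <- list(sites, sites)
  write_distance_matrix(dist_matrix(D, "geographic_km"), paths$distance)

  C <- exp(-D / lambda)
  diag(C) <- 0
  if (is.null(corridor) && !is.null(cfg$corridor_demes)) {
    corridor <- sprintf("s%02d", cfg$corridor_demes)
    if (!all(corridor %in% sites)) corridor <- NULL
  }
  corridor <- corridor %||% c(sites[1], sites[length(sites)])
  C[corridor[1], corridor[2]] <- corridor_prob
  C[corridor[2], corridor[1]] <- corridor_prob
  dimnames(C) <- list(sites, sites)
  write.csv(as.data.frame(C), paths$connectivity, row.names = TRUE)

  sv <- tibble::tibble(
    site_id = sample(sites, n_surveys, replace = TRUE),
    transect_length_m = round(rnorm(n_surveys, 655, 51)),
    area_km2 = 0.01
  )
  dens <- stats::rlnorm(n_surveys, survey_meanlog, survey_sdlog)
  sv$fish_count <- pmax(0L, as.integer(round(dens * sv$area_km2)))
  readr::write_csv(sv, paths$surveys)

  jsonlite::write_json(sim$truth[c("de_true", "sigma_true", "expected_slope")],
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
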
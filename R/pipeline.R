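#' Read an analysis configuration
#'
#' Reads a flat YAML key-value file describing one full analysis run and
#' fills in every default explicitly, so the configuration echoed into the
#' report is complete (no silent defaults).
#'
#' Recognized keys: paths (`genepop`, `site_table`, `distance`,
#' `connectivity`, `surveys`), `min_site_n` (default 5), `ibd_region`
#' (site ids; default = `in_ibd_region` flags of the site table),
#' `outlier_site` (site excluded from the refined IBD fit; optional),
#' `pcrit` (0.02), `mating_model` ("monogamy"), `adult_lifespan` (7.05),
#' `age_at_maturity` (1.68), `ratio_sd` (0.186), `region_length_km` (130),
#' `reef_area_km2` (648), `n_draws` (1e5), `n_permutations` (999),
#' `exceedance_thresholds_km` (c(11, 17)), `seed` (1).
#'
#' @param path YAML file path.
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  defaults <- list(
    genepop = NULL, site_table = NULL, distance = NULL,
    connectivity = NULL, surveys = NULL,
    min_site_n = 5, ibd_region = NULL, outlier_site = NULL,
    pcrit = 0.02, mating_model = "monogamy",
    adult_lifespan = 7.05, age_at_maturity = 1.68, ratio_sd = 0.186,
    region_length_km = 130, reef_area_km2 = 648,
    n_draws = 1e5, n_permutations = 999,
    exceedance_thresholds_km = c(11, 17), seed = 1
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  for (k in c("genepop", "site_table", "distance", "connectivity", "surveys")) {
    cfg[[k]] <- resolve(cfg[[k]])
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      abort(sprintf("config path `%s` does not exist: %s", k, cfg[[k]]))
    }
  }
  structure(cfg, class = "analysis_config")
}

#' Run the full dispersal analysis
#'
#' Executes the complete inference chain on one configuration: site
#' filtering, pairwise F_ST and linearization, Mantel tests of
#' isolation-by-distance (all sites, then excluding the designated outlier
#' site), the IBD regression, the LD estimate of the effective number of
#' breeders on the pooled IBD-region sample, the overlapping-generations
#' adjustment to effective size and linear effective density, the
#' dispersal-spread point estimate with Monte-Carlo error propagation and
#' exceedance fractions, the census-density estimate, and — when a
#' connectivity matrix is supplied — the isolation-by-oceanography
#' comparisons. Stages whose inputs are absent are recorded as skipped
#' rather than failing the run.
#'
#' The outlier site is a configuration designation, not an automated
#' detection: departures from an IBD trend are judged by inspection.
#'
#' @param cfg An `analysis_config` from [read_analysis_config()], or a
#'   list of the same shape.
#' @return An `analysis_report`: named list of per-stage results plus
#'   `config` (echo), `skipped`, `version` and `seed`.
#' @export
run_full_analysis <- function(cfg) {
  report <- list(config = unclass(cfg), skipped = character(0),
                 version = as.character(utils::packageVersion("ibdkernel")),
                 seed = cfg$seed)
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "ibd_stage_failure", partial_report = report)
    })
  }

  if (is.null(cfg$genepop)) abort("config must point at a genepop file")
  g <- stage("genotype_io", {
    site_ids <- NULL
    if (!is.null(cfg$site_table)) {
      st <- read_site_table(cfg$site_table)
      site_ids <- st$site_id
      report$site_table <- st
    }
    gg <- read_genepop(cfg$genepop, site_ids = site_ids)
    filter_sites(gg, cfg$min_site_n)
  })
  report$site_sizes <- site_sizes(g)

  fst <- stage("fst", pairwise_fst(g))
  report$fst <- tidy(fst)
  linfst <- dist_matrix(linearize_fst(as.matrix(fst)), "linearized_fst")

  ibd_region <- cfg$ibd_region
  if (is.null(ibd_region) && !is.null(report$site_table) &&
      "in_ibd_region" %in% names(report$site_table)) {
    ibd_region <- report$site_table$site_id[report$site_table$in_ibd_region]
  }
  ibd_region <- intersect(ibd_region %||% sites_of(g), sites_of(g))

  if (is.null(cfg$distance)) {
    report$skipped <- c(report$skipped, "mantel_ibd", "ibd_regression",
                        "sigma_propagation")
  } else {
    geo <- stage("distance_io",
                 align_labels(read_distance_matrix(cfg$distance),
                              sites_of(g), "distance"))
    report$mantel_all <- stage("mantel_ibd",
      tidy(mantel(dist_matrix(geo, "geographic_km"), linfst,
                  n_perm = cfg$n_permutations)))
    keep <- setdiff(sites_of(g), cfg$outlier_site)
    geo_k <- geo[keep, keep]
    lin_k <- as.matrix(linfst)[keep, keep]
    report$mantel_no_outlier <- stage("mantel_ibd",
      tidy(mantel(dist_matrix(geo_k, "geographic_km"),
                  dist_matrix(lin_k, "linearized_fst"),
                  n_perm = cfg$n_permutations)))
    ibd_fit <- stage("ibd_regression",
      ibd_regression(dist_matrix(geo_k, "geographic_km"),
                     dist_matrix(lin_k, "linearized_fst")))
    report$ibd_fit <- glance(ibd_fit)
  }

  nb <- stage("ld_nb", {
    pool <- filter_sites(g, 1)
    pool <- genotypes(tibble::as_tibble(pool)[pool$site %in% ibd_region, ],
                      loci = loci_of(pool), sites = ibd_region)
    ld_nb(pool, pcrit = cfg$pcrit, mating_model = cfg$mating_model)
  })
  report$nb <- tidy(nb)

  ratio <- nb_ne_ratio(cfg$adult_lifespan, cfg$age_at_maturity, cfg$ratio_sd)
  report$ratio <- list(ratio = ratio$ratio, ratio_sd = ratio$ratio_sd)
  if (is.finite(nb$nb_point)) {
    adj <- ne_from_nb(nb$nb_point, ratio)
    ci_ne <- c(NA_real_, NA_real_)
    if (is.finite(nb$ci_low) && nb$ci_low > 0) {
      ci_ne[1] <- ne_from_nb(nb$ci_low, ratio)$ne
    }
    if (!is.na(nb$ci_high)) {
      ci_ne[2] <- if (is.finite(nb$ci_high))
        ne_from_nb(nb$ci_high, ratio)$ne else Inf
    }
    de <- linear_effective_density(adj$ne, cfg$region_length_km,
                                   ci_ne[1], ci_ne[2])
    report$effective_density <- list(nb_adjusted = adj$nb_adjusted,
                                     ne = adj$ne, de = de$de,
                                     de_ci_low = de$ci_low,
                                     de_ci_high = de$ci_high)

    if (!is.null(report$ibd_fit) && report$ibd_fit$slope > 0 &&
        is.finite(nb$ci_low) && nb$ci_low > 0 && nb$ci_low < nb$nb_point) {
      sig <- stage("sigma_propagation",
        propagate_sigma(nb$nb_point, nb$ci_low, ratio$ratio, ratio$ratio_sd,
                        report$ibd_fit$slope, report$ibd_fit$slope_se,
                        cfg$region_length_km, n_draws = cfg$n_draws,
                        seed = cfg$seed))
      report$sigma <- tidy(sig)
      report$exceedance <- tibble::tibble(
        threshold_km = cfg$exceedance_thresholds_km,
        fraction = vapply(cfg$exceedance_thresholds_km,
                          function(th) exceedance_fraction(sig, th),
                          numeric(1)))
    } else {
      report$skipped <- c(report$skipped, "sigma_propagation")
    }
  } else {
    report$skipped <- c(report$skipped, "effective_density", "sigma_propagation")
  }

  if (is.null(cfg$surveys)) {
    report$skipped <- c(report$skipped, "census")
  } else {
    cen <- stage("census",
      linear_census_density(read_surveys(cfg$surveys), cfg$reef_area_km2,
                            cfg$region_length_km, seed = cfg$seed))
    report$census <- tidy(cen)
  }

  if (is.null(cfg$connectivity)) {
    report$skipped <- c(report$skipped, "connectivity")
  } else {
    stage("connectivity", {
      conn <- read_connectivity(cfg$connectivity)
      shared <- intersect(rownames(conn), sites_of(g))
      conn_s <- conn[shared, shared]
      lin_s <- as.matrix(linfst)[shared, shared]
      report$connectivity_mantel <- tidy(connectivity_vs_genetics(
        conn_s, dist_matrix(lin_s, "linearized_fst"),
        mode = "mantel", n_perm = cfg$n_permutations))
      if (!is.null(cfg$distance)) {
        geo_s <- read_distance_matrix(cfg$distance)[shared, shared]
        report$connectivity_partial <- tidy(connectivity_vs_genetics(
          conn_s, dist_matrix(lin_s, "linearized_fst"),
          mode = "partial_mantel",
          control = dist_matrix(geo_s, "geographic_km"),
          n_perm = cfg$n_permutations))
      }
      if (!is.null(cfg$outlier_site) && cfg$outlier_site %in% shared) {
        report$connectivity_focal <- tidy(connectivity_vs_genetics(
          conn_s, dist_matrix(lin_s, "linearized_fst"),
          mode = "focal_regression", focal_site = cfg$outlier_site))
      }
      NULL
    })
  }

  structure(report, class = "analysis_report")
}

#' Write an analysis report as JSON
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  stages:", paste(setdiff(names(x), c("config", "skipped", "version",
                                             "seed")), collapse = ", "), "\n")
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
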
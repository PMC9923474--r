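#' Read a potential-connectivity matrix
#'
#' Reads a square labeled CSV of directed larval-transport probabilities
#' (source rows to sink columns) produced by an ocean-circulation particle
#' simulation. Rows need not sum to one: larvae lost offshore simply do
#' not arrive anywhere.
#'
#' @param path CSV path; header row, labels in the first column.
#' @param pld_days Optional pelagic-larval-duration metadata (days).
#' @param window Optional free-text description of the averaging window.
#' @return A `connectivity_matrix`: matrix with attributes `pld_days` and
#'   `window`.
#' @export
read_connectivity <- function(path, pld_days = NA_real_, window = NA_character_) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) abort("connectivity matrix must be square")
  if (!identical(rownames(m), colnames(m))) {
    abort("connectivity labels must match between rows and columns")
  }
  if (any(m < 0) || any(m > 1)) {
    abort("connectivity entries must be probabilities in [0, 1]")
  }
  structure(m, pld_days = pld_days, window = window,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @rdname read_connectivity
#' @param x A `connectivity_matrix`.
#' @export
write_connectivity <- function(x, path) {
  write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' Assign sampling sites to their nearest release sites
#'
#' Maps each genetic sampling site to the closest particle release site by
#' great-circle distance. Sampling sites sharing a release site form a
#' merge group: their genotype samples should be pooled (see
#' [merge_sites()]) before comparing genetic distance with connectivity,
#' since the ocean model cannot distinguish them.
#'
#' @param sites Data frame with `site_id`, `longitude`, `latitude`
#'   (decimal degrees), e.g. from [read_site_table()].
#' @param release_coords Data frame with `release_id`, `longitude`,
#'   `latitude`.
#' @return List with `assignment` (tibble: `site_id`, `release_id`,
#'   `distance_km`) and `merge_groups` (list of character vectors of
#'   sampling sites sharing a release site; groups of one omitted).
#' @export
assign_release_sites <- function(sites, release_coords) {
  for (col in c("longitude", "latitude")) {
    if (anyNA(sites[[col]]) || is.null(sites[[col]])) {
      abort("sampling sites need complete coordinates")
    }
    if (anyNA(release_coords[[col]]) || is.null(release_coords[[col]])) {
      abort("release sites need complete coordinates")
    }
  }
  d <- geosphere::distm(as.matrix(sites[c("longitude", "latitude")]),
                        as.matrix(release_coords[c("longitude", "latitude")]),
                        fun = geosphere::distHaversine) / 1000
  nearest <- apply(d, 1L, which.min)
  assignment <- tibble::tibble(
    site_id = as.character(sites$site_id),
    release_id = as.character(release_coords$release_id)[nearest],
    distance_km = d[cbind(seq_len(nrow(d)), nearest)]
  )
  groups <- split(assignment$site_id, assignment$release_id)
  groups <- unname(groups[vapply(groups, length, 1L) > 1L])
  list(assignment = assignment, merge_groups = groups)
}

#' Symmetrize a directed connectivity matrix
#'
#' Reduces the two directed transport probabilities of each unordered site
#' pair to one value: arithmetic `mean` of the two directions (default,
#' the least-assumption choice), `max` (the stronger direction governs),
#' or `forward` (keep the matrix as is; rejected by Mantel, which needs
#' symmetry).
#'
#' @param conn A `connectivity_matrix` or labeled square matrix.
#' @param method `"mean"`, `"max"` or `"forward"`.
#' @return A plain labeled matrix (symmetric unless `"forward"`).
#' @export
symmetrize_connectivity <- function(conn, method = c("mean", "max", "forward")) {
  method <- match.arg(method)
  m <- unclass(as.matrix(conn))
  attr(m, "pld_days") <- NULL; attr(m, "window") <- NULL
  switch(method,
         mean = (m + t(m)) / 2,
         max = pmax(m, t(m)),
         forward = m)
}

#' Compare potential connectivity with genetic distance
#'
#' Tests isolation-by-oceanography: does larval-transport probability
#' explain pairwise genetic distance? Three modes:
#' * `mantel` - Mantel test of symmetrized connectivity against
#'   linearized F_ST. A negative correlation is the expected signal
#'   (better-connected pairs are genetically closer), so with the default
#'   one-tailed "greater" convention a strong negative association shows
#'   up as r < 0 with p near 1 (test `tail = "less"` for the complement).
#' * `partial_mantel` - as above while controlling for a third matrix
#'   (typically geographic distance), or geographic distance against
#'   F_ST controlling for connectivity if you swap the arguments.
#' * `focal_regression` - OLS of linearized F_ST on connectivity over the
#'   pairs containing one focal site (used for a site that departs from
#'   the isolation-by-distance trend).
#'
#' @param conn A `connectivity_matrix` (directed) or symmetric matrix.
#' @param linfst Linearized-F_ST [dist_matrix] with matching labels.
#' @param mode `"mantel"`, `"partial_mantel"` or `"focal_regression"`.
#' @param focal_site Focal site id (focal_regression mode).
#' @param control Control [dist_matrix] (partial_mantel mode).
#' @param symmetrization Passed to [symmetrize_connectivity()].
#' @param n_perm,seed,tail Passed to the Mantel machinery.
#' @return A `mantel_result`, or for `focal_regression` a `focal_fit`
#'   (list with `slope`, `intercept`, `r_squared`, `p_value`, `data`).
#' @export
connectivity_vs_genetics <- function(conn, linfst,
                                     mode = c("mantel", "partial_mantel",
                                              "focal_regression"),
                                     focal_site = NULL, control = NULL,
                                     symmetrization = "mean",
                                     n_perm = 999, seed = NULL,
                                     tail = "greater") {
  mode <- match.arg(mode)
  cs <- symmetrize_connectivity(conn, symmetrization)
  if (mode == "mantel") {
    return(mantel(dist_matrix_like(cs), linfst, n_perm = n_perm, seed = seed,
                  tail = tail))
  }
  if (mode == "partial_mantel") {
    if (is.null(control)) abort("partial_mantel needs a `control` matrix")
    return(partial_mantel(dist_matrix_like(cs), linfst, control,
                          n_perm = n_perm, seed = seed, tail = tail))
  }
  # focal regression over the focal site's pairs
  if (is.null(focal_site)) abort("focal_regression needs `focal_site`")
  m <- as.matrix(linfst)
  if (!focal_site %in% rownames(m) || !focal_site %in% rownames(cs)) {
    abort(paste0("focal site not present: ", focal_site), class = "ibd_lookup")
  }
  others <- setdiff(rownames(m), focal_site)
  others <- intersect(others, rownames(cs))
  if (length(others) < 3L) abort("fewer than 3 focal pairs")
  dat <- tibble::tibble(
    other_site = others,
    connectivity = cs[focal_site, others],
    linearized_fst = m[focal_site, others]
  )
  fit <- lm(linearized_fst ~ connectivity, data = dat)
  sm <- summary(fit)
  structure(list(
    focal_site = focal_site,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["connectivity", "Pr(>|t|)"],
    n_pairs = nrow(dat), data = dat, fit = fit
  ), class = "focal_fit")
}

# wrap a symmetric matrix for mantel() without a semantic kind check
dist_matrix_like <- function(m) {
  diag(m) <- 0
  m
}

#' @export
print.focal_fit <- function(x, ...) {
  cat(sprintf("Focal regression (site %s, %d pairs): slope = %.4g, R^2 = %.3f, p = %.4g\n",
              x$focal_site, x$n_pairs, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
tidy.focal_fit <- function(x, ...) {
  tibble::tibble(focal_site = x$focal_site, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 p_value = x$p_value, n_pairs = x$n_pairs)
}

#' @export
glance.focal_fit <- function(x, ...) tidy(x)
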
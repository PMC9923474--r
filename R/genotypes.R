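#' Diploid multilocus genotype tables
#'
#' A `genotypes` object is a long tibble of diploid allele calls with one row
#' per individual and locus, the container every genetic statistic in this
#' package consumes. Columns are `id` (individual label), `site` (sampling
#' site id), `locus` (locus name) and the two allele codes `a1`, `a2`
#' (positive integers; the pair is unordered and stored sorted). A fully
#' missing call is coded `(0, 0)`; a half-missing call (exactly one zero) is
#' invalid because diploid genotype files have no half-call semantics.
#'
#' Site order and locus order are kept as attributes so that downstream
#' matrices (pairwise F_ST, distance matrices) have a stable, shared label
#' order.
#'
#' @param x A data frame with columns `id`, `site`, `locus`, `a1`, `a2`.
#'   Every individual must have exactly one row per locus.
#' @param loci Optional character vector fixing locus order; defaults to
#'   order of first appearance.
#' @param sites Optional character vector fixing site order; defaults to
#'   order of first appearance.
#'
#' @return A `genotypes` object (a tibble subclass).
#' @examples
#' g <- genotypes(tibble::tibble(
#'   id = rep(c("i1", "i2"), each = 2),
#'   site = "A",
#'   locus = rep(c("L1", "L2"), 2),
#'   a1 = c(101, 120, 103, 120),
#'   a2 = c(103, 122, 103, 0)
#' ))
#' # (120, 0) is half-missing and rejected:
#' # genotypes() above fails; code (0, 0) for a missing call instead.
#' @export
genotypes <- function(x, loci = NULL, sites = NULL) {
  x <- tibble::as_tibble(x)
  needed <- c("id", "site", "locus", "a1", "a2")
  if (!all(needed %in% names(x))) {
    abort(paste0("genotype table needs columns: ",
                 paste(setdiff(needed, names(x)), collapse = ", ")))
  }
  x$id <- as.character(x$id)
  x$site <- as.character(x$site)
  x$locus <- as.character(x$locus)
  x$a1 <- as.integer(x$a1)
  x$a2 <- as.integer(x$a2)
  if (nrow(x) == 0L) abort("empty genotype table", class = "ibd_empty_input")
  if (anyNA(x$a1) || anyNA(x$a2)) abort("allele codes must be integers, not NA")
  if (any(x$a1 < 0L | x$a2 < 0L)) abort("allele codes must be non-negative")
  half <- xor(x$a1 == 0L, x$a2 == 0L)
  if (any(half)) {
    abort(sprintf("half-missing genotype call(s), e.g. individual '%s' locus '%s'",
                  x$id[which(half)[1]], x$locus[which(half)[1]]),
          class = "ibd_half_missing")
  }
  # unordered pair: store sorted
  lo <- pmin(x$a1, x$a2)
  hi <- pmax(x$a1, x$a2)
  x$a1 <- lo
  x$a2 <- hi

  loci <- loci %||% unique(x$locus)
  sites <- sites %||% unique(x$site)
  if (!setequal(loci, unique(x$locus))) abort("`loci` does not match table loci")
  if (!setequal(sites, unique(x$site))) abort("`sites` does not match table sites")

  # one row per (individual, locus), same locus set for everyone
  cnt <- table(x$id, x$locus)
  if (any(cnt != 1L)) {
    abort("every individual needs exactly one row per locus",
          class = "ibd_ragged")
  }
  key <- paste(x$id, x$site)
  if (anyDuplicated(unique(data.frame(id = x$id, site = x$site))$id) > 0L) {
    abort("an individual id appears in more than one site")
  }

  x <- dplyr::arrange(x,
                      match(.data$site, sites),
                      match(.data$id, unique(x$id)),
                      match(.data$locus, loci))
  structure(x,
            loci = loci, sites = sites,
            class = c("genotypes", class(tibble::tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("<genotypes> %d individuals, %d loci, %d sites\n",
              n_individuals(x), length(loci_of(x)), length(sites_of(x))))
  NextMethod()
}

#' Accessors for genotype objects
#'
#' @param g A [genotypes] object.
#' @return `loci_of()` and `sites_of()` return character vectors in stored
#'   order; `n_individuals()` an integer; `site_sizes()` a tibble with
#'   columns `site` and `n`.
#' @export
loci_of <- function(g) attr(g, "loci")

#' @rdname loci_of
#' @export
sites_of <- function(g) attr(g, "sites")

#' @rdname loci_of
#' @export
n_individuals <- function(g) length(unique(g$id))

#' @rdname loci_of
#' @export
site_sizes <- function(g) {
  ind <- dplyr::distinct(tibble::as_tibble(g)[c("id", "site")])
  out <- dplyr::count(ind, .data$site, name = "n")
  out[match(sites_of(g), out$site), , drop = FALSE]
}

# wide allele matrices (individuals x loci) for numeric work
gt_wide <- function(g) {
  loci <- loci_of(g)
  ind <- dplyr::distinct(tibble::as_tibble(g)[c("id", "site")])
  n <- nrow(ind)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(ind$id, loci))
  a2 <- a1
  ri <- match(g$id, ind$id)
  ci <- match(g$locus, loci)
  a1[cbind(ri, ci)] <- g$a1
  a2[cbind(ri, ci)] <- g$a2
  list(a1 = a1, a2 = a2, id = ind$id, site = ind$site)
}

# rebuild a genotypes object from wide matrices
gt_from_wide <- function(a1, a2, id, site, loci, sites = unique(site)) {
  n <- length(id)
  tbl <- tibble::tibble(
    id = rep(id, each = length(loci)),
    site = rep(site, each = length(loci)),
    locus = rep(loci, times = n),
    a1 = as.integer(t(a1)),
    a2 = as.integer(t(a2))
  )
  genotypes(tbl, loci = loci, sites = sites)
}

#' Compare two genotype datasets up to individual labels
#'
#' Two datasets are considered equal when they have the same loci (in
#' order), the same sites (in order), and for each site the same multiset of
#' multilocus genotypes. Individual labels are free text in Genepop files
#' and are ignored.
#'
#' @param a,b [genotypes] objects.
#' @return Logical scalar.
#' @export
gt_equal <- function(a, b) {
  if (!identical(loci_of(a), loci_of(b))) return(FALSE)
  if (!identical(sites_of(a), sites_of(b))) return(FALSE)
  sig <- function(g) {
    w <- gt_wide(g)
    code <- apply(cbind(w$a1, w$a2), 1L, paste, collapse = ",")
    split(code, w$site)
  }
  sa <- sig(a); sb <- sig(b)
  all(vapply(sites_of(a),
             function(s) identical(sort(sa[[s]]), sort(sb[[s]])),
             logical(1)))
}

#' Drop sites with small sample sizes
#'
#' Removes every site whose sample size falls below `min_n`, the screening
#' applied before any between-site statistic (sites with fewer than five
#' fish carry almost no information about allele frequencies).
#'
#' @param g A [genotypes] object.
#' @param min_n Minimum number of individuals a site must have to be kept.
#' @return A [genotypes] object containing only the retained sites; locus
#'   list unchanged.
#' @export
filter_sites <- function(g, min_n = 5) {
  stopifnot(min_n >= 1)
  sz <- site_sizes(g)
  keep <- sz$site[sz$n >= min_n]
  if (length(keep) == 0L) {
    abort(sprintf("all sites have fewer than %d individuals", min_n),
          class = "ibd_empty_result")
  }
  tbl <- tibble::as_tibble(g)[g$site %in% keep, , drop = FALSE]
  genotypes(tbl, loci = loci_of(g), sites = intersect(sites_of(g), keep))
}

#' Merge sampling sites into one
#'
#' Pools the individuals of two or more sites under a single new site id,
#' as done when physically close sites share one oceanographic release
#' cell. Total individual count and all genotypes are conserved.
#'
#' @param g A [genotypes] object.
#' @param site_ids Two or more distinct site ids to merge.
#' @param new_id Site id for the merged site; it takes the position of the
#'   first merged site in the site order.
#' @return A [genotypes] object.
#' @export
merge_sites <- function(g, site_ids, new_id) {
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) abort("duplicate ids in `site_ids`")
  if (length(site_ids) < 2L) abort("need at least two sites to merge")
  missing_ids <- setdiff(site_ids, sites_of(g))
  if (length(missing_ids)) {
    abort(paste0("unknown site id(s): ", paste(missing_ids, collapse = ", ")),
          class = "ibd_lookup")
  }
  tbl <- tibble::as_tibble(g)
  tbl$site[tbl$site %in% site_ids] <- new_id
  old <- sites_of(g)
  pos <- min(match(site_ids, old))
  new_order <- old
  new_order[pos] <- new_id
  new_order <- setdiff(new_order, setdiff(site_ids, new_id))
  genotypes(tbl, loci = loci_of(g), sites = new_order)
}

#' Read a site metadata table
#'
#' Reads the sidecar CSV describing sampling sites: short id, name, island,
#' coordinates and whether the site belongs to the isolation-by-distance
#' study region.
#'
#' @param path CSV with header
#'   `site_id,name,island,longitude,latitude,in_ibd_region` (coordinates
#'   optional, `in_ibd_region` logical or 0/1).
#' @return A tibble.
#' @export
read_site_table <- function(path) {
  st <- readr::read_csv(path, show_col_types = FALSE)
  if (!"site_id" %in% names(st)) abort("site table needs a `site_id` column")
  st$site_id <- as.character(st$site_id)
  if (anyDuplicated(st$site_id)) abort("site ids must be unique")
  if ("in_ibd_region" %in% names(st)) {
    st$in_ibd_region <- as.logical(st$in_ibd_region)
  }
  st
}
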
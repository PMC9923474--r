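#' Read a Genepop genotype file
#'
#' Parses the classic Genepop text dialect for diploid data: a title line,
#' locus names (one per line, or comma-separated), `pop` separator lines,
#' then one line per individual of the form `label , 0101 0203 ...`. Both
#' 2- and 3-digit allele coding are supported; `auto` infers the width from
#' the genotype token length. A genotype is missing iff both alleles decode
#' to zero; a half-missing call (exactly one zero) is rejected.
#'
#' Genepop individual labels are free text, so site ids come from the
#' `site_ids` argument when given; otherwise the first individual label of
#' each `pop` block is used as that site's id (the common convention of
#' labelling every fish with its site), falling back to `pop_<k>` when
#' those labels are not unique.
#'
#' @param path Path to a Genepop file.
#' @param allele_digits `"auto"` (default), `2` or `3`.
#' @param site_ids Optional character vector of site ids, one per `pop`
#'   block.
#' @return A [genotypes] object.
#' @export
read_genepop <- function(path, allele_digits = "auto", site_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("﻿", "", lines, fixed = TRUE)
  trimmed <- trimws(lines)
  if (length(trimmed) < 3L) abort("not a Genepop file: too few lines",
                                  class = "ibd_empty_input")
  is_pop <- grepl("^pop\\b", trimmed, ignore.case = TRUE) & !grepl(",", trimmed)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("no `pop` separator found",
                              class = "ibd_empty_input")
  header <- if (first_pop > 2L) trimmed[2:(first_pop - 1L)] else character(0)
  header <- header[nzchar(header)]
  loci <- unlist(strsplit(header, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) abort("zero loci in header", class = "ibd_empty_input")

  blocks <- cumsum(is_pop)
  body_idx <- which(blocks > 0L & !is_pop & nzchar(trimmed))
  if (length(body_idx) == 0L) abort("no individuals found",
                                    class = "ibd_empty_input")
  n_pops <- max(blocks)

  parse_row <- function(i) {
    ln <- trimmed[i]
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0L) {
      abort(sprintf("line %d: missing `,` between label and genotypes", i),
            class = "ibd_parse")
    }
    label <- trimws(substr(ln, 1L, comma - 1L))
    toks <- strsplit(trimws(substr(ln, comma + 1L, nchar(ln))), "[ \t]+")[[1]]
    list(line = i, pop = blocks[i], label = label, toks = toks)
  }
  rows <- lapply(body_idx, parse_row)

  tok_lens <- unique(nchar(unlist(lapply(rows, `[[`, "toks"))))
  digits <- if (identical(allele_digits, "auto")) {
    if (length(tok_lens) != 1L) {
      abort(sprintf("mixed genotype token lengths (%s): cannot infer coding",
                    paste(tok_lens, collapse = ", ")), class = "ibd_parse")
    }
    if (tok_lens == 4L) 2L else if (tok_lens == 6L) 3L else
      abort(sprintf("token length %d is neither 2- nor 3-digit diploid coding",
                    tok_lens), class = "ibd_parse")
  } else {
    as.integer(allele_digits)
  }
  if (!digits %in% c(2L, 3L)) abort("allele_digits must be 2, 3 or \"auto\"")

  recs <- lapply(rows, function(r) {
    toks <- r$toks
    if (length(toks) != length(loci)) {
      abort(sprintf("line %d: %d genotype tokens but %d loci",
                    r$line, length(toks), length(loci)), class = "ibd_parse")
    }
    bad <- nchar(toks) != 2L * digits | grepl("[^0-9]", toks)
    if (any(bad)) {
      abort(sprintf("line %d: malformed genotype token '%s' for %d-digit coding",
                    r$line, toks[which(bad)[1]], digits), class = "ibd_parse")
    }
    tibble::tibble(
      pop = r$pop, label = r$label, locus = loci,
      a1 = as.integer(substr(toks, 1L, digits)),
      a2 = as.integer(substr(toks, digits + 1L, 2L * digits))
    )
  })
  tbl <- dplyr::bind_rows(recs)

  first_labels <- vapply(split(vapply(rows, `[[`, "", "label"),
                               vapply(rows, `[[`, 0, "pop")),
                         `[`, "", 1L)
  if (is.null(site_ids)) {
    site_ids <- unname(first_labels[as.character(seq_len(n_pops))])
    if (anyDuplicated(site_ids)) site_ids <- paste0("pop_", seq_len(n_pops))
  }
  if (length(site_ids) != n_pops) {
    abort(sprintf("%d site ids supplied for %d pop blocks",
                  length(site_ids), n_pops))
  }
  tbl$site <- site_ids[tbl$pop]
  # individual ids: site id + running index within site
  idx <- ave(seq_along(rows), vapply(rows, `[[`, 0, "pop"), FUN = seq_along)
  ids <- sprintf("%s_%02d", site_ids[vapply(rows, `[[`, 0, "pop")], idx)
  tbl$id <- rep(ids, each = length(loci))
  genotypes(tbl[c("id", "site", "locus", "a1", "a2")],
            loci = loci, sites = site_ids)
}

#' Write a Genepop genotype file
#'
#' Writes a [genotypes] object in Genepop dialect: title line, one locus
#' name per line, `pop` separators, and individual lines labelled with
#' their site id (so a re-read recovers the same sites). Missing calls are
#' written as all-zero tokens.
#'
#' @param g A [genotypes] object.
#' @param path Output path.
#' @param allele_digits 2 or 3 (default 3; microsatellite repeat codes
#'   routinely exceed 99).
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, allele_digits = 3, title = "ibdkernel export") {
  digits <- as.integer(allele_digits)
  if (!digits %in% c(2L, 3L)) abort("allele_digits must be 2 or 3")
  w <- gt_wide(g)
  mx <- max(w$a1, w$a2)
  if (mx >= 10^digits) {
    abort(sprintf("allele code %d does not fit %d-digit coding", mx, digits),
          class = "ibd_width")
  }
  fmt <- function(a, b) paste0(sprintf("%0*d", digits, a),
                               sprintf("%0*d", digits, b))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci_of(g), con)
  for (s in sites_of(g)) {
    writeLines("pop", con)
    rows <- which(w$site == s)
    for (r in rows) {
      toks <- fmt(w$a1[r, ], w$a2[r, ])
      writeLines(paste0(s, " ,  ", paste(toks, collapse = " ")), con)
    }
  }
  invisible(path)
}
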
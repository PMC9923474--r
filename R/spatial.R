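#' Labeled pairwise distance matrices
#'
#' Light wrapper that validates a square labeled matrix for use in Mantel
#' tests and the isolation-by-distance regression. Geographic and genetic
#' kinds must be symmetric with a zero diagonal; connectivity matrices may
#' be asymmetric (transport probabilities are directed).
#'
#' @param m Square numeric matrix with identical, unique row and column
#'   names.
#' @param kind One of `"geographic_km"`, `"linearized_fst"`,
#'   `"connectivity_probability"`.
#' @return The matrix with class `dist_matrix` and attribute `kind`.
#' @export
dist_matrix <- function(m, kind = c("geographic_km", "linearized_fst",
                                    "connectivity_probability")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    abort("matrix needs identical row and column labels")
  }
  if (anyDuplicated(rownames(m))) abort("labels must be unique")
  if (kind != "connectivity_probability") {
    if (max(abs(m - t(m))) > 1e-8) abort(paste(kind, "matrix must be symmetric"))
    if (any(abs(diag(m)) > 1e-12)) abort("diagonal must be zero")
    m <- (m + t(m)) / 2
    diag(m) <- 0
  }
  structure(m, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @rdname dist_matrix
#' @param path CSV path; square layout with a header row and the labels in
#'   the first column.
#' @export
read_distance_matrix <- function(path, kind = "geographic_km") {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  dist_matrix(as.matrix(df), kind = kind)
}

#' @rdname dist_matrix
#' @param x A `dist_matrix`.
#' @export
write_distance_matrix <- function(x, path) {
  write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

# reorder a matrix to a reference label order, failing on mismatch
align_labels <- function(m, labels, what = "matrix") {
  if (!setequal(rownames(m), labels)) {
    abort(sprintf("%s labels do not match: {%s} vs {%s}", what,
                  paste(rownames(m), collapse = ","),
                  paste(labels, collapse = ",")), class = "ibd_labels")
  }
  m[labels, labels, drop = FALSE]
}

lower_vec <- function(m) m[lower.tri(m)]

# all permutations of 1:n as an n! x n integer matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub + (sub >= pos), rep(pos, nrow(sub)))
    # insert n-th element value `pos`: remap so values are 1..n
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

perm_count <- function(n) factorial(n)

#' Mantel permutation test
#'
#' Pearson correlation between the lower-triangle entries of two aligned
#' symmetric distance matrices, with significance from simultaneous
#' row-and-column permutation of the first matrix. When the number of
#' possible relabelings is no larger than the requested permutations
#' (`n! - 1 <= n_perm`), all of them are enumerated and the test is exact;
#' the reported permutation count is then `n! - 1`, matching the
#' minimum-permutation correction applied by standard Mantel
#' implementations (e.g. 5039 for 7 sites, 719 for 6, 23 for 4).
#'
#' @param A,B [dist_matrix] objects (or labeled symmetric matrices) with
#'   the same labels; at least 4 sites.
#' @param n_perm Requested number of permutations (default 999).
#' @param seed Optional integer seed (used in sampled mode).
#' @param tail `"greater"` (default; positive association), `"less"`, or
#'   `"two-sided"`.
#' @param mode `"auto"` (default: enumerate exhaustively whenever
#'   `n! - 1 <= n_perm`), or force `"sampled"` / `"exhaustive"`.
#' @return A `mantel_result`: list with `r`, `p_value`, `n_permutations`,
#'   `mode` (`"exhaustive"` or `"sampled"`), `tail`, `n_sites`.
#' @export
mantel <- function(A, B, n_perm = 999, seed = NULL,
                   tail = c("greater", "less", "two-sided"),
                   mode = c("auto", "sampled", "exhaustive")) {
  tail <- match.arg(tail)
  mode <- match.arg(mode)
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (n < 4L) abort("need at least 4 sites for a Mantel test")
  B <- align_labels(B, rownames(A), "second matrix")
  check_sym <- function(m) if (max(abs(m - t(m))) > 1e-8)
    abort("Mantel requires symmetric matrices", class = "ibd_asymmetric")
  check_sym(A); check_sym(B)
  va <- lower_vec(A); vb <- lower_vec(B)
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("constant matrix: correlation undefined", class = "ibd_degenerate")
  }
  r_obs <- cor(va, vb)
  perm_r <- mantel_perm_r(A, function(Ap) cor(lower_vec(Ap), vb),
                          n, n_perm, seed, mode)
  res <- perm_p(r_obs, perm_r$r, perm_r$mode, tail)
  structure(list(r = r_obs, p_value = res, n_permutations = perm_r$n_perm,
                 mode = perm_r$mode, tail = tail, n_sites = n,
                 method = "mantel"),
            class = "mantel_result")
}

#' Partial Mantel permutation test
#'
#' First-order partial correlation
#' \eqn{r_{AB.C} = (r_{AB} - r_{AC} r_{BC}) / \sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}}
#' between two distance matrices while controlling for a third, with the
#' null distribution built by permuting the first matrix (rows and columns
#' simultaneously), under the same exhaustive-vs-sampled rule as
#' [mantel()].
#'
#' @inheritParams mantel
#' @param C Control [dist_matrix], aligned with `A` and `B`.
#' @return A `mantel_result`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999, seed = NULL,
                           tail = c("greater", "less", "two-sided"),
                           mode = c("auto", "sampled", "exhaustive")) {
  tail <- match.arg(tail)
  mode <- match.arg(mode)
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  n <- nrow(A)
  if (n < 4L) abort("need at least 4 sites")
  B <- align_labels(B, rownames(A), "second matrix")
  C <- align_labels(C, rownames(A), "control matrix")
  vb <- lower_vec(B); vc <- lower_vec(C)
  r_bc <- cor(vb, vc)
  if (abs(r_bc) >= 1 - 1e-12) {
    abort("control matrix collinear with second matrix",
          class = "ibd_degenerate_control")
  }
  pcor <- function(Ap) {
    va <- lower_vec(Ap)
    r_ab <- cor(va, vb); r_ac <- cor(va, vc)
    if (abs(r_ac) >= 1 - 1e-12) {
      abort("control matrix collinear with first matrix",
            class = "ibd_degenerate_control")
    }
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- pcor(A)
  perm_r <- mantel_perm_r(A, pcor, n, n_perm, seed, mode)
  res <- perm_p(r_obs, perm_r$r, perm_r$mode, tail)
  structure(list(r = r_obs, p_value = res, n_permutations = perm_r$n_perm,
                 mode = perm_r$mode, tail = tail, n_sites = n,
                 method = "partial_mantel"),
            class = "mantel_result")
}

# permuted statistics under the exhaustive / sampled rule.
# Returns list(r = statistics including or excluding identity per mode,
#              mode, n_perm reported)
mantel_perm_r <- function(A, stat, n, n_perm, seed, mode = "auto") {
  if (mode == "exhaustive" ||
      (mode == "auto" && perm_count(n) - 1 <= n_perm)) {
    P <- all_permutations(n)
    r <- apply(P, 1L, function(p) stat(A[p, p, drop = FALSE]))
    list(r = r, mode = "exhaustive", n_perm = perm_count(n) - 1)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r <- replicate(n_perm, {
      p <- sample.int(n)
      stat(A[p, p, drop = FALSE])
    })
    list(r = r, mode = "sampled", n_perm = n_perm)
  }
}

perm_p <- function(r_obs, r_perm, mode, tail) {
  eps <- 1e-12
  hit <- switch(tail,
    greater = r_perm >= r_obs - eps,
    less = r_perm <= r_obs + eps,
    `two-sided` = abs(r_perm) >= abs(r_obs) - eps
  )
  if (mode == "exhaustive") {
    # r_perm covers all n! relabelings including the identity
    mean(hit)
  } else {
    (sum(hit) + 1) / (length(r_perm) + 1)
  }
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s: r = %.4f, p = %.4g (%s, %d permutations, %d sites, tail=%s)\n",
              x$method, x$r, x$p_value, x$mode, x$n_permutations, x$n_sites,
              x$tail))
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(method = x$method, r = x$r, p_value = x$p_value,
                 n_permutations = x$n_permutations, mode = x$mode,
                 tail = x$tail, n_sites = x$n_sites)
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' Isolation-by-distance regression
#'
#' Ordinary least-squares regression of pairwise linearized F_ST on
#' pairwise geographic distance (km), each unordered site pair contributing
#' one observation. The slope `m` (per km) is the quantity that enters the
#' one-dimensional dispersal-spread relation `sigma = 1/sqrt(4 De m)`;
#' pair non-independence is accepted, as is standard for this use.
#'
#' @param geo Geographic [dist_matrix] in km.
#' @param linfst Linearized-F_ST [dist_matrix] with the same labels.
#' @return An `ibd_fit`: list with `slope`, `intercept`, `slope_se`,
#'   `r_squared`, `n_pairs` and the pair table `data`. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
ibd_regression <- function(geo, linfst) {
  geo <- as.matrix(geo)
  linfst <- align_labels(as.matrix(linfst), rownames(geo), "genetic matrix")
  labs <- rownames(geo)
  idx <- which(lower.tri(geo), arr.ind = TRUE)
  dat <- tibble::tibble(
    site1 = labs[idx[, 2]], site2 = labs[idx[, 1]],
    distance_km = geo[idx], linearized_fst = linfst[idx]
  )
  if (nrow(dat) < 3L) abort("need at least 3 site pairs")
  if (sd(dat$distance_km) == 0) {
    abort("zero variance in distances: slope undefined", class = "ibd_degenerate")
  }
  fit <- lm(linearized_fst ~ distance_km, data = dat)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    slope_se = sm$coefficients["distance_km", "Std. Error"],
    r_squared = sm$r.squared,
    n_pairs = nrow(dat),
    data = dat,
    fit = fit
  ), class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat(sprintf("IBD regression: slope = %.4g +/- %.4g per km, R^2 = %.3f (%d pairs)\n",
              x$slope, x$slope_se, x$r_squared, x$n_pairs))
  invisible(x)
}

#' @export
tidy.ibd_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope_per_km"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(summary(x$fit)$coefficients[1, 2], x$slope_se))
}

#' @export
glance.ibd_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se,
                 intercept = x$intercept, r_squared = x$r_squared,
                 n_pairs = x$n_pairs)
}
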
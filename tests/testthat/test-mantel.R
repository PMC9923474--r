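test_that("mantel r respects affine relations between matrices", {
  set.seed(4)
  labs <- paste0("s", 1:6)
  A <- sym_mat(runif(15, 1, 100), labs)
  r1 <- mantel(dist_matrix(A, "geographic_km"),
               dist_matrix(2 * A + 3 - diag(3, 6), "geographic_km"))
  expect_equal(r1$r, 1)
  B <- -A
  diag(B) <- 0
  r2 <- mantel(A, B)
  expect_equal(r2$r, -1)
  expect_gt(r2$p_value, 0.9)
})

test_that("exhaustive mode reports n!-1 permutations and exact p-values", {
  set.seed(11)
  for (n in c(4, 6, 7)) {
    labs <- paste0("s", seq_len(n))
    A <- sym_mat(runif(n * (n - 1) / 2, 0, 50), labs)
    B <- sym_mat(A[lower.tri(A)] * 1e-5 + rnorm(n * (n - 1) / 2, 0, 2e-4), labs)
    res <- mantel(A, B, n_perm = 999999)
    expect_identical(res$mode, "exhaustive")
    expect_equal(res$n_permutations, factorial(n) - 1)
  }
  # the permutation counts the survey reports for 7, 6 and 4 sites
  expect_equal(factorial(7) - 1, 5039)
  expect_equal(factorial(6) - 1, 719)
  expect_equal(factorial(4) - 1, 23)
})

test_that("4-site p equals the 24-relabeling brute force", {
  set.seed(21)
  labs <- paste0("s", 1:4)
  for (rep in 1:3) {
    A <- sym_mat(runif(6, 1, 9), labs)
    B <- sym_mat(runif(6, 1, 9), labs)
    res <- mantel(A, B, n_perm = 999)
    orc <- oracle_mantel_exhaustive(A, B)
    expect_equal(res$r, orc$r)
    expect_equal(res$p_value, orc$p)
  }
})

test_that("sampled and exhaustive p-values agree for 5 sites", {
  set.seed(31)
  labs <- paste0("s", 1:5)
  A <- sym_mat(runif(10, 0, 10), labs)
  B <- sym_mat(A[lower.tri(A)] + rnorm(10, 0, 3), labs)
  ex <- mantel(A, B, n_perm = 999)      # 119 <= 999: exhaustive
  sam <- mantel(A, B, n_perm = 1e5, seed = 5, mode = "sampled")
  expect_identical(ex$mode, "exhaustive")
  expect_identical(sam$mode, "sampled")
  expect_lt(abs(ex$p_value - sam$p_value), 0.01)
})

test_that("mantel statistic agrees with vegan and relabeling is neutral", {
  skip_if_not_installed("vegan")
  set.seed(41)
  labs <- paste0("s", 1:7)
  A <- sym_mat(runif(21, 0, 100), labs)
  B <- sym_mat(runif(21, 0, 1), labs)
  ours <- mantel(A, B, n_perm = 9999)
  veg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)

  perm <- sample(7)
  ours2 <- mantel(A[perm, perm], B[perm, perm], n_perm = 9999)
  expect_equal(ours2$r, ours$r)
  expect_equal(ours2$p_value, ours$p_value)
})

test_that("degenerate mantel inputs error", {
  labs <- paste0("s", 1:4)
  A <- sym_mat(rep(1, 6), labs)
  B <- sym_mat(runif(6), labs)
  expect_error(mantel(A, B), class = "ibd_degenerate")
  asym <- B; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel(asym, B), class = "ibd_asymmetric")
  C <- sym_mat(runif(6), paste0("x", 1:4))
  expect_error(mantel(B, C), class = "ibd_labels")
})

test_that("partial mantel recovers identity and independence", {
  set.seed(51)
  labs <- paste0("s", 1:6)
  A <- sym_mat(runif(15, 0, 10), labs)
  C <- sym_mat(runif(15, 0, 10), labs)
  resAA <- partial_mantel(A, A, C)
  expect_equal(resAA$r, 1)

  # A and B share only the control signal: partial r near zero
  set.seed(52)
  base <- runif(45, 0, 10)
  rs <- replicate(60, {
    Cm <- sym_mat(base[1:15], labs)
    Am <- sym_mat(base[1:15] + rnorm(15, 0, 2), labs)
    Bm <- sym_mat(base[1:15] + rnorm(15, 0, 2), labs)
    partial_mantel(Am, Bm, Cm, n_perm = 23)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("partial mantel matches its closed form and enumeration", {
  set.seed(61)
  labs <- paste0("s", 1:4)
  A <- sym_mat(runif(6), labs); B <- sym_mat(runif(6), labs)
  C <- sym_mat(runif(6), labs)
  res <- partial_mantel(A, B, C, n_perm = 999)
  # closed-form first-order partial correlation
  va <- A[lower.tri(A)]; vb <- B[lower.tri(B)]; vc <- C[lower.tri(C)]
  rab <- cor(va, vb); rac <- cor(va, vc); rbc <- cor(vb, vc)
  expect_equal(res$r, (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2)))
  # enumeration oracle over permutations of A
  perms <- ibdkernel:::all_permutations(4)
  rs <- apply(perms, 1, function(p) {
    vap <- A[p, p][lower.tri(A)]
    (cor(vap, vb) - cor(vap, vc) * rbc) /
      sqrt((1 - cor(vap, vc)^2) * (1 - rbc^2))
  })
  expect_equal(res$p_value, mean(rs >= res$r - 1e-12))
  expect_identical(res$mode, "exhaustive")
  expect_equal(res$n_permutations, 23)

  skip_if_not_installed("vegan")
  veg <- vegan::mantel.partial(as.dist(A), as.dist(B), as.dist(C),
                               permutations = 23)
  expect_equal(res$r, unname(veg$statistic), tolerance = 1e-12)
})

test_that("IBD regression equals the closed-form normal equations", {
  labs <- paste0("s", 1:5)
  D <- sym_mat(c(10, 20, 30, 40, 12, 22, 32, 14, 24, 16), labs)
  exact <- dist_matrix(1e-5 * D, "linearized_fst")
  fit <- suppressWarnings(   # lm flags the deliberately perfect fit
    ibd_regression(dist_matrix(D, "geographic_km"), exact))
  expect_equal(fit$slope, 1e-5)
  expect_equal(fit$slope_se, 0, tolerance = 1e-18)
  expect_equal(fit$r_squared, 1)

  set.seed(71)
  Y <- sym_mat(1e-5 * D[lower.tri(D)] + rnorm(10, 0, 1e-4), labs)
  fit2 <- ibd_regression(dist_matrix(D, "geographic_km"),
                         dist_matrix(Y, "linearized_fst"))
  x <- D[lower.tri(D)]; y <- Y[lower.tri(Y)]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sum((x - mean(x))^2))
  expect_equal(fit2$slope, b)
  expect_equal(fit2$intercept, a)
  expect_equal(fit2$slope_se, se)

  # slope invariant to adding a constant to all y
  Y2 <- Y + 0.37; diag(Y2) <- 0
  fit3 <- ibd_regression(dist_matrix(D, "geographic_km"), Y2)
  expect_equal(fit3$slope, fit2$slope)

  expect_error(ibd_regression(dist_matrix(sym_mat(rep(5, 10), labs),
                                          "geographic_km"), exact),
               class = "ibd_degenerate")
})
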
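test_that("connectivity matrices validate and round-trip", {
  labs <- paste0("r", 1:3)
  m <- diag(1, 3); dimnames(m) <- list(labs, labs)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(m), path)
  cm <- read_connectivity(path, pld_days = 10)
  expect_equal(unclass(cm)[, ], m)
  expect_equal(attr(cm, "pld_days"), 10)

  out <- withr::local_tempfile(fileext = ".csv")
  write_connectivity(cm, out)
  cm2 <- read_connectivity(out)
  expect_equal(unclass(cm2)[, ], m)

  bad <- m; bad[1, 2] <- 1.2
  write.csv(as.data.frame(bad), path)
  expect_error(read_connectivity(path), "probabilities")
})

test_that("release-site assignment is nearest-neighbor by great circle", {
  set.seed(81)
  sites <- tibble::tibble(site_id = paste0("s", 1:6),
                          longitude = runif(6, 123, 125),
                          latitude = runif(6, 9, 11))
  rel <- tibble::tibble(release_id = paste0("R", 1:4),
                        longitude = runif(4, 123, 125),
                        latitude = runif(4, 9, 11))
  asg <- assign_release_sites(sites, rel)
  # exhaustive scan oracle
  for (i in 1:6) {
    d <- geosphere::distHaversine(c(sites$longitude[i], sites$latitude[i]),
                                  as.matrix(rel[c("longitude", "latitude")]))
    expect_equal(asg$assignment$release_id[i], rel$release_id[which.min(d)])
  }
  expect_equal(nrow(asg$assignment), 6)

  # a site on a release point is assigned at zero distance
  sites2 <- tibble::tibble(site_id = "x", longitude = rel$longitude[2],
                           latitude = rel$latitude[2])
  asg2 <- assign_release_sites(sites2, rel)
  expect_equal(asg2$assignment$release_id, "R2")
  expect_equal(asg2$assignment$distance_km, 0)

  # two co-located sampling sites share a release cell: one merge group
  sites3 <- tibble::tibble(site_id = c("a", "b", "c"),
                           longitude = c(rel$longitude[1] + 0.001,
                                         rel$longitude[1] - 0.001,
                                         rel$longitude[3]),
                           latitude = c(rel$latitude[1], rel$latitude[1],
                                        rel$latitude[3]))
  asg3 <- assign_release_sites(sites3, rel)
  expect_length(asg3$merge_groups, 1)
  expect_setequal(asg3$merge_groups[[1]], c("a", "b"))
})

test_that("symmetrization modes behave and Mantel demands symmetry", {
  labs <- paste0("s", 1:4)
  m <- matrix(runif(16, 0, 0.5), 4, 4, dimnames = list(labs, labs))
  diag(m) <- 0
  sm <- symmetrize_connectivity(m, "mean")
  expect_equal(sm, t(sm))
  expect_equal(symmetrize_connectivity(sm, "mean"), sm)  # idempotent
  mx <- symmetrize_connectivity(m, "max")
  expect_equal(mx, pmax(m, t(m)))
  expect_equal(symmetrize_connectivity(mx, "max"), mx)
  fw <- symmetrize_connectivity(m, "forward")
  expect_equal(unname(fw), unname(m))
  B <- sym_mat(runif(6), labs)
  expect_error(mantel(fw, B), class = "ibd_asymmetric")
})

test_that("distance-decaying connectivity flips the Mantel sign", {
  set.seed(91)
  labs <- paste0("s", 1:6)
  D <- sym_mat(as.vector(dist(cumsum(runif(6, 10, 30)))), labs)
  lin <- sym_mat(1e-5 * D[lower.tri(D)] + rnorm(15, 0, 5e-5), labs)
  conn <- exp(-D / 50); diag(conn) <- 0
  r_dist <- mantel(D, lin)$r
  r_conn <- connectivity_vs_genetics(conn, lin, mode = "mantel")$r
  expect_gt(r_dist * -1 * r_conn, 0)  # opposite signs
})

test_that("focal regression recovers an exact linear relation", {
  labs <- paste0("s", 1:6)
  set.seed(92)
  conn <- matrix(runif(36, 0, 0.4), 6, 6, dimnames = list(labs, labs))
  conn <- (conn + t(conn)) / 2; diag(conn) <- 0
  a <- 0.02; b <- 0.03
  lin <- a - b * conn; diag(lin) <- 0
  fit <- suppressWarnings(   # lm flags the deliberately perfect fit
    connectivity_vs_genetics(conn, lin, mode = "focal_regression",
                             focal_site = "s3"))
  expect_equal(fit$slope, -b)
  expect_equal(fit$intercept, a)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_pairs, 5)
  expect_error(connectivity_vs_genetics(conn, lin, mode = "focal_regression",
                                        focal_site = "zz"),
               class = "ibd_lookup")
})

test_that("partial mantel mode delegates with a control matrix", {
  set.seed(93)
  labs <- paste0("s", 1:5)
  conn <- sym_mat(runif(10, 0, 0.5), labs)
  lin <- sym_mat(runif(10, 0, 0.01), labs)
  geo <- sym_mat(runif(10, 5, 100), labs)
  res <- connectivity_vs_genetics(conn, lin, mode = "partial_mantel",
                                  control = dist_matrix(geo, "geographic_km"))
  expect_s3_class(res, "mantel_result")
  direct <- partial_mantel(symmetrize_connectivity(conn, "mean"), lin, geo)
  expect_equal(res$r, direct$r)
})
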
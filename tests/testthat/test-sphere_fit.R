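test_that("least-squares fit is exact on noiseless spherical data", {
  cl <- sphere_cloud(100)
  s <- fit_sphere_lsq(cl)
  expect_lt(max(abs(s$center)), 1e-9)
  expect_lt(abs(s$radius - 1), 1e-9)

  cl2 <- sphere_cloud(200, center = c(10, -5, 3), radius = 32.89)
  s2 <- fit_sphere_lsq(cl2)
  expect_lt(sqrt(sum((s2$center - c(10, -5, 3))^2)), 1e-6)
  expect_lt(abs(s2$radius - 32.89), 1e-6)
})

test_that("degenerate point sets are rejected with a diagnostic", {
  flat <- cbind(runif(20), runif(20), 0)
  expect_error(fit_sphere_lsq(flat), "degenerate|coplanar")
  expect_error(fit_sphere_lsq(flat[1:3, ]), "at least 4")
})

test_that("fit is equivariant under rigid motions", {
  set.seed(42)
  pts <- sphere_cloud(80, center = c(3, 1, -2), radius = 12)$points +
    matrix(rnorm(240, 0, 0.1), 80, 3)
  s <- fit_sphere_lsq(pts)
  # random rotation via QR of a Gaussian matrix
  qrq <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qrq) < 0) qrq[, 1] <- -qrq[, 1]
  shift <- c(5, -7, 2)
  s2 <- fit_sphere_lsq(sweep(pts %*% t(qrq), 2, shift, "+"))
  expect_lt(sqrt(sum((s2$center - (qrq %*% s$center + shift))^2)), 1e-9)
  expect_lt(abs(s2$radius - s$radius), 1e-9)
})

test_that("algebraic fit attains the grid-search minimum on small clouds", {
  set.seed(7)
  pts <- sphere_cloud(50, center = c(1, 2, 0.5), radius = 8)$points +
    matrix(rnorm(150, 0, 0.3), 50, 3)
  s <- fit_sphere_lsq(pts, refine = FALSE)
  loss <- function(cc, r) sum((rowSums(sweep(pts, 2, cc)^2) - r^2)^2)
  grid <- expand.grid(x = seq(0, 2, 0.25), y = seq(1, 3, 0.25),
                      z = seq(-0.5, 1.5, 0.25), r = seq(7, 9, 0.1))
  grid_min <- min(mapply(function(x, y, z, r) loss(c(x, y, z), r),
                         grid$x, grid$y, grid$z, grid$r))
  expect_lte(loss(s$center, s$radius), grid_min)
})

test_that("normal filter applies the scalar-product elimination rule", {
  s <- sphere(c(0, 0, 0), 10)
  inward <- sphere_cloud(50, radius = 10, normal_sign = -1)
  kept <- filter_by_normal(inward, s)
  expect_equal(nrow(kept$points), 50)
  expect_equal(attr(kept, "eliminated"), 0L)

  outward <- sphere_cloud(50, radius = 10, normal_sign = 1)
  expect_error(filter_by_normal(outward, s), "normal_sign")
  kept_out <- filter_by_normal(outward, s,
                               fit_config(normal_sign = "outward"))
  expect_equal(nrow(kept_out$points), 50)

  # mixed cloud: retained count must equal the per-point sign rule
  mix <- oriented_cloud(rbind(inward$points, outward$points),
                        rbind(inward$normals, outward$normals))
  expected_keep <- rowSums(mix$normals * mix$points) <= 0
  kept_mix <- filter_by_normal(mix, s)
  expect_equal(nrow(kept_mix$points), sum(expected_keep))
  expect_equal(attr(kept_mix, "eliminated"), sum(!expected_keep))
})

test_that("distance pruning removes the farthest points with stable ties", {
  s <- sphere(c(0, 0, 0), 10)
  on_sphere <- sphere_cloud(90, radius = 10)
  far <- sphere_cloud(10, radius = 20)
  cl <- oriented_cloud(rbind(on_sphere$points, far$points),
                       rbind(on_sphere$normals, far$normals))
  pruned <- prune_farthest(cl, s, 0.10)
  expect_equal(nrow(pruned$points), 90)
  expect_equal(pruned$points, on_sphere$points)

  expect_identical(prune_farthest(cl, s, 0), cl)

  # symmetric degeneracy: all points exactly on the sphere, any 10% may go
  # but the refit must not move
  refit <- fit_sphere_lsq(prune_farthest(on_sphere, s, 0.10))
  expect_lt(abs(refit$radius - 10), 1e-9)
  expect_lt(max(abs(refit$center)), 1e-9)
})

test_that("iterative fit converges on clean data and resists outliers", {
  clean <- sphere_cloud(120, center = c(2, 0, 1), radius = 30)
  res <- iterate_fit(clean)
  expect_lt(abs(res$sphere$radius - 30), 1e-9)
  expect_lte(nrow(res$diagnostics), 2) # converged at the radius tolerance

  # 20% planar outliers with plane-consistent normals
  set.seed(11)
  n_out <- 30
  plane_pts <- cbind(runif(n_out, -20, 20), runif(n_out, -20, 20), 45)
  outliers <- oriented_cloud(plane_pts,
                             matrix(rep(c(0, 0, 1), n_out), ncol = 3,
                                    byrow = TRUE))
  cl <- oriented_cloud(rbind(clean$points, plane_pts),
                       rbind(clean$normals, outliers$normals))
  res2 <- iterate_fit(cl)
  expect_lt(abs(res2$sphere$radius - 30), 0.5)
  expect_lt(sqrt(sum((res2$sphere$center - c(2, 0, 1))^2)), 0.5)
})

test_that("algebraic loss never increases across iterations", {
  set.seed(3)
  base <- sphere_cloud(150, radius = 25)
  noisy <- oriented_cloud(base$points + matrix(rnorm(450, 0, 0.5), 150, 3),
                          base$normals)
  res <- iterate_fit(noisy, fit_config(radius_tol = 1e-9,
                                       max_iterations = 5))
  expect_true(all(diff(res$diagnostics$algebraic_loss) <= 1e-8))
})

test_that("the loop refuses to continue with fewer than 4 points", {
  tiny <- sphere_cloud(5, radius = 10)
  expect_error(iterate_fit(tiny, fit_config(prune_fraction = 0.5,
                                            max_iterations = 5,
                                            radius_tol = 1e-12)),
               "fewer than 4")
})
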
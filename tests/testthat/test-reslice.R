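test_that("plane frames contain their defining points and are orthonormal", {
  fr <- plane_from_three_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(fr$normal), c(0, 0, 1), tolerance = 1e-12)
  B <- cbind(fr$x, fr$y, fr$normal)
  expect_equal(crossprod(B), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(det(B), 0)

  set.seed(21)
  for (i in 1:20) {
    pts <- matrix(rnorm(9, sd = 30), 3)
    if (coaptR:::vnorm(coaptR:::cross3(pts[2, ] - pts[1, ],
                                       pts[3, ] - pts[1, ])) < 1) next
    fr <- plane_from_three_points(pts[1, ], pts[2, ], pts[3, ],
                                  ydir = rnorm(3))
    resid <- apply(pts, 1, function(p) coaptR:::plane_offset(fr, p))
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("collinear or degenerate landmark triples are rejected", {
  expect_error(plane_from_three_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
  expect_error(plane_from_three_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                       ydir = c(0, 0, 1)),
               "perpendicular")
})

test_that("plane frames are rigid and equivariant under rotation", {
  p1 <- c(-20, 21, 0); p2 <- c(-10, 39, -9); p3 <- c(10, -60, 0)
  fr <- plane_from_three_points(p1, p2, p3)
  a <- project_to_plane(fr, p1)
  b <- project_to_plane(fr, p2)
  expect_equal(sqrt(sum((a - b)^2)), sqrt(sum((p1 - p2)^2)),
               tolerance = 1e-9) # both points lie in the plane
  # round trip
  expect_equal(plane_to_world(fr, a), p1, tolerance = 1e-9)

  th <- 0.4
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  fr2 <- plane_from_three_points(R %*% p1, R %*% p2, R %*% p3,
                                 ydir = R %*% c(0, 1, 0))
  # in-plane coordinates of corresponding points agree up to the lateral
  # sign convention
  a2 <- project_to_plane(fr2, as.numeric(R %*% p1))
  expect_equal(abs(a2), abs(a), tolerance = 1e-9)
})

test_that("insertion-point walk covers the arc in fixed steps", {
  arc <- list(center = c(0, 40, 0), radius = 30, span = c(0, 180))
  pts <- insertion_points(arc, 10)
  expect_equal(nrow(pts), 19)
  expect_equal(pts$arc_index, 0:18)
  expect_error(insertion_points(arc, 0), "positive")
  expect_error(insertion_points(list(center = c(0, 0, 0), radius = 10,
                                     span = c(0, 20))), "30 degrees")
})

test_that("the cubic kernel has the stated closed form", {
  expect_equal(cubic_weight(0), 1)
  expect_equal(cubic_weight(0.5), 0.5)
  expect_equal(cubic_weight(1), 0)
  t <- seq(0, 1, 0.05)
  expect_equal(cubic_weight(t) + cubic_weight(1 - t), rep(1, length(t)),
               tolerance = 1e-12)
})

test_that("resampling reproduces constant and linear fields", {
  const <- labeled_volume(array(2L, c(14, 14, 14)), c(2, 2, 2),
                          c(-13, -13, -13))
  fr <- plane_from_three_points(c(0, 0, 1), c(5, 0, 1), c(0, 5, 1))
  sl <- resample(const, fr, extent = 12, center = c(0, 0))
  expect_true(all(sl$image == 2))
  expect_true(all(sl$labels == 2L))

  # axis-aligned plane through voxel centres: the kernel weights collapse
  # to w(0) = 1 and the voxel values are reproduced exactly
  vol <- labeled_volume(array(rep(0:1, length.out = 8000), c(20, 20, 20)),
                        c(1, 1, 1), c(0, 0, 0))
  frz <- plane_from_three_points(c(0, 0, 10), c(1, 0, 10), c(0, 1, 10),
                                 pixel_spacing = 1)
  slz <- resample(vol, frz, extent = 8, center = c(9.5, 9.5))
  ij <- expand.grid(x = slz$xs, y = slz$ys)
  direct <- vol$voxels[cbind(ij$x + 1, ij$y + 1, 11)]
  expect_equal(as.numeric(slz$image), as.numeric(direct), tolerance = 1e-6)

  expect_error(resample(const, plane_from_three_points(
    c(0, 0, 500), c(1, 0, 500), c(0, 1, 500)), extent = 10,
    center = c(0, 0)), "outside")
})

test_that("slice circles satisfy the Pythagorean identity", {
  s <- sphere(c(0, 0, 0), 30)
  fr0 <- plane_from_three_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(slice_circle(s, fr0)$radius, 30)

  fr15 <- plane_from_three_points(c(0, 0, 15), c(1, 0, 15), c(0, 1, 15))
  circ <- slice_circle(s, fr15)
  expect_equal(circ$radius, sqrt(900 - 225), tolerance = 1e-9)
  expect_equal(attr(circ, "plane_distance"), 15)

  set.seed(9)
  for (i in 1:15) {
    pts <- matrix(rnorm(9, sd = 20), 3)
    fr <- try(plane_from_three_points(pts[1, ], pts[2, ], pts[3, ],
                                      ydir = rnorm(3)), silent = TRUE)
    if (inherits(fr, "try-error")) next
    circ <- try(slice_circle(s, fr), silent = TRUE)
    if (inherits(circ, "try-error")) next
    expect_equal(circ$radius^2 + attr(circ, "plane_distance")^2, 900,
                 tolerance = 1e-9)
  }

  fr_far <- plane_from_three_points(c(0, 0, 31), c(1, 0, 31), c(0, 1, 31))
  expect_error(slice_circle(s, fr_far), "misses")
})
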
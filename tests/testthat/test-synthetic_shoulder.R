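test_that("parameter validation rejects impossible configurations", {
  expect_error(shoulder_params(implant_radius = -1), "positive")
  expect_error(shoulder_params(distal_insertion = c(5, -5, 0)),
               "inside the implant")
  expect_error(shoulder_params(distal_insertion = c(0, 60, 0)),
               "distal")
  expect_error(shoulder_params(insertion_angles = c(P1 = 10, M1 = -20,
                                                    A3 = 10, A2 = 40)),
               "ordered")
  expect_error(shoulder_params(voxel_spacing = c(1, 0, 1)), "positive")
})

test_that("generation is deterministic and noise is seed-dependent", {
  p <- ref_params(noise_sd = 0.3)
  a <- generate_shoulder(p, seed = 5, with_volume = FALSE)
  b <- generate_shoulder(p, seed = 5, with_volume = FALSE)
  expect_identical(a$clouds, b$clouds)
  d <- generate_shoulder(p, seed = 6, with_volume = FALSE)
  expect_false(identical(a$clouds$deltoid$points, d$clouds$deltoid$points))
})

test_that("the noiseless deltoid sheet is tangent to the implant sphere", {
  p <- ref_params()
  gen <- generate_shoulder(p, with_volume = FALSE)
  cl <- gen$clouds$deltoid
  contact <- attr(cl, "contact")
  expect_gt(sum(contact), 0)
  d <- sqrt(rowSums(sweep(cl$points[contact, ], 2, p$implant_center)^2))
  expect_lt(max(abs(d - p$implant_radius)), 1e-9)
  # contact normals point at the implant centre (inward convention)
  dir_to_c <- sweep(-cl$points[contact, ], 2, -p$implant_center)
  dp <- rowSums(cl$normals[contact, ] * dir_to_c)
  expect_true(all(dp > 0))
  # off-contact internal-aspect points are consistent with the inward rule
  dp_all <- rowSums(cl$normals * sweep(cl$points, 2, p$implant_center))
  expect_true(all(dp_all <= 1e-9))
})

test_that("ground-truth CER reproduces the closed-form formula exactly", {
  gt <- generate_shoulder(ref_params(), with_volume = FALSE)$ground_truth
  expect_equal(gt$per_slice$cer,
               cer(gt$per_slice$T, gt$per_slice$E), tolerance = 1e-12)
  expect_true(all(gt$per_slice$T > 0 & gt$per_slice$T < 90))
  expect_true(all(gt$per_slice$E >= 0 & gt$per_slice$E < 90))
  expect_equal(gt$per_slice$T, gt$per_slice$B / 2, tolerance = 1e-12)
})

test_that("analytic angles respond monotonically to lateralization", {
  p <- ref_params()
  for (sl in c("S1", "S2", "S3", "S4")) {
    a <- lapply(c(0, 6, 9, 12), function(off) analytic_angles(p, sl, off))
    Tv <- sapply(a, `[[`, "T")
    Ev <- sapply(a, `[[`, "E")
    expect_true(all(diff(Tv) < 0), info = sl)
    expect_true(all(diff(Ev) > 0), info = sl)
  }
})

test_that("analytic tangents agree with a brute-force direction scan", {
  circ <- circle2d(c(0, 0), 30)
  md <- tangent_from_point(c(5, -80), circ, "left")
  prox <- tangent_from_point(c(-40, 30), circ, "right")
  bf_md <- brute_force_tangent(c(5, -80), circ, "left")
  bf_prox <- brute_force_tangent(c(-40, 30), circ, "right")
  ang <- function(u, v) acos(min(1, abs(sum(u * v)))) * 180 / pi
  expect_lt(ang(md$direction, bf_md), 0.01)
  expect_lt(ang(prox$direction, bf_prox), 0.01)
})

test_that("the arm-position parameter rotates the humerus rigidly", {
  p80 <- ref_params()
  p90 <- ref_params(arm_angle = 90)
  g80 <- coaptR:::effective_geometry(p80)
  g90 <- coaptR:::effective_geometry(p90)
  expect_equal(g80$distal_insertion, p80$distal_insertion)
  # rotation preserves the distance to the implant centre
  expect_equal(sqrt(sum(g90$distal_insertion^2)),
               sqrt(sum(g80$distal_insertion^2)), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(g90$distal_insertion,
                                g80$distal_insertion)))
  # and changes the measured angles
  expect_false(isTRUE(all.equal(analytic_angles(p90, "S2")$E,
                                analytic_angles(p80, "S2")$E)))
})

test_that("segmentation perturbation is smooth, seeded and bounded", {
  p <- ref_params()
  vol <- generate_shoulder(p)$volume
  expect_identical(perturb_segmentation(vol, 0), vol)
  a <- perturb_segmentation(vol, 0.5, seed = 1)
  b <- perturb_segmentation(vol, 0.5, seed = 1)
  c2 <- perturb_segmentation(vol, 0.5, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a$voxels, c2$voxels))
  fit_of <- function(v) {
    surf <- extract_internal_surface(v, 1L, toward = p$implant_center,
                                     max_distance = 1.3 * p$implant_radius)
    iterate_fit(surf)$sphere$radius
  }
  r1 <- fit_of(a); r2 <- fit_of(c2)
  expect_lt(abs(r1 - r2), 1)
  # the voxel-face surface recovers the radius to sub-voxel accuracy
  expect_lt(abs(fit_of(vol) - p$implant_radius), 1.5)
})

test_that("labeled volumes restrict codes and carry a diagonal affine", {
  expect_error(labeled_volume(array(7L, c(2, 2, 2)), c(1, 1, 1)),
               "restricted")
  v <- labeled_volume(array(0:1, c(4, 4, 4)), c(1.5, 1.5, 3), c(-5, 0, 5))
  expect_equal(diag(v$affine)[1:3], c(1.5, 1.5, 3))
  expect_equal(v$affine[1:3, 4], c(-5, 0, 5))
})
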
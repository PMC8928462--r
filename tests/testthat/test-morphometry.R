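test_that("radial profile of a disk is flat and normalized", {
  rp <- radialProfile(diskMask(20))
  expect_gte(length(rp$nd), 8)
  expect_equal(max(rp$nd), 1)
  expect_true(all(rp$nd > 1 - 0.08))
  ang <- atan2(-(rp$boundary[, 1] - rp$centroid[1]),
               rp$boundary[, 2] - rp$centroid[2])
  expect_true(all(diff(ang) >= 0))  # ordered by polar angle
})

test_that("degenerate masks raise feature-undefined errors", {
  expect_error(radialProfile(matrix(0, 8, 8)),
               class = "featureUndefinedError")
  one <- matrix(0, 8, 8); one[4, 4] <- 1
  expect_error(radialProfile(one), class = "featureUndefinedError")
  two <- matrix(0, 10, 10); two[2, 2] <- 1; two[8, 8] <- 1
  expect_error(radialProfile(two), class = "featureUndefinedError")
  expect_error(shapeFeatures(matrix(0, 8, 8)),
               class = "featureUndefinedError")
})

test_that("rectangle radial extremes sit at corners and edge midpoints", {
  # 20x10 pixel rectangle: pixel-center half-extents 9.5 (rows) and 4.5
  # (cols), so max d = sqrt(9.5^2 + 4.5^2) = 10.51 at the corners and
  # min d = 4.5 at the long-edge midpoints
  m <- matrix(0, 40, 40); m[11:30, 16:25] <- 1
  rp <- radialProfile(m)
  expect_lt(abs(max(rp$d) - sqrt(9.5^2 + 4.5^2)), 0.6)
  expect_lt(abs(min(rp$d) - 4.5), 0.6)
  expect_lt(abs(min(rp$d) / max(rp$d) - 4.5 / sqrt(9.5^2 + 4.5^2)), 0.1)
  corner <- rp$boundary[which.max(rp$d), ]
  expect_true(corner[1] %in% c(11, 30) && corner[2] %in% c(16, 25))
})

test_that("disk features sit at their circular limits", {
  f <- shapeFeatures(diskMask(20))
  expect_gte(f[["roundness"]], 0.9)
  expect_lte(f[["nrl_sd"]], 0.03)
  expect_equal(f[["leaflet_count"]], 0)
  expect_equal(f[["spiculation"]], 0)
  expect_lt(abs(f[["elongation"]] - 1), 0.05)
  expect_lt(abs(f[["bbox_aspect_ratio"]] - 1), 0.1)
  expect_gt(f[["norm_ellipse_contour"]], 0.95)
})

test_that("leaflet count recovers the harmonic order of lobulated contours", {
  for (k in 3:5) {
    ph <- makePhantom(phantomSpec(imageSize = 96L, baseRadius = 20,
                                  lobulationOrder = k, lobulationAmp = 0.3,
                                  spiculeCount = 0L, seed = 2L))
    expect_equal(shapeFeatures(lesionMask(ph))[["leaflet_count"]], k)
  }
})

test_that("inertia ellipse recovers axes and orientation of an ellipse", {
  f <- shapeFeatures(ellipseMask(20, 10, theta = 0.4))
  expect_lt(abs(f[["elongation"]] - 2), 0.1)
  expect_lt(abs(f[["direction_angle"]] - 0.4), 0.05)
  expect_lt(abs(f[["bbox_aspect_ratio"]] - 2), 0.2)
  expect_gt(f[["norm_ellipse_contour"]], 0.95)
  expect_lt(abs(f[["norm_ellipse_circumference"]] - 1), 0.1)
})

test_that("features are invariant under 90-degree rotation except direction", {
  m <- ellipseMask(18, 9, theta = 0.3, S = 64)
  f1 <- shapeFeatures(m)
  f2 <- shapeFeatures(rotate90(m))
  others <- setdiff(names(f1), "direction_angle")
  rel <- abs(f2[others] - f1[others]) / pmax(abs(f1[others]), 1e-9)
  expect_true(all(rel < 0.05))
  shift <- (f2[["direction_angle"]] - f1[["direction_angle"]]) %% pi
  expect_lt(min(abs(shift - pi / 2), abs(shift - pi / 2 - pi),
                abs(shift + pi / 2 - pi)), 0.06)
})

test_that("features are exactly invariant under integer translation", {
  base <- matrix(0, 64, 64)
  lump <- lesionMask(makePhantom(phantomSpec(
    imageSize = 40L, baseRadius = 9, lobulationOrder = 3L,
    lobulationAmp = 0.2, spiculeCount = 2L, seed = 6L)))
  a <- base; a[3 + seq_len(40), 5 + seq_len(40)] <- lump
  b <- base; b[15 + seq_len(40), 20 + seq_len(40)] <- lump
  expect_equal(shapeFeatures(a), shapeFeatures(b), tolerance = 1e-12)
})

test_that("scale-free features move < 5% under 2x upscaling", {
  p1 <- makePhantom(phantomSpec(imageSize = 80L, baseRadius = 16,
                                lobulationOrder = 3L, lobulationAmp = 0.2,
                                spiculeCount = 0L, seed = 5L))
  p2 <- makePhantom(phantomSpec(imageSize = 160L, baseRadius = 32,
                                lobulationOrder = 3L, lobulationAmp = 0.2,
                                spiculeCount = 0L, seed = 5L))
  f1 <- shapeFeatures(lesionMask(p1))
  f2 <- shapeFeatures(lesionMask(p2))
  # spiculation and boundary_roughness are first-difference statistics of
  # the NRL series and scale with boundary sampling density by definition;
  # direction is meaningless for a near-isotropic contour
  keep <- setdiff(names(f1),
                  c("spiculation", "boundary_roughness", "direction_angle"))
  rel <- abs(f2[keep] - f1[keep]) / pmax(abs(f1[keep]), 1e-9)
  expect_true(all(rel < 0.05))
})

test_that("spiculation and roughness grow with spicule count", {
  feats <- lapply(c(0L, 4L, 8L), function(ns) {
    ph <- makePhantom(phantomSpec(imageSize = 96L, baseRadius = 18,
                                  spiculeCount = ns, spiculeLen = 0.5,
                                  lobulationAmp = 0.05, seed = 3L))
    shapeFeatures(lesionMask(ph))
  })
  spic <- vapply(feats, `[[`, 0, "spiculation")
  rough <- vapply(feats, `[[`, 0, "boundary_roughness")
  expect_true(all(diff(spic) >= 0) && spic[3] > spic[1])
  expect_true(all(diff(rough) >= 0) && rough[3] > rough[1])
})

test_that("shape vector has 13 finite values in the documented order", {
  f <- shapeFeatures(diskMask(12))
  expect_identical(names(f), shapeFeatureNames())
  expect_length(f, 13)
  expect_true(all(is.finite(f)))
  expect_gte(f[["nrl_sd"]], 0)
  expect_true(f[["direction_angle"]] >= 0 && f[["direction_angle"]] < pi)
  expect_equal(f[["leaflet_count"]] %% 1, 0)
})
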
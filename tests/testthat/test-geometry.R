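test_that("control point generation follows arc direction, spacing and endpoints", {
  cp <- control_points(arc_spec(179, 181, "CCW", 2))
  expect_length(cp, 180)
  expect_equal(cp[1:3], c(179, 177, 175))
  expect_equal(cp[90:91], c(1, 359))   # passes through 0
  expect_equal(cp[180], 181)

  expect_equal(control_points(arc_spec(0, 90, "CW", 30)), c(0, 30, 60, 90))

  # full 360-degree arc drops the duplicate endpoint
  full <- control_points(arc_spec(0, 0, "CW", 2))
  expect_length(full, 180)
  expect_equal(full[1], 0)
  expect_equal(full[180], 358)

  expect_error(arc_spec(179, 181, "CCW", 7), class = "subarcvmat_config_error")
  expect_error(linac_geometry(sad = -5), class = "subarcvmat_config_error")
})

test_that("contour rasterization reproduces analytic volumes", {
  s <- sphere_structure("t", c(0, 0, 0), 10)
  v <- mask_volume_cc(rasterize_structure(s, voxel = 1))
  expect_lt(abs(v - 4 / 3 * pi) / (4 / 3 * pi), 0.02)

  # additivity for disjoint spheres
  s2 <- rbind(sphere_structure("a", c(-30, 0, 0), 10),
              sphere_structure("b", c(30, 0, 0), 10))
  v2 <- mask_volume_cc(rasterize_structure(s2, voxel = 1))
  expect_lt(abs(v2 - 2 * 4 / 3 * pi) / (2 * 4 / 3 * pi), 0.02)

  # ellipsoid with the same volume as an r = 10 sphere
  e <- ellipsoid_structure("e", c(0, 0, 0), c(12.5, 10, 8))
  ve <- mask_volume_cc(rasterize_structure(e, voxel = 1))
  expect_lt(abs(ve - 4 / 3 * pi) / (4 / 3 * pi), 0.02)

  expect_error(rasterize_structure(tibble::tibble()), class = "subarcvmat_contour_error")
  degen <- contour_tbl("d", c(1L, 1L, 2L), z = c(0, 0, 0),
                       x = c(0, 1, 5), y = c(0, 0, 5))
  degen <- rbind(degen, sphere_structure("s", c(0, 0, 0), 8))
  expect_warning(rasterize_structure(degen), "degenerate")
})

test_that("a voxel at the isocenter projects to the raster center at every gantry angle", {
  pt <- matrix(0, 1, 3)
  for (g in c(0, 37, 90, 181, 299)) {
    b <- project_bev(pt, g)
    idx <- which(b$pixels, arr.ind = TRUE)
    expect_identical(mean(b$u_centers[idx[, 1]]), 0)
    expect_identical(mean(b$v_centers[idx[, 2]]), 0)
  }
})

test_that("divergent projection matches the tangent-cone closed form", {
  # sphere at the isocenter: silhouette radius sad * r / sqrt(sad^2 - r^2)
  vox <- rasterize_structure(sphere_structure("s", c(0, 0, 0), 20))
  b <- project_bev(vox, 33)
  r_meas <- sqrt(bev_area_cm2(b) * 100 / pi)
  expect_lt(abs(r_meas - 20.004), 0.5)

  # sphere offset 50 mm toward the source: radius sad * r / sqrt(L^2 - r^2)
  vox2 <- rasterize_structure(sphere_structure("s", c(0, -50, 0), 10))
  b2 <- project_bev(vox2, 0)   # gantry 0: source anterior, offset toward it
  r_pred <- 1000 * 10 / sqrt(950^2 - 100)
  expect_lt(abs(sqrt(bev_area_cm2(b2) * 100 / pi) - r_pred), 0.5)
})

test_that("magnification grows toward the source in divergent mode only", {
  at_iso <- rasterize_structure(sphere_structure("s", c(0, 0, 0), 10))
  toward <- rasterize_structure(sphere_structure("s", c(0, -60, 0), 10))
  a_iso <- bev_area_cm2(project_bev(at_iso, 0))
  a_tow <- bev_area_cm2(project_bev(toward, 0))
  expect_gt(a_tow, a_iso)
  p_iso <- bev_area_cm2(project_bev(at_iso, 0, mode = "parallel"))
  p_tow <- bev_area_cm2(project_bev(toward, 0, mode = "parallel"))
  expect_equal(p_tow, p_iso, tolerance = 1e-12)

  behind <- matrix(c(0, -1100, 0), 1, 3)
  expect_error(project_bev(behind, 0), class = "subarcvmat_geometry_error")
})

test_that("superior-inferior offsets keep a constant v centroid across a coplanar arc", {
  vox0 <- rasterize_structure(sphere_structure("s", c(0, 0, 0), 10))
  voxz <- rasterize_structure(sphere_structure("s", c(0, 0, 30), 10))
  offs <- vapply(c(0, 45, 90, 217, 304), function(g) {
    b0 <- project_bev(vox0, g, mode = "parallel")
    bz <- project_bev(voxz, g, mode = "parallel")
    i0 <- which(b0$pixels, arr.ind = TRUE)
    iz <- which(bz$pixels, arr.ind = TRUE)
    mean(bz$v_centers[iz[, 2]]) - mean(b0$v_centers[i0[, 2]])
  }, numeric(1))
  expect_true(all(abs(offs - 30) < 0.5))
  expect_lt(max(offs) - min(offs), 0.5)
})

test_that("collimator-frame rotation preserves identity, area and symmetry", {
  d <- disk_mask(20)
  expect_identical(rotate_bev(d, 0)$pixels, d$pixels)
  for (th in c(17, 45, 90, 133, 178)) {
    expect_lt(abs(bev_area_cm2(rotate_bev(d, th)) / bev_area_cm2(d) - 1), 0.01)
  }
  sq <- rect_mask(20, 20)
  r90 <- rotate_bev(sq, 90)
  disagree <- sum(xor(r90$pixels, sq$pixels)) / sum(sq$pixels)
  expect_lt(disagree, 0.01)
})
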
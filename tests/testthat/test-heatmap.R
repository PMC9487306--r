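test_that("a centered sphere yields a flat heatmap along both axes", {
  # fine slicing/pixels so the check isolates algorithmic anisotropy from
  # the genuinely anisotropic flat polar caps of coarsely sliced stacks
  s <- sphere_structure("s", c(0, 0, 0), 12, z_spacing = 0.25)
  h <- mci_heatmap(s, arc_spec(0, 352, "CW", 8), thetas = seq(0, 176, 4),
                   pixel = 0.25)
  expect_identical(dim(h$values), c(45L, 45L))
  expect_true(all(h$values > 0 & h$values <= 1))
  row_range <- apply(h$values, 1, function(r) max(r) - min(r))
  col_range <- apply(h$values, 2, function(r) max(r) - min(r))
  expect_lt(max(row_range), 0.02)
  expect_lt(max(col_range), 0.02)
})

test_that("SI-separated spheres select the separating collimator at every control point", {
  s <- rbind(sphere_structure("PTV1", c(0, 0, -30), 10),
             sphere_structure("PTV2", c(0, 0, 30), 10))
  h <- mci_heatmap(s, arc_spec(), thetas = seq(0, 178, 2))
  am <- h$thetas[apply(h$values, 1, which.max)]
  expect_true(all(theta_dist(am, 0) <= 10))
})

test_that("opposed beams in parallel mode are exact theta-mirrors", {
  s <- rbind(sphere_structure("a", c(20, 0, -25), 9),
             sphere_structure("b", c(-5, 0, 25), 11))
  h <- mci_heatmap(rasterize_structure(s), arc_spec(0, 180, "CW", 180),
                   thetas = 0:179, mode = "parallel")
  mirror <- h$values[1, c(1, 180:2)]   # row 1 evaluated at (-theta) mod 180
  expect_lt(max(abs(h$values[2, ] - mirror)), 1e-6)
})

test_that("the boundary-point fast path agrees with rotate-and-fit", {
  s <- rbind(sphere_structure("a", c(15, 10, -20), 9),
             sphere_structure("b", c(-18, -5, 22), 12))
  vox <- rasterize_structure(s)
  h <- mci_heatmap(vox, arc_spec(), thetas = 0:179)
  cells <- withr::with_seed(4, cbind(sample(180, 6), sample(180, 6)))
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    bev <- project_bev(vox, h$gantry[i])
    rb <- rotate_bev(bev, h$thetas[j])
    slow <- compute_mci(rb, fit_aperture(rb))$mci
    expect_lt(abs(h$values[i, j] - slow), 0.08)
  }
})

test_that("rotating the case about the beam axis shifts the collimator profile equivariantly", {
  s <- rbind(sphere_structure("a", c(-20, 0, 0), 8),
             sphere_structure("b", c(20, 0, 0), 8))
  pts <- vox_points(rasterize_structure(s))
  one_cp <- arc_spec(0, 2, "CW", 2)
  hA <- mci_heatmap(pts, one_cp, thetas = 0:179, mode = "parallel")
  d <- 30 * pi / 180   # rotate by -30 deg in the BEV plane (about +y at gantry 0)
  pts2 <- cbind(pts[, 1] * cos(d) + pts[, 3] * sin(d), pts[, 2],
                -pts[, 1] * sin(d) + pts[, 3] * cos(d))
  hB <- mci_heatmap(pts2, one_cp, thetas = 0:179, mode = "parallel")
  rA <- hA$values[1, ]; rB <- hB$values[1, ]
  align <- vapply(0:179, function(sft) {
    mean(abs(rB - rA[((0:179 + sft) %% 180) + 1]))
  }, numeric(1))
  expect_lte(theta_dist(which.min(align) - 1, 30), 2)
  expect_lt(align[31], 0.04)
})

test_that("select_collimator sums rows and breaks ties toward the lowest angle", {
  g <- c(179, 177)
  h1 <- as_mci_heatmap(matrix(c(0.5, 0.9, 0.7), 1, 3), 179, c(0, 60, 120))
  expect_equal(select_collimator(h1), tibble::tibble(theta = 60, score = 0.9))
  h2 <- as_mci_heatmap(matrix(c(0.2, 0.8, 0.3, 0.1, 0.7, 0.2), 2, 3,
                              byrow = TRUE),
                       g, c(0, 45, 90))
  expect_equal(select_collimator(h2)$theta, 45)
  expect_equal(select_collimator(h2)$score, 0.8 + 0.7)
  h3 <- as_mci_heatmap(matrix(0.4, 2, 4), g, c(0, 45, 90, 135))
  expect_equal(select_collimator(h3), tibble::tibble(theta = 0, score = 0.8))
  expect_error(select_collimator(h3, integer(0)), class = "subarcvmat_config_error")
})

test_that("constant heatmaps collapse to a single full-arc sub-arc", {
  h <- as_mci_heatmap(matrix(0.7, 180, 180), control_points(arc_spec()), 0:179)
  p <- segment_subarcs(h)
  expect_identical(nrow(p), 1L)
  expect_equal(p$collimator, 0)
  expect_equal(p$span, 358)
  expect_equal(attr(p, "total_score"), 0.7 * 180)
})

test_that("a two-block heatmap splits exactly at the block boundary", {
  V <- matrix(0.5, 180, 180)
  V[1:90, 31] <- 0.9; V[91:180, 121] <- 0.9
  h <- as_mci_heatmap(V, control_points(arc_spec()), 0:179)
  p <- segment_subarcs(h)
  expect_identical(p$cp_end, c(90L, 180L))
  expect_equal(p$collimator, c(30, 120))
  expect_equal(attr(p, "total_score"), 162)
  expect_equal(plan_string(p), "179-359/30, 359-181/120")
})

test_that("dynamic programming equals brute-force enumeration on random heatmaps", {
  for (seed in 101:115) {
    h <- random_heatmap(seed)
    cons <- withr::with_seed(seed + 1000,
                             list(ms = sample(c(8, 10, 12), 1),
                                  mk = sample(3:6, 1)))
    pd <- segment_subarcs(h, min_span = cons$ms, max_subarcs = cons$mk)
    pb <- brute_force_segment(h, min_span = cons$ms, max_subarcs = cons$mk)
    expect_equal(attr(pd, "total_score"), attr(pb, "total_score"),
                 tolerance = 1e-9)
    expect_identical(pd$cp_end, pb$cp_end)
    expect_identical(pd$collimator, pb$collimator)
  }
})

test_that("sub-arc plans always satisfy the span and count constraints", {
  for (seed in 201:208) {
    h <- random_heatmap(seed)
    p <- segment_subarcs(h, min_span = 10, max_subarcs = 9)
    expect_lte(nrow(p), 9L)
    expect_true(all(p$span >= 10))
    # contiguous cover of all control points
    expect_identical(p$cp_start, c(1L, utils::head(p$cp_end, -1) + 1L))
    expect_identical(p$cp_end[nrow(p)], nrow(h$values))
    expect_equal(sum(p$span), (nrow(h$values) - 1L) * 2)
  }
})

test_that("relaxing the constraints never lowers the optimal score", {
  h <- random_heatmap(777)
  s_k <- vapply(c(2, 4, 6), function(k) {
    attr(segment_subarcs(h, min_span = 10, max_subarcs = k, delta = 0),
         "total_score")
  }, numeric(1))
  expect_true(all(diff(s_k) >= -1e-12))
  s_span <- vapply(c(16, 12, 8), function(ms) {
    attr(segment_subarcs(h, min_span = ms, max_subarcs = 5, delta = 0),
         "total_score")
  }, numeric(1))
  expect_true(all(diff(s_span) >= -1e-12))
})

test_that("infeasible segmentation constraints are rejected up front", {
  h <- as_mci_heatmap(matrix(0.5, 10, 4), (179 - 2 * (0:9)) %% 360,
                      c(0, 45, 90, 135))
  expect_error(segment_subarcs(h, min_span = 100), class = "subarcvmat_config_error")
  expect_error(segment_subarcs(h, min_span = 1), class = "subarcvmat_config_error")
  big <- as_mci_heatmap(matrix(0.5, 41, 4), (179 - 2 * (0:40)) %% 360,
                        c(0, 45, 90, 135))
  expect_error(brute_force_segment(big), class = "subarcvmat_config_error")
})
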
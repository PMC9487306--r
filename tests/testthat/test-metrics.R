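# box-shaped structure as a contour stack, for dose-grid tests
box_contours <- function(name, half = c(15, 15, 15), center = c(0, 0, 0)) {
  zs <- seq(center[3] - half[3], center[3] + half[3], by = 1)
  dplyr::bind_rows(lapply(seq_along(zs), function(i) {
    contour_tbl(name, i, zs[i],
                x = center[1] + c(-1, 1, 1, -1) * half[1],
                y = center[2] + c(-1, -1, 1, 1) * half[2])
  }))
}

test_that("DVH point metrics are exact for uniform dose and sane for gradients", {
  arr <- array(30, dim = c(41, 41, 41))
  g <- dose_grid(arr, origin = c(-20, -20, -20), spacing = 1)
  box <- box_contours("t")
  dv <- dvh(g, box, "t")
  expect_equal(dvh_dose_at(dv, 2), 30)
  expect_equal(dvh_dose_at(dv, 50), 30)
  expect_equal(dvh_dose_at(dv, 98), 30)

  # dose rising linearly 0 -> 30 Gy across the box: D50 is the midpoint
  lin <- array(rep((0:40) / 40 * 30, times = 41 * 41), dim = c(41, 41, 41))
  gl <- dose_grid(lin, origin = c(-20, -20, -20), spacing = 1)
  dvl <- dvh(gl, box, "t")
  expect_lt(abs(dvh_dose_at(dvl, 50) - 15), 30 / 30)
  expect_gte(dvh_dose_at(dvl, 2), dvh_dose_at(dvl, 50))
  expect_gte(dvh_dose_at(dvl, 50), dvh_dose_at(dvl, 98))

  # cumulative curve is non-increasing in the threshold
  expect_true(all(diff(dvl$volume_cc) <= 0))

  far <- box_contours("far", center = c(500, 0, 0))
  expect_error(dvh(g, far, "far"), class = "subarcvmat_dose_error")
})

test_that("a sharp-edged prescription dose gives CI 1, HI 0, full coverage", {
  ph <- phantom_case(n_lesions = 1, volumes_cc = 4.18879,
                     centers = rbind(c(0, 0, 0)))
  dg <- make_synthetic_dose(ph, dp = 30, sigma = 0.1)
  idx <- plan_indices(dg, target_contours(ph), target = "PTV1", dp = 30)
  expect_lt(abs(idx$ci - 1), 0.02)
  expect_identical(idx$hi, 0)
  expect_equal(idx$coverage, 100)
  expect_equal(idx$d_max, 30)
  # step-function limit of the falloff: on a half-mm grid, because the 50%
  # isodose shell is thinner than a 1 mm lattice cell
  dg2 <- make_synthetic_dose(ph, dp = 30, sigma = 0.1, spacing = 0.5)
  idx2 <- plan_indices(dg2, target_contours(ph), target = "PTV1", dp = 30)
  expect_lt(abs(idx2$gi - 1), 0.05)
})

test_that("the radial falloff dose reproduces the closed-form gradient index", {
  ph <- phantom_case(n_lesions = 1, volumes_cc = 4.18879,
                     centers = rbind(c(0, 0, 0)))
  dg <- make_synthetic_dose(ph, dp = 30, sigma = 5)
  idx <- plan_indices(dg, target_contours(ph), target = "PTV1", dp = 30)
  gi_pred <- (1 + (5 / 10) * sqrt(2 * log(2)))^3
  expect_lt(abs(idx$gi - gi_pred) / gi_pred, 0.03)
  expect_lt(abs(idx$ci - 1), 0.02)
  expect_gte(idx$gi, 1)
  expect_identical(idx$hi, 0)        # HI = 0 iff D2 = D98
})

test_that("weighted field size follows the convex-combination arithmetic", {
  one <- tibble::tibble(span = 358, fs_cm2 = 100)
  expect_equal(weighted_field_size(one, 358), 100)
  two <- tibble::tibble(span = c(179, 179), fs_cm2 = c(100, 200))
  expect_equal(weighted_field_size(two, 358), 150)
  three <- tibble::tibble(span = c(100, 158, 100), fs_cm2 = c(50, 80, 120))
  expect_equal(weighted_field_size(three, 358), 29640 / 358)
  expect_gte(weighted_field_size(three, 358), min(three$fs_cm2))
  expect_lte(weighted_field_size(three, 358), max(three$fs_cm2))
  bad <- tibble::tibble(span = c(100, 100), fs_cm2 = c(50, 80))
  expect_error(weighted_field_size(bad, 358), class = "subarcvmat_config_error")
})

test_that("cohort summaries reproduce the bundled cohort's printed statistics", {
  cs <- cohort_summary(cohort_table())
  vol <- cs[cs$metric == "total_volume_cc", ]
  expect_equal(c(vol$median, vol$min, vol$max), c(19.6, 8.2, 48.2))
  rx <- cs[cs$metric == "rmax_x_cm", ]
  expect_equal(c(rx$median, rx$min, rx$max), c(8.8, 3.0, 12.5))
  ry <- cs[cs$metric == "rmax_y_cm", ]
  expect_equal(c(ry$median, ry$min, ry$max), c(7.5, 3.8, 10.8))
  rz <- cs[cs$metric == "rmax_z_cm", ]
  expect_equal(c(rz$median, rz$min, rz$max), c(10.2, 4.3, 17.6))

  single <- cohort_table()[3, ]
  cs1 <- cohort_summary(single)
  v1 <- cs1[cs1$metric == "total_volume_cc", ]
  expect_equal(v1$median, v1$min)
  expect_equal(v1$median, v1$max)
  expect_error(cohort_summary(cohort_table()[0, ]), class = "subarcvmat_config_error")
})

test_that("dose grids reject negative or non-finite values", {
  expect_error(dose_grid(array(-1, c(2, 2, 2))), class = "subarcvmat_dose_error")
  expect_error(dose_grid(array(NA_real_, c(2, 2, 2))), class = "subarcvmat_dose_error")
})
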
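#' Dose grid
#'
#' A 3D scalar dose array (Gy) on a regular grid. `origin` is the center of
#' voxel `[1, 1, 1]` in mm (LPS); `spacing` the voxel size per axis.
#'
#' @param dose Numeric 3D array, Gy, non-negative and finite.
#' @param origin 3-vector, mm.
#' @param spacing 3-vector (or scalar), mm.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose, origin = c(0, 0, 0), spacing = 1) {
  stopifnot(is.array(dose), length(dim(dose)) == 3L)
  if (any(!is.finite(dose)) || any(dose < 0)) {
    abort("dose must be finite and non-negative", class = "subarcvmat_dose_error")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0), length(origin) == 3L)
  structure(list(dose = dose, origin = as.numeric(origin), spacing = spacing),
            class = "dose_grid")
}

grid_axis <- function(g, k) g$origin[k] + (seq_len(dim(g$dose)[k]) - 1L) * g$spacing[k]

voxel_cc <- function(g) prod(g$spacing) / 1000

# logical mask of a structure on a dose grid (even-odd, nearest slice in z)
structure_mask_on_grid <- function(g, contours, structure = NULL) {
  contours <- validate_contour_tbl(contours)
  if (!is.null(structure)) contours <- contours[contours$structure %in% structure, ]
  if (nrow(contours) == 0L) abort("structure not found in contour table",
                                  class = "subarcvmat_contour_error")
  xs <- grid_axis(g, 1); ys <- grid_axis(g, 2); zs <- grid_axis(g, 3)
  key <- paste(contours$structure, contours$contour)
  polys <- split(contours[c("x", "y", "z")], key)
  pz <- vapply(polys, function(p) p$z[1], numeric(1))
  m <- array(FALSE, dim = dim(g$dose))
  # a grid slice maps to the nearest contour within half the coarser of the
  # two spacings (a dose grid finer than the contour stack must still see
  # every slice)
  zsu <- sort(unique(pz))
  slice_sp <- if (length(zsu) > 1L) min(diff(zsu)) else g$spacing[3]
  thr <- max(g$spacing[3], slice_sp) / 2 + 1e-9
  for (k in seq_along(zs)) {
    dz <- abs(pz - zs[k])
    sel <- which(dz <= thr)
    if (length(sel) == 0L) next
    sel <- sel[dz[sel] <= min(dz[sel]) + 1e-9]
    for (s in sel) {
      p <- polys[[s]]
      ix <- which(xs >= min(p$x) - g$spacing[1] & xs <= max(p$x) + g$spacing[1])
      iy <- which(ys >= min(p$y) - g$spacing[2] & ys <= max(p$y) + g$spacing[2])
      if (length(ix) == 0L || length(iy) == 0L) next
      gx <- rep(xs[ix], times = length(iy))
      gy <- rep(ys[iy], each = length(ix))
      io <- pracma::inpolygon(gx, gy, p$x, p$y, boundary = TRUE)
      m[ix, iy, k] <- xor(m[ix, iy, k], matrix(io, length(ix), length(iy)))
    }
  }
  m
}

#' Dose-volume histogram of a structure
#'
#' Samples the dose at voxel centers inside the structure and returns the
#' cumulative DVH. `D_x%` values (dose received by at least x% of the
#' volume) are linearly interpolated on the sorted sample
#' (`stats::quantile` type 7); `V_t` is the absolute volume at dose >= t.
#'
#' @param dose A [dose_grid()].
#' @param contours A `contour_tbl` containing the structure.
#' @param structure Structure name (default: all structures in `contours`).
#' @return A tibble of class `dvh_curve` (`dose`, `volume_cc`,
#'   `volume_frac`), with the raw samples and voxel volume as attributes.
#' @export
dvh <- function(dose, contours, structure = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  m <- structure_mask_on_grid(dose, contours, structure)
  if (!any(m)) abort("structure does not overlap the dose grid",
                     class = "subarcvmat_dose_error")
  samples <- dose$dose[m]
  vox <- voxel_cc(dose)
  d <- sort(unique(c(0, samples)))
  vol <- vapply(d, function(t) sum(samples >= t - 1e-12), numeric(1)) * vox
  out <- tibble(dose = d, volume_cc = vol, volume_frac = vol / (length(samples) * vox))
  class(out) <- c("dvh_curve", class(out))
  attr(out, "samples") <- samples
  attr(out, "voxel_cc") <- vox
  out
}

#' @rdname dvh
#' @param curve A `dvh_curve`.
#' @param x Percent volume (for `dvh_dose_at`, the D_x% metric).
#' @export
dvh_dose_at <- function(curve, x) {
  s <- attr(curve, "samples")
  as.numeric(quantile(s, 1 - x / 100, type = 7, names = FALSE))
}

#' @rdname dvh
#' @param threshold Dose threshold, Gy (for `dvh_volume_at`, the V_t metric).
#' @export
dvh_volume_at <- function(curve, threshold) {
  s <- attr(curve, "samples")
  sum(s >= threshold - 1e-12) * attr(curve, "voxel_cc")
}

#' Plan-quality indices
#'
#' DVH-derived indices of a dose distribution against a planning target:
#' conformity index `CI = V_ref / V_T` (prescription isodose volume over
#' target volume), homogeneity index `HI = (D2% - D98%) / Dp`, gradient
#' index `GI = V50% / V100%` (absolute tissue volumes at 50% and 100% of the
#' prescription dose), target coverage, and the D/V point metrics.
#' `V_ref`/`V_x%` are counted inside the body structure when one is given,
#' otherwise over the whole grid.
#'
#' @param dose A [dose_grid()].
#' @param contours Contour table holding the target (and optionally body).
#' @param target Target structure name(s) (all combined as one PTV).
#' @param body Optional body structure name.
#' @param dp Prescription dose, Gy.
#' @return A one-row tibble of class `plan_indices`.
#' @export
plan_indices <- function(dose, contours, target, body = NULL, dp) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!is.numeric(dp) || dp <= 0) abort("`dp` must be positive",
                                        class = "subarcvmat_dose_error")
  vox <- voxel_cc(dose)
  tmask <- structure_mask_on_grid(dose, contours, target)
  if (!any(tmask)) abort("target does not overlap the dose grid",
                         class = "subarcvmat_dose_error")
  ts <- dose$dose[tmask]
  tissue <- if (is.null(body)) dose$dose else {
    bm <- structure_mask_on_grid(dose, contours, body)
    dose$dose[bm]
  }
  v100 <- sum(tissue >= dp - 1e-12) * vox
  v50 <- sum(tissue >= dp / 2 - 1e-12) * vox
  if (v100 <= 0) abort("GI undefined: no tissue at the prescription dose",
                       class = "subarcvmat_dose_error")
  d2 <- as.numeric(quantile(ts, 0.98, type = 7, names = FALSE))
  d50 <- as.numeric(quantile(ts, 0.50, type = 7, names = FALSE))
  d98 <- as.numeric(quantile(ts, 0.02, type = 7, names = FALSE))
  out <- tibble(
    ci = v100 / (sum(tmask) * vox),
    hi = (d2 - d98) / dp,
    gi = v50 / v100,
    coverage = 100 * mean(ts >= dp - 1e-12),
    d_min = min(ts), d_max = max(ts), d_mean = mean(ts),
    d2 = d2, d50 = d50, d98 = d98,
    v100_cc = v100, v50_cc = v50,
    target_cc = sum(tmask) * vox,
    dp = dp)
  class(out) <- c("plan_indices", class(out))
  out
}

#' Arc-weighted mean field size
#'
#' `FS = sum_i (phi_i / Phi) * fs_i` over the sub-arcs of one arc, where
#' `phi_i` is the sub-arc's gantry span and `Phi` the full arc span
#' (358 degrees for a 179 -> 181 arc). A convex combination of the per-sub-arc
#' jaw field sizes.
#'
#' @param plan A `subarc_plan` with an `fs_cm2` column (see
#'   [subarc_field_sizes()]), or any data frame with `span` and `fs_cm2`.
#' @param phi_total Full arc span, degrees; defaults to `sum(plan$span)`.
#' @return Weighted field size, cm2.
#' @export
weighted_field_size <- function(plan, phi_total = NULL) {
  stopifnot(is.data.frame(plan), all(c("span", "fs_cm2") %in% names(plan)))
  phi_total <- phi_total %||% sum(plan$span)
  tol <- if (inherits(plan, "subarc_plan")) attr(plan, "cp_spacing") %||% 2 else 2
  if (abs(sum(plan$span) - phi_total) > tol + 1e-9) {
    abort(sprintf("sub-arc spans sum to %g, expected the arc span %g",
                  sum(plan$span), phi_total),
          class = "subarcvmat_config_error")
  }
  sum(plan$span / phi_total * plan$fs_cm2)
}

#' Cohort summary statistics
#'
#' Median and range of the total target volume and of the per-axis maximum
#' inter-lesion distance over a cohort table (see [cohort_table()]). Medians
#' of even-sized cohorts are the midpoint of the two central values; results
#' are rounded to one decimal, half away from zero (the reporting
#' convention).
#'
#' @param cohort A data frame with columns `total_volume_cc`, `rmax_x_cm`,
#'   `rmax_y_cm`, `rmax_z_cm`.
#' @return A tibble with one row per metric: `metric`, `median`, `min`, `max`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) abort("empty cohort table",
                                class = "subarcvmat_config_error")
  metrics <- c("total_volume_cc", "rmax_x_cm", "rmax_y_cm", "rmax_z_cm")
  metrics <- metrics[metrics %in% names(cohort)]
  if (length(metrics) == 0L) abort("no summarizable columns in cohort table",
                                   class = "subarcvmat_config_error")
  bind_rows(lapply(metrics, function(m) {
    v <- cohort[[m]]
    tibble(metric = m,
           median = round_half_away(median(v), 1),
           min = round_half_away(min(v), 1),
           max = round_half_away(max(v), 1))
  }))
}
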
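#' MLC model
#'
#' Leaf-bank description projected to the isocenter plane. The default is a
#' Millennium-120-class bank: per side 10 outer leaves of 10 mm, 40 central
#' leaves of 5 mm, 10 outer leaves of 10 mm (60 opposed pairs, 400 mm bank
#' height). The bank is centered on the isocenter projection (v = 0 at bank
#' center); leaves travel along u.
#'
#' @param leaf_widths Ordered leaf widths, mm, at isocenter.
#' @param max_span Maximum leaf-pair opening, mm (stored; deliverability is
#'   not modeled).
#' @return An object of class `mlc_model` with precomputed band `edges`.
#' @export
mlc_model <- function(leaf_widths = c(rep(10, 10), rep(5, 40), rep(10, 10)),
                      max_span = 150) {
  stopifnot(is.numeric(leaf_widths), all(leaf_widths > 0), max_span > 0)
  leaf_widths <- as.numeric(leaf_widths)
  total <- sum(leaf_widths)
  edges <- cumsum(c(0, leaf_widths)) - total / 2
  structure(list(leaf_widths = as.numeric(leaf_widths),
                 edges = edges,
                 n_pairs = length(leaf_widths),
                 bank_height = total,
                 max_span = max_span,
                 symmetric = isTRUE(all.equal(leaf_widths, rev(leaf_widths)))),
            class = "mlc_model")
}

#' Load an MLC model from a JSON machine file
#'
#' Expects `{"leaf_widths_mm": [...], "max_span_mm": ...}`.
#' @param path Path to a JSON file.
#' @export
read_mlc_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mlc_model(leaf_widths = x$leaf_widths_mm,
            max_span = x$max_span_mm %||% 150)
}

# snap pixel-center extents outward to pixel edges, +/- margin
snap_left  <- function(u, px, margin) floor((u - px / 2) / px + 1e-9) * px - margin
snap_right <- function(u, px, margin) ceiling((u + px / 2) / px - 1e-9) * px + margin

#' Fit a conformal MLC aperture to a BEV silhouette
#'
#' For every leaf pair whose v-band intersects true pixels, the leaf tips are
#' set to the outermost pixel extent in that band, snapped outward to pixel
#' edges, plus an optional margin. Pairs without target are closed. A leaf
#' pair is a single interval: disconnected blobs sharing a band produce one
#' spanning opening — this is exactly what creates the island-blocking
#' problem.
#'
#' @param bev A [bev_mask()] in the collimator frame.
#' @param mlc An [mlc_model()].
#' @param margin Extra opening per side, mm (default 0; the PTV margin is
#'   assumed already included in the structure).
#' @return A tibble of class `mlc_aperture` with one row per leaf pair
#'   (`pair`, `v_low`, `v_high`, `u_left`, `u_right`, `open`), attributes
#'   `a_mlc_cm2` (open aperture area) and `jaw` (tight bounding rectangle,
#'   named vector u_min/u_max/v_min/v_max).
#' @export
fit_aperture <- function(bev, mlc = mlc_model(), margin = 0) {
  stopifnot(inherits(bev, "bev_mask"), inherits(mlc, "mlc_model"), margin >= 0)
  idx <- which(bev$pixels, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    abort("cannot fit an aperture to an empty BEV mask",
          class = "subarcvmat_aperture_error")
  }
  px <- bev$pixel_spacing
  uu <- bev$u_centers[idx[, 1]]
  vv <- bev$v_centers[idx[, 2]]
  band <- findInterval(vv, mlc$edges)
  if (any(band < 1L) || any(band > mlc$n_pairs)) {
    abort("silhouette exceeds the MLC bank height",
          class = "subarcvmat_aperture_error")
  }
  ext <- data.table::data.table(band = band, u = uu)[
    , list(umin = min(u), umax = max(u)), by = "band"]
  open <- logical(mlc$n_pairs)
  open[ext$band] <- TRUE
  u_left <- rep(NA_real_, mlc$n_pairs)
  u_right <- rep(NA_real_, mlc$n_pairs)
  u_left[ext$band] <- snap_left(ext$umin, px, margin)
  u_right[ext$band] <- snap_right(ext$umax, px, margin)
  widths <- mlc$leaf_widths
  a_mlc <- sum((u_right - u_left)[open] * widths[open]) / 100  # cm^2
  jaw <- c(u_min = min(u_left[open]), u_max = max(u_right[open]),
           v_min = mlc$edges[min(which(open))],
           v_max = mlc$edges[max(which(open)) + 1L])
  out <- tibble(pair = seq_len(mlc$n_pairs),
                v_low = mlc$edges[-length(mlc$edges)],
                v_high = mlc$edges[-1L],
                u_left = u_left, u_right = u_right, open = open)
  class(out) <- c("mlc_aperture", class(out))
  attr(out, "a_mlc_cm2") <- a_mlc
  attr(out, "jaw") <- jaw
  attr(out, "pixel_spacing") <- px
  attr(out, "margin") <- margin
  out
}

#' MLC conformity index
#'
#' `MCI = A_TP / A_MLC`: the ratio of the target-projection area in the BEV
#' to the area of the fitted MLC aperture. 1 is perfect conformity; values
#' below 1 quantify unshielded normal tissue inside the aperture (e.g. the
#' island-blocking bridge between targets sharing a leaf pair).
#'
#' @param bev The [bev_mask()] the aperture was fitted to.
#' @param aperture The corresponding [fit_aperture()] result.
#' @return A one-row tibble: `mci`, `a_tp_cm2`, `a_mlc_cm2`.
#' @export
compute_mci <- function(bev, aperture) {
  stopifnot(inherits(bev, "bev_mask"), inherits(aperture, "mlc_aperture"))
  a_tp <- bev_area_cm2(bev)
  a_mlc <- attr(aperture, "a_mlc_cm2")
  if (!is.finite(a_mlc) || a_mlc <= 0) {
    abort("undefined MCI: aperture area is zero", class = "subarcvmat_aperture_error")
  }
  # coverage guarantee: every true pixel inside its open pair's rectangle
  idx <- which(bev$pixels, arr.ind = TRUE)
  vv <- bev$v_centers[idx[, 2]]
  uu <- bev$u_centers[idx[, 1]]
  band <- findInterval(vv, c(aperture$v_low[1L], aperture$v_high))
  ok <- band >= 1L & band <= nrow(aperture)
  ok[ok] <- aperture$open[band[ok]] &
    uu[ok] >= aperture$u_left[band[ok]] - 1e-9 &
    uu[ok] <= aperture$u_right[band[ok]] + 1e-9
  if (!all(ok)) {
    abort("aperture does not cover the silhouette it is scored against",
          class = "subarcvmat_aperture_error")
  }
  mci <- min(a_tp / a_mlc, 1)
  tibble(mci = mci, a_tp_cm2 = a_tp, a_mlc_cm2 = a_mlc)
}

#' Jaw field size of an aperture
#'
#' Area of the tight jaw rectangle bounding all open leaf pairs, in cm2.
#' @param aperture A [fit_aperture()] result.
#' @export
aperture_field_size <- function(aperture) {
  stopifnot(inherits(aperture, "mlc_aperture"))
  if (!any(aperture$open)) {
    abort("all leaf pairs closed: no field", class = "subarcvmat_aperture_error")
  }
  jaw <- attr(aperture, "jaw")
  unname((jaw["u_max"] - jaw["u_min"]) * (jaw["v_max"] - jaw["v_min"]) / 100)
}

#' Export an aperture to CSV
#' @param aperture A [fit_aperture()] result.
#' @param path Output file.
#' @export
write_aperture_csv <- function(aperture, path) {
  data.table::fwrite(as.data.frame(aperture), path)
  invisible(path)
}
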
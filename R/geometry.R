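#' Linac geometry
#'
#' Machine geometry for the beam's-eye-view (BEV) projection: a C-arm linac
#' with source-axis distance `sad` rotating about an isocenter, gantry angles
#' per IEC 61217 (0 = source anterior, 90 = source at patient left).
#'
#' @param sad Source-axis distance, mm (default 1000).
#' @param isocenter 3-vector, mm, patient LPS coordinates.
#' @return An object of class `linac_geometry`.
#' @export
linac_geometry <- function(sad = 1000, isocenter = c(0, 0, 0)) {
  if (!is.numeric(sad) || length(sad) != 1L || !is.finite(sad) || sad <= 0) {
    abort("`sad` must be a single positive number (mm)",
          class = "subarcvmat_config_error")
  }
  stopifnot(length(isocenter) == 3, all(is.finite(isocenter)))
  structure(list(sad = sad, isocenter = as.numeric(isocenter),
                 gantry_convention = "IEC 61217"),
            class = "linac_geometry")
}

#' Arc specification and control points
#'
#' A coplanar VMAT arc discretized into control points (CPs) every
#' `cp_spacing` degrees of gantry rotation. The clinical default is a dual
#' full arc 179 -> 181 -> 179 (each arc spanning 358 degrees, skipping the
#' posterior 2-degree sector); with 2 degrees/CP that gives 180 CPs per arc.
#' `direction = "CCW"` means decreasing gantry angle (179, 177, ..., 181).
#'
#' @param start,stop Gantry start/stop angles, degrees in `[0, 360)`.
#' @param direction `"CW"` or `"CCW"`.
#' @param cp_spacing Degrees of gantry rotation per control point (default 2).
#' @return `arc_spec()`: an object of class `arc_spec` with the derived
#'   `total_span` and `n_cp`. `control_points()`: numeric vector of gantry
#'   angles in `[0, 360)`, endpoints inclusive (for a full 360-degree arc the
#'   duplicate stop angle is dropped).
#' @examples
#' control_points(arc_spec(0, 90, "CW", 30))   # 0 30 60 90
#' length(control_points(arc_spec()))          # 180
#' @export
arc_spec <- function(start = 179, stop = 181, direction = c("CCW", "CW"),
                     cp_spacing = 2) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(start), is.numeric(stop), cp_spacing > 0)
  start <- start %% 360; stop <- stop %% 360
  span <- if (direction == "CCW") (start - stop) %% 360 else (stop - start) %% 360
  if (span == 0) span <- 360
  if (abs(span / cp_spacing - round(span / cp_spacing)) > 1e-9) {
    abort(sprintf("cp_spacing %g does not divide the arc span %g", cp_spacing, span),
          class = "subarcvmat_config_error")
  }
  n_cp <- as.integer(round(span / cp_spacing)) + 1L
  if (span == 360) n_cp <- n_cp - 1L  # duplicate endpoint dropped
  structure(list(start = start, stop = stop, direction = direction,
                 cp_spacing = cp_spacing, total_span = span, n_cp = n_cp),
            class = "arc_spec")
}

#' @rdname arc_spec
#' @param arc An `arc_spec`.
#' @export
control_points <- function(arc) {
  stopifnot(inherits(arc, "arc_spec"))
  step <- if (arc$direction == "CCW") -arc$cp_spacing else arc$cp_spacing
  (arc$start + step * (seq_len(arc$n_cp) - 1L)) %% 360
}

#' Rasterize a contour stack into a 3D voxel mask
#'
#' Voxel centers lie on the contour z grid in z (so CT-like slices are
#' sampled exactly) and at half-voxel offsets in x/y. Interior test is the
#' even-odd rule; multiple contours on one slice XOR (holes supported).
#' Degenerate (zero-area) polygons are skipped with a warning.
#'
#' @param contours A `contour_tbl` (one or more structures; their union is
#'   rasterized).
#' @param voxel Voxel edge length, mm (default 1).
#' @return An object of class `vox_mask`: logical 3D array plus grid metadata.
#' @export
rasterize_structure <- function(contours, voxel = 1) {
  contours <- validate_contour_tbl(contours)
  stopifnot(voxel > 0)
  key <- paste(contours$structure, contours$contour)
  polys <- split(contours[c("x", "y", "z")], key)
  areas <- vapply(polys, function(p) polygon_area(p$x, p$y), numeric(1))
  if (any(areas <= 1e-9)) {
    warn(sprintf("skipping %d degenerate (zero-area) contour(s)",
                 sum(areas <= 1e-9)))
    polys <- polys[areas > 1e-9]
  }
  if (length(polys) == 0L) {
    abort("no non-degenerate contours to rasterize",
          class = "subarcvmat_contour_error")
  }
  xr <- range(unlist(lapply(polys, `[[`, "x")))
  yr <- range(unlist(lapply(polys, `[[`, "y")))
  zs_all <- vapply(polys, function(p) p$z[1], numeric(1))
  zr <- range(zs_all)
  # x/y centers at half-voxel offsets from the mm grid; z centers on slice z's
  x0 <- floor(xr[1] / voxel) * voxel - voxel
  y0 <- floor(yr[1] / voxel) * voxel - voxel
  xc <- seq(x0 + voxel / 2, xr[2] + voxel, by = voxel)
  yc <- seq(y0 + voxel / 2, yr[2] + voxel, by = voxel)
  zc <- seq(round(zr[1] / voxel) * voxel, round(zr[2] / voxel) * voxel, by = voxel)
  arr <- array(FALSE, dim = c(length(xc), length(yc), length(zc)))
  for (k in seq_along(zc)) {
    dz <- abs(zs_all - zc[k])
    sel <- which(dz <= voxel / 2 + 1e-9)
    if (length(sel) == 0L) next
    # nearest slice only (ties include both z's -> still XORed per polygon)
    sel <- sel[dz[sel] <= min(dz[sel]) + 1e-9]
    for (s in sel) {
      p <- polys[[s]]
      # candidate voxels restricted to the polygon's bounding box
      ix <- which(xc >= min(p$x) - voxel & xc <= max(p$x) + voxel)
      iy <- which(yc >= min(p$y) - voxel & yc <= max(p$y) + voxel)
      if (length(ix) == 0L || length(iy) == 0L) next
      gx <- rep(xc[ix], times = length(iy))
      gy <- rep(yc[iy], each = length(ix))
      io <- pracma::inpolygon(gx, gy, p$x, p$y, boundary = TRUE)
      arr[ix, iy, k] <- xor(arr[ix, iy, k], matrix(io, length(ix), length(iy)))
    }
  }
  if (!any(arr)) {
    abort("rasterization produced an empty mask", class = "subarcvmat_contour_error")
  }
  structure(list(mask = arr, xc = xc, yc = yc, zc = zc, voxel = voxel),
            class = "vox_mask")
}

#' @rdname rasterize_structure
#' @param x A `vox_mask`.
#' @export
vox_points <- function(x) {
  stopifnot(inherits(x, "vox_mask"))
  idx <- which(x$mask, arr.ind = TRUE)
  cbind(x = x$xc[idx[, 1]], y = x$yc[idx[, 2]], z = x$zc[idx[, 3]])
}

#' @rdname rasterize_structure
#' @export
mask_volume_cc <- function(x) {
  stopifnot(inherits(x, "vox_mask"))
  sum(x$mask) * x$voxel^3 / 1000
}

#' BEV mask
#'
#' Binary raster of a target silhouette on the isocenter plane for one
#' control point. The u axis is the MLC leaf-travel direction at collimator 0,
#' v the leaf-stacking direction. Pixel edges lie on multiples of
#' `pixel_spacing` and the isocenter projects to the raster center.
#'
#' @param pixels Logical matrix, rows indexing u, columns indexing v.
#' @param pixel_spacing Pixel size, mm (default 0.5).
#' @return An object of class `bev_mask`.
#' @export
bev_mask <- function(pixels, pixel_spacing = 0.5) {
  stopifnot(is.matrix(pixels), is.logical(pixels), pixel_spacing > 0)
  nu <- nrow(pixels); nv <- ncol(pixels)
  structure(list(pixels = pixels,
                 pixel_spacing = pixel_spacing,
                 u_centers = (seq_len(nu) - nu / 2 - 0.5) * pixel_spacing,
                 v_centers = (seq_len(nv) - nv / 2 - 0.5) * pixel_spacing),
            class = "bev_mask")
}

#' @rdname bev_mask
#' @param bev A `bev_mask`.
#' @export
bev_area_cm2 <- function(bev) {
  stopifnot(inherits(bev, "bev_mask"))
  sum(bev$pixels) * bev$pixel_spacing^2 / 100
}

# beam frame unit vectors for a gantry angle (deg), patient LPS.
# w: source -> isocenter; u: leaf travel at collimator 0; v: leaf stacking
# (patient superior). Source sits at sad * (sin g, -cos g, 0).
beam_frame <- function(gantry) {
  g <- gantry * pi / 180
  list(u = c(cos(g), sin(g), 0),
       v = c(0, 0, 1),
       w = c(-sin(g), cos(g), 0))
}

# project 3D points (n x 3, LPS mm) for one gantry angle -> list(u, v) on the
# isocenter plane
project_points <- function(pts, gantry, geom, mode) {
  fr <- beam_frame(gantry)
  p <- sweep(pts, 2L, geom$isocenter)
  t_beam <- p %*% fr$w        # signed distance along beam axis from isocenter
  d <- -t_beam                # distance toward the source
  if (mode == "divergent") {
    if (any(d >= geom$sad - 1e-6)) {
      abort("structure voxel at or behind the radiation source",
            class = "subarcvmat_geometry_error")
    }
    s <- geom$sad / (geom$sad - d)
  } else {
    s <- rep(1, nrow(p))
  }
  list(u = as.numeric((p %*% fr$u) * s), v = as.numeric((p %*% fr$v) * s))
}

# rasterize projected points onto a centered BEV grid and close 1-px holes.
# A point lying exactly on a pixel edge marks the pixels on both sides, so
# rasterization commutes with mirror reflection (needed for exact
# opposed-beam symmetry in parallel mode).
points_to_bev <- function(u, v, pixel) {
  tol <- 1e-6
  half <- max(abs(c(u, v)), pixel) + 4 * pixel
  nh <- as.integer(ceiling(half / pixel))
  n <- 2L * nh
  iu0 <- as.integer(floor((u - tol) / pixel)) + nh + 1L
  iu1 <- as.integer(floor((u + tol) / pixel)) + nh + 1L
  iv0 <- as.integer(floor((v - tol) / pixel)) + nh + 1L
  iv1 <- as.integer(floor((v + tol) / pixel)) + nh + 1L
  m <- matrix(0L, n, n)
  m[cbind(iu0, iv0)] <- 1L
  m[cbind(iu1, iv0)] <- 1L
  m[cbind(iu0, iv1)] <- 1L
  m[cbind(iu1, iv1)] <- 1L
  # disc brush sized to the voxel scale: fills both the sampling holes and
  # the ~1-voxel rim bites of the voxelized solid isotropically, so chord
  # measurements are direction-independent
  closed <- EBImage::closing(m, EBImage::makeBrush(5L, "disc"))
  bev_mask(closed > 0.5, pixel)
}

# silhouette of contour stacks for one gantry angle, by an analytic row-span
# sweep. All arcs here are coplanar, so the beam axis lies in every slice
# plane and a filled slice polygon casts a shadow that is exactly one
# u-interval at v ~ z * scale (the in-slice divergence spread of v, well
# below half a pixel, is collapsed to the mean). Between adjacent slices the
# contour is linearly interpolated vertex-wise (exact for the generated
# equal-vertex stacks; structures with ambiguous slice pairing fall back to
# slab extrusion), sampled every half pixel in z so every raster row in the
# structure's span is hit; end slices are extruded half a slice spacing.
# Union over polygons -- a shadow has no holes from inner contours. The
# result is continuous-geometry silhouettes with no voxel-lattice
# raggedness at the rim.
# row-slab decomposition of the projected silhouette: one u-interval per
# half-pixel z sample, plus cap flags for the first/last slab of each
# structure chain
contour_slab_samples <- function(contours, gantry, geom, pixel, mode) {
  contours <- validate_contour_tbl(contours)
  key <- paste(contours$structure, contours$contour)
  polys <- split(contours[c("x", "y", "z")], key)
  areas <- vapply(polys, function(p) polygon_area(p$x, p$y), numeric(1))
  polys <- polys[areas > 1e-9]
  if (length(polys) == 0L) {
    abort("no non-degenerate contours to project",
          class = "subarcvmat_contour_error")
  }
  struct_of <- sub(" [0-9]+$", "", names(polys))
  zstep <- pixel / 2
  samples <- list()
  add <- function(x, y, z, cap = FALSE) {
    samples[[length(samples) + 1L]] <<- list(x = x, y = y, z = z, cap = cap)
  }
  for (nm in unique(struct_of)) {
    sp <- polys[struct_of == nm]
    zs <- vapply(sp, function(p) p$z[1], numeric(1))
    sp <- sp[order(zs)]; zs <- sort(zs)
    half <- if (length(zs) > 1L) min(diff(zs)) / 2 else 0.5
    interp_ok <- !any(duplicated(zs)) &&
      length(unique(lengths(lapply(sp, `[[`, "x")))) == 1L
    for (k in seq_along(sp)) {
      p <- sp[[k]]
      if (k < length(sp)) {
        q <- sp[[k + 1L]]
        dz <- q$z[1] - p$z[1]
        nt <- max(2L, as.integer(ceiling(dz / zstep)) + 1L)
        if (interp_ok) {
          for (t in seq(0, 1, length.out = nt)) {
            add((1 - t) * p$x + t * q$x, (1 - t) * p$y + t * q$y,
                (1 - t) * p$z[1] + t * q$z[1])
          }
        } else {
          for (zz in seq(p$z[1] - half, p$z[1] + half, by = zstep)) {
            add(p$x, p$y, zz, cap = TRUE)
          }
        }
      }
      if (k == 1L || !interp_ok) {
        for (zz in seq(p$z[1] - half, p$z[1], by = zstep)) {
          add(p$x, p$y, zz, cap = zz == p$z[1] - half)
        }
      }
      if (k == length(sp) || !interp_ok) {
        for (zz in seq(p$z[1], p$z[1] + half, by = zstep)) {
          add(p$x, p$y, zz, cap = zz == p$z[1] + half)
        }
      }
    }
  }
  nv <- vapply(samples, function(s) length(s$x), integer(1))
  verts <- cbind(unlist(lapply(samples, `[[`, "x")),
                 unlist(lapply(samples, `[[`, "y")),
                 rep.int(vapply(samples, function(s) s$z[1], numeric(1)), nv))
  pr <- project_points(verts, gantry, geom, mode)
  grp <- rep.int(seq_along(samples), nv)
  list(umin = vapply(split(pr$u, grp), min, numeric(1)),
       umax = vapply(split(pr$u, grp), max, numeric(1)),
       vbar = vapply(split(pr$v, grp), mean, numeric(1)),
       cap = vapply(samples, function(s) isTRUE(s$cap), logical(1)),
       zstep = zstep)
}

# boundary point set of the continuous slab silhouette: the interval
# endpoints lie exactly on the left/right envelopes (half-pixel v spacing);
# cap slabs additionally contribute points along their exposed horizontal
# edge. Used for raster-free per-band extent measurement over collimator
# angles.
contour_boundary_points <- function(sl, pixel) {
  pts <- rbind(cbind(sl$umin, sl$vbar), cbind(sl$umax, sl$vbar))
  caps <- which(sl$cap)
  if (length(caps)) {
    extra <- lapply(caps, function(s) {
      w <- sl$umax[s] - sl$umin[s]
      nu <- max(2L, as.integer(ceiling(w / pixel)) + 1L)
      cbind(seq(sl$umin[s], sl$umax[s], length.out = nu), sl$vbar[s])
    })
    pts <- rbind(pts, do.call(rbind, extra))
  }
  pts
}

contour_slab_bev <- function(contours, gantry, geom, pixel, mode,
                             sl = NULL) {
  if (is.null(sl)) sl <- contour_slab_samples(contours, gantry, geom, pixel, mode)
  umin <- sl$umin; umax <- sl$umax; vbar <- sl$vbar; zstep <- sl$zstep
  halfw <- max(abs(c(umin, umax, vbar)), pixel) + 4 * pixel
  nh <- as.integer(ceiling(halfw / pixel))
  n <- 2L * nh
  m <- matrix(FALSE, n, n)
  tol <- 1e-9
  # a sample covers every row whose center lies inside its half-step slab
  j_lo <- pmax(1L, as.integer(ceiling((vbar - zstep / 2 - tol) / pixel + nh + 0.5 - 1e-12)))
  j_hi <- pmin(n, as.integer(floor((vbar + zstep / 2 + tol) / pixel + nh + 0.5 + 1e-12)))
  i_lo <- pmax(1L, as.integer(ceiling((umin - tol) / pixel + nh + 0.5 - 1e-12)))
  i_hi <- pmin(n, as.integer(floor((umax + tol) / pixel + nh + 0.5 + 1e-12)))
  for (s in seq_along(umin)) {
    if (i_hi[s] >= i_lo[s] && j_hi[s] >= j_lo[s]) {
      m[i_lo[s]:i_hi[s], j_lo[s]:j_hi[s]] <- TRUE
    }
  }
  closed <- EBImage::closing(m * 1L, EBImage::makeBrush(3L, "box"))
  bev_mask(closed > 0.5, pixel)
}

#' Project a structure into the beam's eye view
#'
#' Projects a voxelized structure onto the isocenter plane for one gantry
#' angle. In `divergent` mode each voxel is projected along the ray from the
#' point source (magnification `sad / (sad - d)` for a voxel a distance `d`
#' from the isocenter plane toward the source); `parallel` mode sets the
#' magnification to 1. The projected point cloud is rasterized and
#' morphologically closed (1-pixel radius) to remove sampling holes.
#'
#' @param x A `contour_tbl` (slice polygons projected directly, slab model:
#'   the highest-fidelity route), a `vox_mask`, or an n x 3 matrix of points
#'   (mm, LPS).
#' @param gantry Gantry angle, degrees.
#' @param geom A [linac_geometry()].
#' @param pixel BEV pixel size, mm (default 0.5).
#' @param mode `"divergent"` (physical BEV) or `"parallel"`.
#' @return A [bev_mask()].
#' @export
project_bev <- function(x, gantry, geom = linac_geometry(), pixel = 0.5,
                        mode = c("divergent", "parallel")) {
  mode <- match.arg(mode)
  if (is.data.frame(x)) return(contour_slab_bev(x, gantry, geom, pixel, mode))
  pts <- structure_points(x)
  pr <- project_points(pts, gantry, geom, mode)
  points_to_bev(pr$u, pr$v, pixel)
}

# voxel centers supersampled to the eight sub-voxel centers, so the
# projected point cloud fills the silhouette isotropically at half-voxel
# resolution (plain centers leave ~voxel-scale lattice raggedness at the
# silhouette rim, which shows up as anisotropy over collimator angle)
vox_points_dense <- function(x) {
  p <- vox_points(x)
  h <- x$voxel / 4
  offs <- as.matrix(expand.grid(c(-h, h), c(-h, h), c(-h, h)))
  out <- matrix(0, nrow(p) * 8L, 3L)
  for (k in 1:8) {
    out[seq.int((k - 1L) * nrow(p) + 1L, k * nrow(p)), ] <-
      sweep(p, 2L, offs[k, ], `+`)
  }
  out
}

structure_points <- function(x, voxel = 1) {
  if (inherits(x, "vox_mask")) return(vox_points_dense(x))
  if (is.matrix(x) && ncol(x) == 3L) {
    if (nrow(x) == 0L) abort("no points to project",
                             class = "subarcvmat_geometry_error")
    return(x)
  }
  abort("cannot interpret `x` as a structure (vox_mask or point matrix)",
        class = "subarcvmat_geometry_error")
}

#' Rotate a BEV mask into the collimator frame
#'
#' Rotates the raster by `-theta` about the isocenter projection, so that MLC
#' aperture fitting always happens along fixed (leaf-aligned) axes. Bilinear
#' interpolation thresholded at 0.5.
#'
#' @param bev A [bev_mask()].
#' @param theta Collimator angle, degrees.
#' @return A [bev_mask()] on the same grid.
#' @export
rotate_bev <- function(bev, theta) {
  stopifnot(inherits(bev, "bev_mask"))
  theta <- theta %% 360
  if (theta == 0) return(bev)
  px <- bev$pixel_spacing
  nu <- nrow(bev$pixels); nv <- ncol(bev$pixels)
  ct <- cos(theta * pi / 180); st <- sin(theta * pi / 180)
  pu <- matrix(bev$u_centers, nu, nv)
  pv <- matrix(bev$v_centers, nu, nv, byrow = TRUE)
  # source location in the unrotated frame: q = R(theta) p
  qu <- pu * ct - pv * st
  qv <- pu * st + pv * ct
  fi <- qu / px + nu / 2 + 0.5   # fractional row index (pixel centers integer)
  fj <- qv / px + nv / 2 + 0.5
  i0 <- floor(fi); j0 <- floor(fj)
  di <- fi - i0; dj <- fj - j0
  m <- bev$pixels
  val <- at(m, i0,      j0     ) * (1 - di) * (1 - dj) +
         at(m, i0 + 1L, j0     ) * di       * (1 - dj) +
         at(m, i0,      j0 + 1L) * (1 - di) * dj +
         at(m, i0 + 1L, j0 + 1L) * di       * dj
  bev_mask(matrix(val >= 0.5 - 1e-9, nu, nv), px)
}

# zero-padded matrix lookup for vectorized bilinear sampling
at <- function(m, i, j) {
  ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
  out <- numeric(length(i))
  out[ok] <- m[cbind(i[ok], j[ok])]
  out
}

# boundary pixels of a bev mask (true pixels with a false 4-neighbour);
# returns their (u, v) center coordinates
bev_boundary_points <- function(bev) {
  m <- bev$pixels
  up    <- rbind(m[-1, , drop = FALSE], FALSE)
  down  <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
  left  <- cbind(m[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
  interior <- m & up & down & left & right
  b <- m & !interior
  idx <- which(b, arr.ind = TRUE)
  cbind(u = bev$u_centers[idx[, 1]], v = bev$v_centers[idx[, 2]])
}
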
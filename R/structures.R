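#' Contour tables
#'
#' Structures (targets, body) are represented as tidy contour tables: one row
#' per polygon vertex, with columns `structure` (name), `contour` (integer id,
#' unique within a structure), `z` (slice position, mm), and `x`, `y` (vertex
#' coordinates, mm). Coordinates are patient DICOM LPS in millimetres
#' (x = left, y = posterior, z = superior). Every contour must be a simple
#' closed polygon; the closing vertex is implicit (do not repeat the first
#' point).
#'
#' @param structure Character vector of structure names.
#' @param contour Integer contour ids (unique per planar polygon).
#' @param z,x,y Numeric coordinates in mm.
#' @return A tibble of class `contour_tbl`.
#' @examples
#' sq <- contour_tbl("box", 1L, z = 0, x = c(-10, 10, 10, -10),
#'                   y = c(-10, -10, 10, 10))
#' @export
contour_tbl <- function(structure, contour, z, x, y) {
  out <- tibble(structure = as.character(structure),
                contour = as.integer(contour),
                z = as.numeric(z), x = as.numeric(x), y = as.numeric(y))
  validate_contour_tbl(out)
}

validate_contour_tbl <- function(tbl) {
  need <- c("structure", "contour", "z", "x", "y")
  if (!all(need %in% names(tbl))) {
    abort(paste("contour table must have columns:", paste(need, collapse = ", ")),
          class = "subarcvmat_contour_error")
  }
  if (nrow(tbl) == 0L) {
    abort("contour table is empty", class = "subarcvmat_contour_error")
  }
  if (!all(is.finite(tbl$z)) || !all(is.finite(tbl$x)) || !all(is.finite(tbl$y))) {
    abort("contour coordinates must be finite", class = "subarcvmat_contour_error")
  }
  class(tbl) <- unique(c("contour_tbl", class(tbl)))
  tbl
}

#' @export
structure_names <- function(contours) unique(contours$structure)

#' Spherical and ellipsoidal structures as contour stacks
#'
#' Discretizes a sphere (or axis-aligned ellipsoid) into planar contours at
#' regular slice spacing, the way structures arrive from a planning CT.
#'
#' @param name Structure name.
#' @param center 3-vector, mm (LPS).
#' @param radius Sphere radius, mm.
#' @param semiaxes 3-vector of ellipsoid semi-axes (x, y, z), mm.
#' @param z_spacing Slice spacing, mm (default 1, CT-like).
#' @param n_vertices Polygon vertices per contour.
#' @return A `contour_tbl`.
#' @export
sphere_structure <- function(name, center, radius, z_spacing = 1,
                             n_vertices = 64L) {
  ellipsoid_structure(name, center, rep(radius, 3), z_spacing, n_vertices)
}

#' @rdname sphere_structure
#' @export
ellipsoid_structure <- function(name, center, semiaxes, z_spacing = 1,
                                n_vertices = 64L) {
  stopifnot(length(center) == 3, length(semiaxes) == 3, all(semiaxes > 0),
            z_spacing > 0)
  cz <- center[3]; c_ax <- semiaxes[3]
  # slices on the global z grid (multiples of z_spacing) inside the solid
  z_lo <- ceiling((cz - c_ax) / z_spacing) * z_spacing
  z_hi <- floor((cz + c_ax) / z_spacing) * z_spacing
  zs <- seq(z_lo, z_hi, by = z_spacing)
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  rows <- lapply(seq_along(zs), function(i) {
    zz <- zs[i]
    f2 <- 1 - ((zz - cz) / c_ax)^2
    if (f2 <= 1e-9) return(NULL)
    f <- sqrt(f2)
    tibble(structure = name, contour = i,
           z = zz,
           x = center[1] + semiaxes[1] * f * cos(ang),
           y = center[2] + semiaxes[2] * f * sin(ang))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    abort("structure too thin for the slice spacing: no contours generated",
          class = "subarcvmat_contour_error")
  }
  validate_contour_tbl(out)
}

# shoelace polygon area (mm^2), sign dropped
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
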
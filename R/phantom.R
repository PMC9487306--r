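#' Synthetic multi-lesion head phantom
#'
#' Generates a spherical head shell with 2-5 non-overlapping spherical (or
#' ellipsoidal) target lesions, emulating a multiple-brain-metastases case:
#' lesion volumes of a few to ~18 cc and inter-lesion distances of a few to
#' ~18 cm. Lesions are placed uniformly inside the head with a safety margin
#' from the skull and a minimum surface-to-surface gap, by rejection
#' sampling. Fully reproducible under `seed`.
#'
#' @param n_lesions Number of lesions (2-5); sampled if `NULL`.
#' @param volumes_cc Lesion volumes, cc; sampled uniformly in `[2.2, 18]` if
#'   `NULL`.
#' @param centers Optional n x 3 matrix of lesion centers, mm (skips
#'   placement sampling).
#' @param head_radius Head-shell radius, mm (default 90).
#' @param min_gap Minimum lesion surface-to-surface gap, mm (default 20).
#' @param shape `"sphere"` or `"ellipsoid"` (random axis ratios 0.7-1.3).
#' @param seed Integer seed; all randomness flows through it.
#' @param z_spacing Contour slice spacing, mm.
#' @param max_tries Placement retries before giving up.
#' @return An object of class `phantom`: `contours` (targets + BODY),
#'   `lesions` tibble (center, radius, volume), `head_radius`, `seed`.
#' @export
phantom_case <- function(n_lesions = NULL, volumes_cc = NULL, centers = NULL,
                         head_radius = 90, min_gap = 20,
                         shape = c("sphere", "ellipsoid"), seed = NULL,
                         z_spacing = 1, max_tries = 500L) {
  shape <- match.arg(shape)
  build <- function() {
    n <- n_lesions %||% sample(2:5, 1L)
    vols <- volumes_cc %||% runif(n, 2.2, 18)
    if (length(vols) != n) abort("volumes_cc length must match n_lesions",
                                 class = "subarcvmat_config_error")
    if (any(vols <= 0)) abort("lesion volumes must be positive",
                              class = "subarcvmat_config_error")
    radii <- (3 * vols * 1000 / (4 * pi))^(1 / 3)
    if (any(radii + 8 >= head_radius)) {
      abort("lesion too large for the head shell", class = "subarcvmat_config_error")
    }
    ctr <- centers
    if (is.null(ctr)) {
      ctr <- place_lesions(radii, head_radius, min_gap, max_tries)
    } else {
      ctr <- matrix(as.numeric(ctr), ncol = 3L)
      if (nrow(ctr) != n) abort("centers must be n_lesions x 3",
                                class = "subarcvmat_config_error")
    }
    ratios <- if (shape == "ellipsoid") {
      matrix(runif(3L * n, 0.7, 1.3), ncol = 3L)
    } else matrix(1, n, 3L)
    # rescale so the requested volume is preserved: prod(semi) = r^3
    ratios <- ratios / apply(ratios, 1L, function(r) prod(r)^(1 / 3))
    lesions <- tibble(lesion = paste0("PTV", seq_len(n)),
                      volume_cc = vols, radius_mm = radii,
                      cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
                      sx = radii * ratios[, 1], sy = radii * ratios[, 2],
                      sz = radii * ratios[, 3])
    contours <- bind_rows(
      lapply(seq_len(n), function(i) {
        ellipsoid_structure(lesions$lesion[i], ctr[i, ],
                            c(lesions$sx[i], lesions$sy[i], lesions$sz[i]),
                            z_spacing = z_spacing)
      }),
      sphere_structure("BODY", c(0, 0, 0), head_radius, z_spacing = 5)
    )
    structure(list(contours = validate_contour_tbl(contours),
                   lesions = lesions, head_radius = head_radius, seed = seed),
              class = "phantom")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

place_lesions <- function(radii, head_radius, min_gap, max_tries) {
  n <- length(radii)
  for (try in seq_len(max_tries)) {
    ctr <- t(vapply(radii, function(r) {
      rmax <- head_radius - r - 8
      repeat {
        p <- runif(3L, -rmax, rmax)
        if (sum(p^2) <= rmax^2) return(p)
      }
    }, numeric(3L)))
    if (n == 1L) return(ctr)
    d <- as.matrix(dist(ctr))
    need <- outer(radii, radii, `+`) + min_gap
    diag(d) <- Inf
    if (all(d >= need)) return(ctr)
  }
  abort("could not place non-overlapping lesions; reduce volumes or min_gap",
        class = "subarcvmat_config_error")
}

#' @rdname phantom_case
#' @param phantom A `phantom`.
#' @export
target_contours <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  validate_contour_tbl(phantom$contours[phantom$contours$structure != "BODY", ])
}

#' Per-axis maximum inter-lesion distance
#'
#' For every lesion pair, the distance between the outermost bounding-box
#' extremes along each patient axis; the per-axis maximum over pairs is the
#' cohort's R_max statistic.
#'
#' @param phantom A `phantom` (needs >= 2 lesions).
#' @return A tibble: `axis` (`x`, `y`, `z`), `r_max_cm`.
#' @export
phantom_rmax <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  L <- phantom$lesions
  if (nrow(L) < 2L) abort("R_max needs at least two lesions",
                          class = "subarcvmat_config_error")
  ax <- list(x = c("cx", "sx"), y = c("cy", "sy"), z = c("cz", "sz"))
  bind_rows(imap(ax, function(cols, name) {
    lo <- L[[cols[1]]] - L[[cols[2]]]
    hi <- L[[cols[1]]] + L[[cols[2]]]
    pairs <- utils::combn(nrow(L), 2L)
    span <- apply(pairs, 2L, function(p) {
      max(hi[p[1]], hi[p[2]]) - min(lo[p[1]], lo[p[2]])
    })
    tibble(axis = name, r_max_cm = max(span) / 10)
  }))
}

#' Synthetic dose distribution for a phantom
#'
#' Prescription dose inside every lesion, Gaussian falloff with distance to
#' the lesion surface outside, voxel-wise maximum where lesions interact: a
#' radiosurgery-like dose substrate for exercising the DVH indices. For
#' ellipsoidal lesions the surface distance is approximated by the scaled
#' radial distance.
#'
#' @param phantom A `phantom`.
#' @param dp Prescription dose, Gy (default 30; the 30 Gy / 5 fraction
#'   regimen).
#' @param sigma Falloff scale, mm (default 5).
#' @param spacing Dose-grid voxel size, mm.
#' @param pad Grid padding beyond the lesion bounding box, mm.
#' @return A [dose_grid()].
#' @export
make_synthetic_dose <- function(phantom, dp = 30, sigma = 5, spacing = 1,
                                pad = 25) {
  stopifnot(inherits(phantom, "phantom"), sigma > 0, dp > 0)
  L <- phantom$lesions
  lo <- floor(c(min(L$cx - L$sx), min(L$cy - L$sy), min(L$cz - L$sz)) - pad)
  hi <- ceiling(c(max(L$cx + L$sx), max(L$cy + L$sy), max(L$cz + L$sz)) + pad)
  xs <- seq(lo[1], hi[1], by = spacing)
  ys <- seq(lo[2], hi[2], by = spacing)
  zs <- seq(lo[3], hi[3], by = spacing)
  dims <- c(length(xs), length(ys), length(zs))
  dose <- array(0, dims)
  gx <- rep(xs, times = dims[2] * dims[3])
  gy <- rep(rep(ys, each = dims[1]), times = dims[3])
  gz <- rep(zs, each = dims[1] * dims[2])
  for (i in seq_len(nrow(L))) {
    t <- sqrt(((gx - L$cx[i]) / L$sx[i])^2 + ((gy - L$cy[i]) / L$sy[i])^2 +
                ((gz - L$cz[i]) / L$sz[i])^2)
    rbar <- (L$sx[i] * L$sy[i] * L$sz[i])^(1 / 3)
    d_surf <- (t - 1) * rbar          # exact for spheres
    di <- ifelse(d_surf <= 0, dp, dp * exp(-d_surf^2 / (2 * sigma^2)))
    dose <- pmax(dose, array(di, dims))
  }
  dose_grid(dose, origin = lo, spacing = spacing)
}

#' Bundled reference cohort table
#'
#' Characteristics of a 20-case multiple-brain-metastases cohort (2-5 lesions
#' per case): per-lesion volumes, total target volume, and the per-axis
#' maximum inter-lesion distance R_max. Shipped as plain CSV in
#' `inst/extdata/cohort_characteristics.csv`.
#'
#' @return A tibble with one row per case; `lesion_volumes_cc` is a list
#'   column.
#' @export
cohort_table <- function() {
  path <- system.file("extdata", "cohort_characteristics.csv",
                      package = "subarcvmat", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- as_tibble(raw)
  out$lesion_volumes_cc <- lapply(strsplit(raw$lesion_volumes_cc, ";"), as.numeric)
  out
}
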